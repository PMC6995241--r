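## Independent reference implementations used as oracles. These deliberately
## share no code with the package internals they check.

## Benjamini-Hochberg by the definition: on the sorted scale
## adj_(i) = min(1, min_{j >= i} p_(j) * m / j), mapped back to input order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  s <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(s[i:m] * m / (i:m)))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

## Trapezoidal area under the (FPR, TPR) curve swept over all thresholds
## "predict tumor when value >= t".
auc_trapezoid <- function(values, labels) {
  thr <- sort(unique(values), decreasing = TRUE)
  n1 <- sum(labels == "tumor")
  n0 <- sum(labels == "normal")
  tpr <- c(0, vapply(thr, function(t) sum(values >= t & labels == "tumor") / n1,
                     numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(values >= t & labels == "normal") / n0,
                     numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

## Central finite differences of the training loss with respect to every
## parameter of the model, via the R-side forward pass only.
fd_gradient <- function(model, x, y, h = 1e-5) {
  grad_w <- lapply(model$weights, function(w) array(NA_real_, dim(w)))
  grad_b <- lapply(model$biases, function(b) rep(NA_real_, length(b)))
  for (l in seq_along(model$weights)) {
    for (k in seq_along(model$weights[[l]])) {
      up <- model; up$weights[[l]][k] <- up$weights[[l]][k] + h
      dn <- model; dn$weights[[l]][k] <- dn$weights[[l]][k] - h
      grad_w[[l]][k] <- (mlp_loss(up, x, y) - mlp_loss(dn, x, y)) / (2 * h)
    }
    for (k in seq_along(model$biases[[l]])) {
      up <- model; up$biases[[l]][k] <- up$biases[[l]][k] + h
      dn <- model; dn$biases[[l]][k] <- dn$biases[[l]][k] - h
      grad_b[[l]][k] <- (mlp_loss(up, x, y) - mlp_loss(dn, x, y)) / (2 * h)
    }
  }
  list(grad_weights = grad_w, grad_biases = grad_b)
}

## Naive per-class precision/recall/F1 from first principles (independent of
## the package's confusion-matrix route).
report_brute <- function(true, pred) {
  out <- lapply(c("normal", "tumor"), function(cls) {
    tp <- sum(true == cls & pred == cls)
    prec <- if (sum(pred == cls) == 0) 0 else tp / sum(pred == cls)
    rec <- if (sum(true == cls) == 0) 0 else tp / sum(true == cls)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1, support = sum(true == cls))
  })
  do.call(rbind, out)
}

## small deterministic study fixture
tiny_study <- function(values, labels, genes = NULL, id = "tiny") {
  m <- matrix(values, nrow = if (is.null(genes)) 1 else length(genes),
              byrow = TRUE)
  if (is.null(genes)) genes <- "g1"
  rownames(m) <- genes
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  expression_study(m, labels, study_id = id)
}

## random two-class study with independent N(0,1) genes (no signal)
random_study <- function(n_genes, n_tumor, n_normal, seed, id = "rand") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n_tumor + n_normal)), nrow = n_genes)
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  expression_study(m, rep(c("tumor", "normal"), c(n_tumor, n_normal)),
                   study_id = id)
}

## a fabricated called DEG table
fake_deg_table <- function(genes, calls) {
  data.frame(gene = genes, log2fc = ifelse(calls == "up", 2,
                                           ifelse(calls == "down", -2, 0)),
             t_stat = 0, p_value = 0.01, adj_p = 0.01, call = calls,
             stringsAsFactors = FALSE)
}
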