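#' Feed-forward network architecture
#'
#' @param hidden_sizes integer vector of hidden-layer widths (length 1 or 2).
#' @param input_size number of input nodes (one per marker gene).
#' @param output_size number of output nodes (normal, tumor).
#' @return list of class `architecture`.
#' @export
architecture <- function(hidden_sizes, input_size = 5L, output_size = 2L) {
  stopifnot(
    "hidden_sizes must have length 1 or 2" = length(hidden_sizes) %in% 1:2,
    "hidden_sizes must be positive integers" =
      all(hidden_sizes >= 1 & hidden_sizes == round(hidden_sizes)),
    is_count(input_size), is_count(output_size)
  )
  structure(list(input_size = as.integer(input_size),
                 hidden_sizes = as.integer(hidden_sizes),
                 output_size = as.integer(output_size)),
            class = "architecture")
}

arch_label <- function(arch) paste(arch$hidden_sizes, collapse = "x")

#' Enumerate the hidden-layer architecture grid
#'
#' All one-layer architectures in ascending node order, followed by all
#' two-layer architectures in lexicographic order. The default grid
#' (2..10 nodes, up to 2 layers) has 9 + 81 = 90 members.
#'
#' @param node_range inclusive range of hidden-layer widths.
#' @param max_layers 1 or 2 hidden layers.
#' @param input_size,output_size passed to [architecture()].
#' @return list of [architecture()] objects in deterministic order.
#' @export
enumerate_architectures <- function(node_range = 2:10, max_layers = 2L,
                                    input_size = 5L, output_size = 2L) {
  stopifnot(length(node_range) >= 1, max_layers %in% 1:2)
  node_range <- as.integer(sort(unique(node_range)))
  out <- lapply(node_range, function(h) {
    architecture(h, input_size, output_size)
  })
  if (max_layers >= 2L) {
    for (h1 in node_range) {
      for (h2 in node_range) {
        out[[length(out) + 1L]] <- architecture(c(h1, h2), input_size, output_size)
      }
    }
  }
  out
}

#' Initialize a network with uniform weights and unit biases
#'
#' Weights are i.i.d. uniform on `[-1, 1]`; every bias is 1. Weight matrix
#' for a layer mapping `a` inputs to `b` outputs has shape `a x b`.
#' Deterministic given the seed.
#'
#' @param arch an [architecture()].
#' @param seed integer seed.
#' @return object of class `mlp_model`: `architecture`, `weights` (list of
#'   matrices), `biases` (list of vectors), `activation`
#'   (`hidden = "relu"`, `output = "softmax"`), `markers` (filled by the
#'   pipeline with the gene order the model expects).
#' @export
init_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "architecture"))
  set.seed(seed)
  sizes <- c(arch$input_size, arch$hidden_sizes, arch$output_size)
  L <- length(sizes) - 1L
  weights <- vector("list", L)
  biases <- vector("list", L)
  for (l in seq_len(L)) {
    weights[[l]] <- matrix(runif(sizes[l] * sizes[l + 1L], -1, 1),
                           nrow = sizes[l], ncol = sizes[l + 1L])
    biases[[l]] <- rep(1, sizes[l + 1L])
  }
  structure(list(architecture = arch, weights = weights, biases = biases,
                 activation = c(hidden = "relu", output = "softmax"),
                 markers = NULL),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  a <- x$architecture
  cat(sprintf("mlp_model: %d-%s-%d (relu hidden, softmax output)%s\n",
              a$input_size, paste(a$hidden_sizes, collapse = "-"),
              a$output_size,
              if (is.null(x$markers)) "" else
                paste0("; markers: ", paste(x$markers, collapse = ", "))))
  invisible(x)
}

#' Forward pass: class probabilities for a batch of samples
#'
#' Hidden layers apply `relu(x W + b)`; the output layer applies a
#' numerically stable softmax. Rows sum to 1 with components in (0, 1).
#' Implemented in plain vectorized R, independently of the compiled
#' training path.
#'
#' @param model an [init_model()] / trained `mlp_model`.
#' @param x numeric matrix (samples x input_size) or a single input vector.
#'   Rescaled expression is expected in `[0, 1]`; values outside trigger a
#'   warning.
#' @return matrix (samples x 2) of class probabilities, columns
#'   `normal`, `tumor`.
#' @export
mlp_forward <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$architecture$input_size) {
    stopf("input has %d columns; model expects %d",
          ncol(x), model$architecture$input_size)
  }
  if (any(x < 0 | x > 1)) warnf("inputs outside [0, 1]; expected rescaled expression")
  L <- length(model$weights)
  a <- x
  for (l in seq_len(L - 1L)) {
    z <- a %*% model$weights[[l]]
    z <- sweep(z, 2, model$biases[[l]], "+")
    a <- pmax(z, 0)
  }
  z <- a %*% model$weights[[L]]
  z <- sweep(z, 2, model$biases[[L]], "+")
  z <- z - apply(z, 1, max)  # shift-invariant softmax
  e <- exp(z)
  p <- e / rowSums(e)
  colnames(p) <- class_levels()
  rownames(p) <- rownames(x)
  p
}

## mean categorical cross-entropy of the R-side forward pass; the
## finite-difference gradient oracle in the tests perturbs parameters
## through this function, independently of the compiled backprop.
mlp_loss <- function(model, x, y) {
  p <- mlp_forward(model, x)
  -mean(log(p[cbind(seq_len(nrow(p)), y + 1L)]))
}

## analytic gradient of the mean cross-entropy for one batch (compiled)
mlp_gradient <- function(model, x, y) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  cpp_mlp_gradient(x, as.integer(y), model$weights, model$biases)
}

labels_to_y <- function(labels) as.integer(check_labels(labels) == "tumor")

#' Train a network by mini-batch stochastic gradient descent
#'
#' Minimizes the mean categorical cross-entropy with plain SGD: `epochs`
#' full passes, samples shuffled each epoch, fixed learning rate. The
#' per-epoch shuffles are drawn from R's RNG under `seed`, so a run is
#' exactly reproducible; the compiled update loop itself is RNG-free.
#'
#' @param model an initialized `mlp_model`.
#' @param x training matrix (samples x input_size), values in `[0, 1]`.
#' @param labels per-sample classes, or an integer 0/1 vector (1 = tumor).
#' @param config a [run_config()] supplying `learning_rate`, `epochs`,
#'   `batch_size`.
#' @param seed integer seed for the epoch shuffles.
#' @return list with `model` (trained) and `record` (class `train_record`):
#'   `seed`, `loss` (per-epoch mean cross-entropy), `train_accuracy`.
#' @export
train_mlp <- function(model, x, labels, config = run_config(), seed = config$seed) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.null(dim(x))) stopf("'x' must be a samples-by-features matrix")
  y <- if (is.numeric(labels)) as.integer(labels) else labels_to_y(labels)
  if (length(y) != nrow(x)) stopf("%d labels for %d samples", length(y), nrow(x))
  if (ncol(x) != model$architecture$input_size) {
    stopf("input has %d features; model expects %d",
          ncol(x), model$architecture$input_size)
  }
  n <- nrow(x)
  set.seed(seed)
  perms <- vapply(seq_len(config$epochs), function(e) sample.int(n), integer(n))
  fit <- cpp_train_mlp(x, y, model$weights, model$biases,
                       t(perms), config$learning_rate, config$batch_size)
  model$weights <- fit$weights
  model$biases <- lapply(fit$biases, as.numeric)
  p <- mlp_forward(model, x)
  acc <- mean((p[, 2] > p[, 1]) == (y == 1L))
  record <- structure(list(seed = as.integer(seed),
                           loss = as.numeric(fit$losses),
                           train_accuracy = acc),
                      class = "train_record")
  list(model = model, record = record)
}

#' Exhaustive architecture search with repeated training
#'
#' Splits the merged samples into train/test (stratified by class, using
#' the config seed), then trains every architecture of the grid
#' `repetitions` times from independent derived seeds
#' (`seed_hash(config$seed, arch_index, rep)` feeds both the weight
#' initialization and the epoch shuffles). Architectures are ranked by
#' mean training accuracy; within the winning architecture the single run
#' with the highest training accuracy is returned as the best-trained
#' network. Ties go to the earlier architecture / repetition.
#'
#' @param data a [rescaled_matrix()] restricted to the marker genes, or a
#'   samples-by-features numeric matrix (then `labels` is required).
#' @param config a [run_config()].
#' @param labels per-sample classes when `data` is a plain matrix.
#' @param verbose log progress.
#' @return object of class `arch_search`: `best_architecture`, `best_model`
#'   (with `markers` attached when known), `best_record`, `table`
#'   (per-architecture mean/sd/best train accuracy), `split` (train/test
#'   indices), `train_accuracy`, `test_accuracy` (of the best model).
#' @export
architecture_search <- function(data, config = run_config(), labels = NULL,
                                verbose = FALSE) {
  t0 <- as.numeric(proc.time()[["elapsed"]])
  if (inherits(data, "rescaled_matrix")) {
    markers <- rownames(data$values)
    x <- t(data$values)
    labels <- data$labels
  } else {
    markers <- colnames(data)
    x <- data
    if (is.null(labels)) stopf("labels required when 'data' is a matrix")
  }
  y <- labels_to_y(labels)
  n <- nrow(x)

  set.seed(config$seed)
  test_idx <- unlist(lapply(c(0L, 1L), function(cls) {
    idx <- which(y == cls)
    sample(idx, round(config$split_fraction * length(idx)))
  }))
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(unique(y[train_idx])) < 2L) stopf("training split lost a class")

  archs <- enumerate_architectures(config$hidden_node_range,
                                   config$max_hidden_layers,
                                   input_size = ncol(x))
  n_arch <- length(archs)
  acc <- matrix(NA_real_, nrow = n_arch, ncol = config$repetitions)
  best_run <- vector("list", n_arch)
  for (a in seq_len(n_arch)) {
    for (r in seq_len(config$repetitions)) {
      s <- seed_hash(config$seed, a, r)
      model <- init_model(archs[[a]], seed = s)
      fit <- train_mlp(model, x[train_idx, , drop = FALSE], y[train_idx],
                       config, seed = s)
      acc[a, r] <- fit$record$train_accuracy
      if (is.null(best_run[[a]]) ||
          fit$record$train_accuracy > best_run[[a]]$record$train_accuracy) {
        best_run[[a]] <- fit
      }
    }
    log_stage(verbose, "search", "arch %s: mean train acc %.3f",
              arch_label(archs[[a]]), mean(acc[a, ]))
  }

  mean_acc <- rowMeans(acc)
  sd_acc <- apply(acc, 1, sd)
  winner <- which.max(mean_acc)  # first max on ties
  best <- best_run[[winner]]
  best$model$markers <- markers

  p_test <- mlp_forward(best$model, x[test_idx, , drop = FALSE])
  test_acc <- mean((p_test[, 2] > p_test[, 1]) == (y[test_idx] == 1L))

  table <- data.frame(
    arch = vapply(archs, arch_label, character(1)),
    n_layers = vapply(archs, function(a) length(a$hidden_sizes), integer(1)),
    nodes1 = vapply(archs, function(a) a$hidden_sizes[1], integer(1)),
    nodes2 = vapply(archs, function(a)
      if (length(a$hidden_sizes) > 1) a$hidden_sizes[2] else NA_integer_,
      integer(1)),
    mean_train_acc = mean_acc, sd_train_acc = sd_acc,
    best_train_acc = apply(acc, 1, max),
    stringsAsFactors = FALSE
  )
  log_stage(verbose, "search",
            "%d architectures x %d repetitions; winner %s (mean %.3f, test %.3f)",
            n_arch, config$repetitions, table$arch[winner],
            mean_acc[winner], test_acc, t0 = t0)

  structure(list(best_architecture = archs[[winner]],
                 best_model = best$model, best_record = best$record,
                 table = table, winner_index = winner,
                 split = list(train = train_idx, test = test_idx),
                 train_accuracy = best$record$train_accuracy,
                 test_accuracy = test_acc),
            class = "arch_search")
}

#' @export
print.arch_search <- function(x, ...) {
  cat(sprintf("arch_search: %d architectures; winner %s (mean train %.3f, best train %.3f, internal test %.3f)\n",
              nrow(x$table), x$table$arch[x$winner_index],
              x$table$mean_train_acc[x$winner_index],
              x$train_accuracy, x$test_accuracy))
  invisible(x)
}

#' Predict sample classes from rescaled marker expression
#'
#' @param object a trained `mlp_model`.
#' @param newdata a [rescaled_matrix()] covering the model's marker genes,
#'   or a samples-by-markers numeric matrix in the training gene order.
#' @param ... unused.
#' @return data.frame `sample`, `label`, `probability` (of the predicted
#'   class), `p_normal`, `p_tumor`. Exact probability ties go to "normal".
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  if (inherits(newdata, "rescaled_matrix")) {
    if (is.null(object$markers)) {
      stopf("model carries no marker list; pass a plain matrix in training order")
    }
    missing <- setdiff(object$markers, rownames(newdata$values))
    if (length(missing) > 0L) {
      stopf("marker gene(s) missing from input: %s", paste(missing, collapse = ", "))
    }
    x <- t(newdata$values[object$markers, , drop = FALSE])
  } else {
    x <- newdata
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  }
  p <- mlp_forward(object, x)
  tumor <- p[, 2] > p[, 1]  # tie -> normal
  data.frame(
    sample = if (is.null(rownames(x))) sprintf("sample%03d", seq_len(nrow(x)))
             else rownames(x),
    label = ifelse(tumor, "tumor", "normal"),
    probability = ifelse(tumor, p[, 2], p[, 1]),
    p_normal = p[, 1], p_tumor = p[, 2],
    stringsAsFactors = FALSE, row.names = NULL
  )
}
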