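## Internal helpers shared across modules.

#' Derive a child seed from a base seed and up to two indices
#'
#' Deterministic, injective over `0 <= a, b < 31` blocks per base seed:
#' `h = ((seed mod M) * 31 + a) * 31 + b mod M` with `M = 2^31 - 1`.
#' All intermediates stay below 2^53, so the arithmetic is exact in doubles.
#' Used so that any single training run (architecture `a`, repetition `b`)
#' can be reproduced in isolation from the pipeline seed.
#'
#' @param seed integer base seed.
#' @param a,b non-negative integer indices.
#' @return a single integer seed.
#' @export
seed_hash <- function(seed, a = 0L, b = 0L) {
  M <- 2147483647
  h <- as.numeric(seed) %% M
  h <- (h * 31 + as.numeric(a)) %% M
  h <- (h * 31 + as.numeric(b)) %% M
  as.integer(h)
}

## full-precision number -> text (round-trips exactly through as.numeric)
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## stage logging: one line with dims and elapsed time (console only, never
## written into report artifacts so re-runs stay byte-identical)
log_stage <- function(verbose, stage, fmt = "", ..., t0 = NULL) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  msg <- if (nzchar(fmt)) sprintf(fmt, ...) else ""
  if (!is.null(t0)) {
    msg <- sprintf("%s [%.2fs]", msg, as.numeric(proc.time()[["elapsed"]]) - t0)
  }
  message(sprintf("[%s] %s", stage, msg))
  invisible(NULL)
}

## row-wise mean and (n-1) variance for a numeric matrix
row_var <- function(x) {
  n <- ncol(x)
  if (n < 2L) stopf("variance needs at least 2 columns, got %d", n)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

class_levels <- function() c("normal", "tumor")

check_labels <- function(labels, what = "labels") {
  bad <- setdiff(unique(as.character(labels)), class_levels())
  if (length(bad) > 0L) {
    stopf("%s contain unknown class token(s): %s (expected 'normal'/'tumor')",
          what, paste(bad, collapse = ", "))
  }
  as.character(labels)
}
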