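#' Classification head configuration
#'
#' A dense head over the fused embedding: hidden layers (default 512 then
#' 128 units) each followed by batch normalization and ReLU, dropout after the
#' first hidden layer, then a linear output layer of `num_classes` logits
#' passed through the sparse entmax-alpha transform. No nonlinearity is
#' applied to the logit layer (a ReLU there would forbid negative logits).
#'
#' @param hidden_units integer vector of hidden widths (default `c(512, 128)`).
#' @param dropout_after_first dropout rate after the first hidden layer
#'   (default 0.3; inactive in eval mode).
#' @param num_classes number of tumor classes C (default 3).
#' @param alpha entmax exponent in \[1, 2\]; 1 is softmax, 2 is sparsemax
#'   (default 1.5).
#' @param bisect_iters bisection iterations for interior alpha (default 50).
#' @param seed RNG seed for Xavier-uniform initialization.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(hidden_units = c(512L, 128L),
                              dropout_after_first = 0.3, num_classes = 3L,
                              alpha = 1.5, bisect_iters = 50L, seed = 42L) {
  assert_that(length(hidden_units) >= 1 && all(hidden_units >= 1),
              "hidden_units must be non-empty positive integers")
  assert_that(alpha >= 1 && alpha <= 2, "alpha must lie in [1, 2]")
  assert_that(num_classes >= 2, "need at least two classes")
  structure(list(hidden_units = as.integer(hidden_units),
                 dropout_after_first = dropout_after_first,
                 num_classes = as.integer(num_classes), alpha = alpha,
                 bisect_iters = as.integer(bisect_iters),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Initialize the classification head
#'
#' @param cfg a [classifier_config].
#' @param in_dim dimension of the fused embedding entering the head.
#' @return An object of class `classifier_head`.
#' @export
init_classifier_head <- function(cfg = classifier_config(), in_dim = 256L) {
  with_seed(cfg$seed, {
    dims <- c(in_dim, cfg$hidden_units)
    hidden <- lapply(seq_along(cfg$hidden_units), function(i) {
      list(W = xavier_uniform(dims[i + 1], dims[i]),
           b = rep(0, dims[i + 1]),
           bn = list(gamma = rep(1, dims[i + 1]), beta = rep(0, dims[i + 1]),
                     mean = rep(0, dims[i + 1]), var = rep(1, dims[i + 1])))
    })
    out <- list(W = xavier_uniform(cfg$num_classes, utils::tail(dims, 1)),
                b = rep(0, cfg$num_classes))
    structure(list(cfg = cfg, hidden = hidden, out = out),
              class = "classifier_head")
  })
}

#' Forward pass of the classification head
#'
#' Maps a fused embedding to raw class logits. Hidden layers apply affine ->
#' batch-norm (running statistics in eval mode) -> ReLU; dropout after the
#' first hidden layer is active only in training mode; the output layer is
#' purely affine.
#'
#' @param fused a [fused_embedding] or plain numeric vector.
#' @param head a [init_classifier_head] model.
#' @param training logical; enables dropout.
#' @return Numeric vector of `num_classes` logits.
#' @export
head_forward <- function(fused, head, training = FALSE) {
  x <- if (inherits(fused, "fused_embedding")) fused$vector else as.numeric(fused)
  assert_that(length(x) == ncol(head$hidden[[1]]$W),
              sprintf("fused vector length %d does not match head input (%d)",
                      length(x), ncol(head$hidden[[1]]$W)),
              "gliofuse_shape_error")
  for (i in seq_along(head$hidden)) {
    lay <- head$hidden[[i]]
    x <- as.numeric(lay$W %*% x + lay$b)
    x <- (x - lay$bn$mean) / sqrt(lay$bn$var + 1e-5) * lay$bn$gamma + lay$bn$beta
    x <- relu(x)
    if (i == 1 && training && head$cfg$dropout_after_first > 0) {
      keep <- stats::runif(length(x)) >= head$cfg$dropout_after_first
      x <- x * keep / (1 - head$cfg$dropout_after_first)
    }
  }
  as.numeric(head$out$W %*% x + head$out$b)
}

#' Sparse class probabilities
#'
#' @param probs length-C probability vector (non-negative, sums to 1).
#' @return An object of class `class_probabilities` with fields `probs` and
#'   `support` (indices of classes with strictly positive probability).
#' @export
class_probabilities <- function(probs) {
  assert_that(all(probs >= 0) && abs(sum(probs) - 1) <= 1e-6,
              "probabilities must be non-negative and sum to 1",
              "gliofuse_contract_error")
  structure(list(probs = as.numeric(probs), support = which(probs > 0)),
            class = "class_probabilities")
}

#' @export
print.class_probabilities <- function(x, ...) {
  cat(sprintf("<class_probabilities> (%s)  support %d/%d\n",
              paste(format(x$probs, digits = 4), collapse = ", "),
              length(x$support), length(x$probs)))
  invisible(x)
}

# Exact sparsemax (Euclidean projection onto the simplex) via sorting.
sparsemax_exact <- function(z) {
  zs <- sort(z, decreasing = TRUE)
  css <- cumsum(zs)
  k <- max(which(1 + seq_along(zs) * zs > css))
  tau <- (css[k] - 1) / k
  pmax(z - tau, 0)
}

#' Entmax transform by threshold bisection
#'
#' Solves for the normalization threshold tau such that
#' `sum(((alpha-1) z - tau)_+^(1/(alpha-1))) = 1` by bisection on the bracket
#' `[max((alpha-1)z) - 1, max((alpha-1)z)]`, then renormalizes the residual
#' (below 1e-8 after the default 50 iterations) without disturbing the exact
#' zeros. Valid for any alpha in (1, 2].
#'
#' @param z numeric logit vector (finite).
#' @param alpha entmax exponent in (1, 2].
#' @param iters bisection iterations.
#' @return Numeric probability vector with exact zeros off-support.
#' @export
entmax_bisect <- function(z, alpha = 1.5, iters = 50L) {
  t <- (alpha - 1) * z
  lo <- max(t) - 1
  hi <- max(t)
  expo <- 1 / (alpha - 1)
  for (i in seq_len(iters)) {
    tau <- (lo + hi) / 2
    s <- sum(pmax(t - tau, 0)^expo)
    if (s >= 1) lo <- tau else hi <- tau
    if (abs(s - 1) <= 1e-12) break
  }
  tau <- (lo + hi) / 2
  p <- pmax(t - tau, 0)^expo
  p / sum(p)
}

#' Entmax-alpha sparse probability transform
#'
#' Maps logits to a probability vector whose sparsity is controlled by
#' `alpha`: `alpha = 1` is the ordinary softmax (dense), `alpha = 2` is
#' sparsemax (computed exactly by sorting), and interior values interpolate
#' (computed by [entmax_bisect]), assigning exact zeros to unlikely classes.
#' Invariant to adding a constant to all logits.
#'
#' @param z numeric logit vector (finite).
#' @param alpha exponent in \[1, 2\] (default 1.5).
#' @param bisect_iters bisection iterations for interior alpha.
#' @return A [class_probabilities].
#' @export
entmax <- function(z, alpha = 1.5, bisect_iters = 50L) {
  assert_that(all(is.finite(z)), "logits must be finite",
              "gliofuse_value_error")
  assert_that(alpha >= 1 && alpha <= 2, "alpha must lie in [1, 2]")
  p <- if (alpha == 1) softmax_vec(z)
       else if (alpha == 2) sparsemax_exact(z)
       else entmax_bisect(z, alpha, bisect_iters)
  class_probabilities(p)
}

# Support-restricted Jacobian helper: for p = entmax_alpha(z) the Jacobian is
# diag(s) - s s^T / sum(s) with s_i = p_i^(2 - alpha) on the support and 0
# elsewhere (reduces to the softmax Jacobian at alpha = 1). Used by the
# training loop to differentiate the NLL through entmax.
entmax_grad_s <- function(p, alpha) {
  s <- numeric(length(p))
  sup <- p > 0
  s[sup] <- p[sup]^(2 - alpha)
  s
}

#' Class-weighted negative log-likelihood on entmax probabilities
#'
#' The per-sample contribution is `w[y] * (-log(max(p[y], eps)))` with
#' `eps = 1e-8`; the clamp keeps the loss finite when entmax assigns the true
#' class an exact zero. The reported loss is the mean over samples, so a
#' class's total contribution is linear in its weight.
#'
#' @param x either a samples x C matrix of probabilities (rows summing to 1),
#'   a matrix of logits (transformed with entmax-`alpha` per row), a single
#'   [class_probabilities], or a numeric vector (treated as one sample).
#' @param labels integer class labels in `1..C`.
#' @param class_weights optional length-C weights (default all 1).
#' @param alpha entmax exponent used when `x` holds logits.
#' @return Scalar loss (mean weighted NLL).
#' @export
classification_loss <- function(x, labels, class_weights = NULL,
                                alpha = 1.5) {
  if (inherits(x, "class_probabilities")) x <- matrix(x$probs, nrow = 1)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1)
  C <- ncol(x)
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > C)) {
    stop_gliofuse("label out of range 1..C", "gliofuse_value_error")
  }
  is_probs <- all(x >= 0) && all(abs(rowSums(x) - 1) <= 1e-6)
  if (!is_probs) {
    x <- t(apply(x, 1, function(z) entmax(z, alpha)$probs))
  }
  if (is.null(class_weights)) class_weights <- rep(1, C)
  p_true <- pmax(x[cbind(seq_len(nrow(x)), labels)], 1e-8)
  mean(class_weights[labels] * (-log(p_true)))
}
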