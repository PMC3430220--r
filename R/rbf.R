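# Exact-design Gaussian radial-basis-function regression: every training
# sample is a hidden-unit center, the kernel bias is 0.8326/spread so that
# a unit sits at activation 1/2 exactly one spread away from its center
# (0.8326 ~ sqrt(ln 2)), and the output weights and bias solve the linear
# design system by minimum-norm least squares.

#' Kernel bias from the spread parameter
#'
#' @param spread Positive expansion coefficient of the Gaussian kernel.
#' @return `0.8326 / spread`.
#' @export
#' @examples
#' bias_from_spread(0.8326)  # 1
bias_from_spread <- function(spread) {
  if (!is.numeric(spread) || length(spread) != 1 || !is.finite(spread) ||
      spread <= 0)
    stop("spread must be a positive number")
  0.8326 / spread
}

#' Fit an exact-design RBF network
#'
#' Centers are the training inputs themselves (Q hidden units for Q
#' samples). With `A[i, j] = exp(-(b1 * ||c_i - p_j||)^2)` the output
#' weights `W` and bias `b2` satisfy `[W b2] %*% rbind(A, 1) = T`; the
#' system has Q equations and Q + 1 unknowns per output and is solved by
#' minimum-norm least squares (Moore-Penrose), which also absorbs the rank
#' deficiency caused by duplicated inputs.
#'
#' @param inputs Numeric matrix Q x M (training samples in rows).
#' @param targets Numeric vector of length Q, or matrix N x Q for N
#'   outputs.
#' @param spread Positive kernel spread.
#' @return List with class `rbf_model`: `centers`, `b1`, `W` (N x Q), `b2`
#'   (length N), `spread`, and `condition` (condition number of the design
#'   block). A warning is issued above 1e12.
#' @export
rbf_fit <- function(inputs, targets, spread = 0.8) {
  inputs <- as.matrix(inputs)
  if (is.null(dim(targets))) targets <- matrix(targets, nrow = 1)
  q <- nrow(inputs)
  stopifnot(q >= 1, ncol(targets) == q)
  if (any(!is.finite(inputs))) stop("non-finite training inputs")
  if (any(!is.finite(targets))) stop("non-finite training targets")
  b1 <- bias_from_spread(spread)
  d <- as.matrix(dist(inputs))
  if (q > 1) {
    dup <- which(d < 1e-12 & upper.tri(d), arr.ind = TRUE)
    if (nrow(dup) > 0)
      warning("near-duplicate training inputs (", nrow(dup),
              " pair(s)); fitting proceeds by least squares")
  }
  a <- exp(-(b1 * d)^2)
  design <- rbind(a, rep(1, q))
  sv <- svd(design, nu = 0, nv = 0)$d
  cond <- sv[1] / max(sv[length(sv)], .Machine$double.xmin)
  if (cond > 1e12)
    warning(sprintf("RBF design condition number %.3g exceeds 1e12", cond))
  wb <- targets %*% MASS::ginv(design)   # N x (Q + 1), minimum-norm LS
  structure(list(centers = inputs,
                 b1 = b1,
                 W = wb[, seq_len(q), drop = FALSE],
                 b2 = wb[, q + 1],
                 spread = spread,
                 condition = cond),
            class = "rbf_model")
}

#' Hidden-layer activations
#'
#' `a_i = exp(-(b1 * ||c_i - p||)^2)`: 1 at the center, 1/2 at distance
#' `spread`, Gaussian decay beyond.
#'
#' @param model An `rbf_model`.
#' @param samples Numeric vector (one sample) or matrix (samples in rows).
#' @return Matrix Q x n of activations (one column per sample).
#' @export
rbf_activations <- function(model, samples) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  samples <- as.matrix(samples)
  if (ncol(samples) != ncol(model$centers))
    stop("sample dimension ", ncol(samples), " != center dimension ",
         ncol(model$centers))
  q <- nrow(model$centers)
  d <- as.matrix(dist(rbind(model$centers, samples)))
  d <- d[seq_len(q), -seq_len(q), drop = FALSE]
  a <- exp(-(model$b1 * d)^2)
  dimnames(a) <- NULL
  a
}

#' Predict from an exact-design RBF network
#'
#' @param object An `rbf_model`.
#' @param newdata Numeric vector or matrix of samples (rows).
#' @param ... Unused.
#' @return Numeric vector (single output) or N x n matrix.
#' @export
predict.rbf_model <- function(object, newdata, ...) {
  a <- rbf_activations(object, newdata)
  out <- object$W %*% a + object$b2
  if (nrow(out) == 1) drop(out) else out
}
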