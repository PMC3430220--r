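# Kohonen self-organizing feature map with a rectangular competitive layer.
# The competitive rule is winner-take-all on negative Euclidean distance
# plus a (fixed, zero) threshold; the update moves the winner and every
# neuron within the current Chebyshev grid radius toward the sample; the
# learning rate and radius decay linearly from their initial values to zero
# over the training run.

#' SOFM configuration
#'
#' @param grid_rows,grid_cols Competitive-layer grid (default 6 x 4, 24
#'   neurons).
#' @param eta0 Initial learning rate, in (0, 1].
#' @param nc0 Initial neighborhood radius (Chebyshev distance on the grid).
#'   The default 5 is the Chebyshev diameter of the 6 x 4 grid, so the
#'   first updates reach the whole map.
#' @param max_steps Number of training iterations T.
#' @param seed Integer seed for weight initialization and sample draws, or
#'   `NULL` to use the current RNG state.
#' @param decay `"linear"`: rate and radius are the initial values scaled
#'   by `(1 - N/T)`. `"recursive"`: the printed recurrences are applied to
#'   the previous value instead, which decays super-linearly.
#' @return A list with class `sofm_config`.
#' @export
sofm_config <- function(grid_rows = 6, grid_cols = 4, eta0 = 0.9, nc0 = 5,
                        max_steps = 500, seed = NULL,
                        decay = c("linear", "recursive")) {
  decay <- match.arg(decay)
  stopifnot(grid_rows >= 1, grid_cols >= 1, eta0 > 0, eta0 <= 1,
            nc0 >= 0, max_steps >= 1)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 eta0 = eta0, nc0 = nc0,
                 max_steps = as.integer(max_steps),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 decay = decay),
            class = "sofm_config")
}

.grid_coords <- function(rows, cols) {
  # neuron 1 at the bottom-left, indices growing up each column
  cbind(row = rep(seq_len(rows), cols), col = rep(seq_len(cols), each = rows))
}

#' Initialize a SOFM
#'
#' Weights are drawn uniformly in \[-0.1, 0.1\] from the seeded generator;
#' thresholds are fixed at zero (no conscience mechanism).
#'
#' @param config A [sofm_config()].
#' @param input_dim Dimension R of the input samples.
#' @return A list with class `sofm_model`: `weights` (S1 x R), `biases`,
#'   `grid` (S1 x 2 grid coordinates), `config`, `steps_trained`.
#' @export
init_sofm <- function(config, input_dim) {
  stopifnot(inherits(config, "sofm_config"), input_dim >= 1)
  s1 <- config$grid_rows * config$grid_cols
  draw <- function() matrix(runif(s1 * input_dim, -0.1, 0.1), nrow = s1)
  w <- if (is.null(config$seed)) draw() else withr::with_seed(config$seed, draw())
  structure(list(weights = w,
                 biases = numeric(s1),
                 grid = .grid_coords(config$grid_rows, config$grid_cols),
                 config = config,
                 steps_trained = 0L),
            class = "sofm_model")
}

#' Winning neuron for one sample
#'
#' The winner maximizes the competitive output
#' `n_i = -||sample - w_i|| + b_i`; ties go to the lowest neuron index.
#'
#' @param model A `sofm_model`.
#' @param sample Numeric vector of length R.
#' @return Integer neuron index.
#' @export
sofm_winner <- function(model, sample) {
  w <- model$weights
  if (length(sample) != ncol(w))
    stop("sample length ", length(sample), " != input dimension ", ncol(w))
  n <- -sqrt(rowSums(sweep(w, 2, sample)^2)) + model$biases
  which.max(n)  # first maximum = lowest index on ties
}

#' Learning-rate and neighborhood decay
#'
#' Linear schedule evaluated at step `N` of `T`:
#' `eta = eta0 (1 - N/T)` and `nc = ceiling(nc0 (1 - N/T))`.
#'
#' @param eta0,nc0 Initial learning rate and neighborhood radius.
#' @param step Current step N, `0 <= N <= T`.
#' @param max_steps Total steps T.
#' @return List with elements `eta` and `nc`.
#' @export
sofm_decay <- function(eta0, nc0, step, max_steps) {
  if (step < 0 || step > max_steps)
    stop("step must lie in [0, max_steps]")
  f <- 1 - step / max_steps
  list(eta = eta0 * f, nc = ceiling(nc0 * f))
}

#' Neighborhood weight update
#'
#' Every neuron whose Chebyshev grid distance to the winner is at most `nc`
#' moves toward the sample by a fraction `eta`; all other rows are
#' untouched.
#'
#' @param model A `sofm_model`.
#' @param sample Numeric vector of length R.
#' @param winner Winning neuron index.
#' @param nc Neighborhood radius.
#' @param eta Learning rate.
#' @return The updated model.
#' @export
sofm_update <- function(model, sample, winner, nc, eta) {
  stopifnot(winner >= 1, winner <= nrow(model$weights), nc >= 0)
  g <- model$grid
  cheb <- pmax(abs(g[, 1] - g[winner, 1]), abs(g[, 2] - g[winner, 2]))
  nb <- which(cheb <= nc)
  w <- model$weights
  w[nb, ] <- w[nb, ] + eta *
    (matrix(sample, length(nb), ncol(w), byrow = TRUE) - w[nb, , drop = FALSE])
  model$weights <- w
  model
}

#' Train a SOFM
#'
#' Runs `max_steps` iterations of: random sample draw, winner search,
#' neighborhood update, schedule decay. The schedule value used at
#' iteration N is the one current on entering the step (so the first
#' iteration uses the initial rate and radius, and the schedule reaches
#' zero after the final iteration). Fully reproducible given
#' `config$seed`.
#'
#' @param samples Numeric matrix, one sample per row.
#' @param config A [sofm_config()].
#' @return A trained `sofm_model` with `steps_trained = max_steps`.
#' @export
train_sofm <- function(samples, config = sofm_config()) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1) stop("no training samples")
  run <- function() {
    model <- init_sofm_unseeded(config, ncol(samples))
    eta <- config$eta0
    nc <- config$nc0
    for (N in seq_len(config$max_steps)) {
      if (config$decay == "linear") {
        sch <- sofm_decay(config$eta0, config$nc0, N - 1, config$max_steps)
        eta <- sch$eta
        nc <- sch$nc
      }
      p <- samples[sample.int(nrow(samples), 1L), ]
      k <- sofm_winner(model, p)
      model <- sofm_update(model, p, k, nc, eta)
      if (config$decay == "recursive") {
        eta <- eta * (1 - N / config$max_steps)
        nc <- ceiling(nc * (1 - N / config$max_steps))
      }
    }
    model$steps_trained <- config$max_steps
    model
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

# init inside an already-seeded context (train_sofm seeds once for both the
# weight draw and the sample sequence)
init_sofm_unseeded <- function(config, input_dim) {
  cfg <- config
  cfg$seed <- NULL
  init_sofm(cfg, input_dim)
}

#' Winning neurons for a sample matrix
#'
#' @param model A trained `sofm_model`.
#' @param samples Matrix of samples (rows).
#' @return Integer vector of winning-neuron indices.
#' @export
assign_winners <- function(model, samples) {
  samples <- as.matrix(samples)
  apply(samples, 1, function(p) sofm_winner(model, p))
}

#' Cluster samples into a partition by shared winner
#'
#' @param model A trained `sofm_model`.
#' @param samples Matrix of samples (rows), parallel to `names`.
#' @param names Character names of the samples.
#' @return A [as_partition()] of `names`.
#' @export
assign_and_partition <- function(model, samples, names) {
  stopifnot(length(names) == nrow(as.matrix(samples)))
  labels <- assign_winners(model, samples)
  labels_to_partition(labels, names)
}

#' Consensus partition over independent SOFM restarts
#'
#' The online map is a stochastic algorithm: individual runs occasionally
#' split a tight cluster across two adjacent neurons or leave one neuron
#' shared between two clusters. Runs disagree in different ways, so the
#' modal partition over a modest number of independently seeded restarts is
#' stable where any single run is not; this is the clustering procedure the
#' pipeline uses. Ties go to the partition seen first.
#'
#' @param samples Matrix of samples (rows), parallel to `names`.
#' @param names Character names of the samples.
#' @param config A [sofm_config()]; restart seeds are derived from
#'   `config$seed`.
#' @param n_restarts Number of restarts (default 25).
#' @return List: `partition` (modal partition), `support` (fraction of
#'   restarts agreeing with it), `partitions` (all restart partitions).
#' @export
consensus_partition <- function(samples, names, config = sofm_config(),
                                n_restarts = 25) {
  stopifnot(n_restarts >= 1)
  base_seed <- if (is.null(config$seed)) {
    sample.int(.Machine$integer.max, 1L)
  } else {
    config$seed
  }
  parts <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    cfg <- config
    cfg$seed <- (base_seed + 7919L * r) %% .Machine$integer.max
    model <- train_sofm(samples, cfg)
    parts[[r]] <- assign_and_partition(model, samples, names)
  }
  sigs <- vapply(parts, partition_signature, "")
  counts <- table(factor(sigs, levels = unique(sigs)))  # first-seen order
  modal <- names(counts)[which.max(counts)]
  list(partition = parts[[match(modal, sigs)]],
       support = max(counts) / n_restarts,
       partitions = parts)
}
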