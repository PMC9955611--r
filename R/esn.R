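#' Reservoir hyperparameter configuration
#'
#' Collects the hyperparameters of the leaky echo state network. The
#' recurrent matrix A and input weights W_in are sampled entrywise as
#' `raw_scale * s * v` and `input_scaling * s * v` with
#' `s ~ Bernoulli(connectivity)` and `v ~ Uniform[-1, 1]`; A is then
#' rescaled multiplicatively so its spectral radius (largest eigenvalue
#' modulus) equals `spectral_radius` exactly — a spectral radius below 1 is
#' the standard necessary condition for the echo state property (states
#' forget their initial condition).
#'
#' @param N reservoir size (number of hidden units).
#' @param spectral_radius target spectral radius of A, in (0, 1).
#' @param leak leaky-integration parameter \eqn{\psi \in [0, 1]}: the new
#'   state is \eqn{(1-\psi) u_{t-1} + \psi \tanh(A u_{t-1} + W_{in} x_t)}.
#' @param connectivity Bernoulli sparsity parameter \eqn{p_s \in (0, 1]}.
#' @param input_scaling input weight scale \eqn{\gamma > 0}; larger values
#'   drive the tanh harder (more nonlinearity).
#' @param raw_scale pre-rescaling magnitude \eqn{\beta} of A's entries;
#'   absorbed by the spectral-radius rescale, default 1.
#' @param ridge ridge penalty \eqn{\alpha \ge 0} of the readout fit.
#' @param washout initial states excluded from fitting and skill
#'   computation (transient removal).
#' @param seed integer seed for reservoir sampling.
#' @param standardize z-standardize input and target series around the fit
#'   (predictions are returned on the original scale).
#' @return object of class `reservoir_config`.
#' @examples
#' reservoir_config(N = 50, spectral_radius = 0.5)
#' @export
reservoir_config <- function(N = 100, spectral_radius = 0.5, leak = 1,
                             connectivity = 0.1, input_scaling = 0.5,
                             raw_scale = 1, ridge = 1e-4, washout = 10,
                             seed = NULL, standardize = TRUE) {
  stopifnot(N >= 1, spectral_radius > 0, spectral_radius < 1,
            leak >= 0, leak <= 1, connectivity > 0, connectivity <= 1,
            input_scaling > 0, raw_scale > 0, ridge >= 0, washout >= 0)
  structure(list(N = as.integer(N), spectral_radius = spectral_radius,
                 leak = leak, connectivity = connectivity,
                 input_scaling = input_scaling, raw_scale = raw_scale,
                 ridge = ridge, washout = as.integer(washout),
                 seed = seed, standardize = isTRUE(standardize)),
            class = "reservoir_config")
}

#' @export
print.reservoir_config <- function(x, ...) {
  cat(sprintf(
    "<reservoir_config> N=%d  lambda_max=%.3g  leak=%.3g  p_s=%.3g  gamma=%.3g  alpha=%.3g  washout=%d\n",
    x$N, x$spectral_radius, x$leak, x$connectivity, x$input_scaling,
    x$ridge, x$washout))
  invisible(x)
}

#' Sample a reservoir (recurrent matrix and input weights)
#'
#' W_in is sampled first, then A, so that reservoirs with equal seeds and
#' sizes are identical. A is rescaled to the configured spectral radius; a
#' reservoir whose sampled A is identically zero (possible at very small
#' `connectivity * N^2`) cannot be rescaled and raises an error.
#'
#' @param config a [reservoir_config()].
#' @return object of class `reservoir`: list with `A` (N x N), `W_in`
#'   (N x 1), `u0` (initial state, zeros) and the `config`.
#' @export
build_reservoir <- function(config) {
  stopifnot(inherits(config, "reservoir_config"))
  N <- config$N
  with_seed(config$seed, {
    w_in <- config$input_scaling *
      stats::rbinom(N, 1L, config$connectivity) *
      stats::runif(N, -1, 1)
    if (all(w_in == 0) && config$connectivity < 1)
      stop("sampled input weights are all zero; increase connectivity (p_s)")
    A <- matrix(config$raw_scale *
                  stats::rbinom(N * N, 1L, config$connectivity) *
                  stats::runif(N * N, -1, 1), nrow = N)
    sr <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (sr == 0)
      stop("sampled reservoir matrix is identically zero and cannot be ",
           "rescaled to the target spectral radius; increase connectivity ",
           "(p_s) or N")
    A <- A * (config$spectral_radius / sr)
    structure(list(A = A, W_in = matrix(w_in, ncol = 1L),
                   u0 = numeric(N), config = config),
              class = "reservoir")
  })
}

#' @export
print.reservoir <- function(x, ...) {
  cat(sprintf("<reservoir> N=%d, spectral radius %.6f, %d/%d nonzero in A\n",
              x$config$N, max(Mod(eigen(x$A, only.values = TRUE)$values)),
              sum(x$A != 0), length(x$A)))
  invisible(x)
}

#' Drive the reservoir with an input series
#'
#' Evolves the leaky state recursion
#' \deqn{u_t^* = \tanh(A u_{t-1} + W_{in} x_t), \quad
#'       u_t = (1-\psi) u_{t-1} + \psi u_t^*}
#' from the initial state `u0` over the whole input series.
#'
#' @param reservoir a [build_reservoir()] result.
#' @param x numeric input series (finite).
#' @param leak optional override of the configured leaky parameter.
#' @param washout optional override of the configured washout; stored as an
#'   attribute marking rows to exclude from fitting.
#' @return T x N matrix of states (row t is \eqn{u_t}), with attribute
#'   `washout`.
#' @export
run_states <- function(reservoir, x, leak = NULL, washout = NULL) {
  stopifnot(inherits(reservoir, "reservoir"))
  if (!length(x)) stop("input series is empty")
  if (anyNA(x) || any(!is.finite(x)))
    stop("non-finite input at index ", which(!is.finite(x))[1L])
  psi <- leak %||% reservoir$config$leak
  wo <- washout %||% reservoir$config$washout
  A <- reservoir$A
  w_in <- as.numeric(reservoir$W_in)
  u <- reservoir$u0
  n <- length(x)
  U <- matrix(0, nrow = n, ncol = length(u))
  for (t in seq_len(n)) {
    u_star <- tanh(as.numeric(A %*% u) + w_in * x[t])
    u <- (1 - psi) * u + psi * u_star
    U[t, ] <- u
  }
  attr(U, "washout") <- min(wo, n)
  U
}

#' Fit the linear readout by ridge regression
#'
#' Solves the standard ridge problem
#' \eqn{\min_w \|U w - y\|_2^2 + \alpha \|w\|_2^2} on the post-washout rows
#' via the normal equations \eqn{(U^\top U + \alpha I) w = U^\top y}.
#'
#' @param states state matrix from [run_states()] (its `washout` attribute
#'   marks excluded rows).
#' @param targets numeric target series aligned with the state rows.
#' @param ridge penalty \eqn{\alpha \ge 0}.
#' @param allow_pinv with `ridge = 0` and a rank-deficient state matrix,
#'   `TRUE` falls back to the minimum-norm (pseudo-inverse) solution;
#'   `FALSE` (default) raises an error.
#' @return object of class `esn_readout`: list with `W_out` (1 x N) and
#'   `ridge`.
#' @export
fit_readout <- function(states, targets, ridge = 0, allow_pinv = FALSE) {
  stopifnot(is.matrix(states), length(targets) == nrow(states),
            ridge >= 0)
  wo <- attr(states, "washout") %||% 0L
  keep <- seq_len(nrow(states)) > wo
  if (!any(keep)) stop("washout leaves no rows to fit on")
  U <- states[keep, , drop = FALSE]
  y <- targets[keep]
  G <- crossprod(U) + diag(ridge, ncol(U))
  b <- crossprod(U, y)
  w <- tryCatch(solve(G, b), error = function(e) {
    if (ridge > 0 || !allow_pinv)
      stop("readout normal equations are singular",
           if (ridge == 0) " (ridge = 0 with rank-deficient states; set allow_pinv = TRUE for the minimum-norm solution)",
           call. = FALSE)
    NULL
  })
  if (is.null(w)) {  # minimum-norm least squares via SVD
    sv <- svd(U)
    pos <- sv$d > max(dim(U)) * .Machine$double.eps * max(sv$d)
    w <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  }
  structure(list(W_out = matrix(as.numeric(w), nrow = 1L), ridge = ridge),
            class = "esn_readout")
}

#' Predict from reservoir states with a trained readout
#'
#' \eqn{\hat y_t = W_{out} u_t} for every state row (including washout
#' rows; callers exclude them from skill computations).
#'
#' @param readout an [fit_readout()] result.
#' @param states state matrix from [run_states()].
#' @return numeric vector of predictions.
#' @export
predict_readout <- function(readout, states) {
  stopifnot(inherits(readout, "esn_readout"), is.matrix(states))
  if (ncol(states) != ncol(readout$W_out))
    stop("state dimension (", ncol(states), ") does not match readout (",
         ncol(readout$W_out), ")")
  as.numeric(states %*% t(readout$W_out))
}

#' Normalized root-mean-squared error
#'
#' \deqn{\mathrm{NRMSE} = \frac{\sqrt{\sum_t (\hat y_t - y_t)^2 / T}}
#'                             {\sum_t y_t / T}}
#' i.e. the RMS error divided by the mean of the observed series. The
#' normalization presumes a positive-mean series (counts, scores); a zero
#' observed mean leaves it undefined and raises an error.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return numeric scalar.
#' @examples
#' nrmse(c(1, 1), c(1, 3))  # sqrt(2)/2
#' @export
nrmse <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 1L)
  m <- mean(observed)
  if (m == 0)
    stop("NRMSE is undefined: the observed series has mean zero")
  sqrt(mean((predicted - observed)^2)) / m
}

#' Serialize a reservoir or readout to JSON (and back)
#'
#' Stores the sampled matrices and configuration at full precision so a
#' reservoir can be reloaded bit-identically for reproducibility.
#'
#' @param x a `reservoir` or `esn_readout`.
#' @param path JSON file path.
#' @export
write_esn_weights <- function(x, path) {
  if (inherits(x, "reservoir")) {
    cfg <- x$config
    cfg$seed <- cfg$seed %||% NA
    obj <- list(kind = "reservoir", A = x$A, W_in = as.numeric(x$W_in),
                u0 = x$u0, config = unclass(cfg))
  } else if (inherits(x, "esn_readout")) {
    obj <- list(kind = "readout", W_out = as.numeric(x$W_out),
                ridge = x$ridge)
  } else stop("cannot serialize objects of class ", class(x)[1L])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_esn_weights
#' @export
read_esn_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$kind, "reservoir")) {
    co <- obj$config
    args <- co[c("N", "spectral_radius", "leak", "connectivity",
                 "input_scaling", "raw_scale", "ridge", "washout",
                 "standardize")]
    if (!is.null(co$seed) && !is.na(co$seed)) args$seed <- co$seed
    cfg <- do.call(reservoir_config, args)
    structure(list(A = matrix(as.numeric(obj$A), nrow = cfg$N),
                   W_in = matrix(as.numeric(obj$W_in), ncol = 1L),
                   u0 = as.numeric(obj$u0), config = cfg),
              class = "reservoir")
  } else if (identical(obj$kind, "readout")) {
    structure(list(W_out = matrix(obj$W_out, nrow = 1L),
                   ridge = obj$ridge),
              class = "esn_readout")
  } else stop("'", path, "' does not contain serialized network weights")
}

#' Fit a leaky echo state network
#'
#' The one-stop fitting interface: builds the reservoir, drives it with the
#' input series, and ridge-fits the linear readout to the target series.
#' When `standardize` is configured (the default), input and target are
#' z-standardized for the fit and predictions are mapped back to the
#' original target scale — the count and score features of a daily panel
#' live on very different scales, and the input scaling \eqn{\gamma} would
#' otherwise be confounded with the data scale.
#'
#' @param x input series driving the reservoir.
#' @param y target series to predict (same length as `x`).
#' @param config a [reservoir_config()].
#' @return object of class `esn` with components `reservoir`, `readout`,
#'   `states`, `fitted`, `config`, and the scaling used. Methods:
#'   `print`, `coef`, `fitted`, `residuals`, `predict` (with optional
#'   `newdata` input series).
#' @examples
#' set.seed(1)
#' x <- sin(seq(0, 20, length.out = 300)) + rnorm(300, 0, 0.05)
#' fit <- esn(x, x, reservoir_config(N = 30, seed = 2))
#' fit
#' @export
esn <- function(x, y, config = reservoir_config()) {
  stopifnot(length(x) == length(y))
  res <- build_reservoir(config)
  xs <- if (config$standardize) standardize(x) else list(z = x, mean = 0, sd = 1)
  ys <- if (config$standardize) standardize(y) else list(z = y, mean = 0, sd = 1)
  states <- run_states(res, xs$z)
  readout <- fit_readout(states, ys$z, ridge = config$ridge)
  fitted <- predict_readout(readout, states) * ys$sd + ys$mean
  structure(list(reservoir = res, readout = readout, states = states,
                 fitted = fitted, y = y,
                 x_scale = xs[c("mean", "sd")], y_scale = ys[c("mean", "sd")],
                 config = config),
            class = "esn")
}

#' @export
print.esn <- function(x, ...) {
  cat("Leaky echo state network fit\n")
  print(x$config)
  wo <- attr(x$states, "washout")
  keep <- seq_along(x$fitted) > wo
  cat(sprintf("  T = %d (washout %d), training NRMSE %.4g, cor(fitted, y) %.4f\n",
              length(x$fitted), wo,
              tryCatch(nrmse(x$fitted[keep], x$y[keep]), error = function(e) NA),
              suppressWarnings(stats::cor(x$fitted[keep], x$y[keep]))))
  invisible(x)
}

#' @export
coef.esn <- function(object, ...) as.numeric(object$readout$W_out)

#' @export
fitted.esn <- function(object, ...) object$fitted

#' @export
residuals.esn <- function(object, ...) object$y - object$fitted

#' @rdname esn
#' @param object a fitted `esn`.
#' @param newdata optional new input series; omitted, the in-sample fitted
#'   values are returned.
#' @param ... unused.
#' @export
predict.esn <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  z <- (newdata - object$x_scale$mean) / object$x_scale$sd
  states <- run_states(object$reservoir, z)
  predict_readout(object$readout, states) * object$y_scale$sd +
    object$y_scale$mean
}
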