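#' Align an input and a target series at lag tau
#'
#' Pairs the input series x with the target series y shifted by tau time
#' steps, using the one-sided index window
#' \eqn{t = 1 + |\tau| - h(\tau), \ldots, T - h(\tau)} with
#' \eqn{h(\tau) = \tau} for \eqn{\tau \ge 0} and 0 for \eqn{\tau < 0}:
#' for tau >= 0, \eqn{x_1 \ldots x_{T-\tau}} predicts
#' \eqn{y_{1+\tau} \ldots y_T} (targets in the input's future); for
#' tau < 0, \eqn{x_{1+|\tau|} \ldots x_T} predicts
#' \eqn{y_1 \ldots y_{T-|\tau|}} (targets in the input's past).
#'
#' @param x input series.
#' @param y target series (same length).
#' @param tau integer lag, `abs(tau) < length(x)`.
#' @return list with `input` and `target`, both of length `T - abs(tau)`,
#'   and `offset`, the number of leading input values dropped (0 for
#'   tau >= 0, `abs(tau)` for tau < 0).
#' @export
align_lagged <- function(x, y, tau) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  tau <- as.integer(tau)
  if (abs(tau) >= n)
    stop("|tau| = ", abs(tau), " must be smaller than the series length ", n)
  if (tau >= 0) {
    list(input = x[seq_len(n - tau)],
         target = y[seq.int(1L + tau, n)], offset = 0L)
  } else {
    k <- -tau
    list(input = x[seq.int(1L + k, n)],
         target = y[seq_len(n - k)], offset = k)
  }
}

#' Cross-map skill: Pearson correlation of lagged predictions
#'
#' The skill \eqn{\rho(\tau)} is the sample Pearson correlation between the
#' lag-\eqn{\tau} predictions and their observations over the aligned index
#' window (sums from \eqn{1+|\tau|-h(\tau)} to \eqn{T-h(\tau)}, means with
#' the \eqn{1/(T-|\tau|)} factor).
#'
#' @param predicted,observed aligned numeric vectors (length
#'   \eqn{T - |\tau|}, at least 3).
#' @return correlation in \[-1, 1\], or `NA` with attribute
#'   `degenerate = TRUE` when either series is constant.
#' @export
lagged_pearson <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  n <- length(observed)
  if (n < 3L) stop("need at least 3 aligned pairs")
  mp <- sum(predicted) / n
  mo <- sum(observed) / n
  dp <- predicted - mp
  do <- observed - mo
  vp <- sum(dp^2)
  vo <- sum(do^2)
  if (vp == 0 || vo == 0)
    return(structure(NA_real_, degenerate = TRUE))
  sum(dp * do) / sqrt(vp * vo)
}

#' Lagged cross-map skill curve for one direction
#'
#' For each lag tau in the grid, aligns the input and target series,
#' drives the reservoir with the aligned input, ridge-fits the readout on
#' the stacked post-washout states of all units, predicts, and records the
#' pooled Pearson skill between predictions and observations. By the
#' cross-mapping rationale the *target* series is the tested cause: if the
#' target variable causes the input variable, the input series embeds the
#' target's history and the skill peaks at a negative lag.
#'
#' States are computed per unit with a state reset between units (no
#' cross-unit leakage). For tau >= 0 the aligned input is a prefix of the
#' unit's series, so states from one full-series run are reused unchanged;
#' for tau < 0 the reservoir is re-run on the suffix.
#'
#' @param panel a [feature_panel()].
#' @param input_feature feature driving the reservoir.
#' @param target_feature feature being predicted (the tested cause).
#' @param config a [reservoir_config()].
#' @param lags integer lag grid, default `-30:30`.
#' @param n_seeds average the skill curve over this many reservoir seeds
#'   (default 1) to damp reservoir sampling noise; seeds are derived
#'   deterministically from `config$seed`.
#' @param evaluation how skill is evaluated. `"loocv"` fits the readout on
#'   the other units' states and predicts each held-out unit (pooled);
#'   `"split"` fits on the first half of each unit's rows and evaluates on
#'   the second half; `"insample"` fits and evaluates on everything.
#'   `"auto"` (default) picks `"loocv"` with two or more units and
#'   `"split"` otherwise. Out-of-sample evaluation keeps the null
#'   distribution of the peak skill honest: an in-sample ridge fit with
#'   hundreds of states can reach spurious correlations above typical
#'   claim thresholds on pure noise.
#' @param interpolate fill interior missing days by linear interpolation
#'   before fitting (see [panel_series()]).
#' @return object of class `cross_map_curve`: data.frame of `lag`, `rho`
#'   plus attributes `peak_lag`, `peak_rho`, `prominence` (peak minus
#'   median skill), and the direction metadata. Peak ties are broken toward
#'   the smallest `abs(lag)`, then toward the negative lag.
#' @examples
#' sim <- gen_coupled_logistic(coupling_spec("x_to_y"), n = 300, seed = 1)
#' cm <- cross_map_skill(sim$panel, "y", "x",
#'                       reservoir_config(N = 30, seed = 1), lags = -5:5)
#' cm
#' @export
cross_map_skill <- function(panel, input_feature, target_feature,
                            config = reservoir_config(), lags = -30:30,
                            n_seeds = 1,
                            evaluation = c("auto", "loocv", "split",
                                           "insample"),
                            interpolate = TRUE) {
  stopifnot(inherits(panel, "feature_panel"),
            inherits(config, "reservoir_config"))
  evaluation <- match.arg(evaluation)
  feats <- panel_features(panel)
  for (f in c(input_feature, target_feature))
    if (!f %in% feats) stop("feature '", f, "' not present in the panel")
  lags <- sort(unique(as.integer(lags)))
  units <- panel_units(panel)
  series <- lapply(units, function(u) {
    xi <- panel_series(panel, u, input_feature, interpolate = interpolate)
    yi <- panel_series(panel, u, target_feature, interpolate = interpolate)
    if (length(xi) != length(yi))
      stop("input and target series of unit '", u, "' differ in length")
    if (anyNA(xi) || anyNA(yi))
      stop("unit '", u, "' still has missing values after interpolation")
    xs <- if (config$standardize) standardize(xi) else
      list(z = xi, mean = 0, sd = 1)
    ys <- if (config$standardize) standardize(yi) else
      list(z = yi, mean = 0, sd = 1)
    list(x = xs$z, y = ys$z, y_mean = ys$mean, y_sd = ys$sd)
  })
  tmin <- min(vapply(series, function(s) length(s$x), 1L))
  if (max(abs(lags)) + config$washout >= tmin)
    stop("series too short for the lag grid: need length > max|lag| + washout")
  if (evaluation == "auto")
    evaluation <- if (length(series) >= 2L) "loocv" else "split"
  if (evaluation == "loocv" && length(series) < 2L)
    stop("loocv evaluation needs at least 2 units; use evaluation = 'split'")

  seeds <- if (n_seeds == 1) list(config$seed) else
    lapply(seq_len(n_seeds), function(k) split_seed(config$seed %||% 0, k))
  curves <- vapply(seeds, function(sd_k) {
    cfg <- config; cfg$seed <- sd_k
    res <- build_reservoir(cfg)
    full_states <- lapply(series, function(s) run_states(res, s$x))
    vapply(lags, function(tau) {
      rows <- list(); tgt_z <- list(); tgt <- list()
      for (i in seq_along(series)) {
        s <- series[[i]]
        al <- align_lagged(s$x, s$y, tau)
        st <- if (tau >= 0) {
          # prefix input: states of the full run are identical
          U <- full_states[[i]][seq_along(al$input), , drop = FALSE]
          attr(U, "washout") <- min(config$washout, nrow(U))
          U
        } else run_states(res, al$input)
        keep <- seq_len(nrow(st)) > attr(st, "washout")
        rows[[i]] <- st[keep, , drop = FALSE]
        tgt_z[[i]] <- al$target[keep]
        tgt[[i]] <- al$target[keep] * s$y_sd + s$y_mean
      }
      fit_on <- function(train_idx)
        tryCatch(fit_readout(
          structure(do.call(rbind, rows[train_idx]), washout = 0L),
          unlist(tgt_z[train_idx], use.names = FALSE),
          ridge = config$ridge), error = function(e) NULL)
      prd <- list(); obs <- list()
      if (evaluation == "insample") {
        ro <- fit_on(seq_along(rows))
        if (is.null(ro)) return(NA_real_)
        for (i in seq_along(rows)) {
          prd[[i]] <- predict_readout(ro, rows[[i]]) * series[[i]]$y_sd +
            series[[i]]$y_mean
          obs[[i]] <- tgt[[i]]
        }
      } else if (evaluation == "loocv") {
        for (i in seq_along(rows)) {
          ro <- fit_on(setdiff(seq_along(rows), i))
          if (is.null(ro)) return(NA_real_)
          prd[[i]] <- predict_readout(ro, rows[[i]]) * series[[i]]$y_sd +
            series[[i]]$y_mean
          obs[[i]] <- tgt[[i]]
        }
      } else {  # temporal split: first half trains, second half evaluates
        tr <- lapply(rows, function(U) seq_len(nrow(U) %/% 2L))
        ro <- tryCatch(fit_readout(
          structure(do.call(rbind, Map(function(U, id)
            U[id, , drop = FALSE], rows, tr)), washout = 0L),
          unlist(Map(function(z, id) z[id], tgt_z, tr),
                 use.names = FALSE),
          ridge = config$ridge), error = function(e) NULL)
        if (is.null(ro)) return(NA_real_)
        for (i in seq_along(rows)) {
          ev <- setdiff(seq_len(nrow(rows[[i]])), tr[[i]])
          prd[[i]] <- predict_readout(ro, rows[[i]][ev, , drop = FALSE]) *
            series[[i]]$y_sd + series[[i]]$y_mean
          obs[[i]] <- tgt[[i]][ev]
        }
      }
      # skill is affine-invariant; computed on the original target scale
      as.numeric(lagged_pearson(unlist(prd, use.names = FALSE),
                                unlist(obs, use.names = FALSE)))
    }, numeric(1))
  }, numeric(length(lags)))
  rho <- rowMeans(matrix(curves, nrow = length(lags)), na.rm = FALSE)
  if (all(is.na(rho)))
    stop("every lag was degenerate (constant predictions or targets)")

  ok <- which(!is.na(rho))
  best <- max(rho[ok])
  cand <- ok[rho[ok] == best]
  # tie-break: smallest |lag|, then the negative one
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  peak_i <- cand[1L]
  out <- data.frame(lag = lags, rho = rho)
  structure(out,
            class = c("cross_map_curve", "data.frame"),
            peak_lag = lags[peak_i], peak_rho = rho[peak_i],
            prominence = rho[peak_i] - stats::median(rho, na.rm = TRUE),
            input_feature = input_feature,
            target_feature = target_feature,
            tested_cause = target_feature,
            evaluation = evaluation,
            config = config)
}

#' @export
print.cross_map_curve <- function(x, ...) {
  cat(sprintf(
    "<cross_map_curve> input %s -> target %s (probes '%s causes %s')\n",
    attr(x, "input_feature"), attr(x, "target_feature"),
    attr(x, "tested_cause"), attr(x, "input_feature")))
  cat(sprintf("  lags %d..%d; peak rho = %.4f at tau = %d (prominence %.4f)\n",
              min(x$lag), max(x$lag), attr(x, "peak_rho"),
              attr(x, "peak_lag"), attr(x, "prominence")))
  invisible(x)
}

#' @export
plot.cross_map_curve <- function(x, ...) {
  graphics::plot(x$lag, x$rho, type = "l",
                 xlab = expression(tau),
                 ylab = expression(rho(tau)),
                 main = sprintf("Cross-map skill: %s -> %s",
                                attr(x, "input_feature"),
                                attr(x, "target_feature")), ...)
  graphics::abline(v = attr(x, "peak_lag"), lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Classify the causal direction of a pair from its two skill curves
#'
#' Applies the peak-lag decision rules to the two directional curves of a
#' pair (X, Y). Writing rho_x for the curve whose target is X (input Y;
#' probes "X causes Y") and rho_y for the curve whose target is Y (input X;
#' probes "Y causes X"):
#' \itemize{
#'   \item rho_x peaks at a negative lag and rho_y at a nonnegative lag
#'     =>  X causes Y (the input series Y embeds X's history);
#'   \item the mirror pattern  =>  Y causes X;
#'   \item both peaks at negative lags  =>  bidirectional coupling;
#'   \item either peak skill below `skill_threshold`, or any other pattern
#'     =>  none/inconclusive.
#' }
#' A coupling delay shifts the peak of the cause-probing curve further into
#' the negative lags.
#'
#' @param curve_x the [cross_map_skill()] curve with the pair's first
#'   variable as target.
#' @param curve_y the curve with the second variable as target.
#' @param skill_threshold minimum peak skill for any causal claim
#'   (default 0.2); below it pure noise would still produce verdicts.
#' @param zero_positive treat a peak at lag 0 as lying in the positive
#'   domain (default TRUE).
#' @return object of class `causal_verdict`.
#' @export
classify_direction <- function(curve_x, curve_y, skill_threshold = 0.2,
                               zero_positive = TRUE) {
  stopifnot(inherits(curve_x, "cross_map_curve"),
            inherits(curve_y, "cross_map_curve"))
  if (!identical(curve_x$lag, curve_y$lag))
    stop("the two curves were computed on different lag grids")
  x_name <- attr(curve_x, "target_feature")
  y_name <- attr(curve_y, "target_feature")
  if (!identical(attr(curve_x, "input_feature"), y_name) ||
      !identical(attr(curve_y, "input_feature"), x_name))
    stop("curves do not describe the two directions of the same pair")
  px <- attr(curve_x, "peak_lag"); rx <- attr(curve_x, "peak_rho")
  py <- attr(curve_y, "peak_lag"); ry <- attr(curve_y, "peak_rho")
  reason <- NULL
  neg <- function(l) if (zero_positive) l < 0 else l <= 0
  if (is.na(rx) || is.na(ry)) {
    verdict <- "none"; reason <- "missing peak skill"
  } else if (rx < skill_threshold || ry < skill_threshold) {
    verdict <- "none"
    reason <- sprintf("peak skill below threshold %.3g", skill_threshold)
  } else if (neg(px) && neg(py)) {
    verdict <- "bidirectional"
  } else if (neg(px) && !neg(py)) {
    verdict <- "x_causes_y"
  } else if (!neg(px) && neg(py)) {
    verdict <- "y_causes_x"
  } else {
    verdict <- "none"; reason <- "both peaks in the positive domain"
  }
  structure(list(pair = c(x = x_name, y = y_name), verdict = verdict,
                 peak_lag_x = px, peak_lag_y = py,
                 peak_rho_x = rx, peak_rho_y = ry,
                 skill_threshold_used = skill_threshold,
                 reason = reason),
            class = "causal_verdict")
}

#' @export
print.causal_verdict <- function(x, ...) {
  lab <- switch(x$verdict,
                x_causes_y = sprintf("%s -> %s", x$pair["x"], x$pair["y"]),
                y_causes_x = sprintf("%s -> %s", x$pair["y"], x$pair["x"]),
                bidirectional = sprintf("%s <-> %s", x$pair["x"], x$pair["y"]),
                none = "none / inconclusive")
  cat(sprintf("<causal_verdict> (%s, %s): %s\n", x$pair["x"], x$pair["y"], lab))
  cat(sprintf("  rho_%s peak %.4f at tau = %d; rho_%s peak %.4f at tau = %d (threshold %.3g)\n",
              x$pair["x"], x$peak_rho_x, x$peak_lag_x,
              x$pair["y"], x$peak_rho_y, x$peak_lag_y,
              x$skill_threshold_used))
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Write a skill curve (or list of curves) as a plot-ready CSV
#'
#' @param curves a `cross_map_curve` or list of them.
#' @param path output CSV path with columns
#'   `input_feature,target_feature,lag,rho`.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "cross_map_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv)
    data.frame(input_feature = attr(cv, "input_feature"),
               target_feature = attr(cv, "target_feature"),
               lag = cv$lag, rho = cv$rho))
  df <- do.call(rbind, rows)
  df$rho <- sprintf("%.17g", df$rho)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
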