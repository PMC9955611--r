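#' Hyperparameter grid for the reservoir search
#'
#' Defaults are the study grid: spectral radius
#' \{0.1, 0.3, 0.5, 0.7, 0.9\}, reservoir size \{50, ..., 300\},
#' connectivity \{0.1, 0.6\}, ridge \{1e-10, 1e-7, 1e-4, 0.1, 100\} and
#' input scaling \{0.1, 0.6\} — 600 combinations.
#'
#' @param spectral_radius,N,connectivity,ridge,input_scaling candidate
#'   value vectors (non-empty, inside each parameter's legal domain).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(spectral_radius = c(0.1, 0.3, 0.5, 0.7, 0.9),
                      N = c(50, 100, 150, 200, 250, 300),
                      connectivity = c(0.1, 0.6),
                      ridge = c(1e-10, 1e-7, 1e-4, 0.1, 100),
                      input_scaling = c(0.1, 0.6)) {
  stopifnot(length(spectral_radius) >= 1, all(spectral_radius > 0),
            all(spectral_radius < 1),
            length(N) >= 1, all(N >= 1),
            length(connectivity) >= 1, all(connectivity > 0),
            all(connectivity <= 1),
            length(ridge) >= 1, all(ridge >= 0),
            length(input_scaling) >= 1, all(input_scaling > 0))
  structure(list(spectral_radius = spectral_radius, N = as.integer(N),
                 connectivity = connectivity, ridge = ridge,
                 input_scaling = input_scaling),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec>", prod(lengths(unclass(x))), "combinations\n")
  for (nm in names(x))
    cat(" ", nm, ":", paste(x[[nm]], collapse = ", "), "\n")
  invisible(x)
}

#' Leave-one-unit-out cross-validated NRMSE
#'
#' For each unit in turn: the readout is ridge-fit on the stacked
#' post-washout states of all *other* units, the held-out unit is
#' predicted, and its NRMSE (on the original target scale) recorded. The
#' reservoir itself is fixed across folds (it is never trained). Returns
#' the mean NRMSE over folds.
#'
#' @param panel a [feature_panel()] with at least 2 units.
#' @param input_feature,target_feature the direction being tuned.
#' @param config a [reservoir_config()].
#' @param tau lag at which the direction is tuned (default 0:
#'   contemporaneous prediction).
#' @param interpolate fill interior missing days before fitting.
#' @return mean NRMSE (numeric scalar) with attribute `folds`, the
#'   per-unit values.
#' @export
loocv_nrmse <- function(panel, input_feature, target_feature,
                        config = reservoir_config(), tau = 0,
                        interpolate = TRUE) {
  stopifnot(inherits(panel, "feature_panel"))
  units <- panel_units(panel)
  if (length(units) < 2L)
    stop("leave-one-unit-out cross-validation needs at least 2 units")
  res <- build_reservoir(config)
  prep <- lapply(units, function(u) {
    xi <- panel_series(panel, u, input_feature, interpolate = interpolate)
    yi <- panel_series(panel, u, target_feature, interpolate = interpolate)
    al <- align_lagged(xi, yi, tau)
    xs <- if (config$standardize) standardize(al$input) else
      list(z = al$input, mean = 0, sd = 1)
    ys <- if (config$standardize) standardize(al$target) else
      list(z = al$target, mean = 0, sd = 1)
    st <- run_states(res, xs$z)
    keep <- seq_len(nrow(st)) > attr(st, "washout")
    list(U = st[keep, , drop = FALSE], z = ys$z[keep],
         y = al$target[keep], y_mean = ys$mean, y_sd = ys$sd)
  })
  folds <- vapply(seq_along(units), function(i) {
    U_tr <- do.call(rbind, lapply(prep[-i], `[[`, "U"))
    z_tr <- unlist(lapply(prep[-i], `[[`, "z"), use.names = FALSE)
    ro <- fit_readout(structure(U_tr, washout = 0L), z_tr,
                      ridge = config$ridge)
    ph <- predict_readout(ro, prep[[i]]$U) * prep[[i]]$y_sd +
      prep[[i]]$y_mean
    tryCatch(nrmse(ph, prep[[i]]$y),
             error = function(e)
               stop("fold '", units[i], "': ", conditionMessage(e),
                    call. = FALSE))
  }, numeric(1))
  structure(mean(folds), folds = stats::setNames(folds, units))
}

#' Exhaustive grid search minimizing leave-one-unit-out NRMSE
#'
#' Evaluates every combination of the grid by [loocv_nrmse()]. One
#' reservoir seed is shared across the whole grid so that combinations
#' differ only in their hyperparameters. Ties at the minimum are broken
#' toward the smaller reservoir size N, then the smaller spectral radius
#' (the cheaper, safer model).
#'
#' @param panel a [feature_panel()].
#' @param input_feature,target_feature the direction being tuned.
#' @param grid a [grid_spec()].
#' @param tau tuning lag (default 0).
#' @param seed reservoir seed shared by all combinations.
#' @param base_config a [reservoir_config()] supplying the non-searched
#'   values (leak, washout, standardize).
#' @return object of class `tuning_result`: list with `table` (one row per
#'   combination with its mean NRMSE), `best_config` (a reservoir_config)
#'   and the direction tuned. Combinations that fail are recorded with an
#'   NA NRMSE and their error message.
#' @export
grid_search <- function(panel, input_feature, target_feature,
                        grid = grid_spec(), tau = 0, seed = NULL,
                        base_config = reservoir_config()) {
  stopifnot(inherits(grid, "grid_spec"))
  combos <- expand.grid(spectral_radius = grid$spectral_radius,
                        N = grid$N,
                        connectivity = grid$connectivity,
                        ridge = grid$ridge,
                        input_scaling = grid$input_scaling,
                        KEEP.OUT.ATTRS = FALSE)
  nr <- rep(NA_real_, nrow(combos))
  err <- rep(NA_character_, nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- reservoir_config(N = combos$N[i],
                            spectral_radius = combos$spectral_radius[i],
                            leak = base_config$leak,
                            connectivity = combos$connectivity[i],
                            input_scaling = combos$input_scaling[i],
                            raw_scale = base_config$raw_scale,
                            ridge = combos$ridge[i],
                            washout = base_config$washout,
                            seed = seed,
                            standardize = base_config$standardize)
    val <- tryCatch(loocv_nrmse(panel, input_feature, target_feature,
                                cfg, tau = tau),
                    error = function(e) conditionMessage(e))
    if (is.character(val)) err[i] <- val else nr[i] <- as.numeric(val)
  }
  if (all(is.na(nr)))
    stop("every grid combination failed; first error: ",
         err[!is.na(err)][1L])
  combos$nrmse <- nr
  combos$error <- err
  ok <- which(!is.na(nr))
  best <- ok[order(nr[ok], combos$N[ok], combos$spectral_radius[ok])][1L]
  best_config <- reservoir_config(N = combos$N[best],
                                  spectral_radius = combos$spectral_radius[best],
                                  leak = base_config$leak,
                                  connectivity = combos$connectivity[best],
                                  input_scaling = combos$input_scaling[best],
                                  raw_scale = base_config$raw_scale,
                                  ridge = combos$ridge[best],
                                  washout = base_config$washout,
                                  seed = seed,
                                  standardize = base_config$standardize)
  structure(list(table = combos, best_config = best_config, best_row = best,
                 input_feature = input_feature,
                 target_feature = target_feature, tau = tau),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %s -> %s: %d combinations (%d failed)\n",
              x$input_feature, x$target_feature, nrow(x$table),
              sum(is.na(x$table$nrmse))))
  cat(sprintf("  best mean LOOCV NRMSE %.5g at:\n",
              x$table$nrmse[x$best_row]))
  print(x$best_config)
  invisible(x)
}

#' @rdname grid_search
#' @param x a `tuning_result`.
#' @param path output path (CSV for the table, JSON for the best config).
#' @export
write_tuning_table <- function(x, path) {
  stopifnot(inherits(x, "tuning_result"))
  utils::write.csv(x$table[setdiff(names(x$table), "error")], path,
                   row.names = FALSE)
  invisible(path)
}
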