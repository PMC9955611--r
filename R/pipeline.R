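#' Configuration of a full pairwise causal study
#'
#' @param features features to examine pairwise; default the five daily
#'   tweet features (`sentiment`, `tweets`, `like`, `reply`, `retweet`).
#' @param lag_max half-width of the symmetric lag grid `-lag_max:lag_max`
#'   (default 30).
#' @param grid a [grid_spec()] for per-direction tuning, or `NULL` to skip
#'   tuning and use `base_config` everywhere.
#' @param base_config a [reservoir_config()]; supplies leak/washout (and
#'   everything else when `grid` is NULL).
#' @param skill_threshold minimum peak skill for a causal claim.
#' @param seed root seed; all per-task seeds are split from it
#'   deterministically.
#' @param n_seeds reservoir realizations averaged per curve.
#' @return object of class `study_config`.
#' @export
study_config <- function(features = c("sentiment", "tweets", "like",
                                      "reply", "retweet"),
                         lag_max = 30, grid = NULL,
                         base_config = reservoir_config(),
                         skill_threshold = 0.2, seed = 1, n_seeds = 1) {
  stopifnot(length(features) >= 2, !anyDuplicated(features),
            lag_max >= 1, is.null(grid) || inherits(grid, "grid_spec"),
            inherits(base_config, "reservoir_config"))
  structure(list(features = features, lag_max = as.integer(lag_max),
                 grid = grid, base_config = base_config,
                 skill_threshold = skill_threshold, seed = seed,
                 n_seeds = n_seeds),
            class = "study_config")
}

#' Run the full pairwise causal study on a panel
#'
#' For every unordered pair of configured features, both directional
#' cross-map skill curves are computed (optionally after per-direction
#' leave-one-unit-out tuning) and the pair is classified by the peak-lag
#' rules. Returns everything needed to reproduce the summary causal graph.
#'
#' @param panel a [feature_panel()] containing all configured features.
#' @param config a [study_config()].
#' @return object of class `study_report`: list with `pairs` (data.frame),
#'   `curves` (named list of [cross_map_skill()] results, two per pair),
#'   `verdicts` (named list of [classify_direction()] results), `tuned`
#'   (per-direction configs), `config` and `meta` (seed, package version).
#' @examples
#' \donttest{
#' sim <- gen_tweet_panel(n_units = 3, n = 120, seed = 1)
#' cfg <- study_config(features = c("sentiment", "like"), lag_max = 10,
#'                     base_config = reservoir_config(N = 30), seed = 1)
#' rep <- run_study(sim$panel, cfg)
#' rep
#' }
#' @export
run_study <- function(panel, config = study_config()) {
  stopifnot(inherits(panel, "feature_panel"),
            inherits(config, "study_config"))
  feats <- config$features
  missing_f <- setdiff(feats, panel_features(panel))
  if (length(missing_f))
    stop("panel lacks feature(s): ", paste(missing_f, collapse = ", "))
  lags <- -config$lag_max:config$lag_max
  pairs <- utils::combn(feats, 2L)
  multi_unit <- length(panel_units(panel)) >= 2L

  curves <- list(); verdicts <- list(); tuned <- list()
  failures <- list()
  task <- 0L
  pair_rows <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    x_name <- pairs[1L, p]; y_name <- pairs[2L, p]
    pair_id <- paste(x_name, y_name, sep = ":")
    result <- tryCatch({
      dir_curve <- function(input, target) {
        task <<- task + 1L
        dir_id <- paste(input, target, sep = "->")
        cfg <- if (!is.null(config$grid) && multi_unit) {
          if (is.null(tuned[[dir_id]])) {
            ts <- grid_search(panel, input, target, grid = config$grid,
                              tau = 0, seed = split_seed(config$seed, task),
                              base_config = config$base_config)
            tuned[[dir_id]] <<- ts$best_config
          }
          tuned[[dir_id]]
        } else config$base_config
        cfg$seed <- split_seed(config$seed, 1000L + task)
        cross_map_skill(panel, input, target, cfg, lags = lags,
                        n_seeds = config$n_seeds)
      }
      curve_x <- dir_curve(y_name, x_name)  # rho_x: probes "x causes y"
      curve_y <- dir_curve(x_name, y_name)  # rho_y: probes "y causes x"
      v <- classify_direction(curve_x, curve_y,
                              skill_threshold = config$skill_threshold)
      list(curve_x = curve_x, curve_y = curve_y, verdict = v)
    }, error = function(e) e)
    if (inherits(result, "error")) {
      failures[[pair_id]] <- conditionMessage(result)
      pair_rows[[p]] <- data.frame(x = x_name, y = y_name,
                                   verdict = "failed",
                                   peak_lag_x = NA_integer_,
                                   peak_lag_y = NA_integer_,
                                   peak_rho_x = NA_real_,
                                   peak_rho_y = NA_real_)
      next
    }
    curves[[paste0(y_name, "->", x_name)]] <- result$curve_x
    curves[[paste0(x_name, "->", y_name)]] <- result$curve_y
    verdicts[[pair_id]] <- result$verdict
    v <- result$verdict
    pair_rows[[p]] <- data.frame(x = x_name, y = y_name,
                                 verdict = v$verdict,
                                 peak_lag_x = v$peak_lag_x,
                                 peak_lag_y = v$peak_lag_y,
                                 peak_rho_x = v$peak_rho_x,
                                 peak_rho_y = v$peak_rho_y)
  }
  structure(list(pairs = do.call(rbind, pair_rows), curves = curves,
                 verdicts = verdicts, tuned = tuned, failures = failures,
                 config = config,
                 meta = list(seed = config$seed,
                             package_version =
                               as.character(utils::packageVersion("esnccm")))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d pairs, %d curves (root seed %s)\n",
              nrow(x$pairs), length(x$curves), format(x$meta$seed)))
  print(x$pairs, row.names = FALSE)
  if (length(x$failures))
    cat("  failed pairs:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Directed edges of the verdict graph
#'
#' @param report a [run_study()] report.
#' @return data.frame with columns `from`, `to`, `peak_lag` — one row per
#'   claimed causal direction (bidirectional verdicts yield two rows).
#' @export
verdict_edges <- function(report) {
  stopifnot(inherits(report, "study_report"))
  rows <- list()
  for (v in report$verdicts) {
    xn <- v$pair[["x"]]; yn <- v$pair[["y"]]
    if (v$verdict %in% c("x_causes_y", "bidirectional"))
      rows[[length(rows) + 1L]] <-
        data.frame(from = xn, to = yn, peak_lag = v$peak_lag_x)
    if (v$verdict %in% c("y_causes_x", "bidirectional"))
      rows[[length(rows) + 1L]] <-
        data.frame(from = yn, to = xn, peak_lag = v$peak_lag_y)
  }
  if (!length(rows))
    return(data.frame(from = character(), to = character(),
                      peak_lag = integer()))
  do.call(rbind, rows)
}

#' @export
plot.study_report <- function(x, ...) {
  edges <- verdict_edges(x)
  if (!requireNamespace("igraph", quietly = TRUE)) {
    warning("package 'igraph' not available; plotting skill curves instead")
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(x$curves)))
    on.exit(graphics::par(old))
    for (cv in x$curves) plot(cv)
    return(invisible(x))
  }
  g <- igraph::graph_from_data_frame(
    edges, vertices = data.frame(name = x$config$features))
  plot(g, main = "Summary of causal relationships", ...)
  invisible(x)
}

#' Serialize a study report to a directory
#'
#' Writes `curves.csv` (pair/direction/lag/skill), `verdicts.json`,
#' `edges.csv` (the verdict graph) and `tuned_configs.json`. Output is
#' deterministic: identical reports produce byte-identical files.
#'
#' @param report a [run_study()] report.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_curves(report$curves, file.path(dir, "curves.csv"))
  vs <- lapply(report$verdicts, function(v)
    list(x = v$pair[["x"]], y = v$pair[["y"]], verdict = v$verdict,
         peak_lag_x = v$peak_lag_x, peak_lag_y = v$peak_lag_y,
         peak_rho_x = v$peak_rho_x, peak_rho_y = v$peak_rho_y,
         skill_threshold = v$skill_threshold_used))
  jsonlite::write_json(vs, file.path(dir, "verdicts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(verdict_edges(report), file.path(dir, "edges.csv"),
                   row.names = FALSE, quote = FALSE)
  cfgs <- lapply(report$tuned, function(cfg)
    cfg[c("N", "spectral_radius", "leak", "connectivity", "input_scaling",
          "ridge", "washout")])
  jsonlite::write_json(cfgs, file.path(dir, "tuned_configs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
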