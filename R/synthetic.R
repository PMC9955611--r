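#' Coupling specification for the coupled logistic-map system
#'
#' Describes the causal structure of a pair of chaotic logistic maps, the
#' standard benchmark system for cross-map causality detection. The maps
#' evolve as
#' \deqn{x_{t+1} = x_t (r_x - r_x x_t - \beta_{xy} y_{t-d})}
#' \deqn{y_{t+1} = y_t (r_y - r_y y_t - \beta_{yx} x_{t-d})}
#' where \eqn{\beta_{yx} > 0} makes x a cause of y (x enters y's update) and
#' \eqn{\beta_{xy} > 0} makes y a cause of x; d is a coupling delay in time
#' steps.
#'
#' @param kind causal structure; one of `"none"`, `"x_to_y"`, `"y_to_x"`,
#'   `"bidirectional"`.
#' @param strength_xy effect of y on x (\eqn{\beta_{xy}}); `NULL` picks 0.32
#'   when the structure requires it, 0 otherwise.
#' @param strength_yx effect of x on y (\eqn{\beta_{yx}}); same default rule.
#' @param delay nonnegative integer coupling delay d (time steps).
#' @param growth_x,growth_y logistic growth rates; defaults 3.8 and 3.5 put
#'   both maps in the chaotic regime.
#' @param noise_sd standard deviation of additive Gaussian observation noise.
#' @return an object of class `coupling_spec`.
#' @examples
#' coupling_spec("x_to_y", delay = 2)
#' @export
coupling_spec <- function(kind = c("none", "x_to_y", "y_to_x", "bidirectional"),
                          strength_xy = NULL, strength_yx = NULL,
                          delay = 0L, growth_x = 3.8, growth_y = 3.5,
                          noise_sd = 0) {
  kind <- match.arg(kind)
  default_strength <- 0.32
  if (is.null(strength_xy))
    strength_xy <- if (kind %in% c("y_to_x", "bidirectional")) default_strength else 0
  if (is.null(strength_yx))
    strength_yx <- if (kind %in% c("x_to_y", "bidirectional")) default_strength else 0
  stopifnot(strength_xy >= 0, strength_yx >= 0, delay >= 0,
            growth_x > 0, growth_y > 0, noise_sd >= 0)
  ok <- switch(kind,
    none          = strength_xy == 0 && strength_yx == 0,
    x_to_y        = strength_yx > 0 && strength_xy == 0,
    y_to_x        = strength_xy > 0 && strength_yx == 0,
    bidirectional = strength_xy > 0 && strength_yx > 0)
  if (!ok)
    stop("coupling strengths are inconsistent with kind = '", kind,
         "' (x_to_y needs strength_yx > 0 and strength_xy = 0, etc.)")
  structure(list(kind = kind, strength_xy = strength_xy,
                 strength_yx = strength_yx, delay = as.integer(delay),
                 growth_x = growth_x, growth_y = growth_y,
                 noise_sd = noise_sd),
            class = "coupling_spec")
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf(
    "<coupling_spec> kind=%s  b_xy=%.3g  b_yx=%.3g  delay=%d  r=(%.2f, %.2f)  noise_sd=%.3g\n",
    x$kind, x$strength_xy, x$strength_yx, x$delay, x$growth_x, x$growth_y,
    x$noise_sd))
  invisible(x)
}

# One step of the coupled map; exposed internally so tests can recompute the
# recursion independently of the generator loop.
logistic_step <- function(x, y, x_lag, y_lag, spec) {
  c(x * (spec$growth_x - spec$growth_x * x - spec$strength_xy * y_lag),
    y * (spec$growth_y - spec$growth_y * y - spec$strength_yx * x_lag))
}

#' Simulate coupled chaotic logistic maps with known causal structure
#'
#' Generates two series `x`, `y` from the system described by a
#' [coupling_spec()], discards a burn-in transient, optionally adds Gaussian
#' observation noise, and returns both a [feature_panel()] (single unit
#' `"sim"`, features `"x"` and `"y"`, consecutive calendar days) and the
#' generating [ground_truth()] graph.
#'
#' Values are kept inside the open unit interval by clipping to
#' (1e-6, 1 - 1e-6); more than 10 consecutive clipped steps signals a
#' divergent parameterization and raises an error.
#'
#' @param spec a [coupling_spec()].
#' @param n length of the returned series (post burn-in); at least 200.
#' @param burn_in transient steps discarded; at least 100.
#' @param seed integer seed; fixed seed gives bit-identical panels.
#' @param start_date first calendar day of the synthesized panel.
#' @return list with elements `panel` (feature_panel), `truth`
#'   (ground_truth), `x`, `y` (numeric vectors of length `n`).
#' @examples
#' sim <- gen_coupled_logistic(coupling_spec("x_to_y"), n = 400, seed = 7)
#' sim$truth
#' @export
gen_coupled_logistic <- function(spec, n = 1000, burn_in = 200, seed = NULL,
                                 start_date = as.Date("2020-02-24")) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (n < 200) stop("n must be at least 200")
  if (burn_in < 100) stop("burn_in must be at least 100")
  if (n <= spec$delay) stop("series length must exceed the coupling delay")
  total <- n + burn_in
  eps <- 1e-6
  with_seed(seed, {
    x <- numeric(total); y <- numeric(total)
    x[1] <- stats::runif(1, 0.2, 0.8)
    y[1] <- stats::runif(1, 0.2, 0.8)
    clip_run <- 0L
    for (t in seq_len(total - 1L)) {
      lag_t <- max(1L, t - spec$delay)
      nxt <- logistic_step(x[t], y[t], x[lag_t], y[lag_t], spec)
      clipped <- nxt < eps | nxt > 1 - eps
      nxt <- pmin(pmax(nxt, eps), 1 - eps)
      clip_run <- if (any(clipped)) clip_run + 1L else 0L
      if (clip_run > 10L)
        stop("trajectory left (0, 1) for more than 10 consecutive steps; ",
             "coupling too strong for the chosen growth rates")
      x[t + 1L] <- nxt[1]; y[t + 1L] <- nxt[2]
    }
    x <- x[(burn_in + 1L):total]
    y <- y[(burn_in + 1L):total]
    if (spec$noise_sd > 0) {
      x <- pmin(pmax(x + stats::rnorm(n, 0, spec$noise_sd), eps), 1 - eps)
      y <- pmin(pmax(y + stats::rnorm(n, 0, spec$noise_sd), eps), 1 - eps)
    }
    edges <- NULL
    if (spec$strength_yx > 0)
      edges <- rbind(edges, data.frame(from = "x", to = "y",
                                       delay = spec$delay))
    if (spec$strength_xy > 0)
      edges <- rbind(edges, data.frame(from = "y", to = "x",
                                       delay = spec$delay))
    dates <- seq(start_date, by = "day", length.out = n)
    panel <- feature_panel(data.frame(
      date = rep(dates, 2L),
      unit = "sim",
      feature = rep(c("x", "y"), each = n),
      value = c(x, y)))
    list(panel = panel, truth = ground_truth(edges), x = x, y = y)
  })
}

#' Simulate a multi-city daily tweet-activity panel with known causality
#'
#' Emulates the five-feature structure of a daily tweet panel: a latent
#' bounded sentiment series per unit (a tanh-squashed AR(1), values in
#' \[-1, 1\]) drives four nonnegative integer activity counts (`tweets`,
#' `like`, `reply`, `retweet`) through a log link with a configurable lag,
#' and the counts may mutually excite one another:
#' \deqn{\log \lambda_{c,t} = a_c + b_c \, s_{t-\ell} + \kappa \,
#'   \bar{e}_{-c,t-1} + \sigma \epsilon_{c,t}, \qquad
#'   n_{c,t} = \mathrm{round}(\lambda_{c,t})}
#' where \eqn{\bar e_{-c,t-1}} is the mean centred log count of the other
#' activities on the previous day and \eqn{\kappa} is `activity_coupling`.
#'
#' The returned ground truth has a `sentiment ->` edge to every count
#' (delay = `sentiment_to_activity_lag`) and, when `activity_coupling > 0`,
#' bidirectional delay-1 edges among all count pairs.
#'
#' @param n_units number of units (cities); default 8.
#' @param n days per unit; default 234 (a late-February-to-mid-October
#'   study window).
#' @param sentiment_to_activity_lag nonnegative lag (days) from sentiment to
#'   the counts.
#' @param activity_coupling strength of mutual count excitation (0 disables).
#' @param sentiment_effect log-link coefficient of lagged sentiment on each
#'   count.
#' @param noise_sd lognormal noise s.d. on the count intensities.
#' @param seed integer seed.
#' @param start_date first calendar day.
#' @return list with `panel` (feature_panel with features `sentiment`,
#'   `tweets`, `like`, `reply`, `retweet`) and `truth` (ground_truth).
#' @examples
#' sim <- gen_tweet_panel(n_units = 2, n = 120, seed = 3)
#' sim$panel
#' @export
gen_tweet_panel <- function(n_units = 8, n = 234,
                            sentiment_to_activity_lag = 7,
                            activity_coupling = 0.3,
                            sentiment_effect = 1.2,
                            noise_sd = 0.05, seed = NULL,
                            start_date = as.Date("2020-02-24")) {
  if (n_units < 1) stop("n_units must be at least 1")
  if (n < 100) stop("n must be at least 100")
  if (sentiment_to_activity_lag < 0) stop("lag must be nonnegative")
  lag <- as.integer(sentiment_to_activity_lag)
  counts <- c(tweets = 3.6, like = 5.0, reply = 4.0, retweet = 4.4)
  with_seed(seed, {
    rows <- vector("list", n_units)
    dates <- seq(start_date, by = "day", length.out = n)
    for (u in seq_len(n_units)) {
      # latent sentiment: bounded, autocorrelated, mildly nonlinear
      s <- numeric(n + lag)
      s[1] <- stats::runif(1, -0.3, 0.3)
      innov <- stats::rnorm(n + lag, 0, 0.45)
      for (t in seq_len(n + lag - 1L))
        s[t + 1L] <- tanh(1.05 * s[t] + innov[t + 1L])
      m <- matrix(0, nrow = n, ncol = 4L,
                  dimnames = list(NULL, names(counts)))
      loge <- matrix(0, nrow = n, ncol = 4L)  # centred log counts
      for (t in seq_len(n)) {
        cross <- if (t == 1L) rep(0, 4L) else {
          tot <- sum(loge[t - 1L, ])
          (tot - loge[t - 1L, ]) / 3
        }
        # s is pre-padded by `lag`: the observed sentiment on day t is
        # s[t + lag], so s[t] is the sentiment `lag` days before day t
        eta <- counts + sentiment_effect * s[t] +
          activity_coupling * cross +
          stats::rnorm(4L, 0, noise_sd)
        lam <- exp(eta)
        m[t, ] <- round(lam)
        loge[t, ] <- log1p(m[t, ]) - counts
      }
      unit <- sprintf("city%02d", u)
      sent_obs <- s[(lag + 1L):(n + lag)]
      rows[[u]] <- data.frame(
        date = rep(dates, 5L),
        unit = unit,
        feature = rep(c("sentiment", names(counts)), each = n),
        value = c(sent_obs, as.vector(m)))
    }
    panel <- feature_panel(do.call(rbind, rows))
    edges <- data.frame(from = "sentiment", to = names(counts), delay = lag)
    if (activity_coupling > 0) {
      pairs <- expand.grid(from = names(counts), to = names(counts),
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$from != pairs$to, ]
      pairs$delay <- 1L
      edges <- rbind(edges, pairs)
    }
    list(panel = panel, truth = ground_truth(edges))
  })
}
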