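# Shared fixtures, all generated in code.

table1_stopwords <- c("I", "me", "myself", "during", "before")

# tiny sentiment lexicon in the published dialect (word<TAB>score)
toy_vader <- c(":-)" = 1.3, lmao = 2.0, lol = 2.9, abducted = -2.3,
               abduction = -2.8, agrees = 1.5, alarm = -1.4, amaze = 2.5)

# tiny emotion lexicon: word -> mood labels
toy_nrc <- list(
  abacus = "trust",
  abandon = c("fear", "negative", "sadness"),
  abandoned = "anger",
  accident = c("negative", "sadness", "surprise"),
  accidental = c("fear", "negative", "surprise"))

# a small random tweet-record table with per-tweet scores
make_tweet_records <- function(n = 60, n_units = 2, seed = 1,
                               start = as.Date("2020-03-01"), span = 20) {
  set.seed(seed)
  data.frame(
    text = replicate(n, paste(sample(letters, 5), collapse = "")),
    date = start + sample.int(span, n, replace = TRUE) - 1L,
    unit = sample(paste0("city", seq_len(n_units)), n, replace = TRUE),
    like_count = rpois(n, 3), reply_count = rpois(n, 1),
    retweet_count = rpois(n, 2),
    language = "en", stringsAsFactors = FALSE)
}

# a panel of independent white-noise series (the null system)
make_noise_panel <- function(n = 500, seed = 1, units = "u") {
  set.seed(seed)
  rows <- lapply(units, function(u)
    data.frame(date = rep(seq(as.Date("2020-02-24"), by = "day",
                              length.out = n), 2L),
               unit = u, feature = rep(c("x", "y"), each = n),
               value = stats::rnorm(2L * n)))
  feature_panel(do.call(rbind, rows))
}

# stack independent realizations of one coupled-logistic system as units,
# so leave-one-unit-out tuning has folds to hold out
make_logistic_panel <- function(spec, n_units = 2, n = 500, seed = 1) {
  rows <- lapply(seq_len(n_units), function(u) {
    sim <- gen_coupled_logistic(spec, n = n, seed = seed + 37L * u)
    df <- as.data.frame(sim$panel)
    df$unit <- paste0("run", u)
    df
  })
  feature_panel(do.call(rbind, rows))
}

# a curve object with prescribed peak metadata, for exercising the
# classification rules in isolation
fake_curve <- function(input, target, peak_lag, peak_rho, lags = -30:30) {
  rho <- rep(0, length(lags))
  rho[match(peak_lag, lags)] <- peak_rho
  structure(data.frame(lag = lags, rho = rho),
            class = c("cross_map_curve", "data.frame"),
            peak_lag = peak_lag, peak_rho = peak_rho,
            prominence = peak_rho,
            input_feature = input, target_feature = target,
            tested_cause = target)
}

# independent ridge solve: augmented least squares via QR, a different
# route than the normal equations used by fit_readout
ridge_oracle <- function(U, y, alpha) {
  Ua <- rbind(U, sqrt(alpha) * diag(ncol(U)))
  ya <- c(y, rep(0, ncol(U)))
  as.numeric(qr.coef(qr(Ua), ya))
}
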