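test_that("clean_text applies the URL, symbol, punctuation and stop-word rules", {
  expect_equal(clean_text("I adore this #mask during winter @dr",
                          stopwords = table1_stopwords),
               c("adore", "this", "mask", "winter", "dr"))
  expect_equal(clean_text(""), character())
  expect_equal(clean_text(NA_character_), character())
  # every token is a URL, a junk character run, or punctuation
  expect_equal(clean_text("https://t.co/xyz ** $$ ,,"), character())
  expect_equal(clean_text("SSS ** = $ & , () ; - ~"), character())
  expect_equal(clean_text("Covid-19 cases UP!! www.who.int #stayhome"),
               c("covid", "19", "cases", "up", "stayhome"))
})

test_that("clean_text is idempotent on fuzzed strings", {
  set.seed(42)
  alphabet <- c(letters, LETTERS, 0:9, strsplit("#@$&*(),;:!?~-_'\"/ ", "")[[1]],
                " ", " ", "https://x.io/a?b=1", "#tag", "@who", "SSS")
  for (i in 1:200) {
    raw <- paste(sample(alphabet, sample(1:40, 1), replace = TRUE),
                 collapse = "")
    t1 <- clean_text(raw, stopwords = table1_stopwords)
    t2 <- clean_text(paste(t1, collapse = " "),
                     stopwords = table1_stopwords)
    expect_identical(t2, t1)
  }
})

test_that("filter_language keeps only the requested tag, order preserved", {
  rec <- data.frame(text = c("a", "b", "c"), language = c("en", "fr", "en"))
  expect_equal(nrow(filter_language(rec, "en")), 2L)
  expect_equal(filter_language(rec, "en")$text, c("a", "c"))
  expect_identical(filter_language(rec[rec$language == "en", ], "en")$text,
                   c("a", "c"))
  expect_equal(nrow(filter_language(rec[0, ], "en")), 0L)
  rec$language[2] <- NA
  expect_warning(out <- filter_language(rec, "en"), "dropped")
  expect_equal(nrow(out), 2L)
})

test_that("mean_lexicon_score divides the lexicon sum by the token count", {
  expect_equal(mean_lexicon_score(c("lol", "abducted"), toy_vader), 0.3)
  expect_equal(mean_lexicon_score(c("zzz", "qqq"), toy_vader), 0)
  out <- mean_lexicon_score(character(), toy_vader)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "no_content"))
  # brute-force dictionary oracle on random token lists
  set.seed(7)
  words <- c(names(toy_vader), "covid", "mask", "city")
  for (i in 1:25) {
    toks <- sample(words, sample(1:12, 1), replace = TRUE)
    oracle <- sum(vapply(toks, function(w)
      if (w %in% names(toy_vader)) toy_vader[[w]] else 0,
      numeric(1))) / length(toks)
    expect_equal(as.numeric(mean_lexicon_score(toks, toy_vader)), oracle)
    expect_lte(abs(mean_lexicon_score(toks, toy_vader)),
               max(abs(toy_vader)))
  }
})

test_that("emotion_frequencies counts mood annotations over total tokens", {
  out <- emotion_frequencies(c("abandon", "abandon"), toy_nrc)
  expect_equal(out[["fear"]], 1)
  expect_equal(out[["negative"]], 1)
  expect_equal(out[["sadness"]], 1)
  expect_equal(sum(out), 3)
  expect_equal(as.numeric(emotion_frequencies(c("zzz", "qqq"), toy_nrc)),
               rep(0, 10))
  empty <- emotion_frequencies(character(), toy_nrc)
  expect_true(attr(empty, "no_content"))
  expect_equal(as.numeric(empty), rep(0, 10))
  # counting oracle on random token lists; components always in [0, 1]
  set.seed(8)
  words <- c(names(toy_nrc), "covid", "mask")
  for (i in 1:25) {
    toks <- sample(words, sample(1:10, 1), replace = TRUE)
    out <- emotion_frequencies(toks, toy_nrc)
    expect_true(all(out >= 0 & out <= 1))
    for (mood in c("fear", "trust", "surprise")) {
      oracle <- sum(vapply(toks, function(w)
        !is.null(toy_nrc[[w]]) && mood %in% toy_nrc[[w]], logical(1))) /
        length(toks)
      expect_equal(out[[mood]], oracle)
    }
  }
  expect_error(emotion_frequencies("a", list(a = "happiness")), "unknown")
})

test_that("lexicon TSV readers parse the published dialects", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("lol\t2.9", "Abducted\t-2.3"), f)
  lex <- read_sentiment_lexicon(f)
  expect_equal(lex[["abducted"]], -2.3)
  g <- tempfile(fileext = ".tsv")
  writeLines(c("abandon\tfear\t1", "abandon\tjoy\t0", "abandon\tsadness\t1"),
             g)
  elex <- read_emotion_lexicon(g)
  expect_setequal(elex[["abandon"]], c("fear", "sadness"))
  unlink(c(f, g))
})

test_that("aggregate_daily computes the five features and conserves totals", {
  rec <- data.frame(
    text = letters[1:3], date = as.Date("2020-03-01"), unit = "toronto",
    like_count = 1:3, reply_count = c(0L, 1L, 0L),
    retweet_count = c(2L, 0L, 1L), language = "en")
  panel <- aggregate_daily(rec, scores = c(0.1, 0.2, 0.3))
  get <- function(f) panel$value[panel$feature == f]
  expect_equal(get("sentiment"), 0.2)
  expect_equal(get("tweets"), 3)
  expect_equal(get("like"), 6)
  expect_equal(get("reply"), 1)
  expect_equal(get("retweet"), 3)
  # single tweet keeps its own score
  one <- aggregate_daily(rec[2, ], scores = 0.7)
  expect_equal(one$value[one$feature == "sentiment"], 0.7)
  # random fixture vs an independent group-by oracle; totals conserved
  rec2 <- make_tweet_records(n = 80, n_units = 2, seed = 3)
  sc <- stats::runif(80, -1, 1)
  p2 <- aggregate_daily(rec2, sc)
  expect_equal(sum(p2$value[p2$feature == "like"], na.rm = TRUE),
               sum(rec2$like_count))
  expect_equal(sum(p2$value[p2$feature == "tweets"], na.rm = TRUE),
               nrow(rec2))
  key <- paste(rec2$unit, rec2$date)
  oracle_sent <- tapply(sc, key, mean)
  for (k in sample(names(oracle_sent), 10)) {
    u <- sub(" .*", "", k); d <- as.Date(sub(".* ", "", k))
    got <- p2$value[p2$feature == "sentiment" & p2$unit == u & p2$date == d]
    expect_equal(got, unname(oracle_sent[[k]]))
  }
})

test_that("days without tweets appear as explicit missing values", {
  rec <- data.frame(text = c("a", "b"),
                    date = as.Date(c("2020-03-01", "2020-03-04")),
                    unit = "u", like_count = 1L, reply_count = 0L,
                    retweet_count = 0L, language = "en")
  panel <- aggregate_daily(rec, scores = c(0, 0))
  tw <- panel[panel$feature == "tweets", ]
  expect_equal(nrow(tw), 4L)
  expect_true(all(is.na(tw$value[tw$date %in%
                                   as.Date(c("2020-03-02", "2020-03-03"))])))
})

test_that("period_descriptives stratifies tweet-wise statistics", {
  rec <- make_tweet_records(n = 120, n_units = 2, seed = 5, span = 30)
  sc <- stats::rnorm(120, 0, 0.5)
  b <- as.Date(c("2020-03-11", "2020-03-21"))
  out <- period_descriptives(rec, sc, b)
  expect_equal(nrow(out), 2L * 3L)
  # stratified-statistics oracle
  for (i in seq_len(nrow(out))) {
    lo <- c(min(rec$date), b)[out$period[i]]
    hi <- c(b, max(rec$date) + 1)[out$period[i]]
    sel <- rec$unit == out$unit[i] & rec$date >= lo & rec$date < hi
    if (!any(sel)) {
      expect_true(is.na(out$mean_score[i]))
    } else {
      expect_equal(out$mean_score[i], mean(sc[sel]))
      expect_equal(out$sd_score[i], stats::sd(sc[sel]))
      expect_equal(out$avg_daily_tweets[i],
                   sum(sel) / as.integer(hi - lo))
    }
  }
  # constant scores give zero s.d.; one period spanning everything gives
  # the global statistics
  outc <- period_descriptives(rec, rep(0.4, 120), b)
  expect_true(all(outc$sd_score[!is.na(outc$sd_score)] == 0))
  g <- period_descriptives(rec[rec$unit == "city1", ],
                           sc[rec$unit == "city1"],
                           min(rec$date) + 15)
  expect_equal(sum(g$avg_daily_tweets * c(15, as.integer(max(rec$date) -
                                                           min(rec$date)) - 14)),
               sum(rec$unit == "city1"))
  expect_error(period_descriptives(rec, sc, min(rec$date)), "inside")
})
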