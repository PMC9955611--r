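#' Clean raw tweet text into a token list
#'
#' Applies the standard social-media cleaning rules: URLs are removed
#' entirely; the hashtag and at-sign symbols are stripped while the attached
#' word is kept; punctuation is removed; text is lowercased and split on
#' whitespace; stop-words and configured junk tokens are dropped.
#'
#' Cleaning is idempotent: re-cleaning the pasted token list returns the
#' same tokens.
#'
#' @param raw a character scalar (one tweet). `NA` is treated as empty.
#' @param stopwords character vector of stop-words (matched
#'   case-insensitively against cleaned tokens).
#' @param junk_tokens alphanumeric junk tokens to drop after cleaning
#'   (non-alphanumeric "meaningless characters" such as `**` or `$` are
#'   already removed by the punctuation rule). Matched case-insensitively.
#' @return character vector of tokens (possibly empty).
#' @examples
#' clean_text("I adore this #mask during winter @dr",
#'            stopwords = c("I", "me", "myself", "during", "before"))
#' @export
clean_text <- function(raw, stopwords = character(),
                       junk_tokens = c("sss")) {
  if (length(raw) != 1L) stop("clean_text takes one string at a time")
  if (is.na(raw) || !nzchar(raw)) return(character())
  x <- tolower(raw)
  x <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x)
  # strip # and @ but keep the attached word; then drop remaining
  # punctuation/symbols (apostrophes inside words survive)
  x <- gsub("[#@]", "", x)
  x <- gsub("[^[:alnum:]'[:space:]]", " ", x)
  x <- gsub("'+", "'", x)
  tokens <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  tokens <- gsub("^'+|'+$", "", tokens)
  tokens <- tokens[nzchar(tokens)]
  drop <- c(tolower(stopwords), tolower(junk_tokens))
  tokens[!(tokens %in% drop)]
}

#' Keep only records in one language
#'
#' @param records data.frame of tweet records with a `language` column.
#' @param keep language tag to retain (default `"en"`).
#' @return the filtered data.frame, order preserved. Records with a missing
#'   tag are dropped with a warning.
#' @export
filter_language <- function(records, keep = "en") {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) return(records)
  if (!"language" %in% names(records))
    stop("records have no 'language' column")
  tag <- as.character(records$language)
  missing_tag <- is.na(tag) | !nzchar(tag)
  if (any(missing_tag))
    warning(sum(missing_tag), " record(s) without a language tag were dropped")
  records[!missing_tag & tag == keep, , drop = FALSE]
}

#' Mean lexicon sentiment score of a token list
#'
#' The tweet-level score is the sum of the lexicon scores of its tokens
#' divided by the total number of tokens. Tokens absent from the lexicon
#' contribute 0 to the numerator but still count in the denominator.
#'
#' @param tokens character vector from [clean_text()].
#' @param lexicon a named numeric vector (word -> score), e.g. from
#'   [read_sentiment_lexicon()].
#' @return a numeric scalar. An empty token list scores 0 and carries
#'   attribute `no_content = TRUE`.
#' @examples
#' lex <- c(lol = 2.9, abducted = -2.3)
#' mean_lexicon_score(c("lol", "abducted"), lex)  # 0.3
#' @export
mean_lexicon_score <- function(tokens, lexicon) {
  stopifnot(is.numeric(lexicon), !is.null(names(lexicon)),
            all(is.finite(lexicon)))
  if (!length(tokens))
    return(structure(0, no_content = TRUE))
  hits <- lexicon[tolower(tokens)]
  hits[is.na(hits)] <- 0
  sum(hits) / length(tokens)
}

# the fixed 10-label mood set, in the conventional order
nrc_moods <- function() {
  c("anticipation", "positive", "negative", "sadness", "disgust",
    "joy", "anger", "surprise", "fear", "trust")
}

#' Per-mood emotion frequencies of a token list
#'
#' For each of the 10 moods (anticipation, positive, negative, sadness,
#' disgust, joy, anger, surprise, fear, trust) returns the count of tokens
#' annotated with that mood divided by the total token count.
#'
#' @param tokens character vector from [clean_text()].
#' @param lexicon a named list (word -> character vector of moods), e.g.
#'   from [read_emotion_lexicon()].
#' @return named numeric vector of length 10, each component in \[0, 1\].
#'   Empty token lists give the zero vector with attribute
#'   `no_content = TRUE`.
#' @examples
#' lex <- list(abandon = c("fear", "negative", "sadness"))
#' emotion_frequencies(c("abandon", "abandon"), lex)
#' @export
emotion_frequencies <- function(tokens, lexicon) {
  stopifnot(is.list(lexicon))
  moods <- nrc_moods()
  bad <- setdiff(unique(unlist(lexicon, use.names = FALSE)), moods)
  if (length(bad))
    stop("lexicon contains unknown mood label(s): ",
         paste(bad, collapse = ", "))
  out <- stats::setNames(numeric(10L), moods)
  if (!length(tokens)) {
    attr(out, "no_content") <- TRUE
    return(out)
  }
  ann <- lexicon[tolower(tokens)]
  tab <- table(factor(unlist(ann, use.names = FALSE), levels = moods))
  out[] <- as.numeric(tab) / length(tokens)
  out
}

#' Read a sentiment lexicon (word<TAB>score)
#'
#' @param path TSV file, two columns, no header: word and numeric score.
#' @return named numeric vector; word lookup keys are lowercased.
#' @export
read_sentiment_lexicon <- function(path) {
  df <- utils::read.delim(path, header = FALSE, quote = "",
                          col.names = c("word", "score"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$score, tolower(df$word))
}

#' Read an emotion lexicon in the published NRC dialect
#'
#' @param path TSV file, three columns, no header: word, emotion label and a
#'   0/1 association flag. Only flagged rows are kept.
#' @return named list mapping each word (lowercased) to its mood labels.
#' @export
read_emotion_lexicon <- function(path) {
  df <- utils::read.delim(path, header = FALSE, quote = "",
                          col.names = c("word", "emotion", "flag"),
                          colClasses = c("character", "character", "integer"))
  df <- df[df$flag == 1L, , drop = FALSE]
  bad <- setdiff(unique(df$emotion), nrc_moods())
  if (length(bad))
    stop("unknown emotion label(s) in '", path, "': ",
         paste(bad, collapse = ", "))
  split(df$emotion, tolower(df$word))
}

#' Read tweet records from CSV or JSON-lines
#'
#' Expected fields: `text`, `date`, `unit`, `like_count`, `reply_count`,
#' `retweet_count`, `language`.
#'
#' @param path input file; `.json`/`.jsonl` is parsed as JSON-lines,
#'   anything else as CSV.
#' @return data.frame of tweet records.
#' @export
read_tweets <- function(path) {
  df <- if (grepl("\\.jsonl?$", path)) {
    jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("text", "date", "unit", "like_count", "reply_count",
            "retweet_count", "language")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("tweet table '", path, "' is missing field(s): ",
         paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  for (cn in c("like_count", "reply_count", "retweet_count")) {
    df[[cn]] <- as.integer(df[[cn]])
    if (any(df[[cn]] < 0, na.rm = TRUE)) stop(cn, " contains negative values")
  }
  df
}

#' Aggregate scored tweets into the daily feature panel
#'
#' Produces, per unit per day, the five study features: mean tweet-wise
#' sentiment score (`sentiment`), number of tweets (`tweets`) and summed
#' `like`, `reply` and `retweet` counts. Days inside a unit's observed date
#' range with no tweets appear as explicit missing values.
#'
#' @param records data.frame of tweet records (see [read_tweets()]).
#' @param scores numeric vector of per-tweet sentiment scores, aligned with
#'   `records` rows.
#' @return a [feature_panel()].
#' @export
aggregate_daily <- function(records, scores) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            length(scores) == nrow(records))
  records$date <- as.Date(records$date)
  df <- data.frame(unit = as.character(records$unit), date = records$date,
                   score = as.numeric(scores), one = 1,
                   like = records$like_count, reply = records$reply_count,
                   retweet = records$retweet_count)
  sums <- stats::aggregate(cbind(one, like, reply, retweet) ~ unit + date,
                           data = df, FUN = sum)
  means <- stats::aggregate(score ~ unit + date, data = df, FUN = mean)
  out <- merge(sums, means, by = c("unit", "date"))
  names(out)[names(out) == "one"] <- "tweets"
  names(out)[names(out) == "score"] <- "sentiment"
  # explicit NA rows for covered-but-silent days, per unit
  full <- do.call(rbind, lapply(split(out, out$unit), function(d) {
    days <- seq(min(d$date), max(d$date), by = "day")
    m <- d[match(days, d$date), , drop = FALSE]
    m$unit <- d$unit[1]; m$date <- days
    m
  }))
  long <- stats::reshape(full, direction = "long",
                         varying = c("sentiment", "tweets", "like", "reply",
                                     "retweet"),
                         v.names = "value", timevar = "feature",
                         times = c("sentiment", "tweets", "like", "reply",
                                   "retweet"))
  feature_panel(long[c("date", "unit", "feature", "value")])
}

#' Period-stratified descriptive statistics of a scored tweet table
#'
#' For each unit and period, reports the average number of daily tweets and
#' the mean and standard deviation of the tweet-wise sentiment scores.
#'
#' @param records data.frame of tweet records.
#' @param scores per-tweet sentiment scores aligned with `records`.
#' @param boundaries Dates cutting the study window into consecutive
#'   periods: a window \[d1, d2\] with boundaries (b1, b2) yields periods
#'   \[d1, b1), \[b1, b2), \[b2, d2\].
#' @return data.frame with columns `unit`, `period`, `avg_daily_tweets`,
#'   `mean_score`, `sd_score`. Units with no tweets in a period get an NA
#'   row.
#' @export
period_descriptives <- function(records, scores, boundaries) {
  stopifnot(is.data.frame(records), length(scores) == nrow(records))
  records$date <- as.Date(records$date)
  boundaries <- sort(as.Date(boundaries))
  d0 <- min(records$date); d1 <- max(records$date)
  if (any(boundaries <= d0) || any(boundaries > d1))
    stop("period boundaries must lie strictly inside the observed date range")
  breaks <- c(d0, boundaries, d1 + 1L)
  records$period <- cut(records$date, breaks = breaks, right = FALSE,
                        labels = seq_len(length(breaks) - 1L))
  # calendar days per period (denominator of the daily average)
  ndays <- as.integer(diff(breaks))
  units <- sort(unique(records$unit))
  grid <- expand.grid(unit = units,
                      period = seq_len(length(breaks) - 1L),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- records$unit == grid$unit[i] &
      as.integer(records$period) == grid$period[i]
    s <- scores[sel]
    data.frame(unit = grid$unit[i], period = grid$period[i],
               avg_daily_tweets = if (any(sel))
                 sum(sel) / ndays[grid$period[i]] else NA_real_,
               mean_score = if (any(sel)) mean(s) else NA_real_,
               sd_score = if (any(sel)) stats::sd(s) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$period, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}
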