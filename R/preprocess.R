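#' Trial-table validation
#'
#' A trial table is a long-format data.frame of lexical-decision trials with
#' columns: `participant`, `group` (`EB` early blind / `SC` sighted control),
#' `stimulus`, `type` (`abstract` / `multimodal` / `visual`; `NA` allowed for
#' pseudowords), `lexicality` (`word` / `pseudoword`), `presentation`
#' (1 or 2), `accuracy` (`correct` / `incorrect`, or logical / 0-1),
#' `rt` (ms, > 0) and `duration` (stimulus audio length, ms, > 0).
#'
#' @param trials a data.frame.
#' @return `trials`, invisibly, after checks.
#' @export
validate_trials <- function(trials) {
  needed <- c("participant", "group", "stimulus", "lexicality", "accuracy",
              "rt", "duration")
  miss <- setdiff(needed, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!trials$group %in% c("EB", "SC")))
    stop("group must be 'EB' or 'SC'", call. = FALSE)
  if (any(!trials$lexicality %in% c("word", "pseudoword")))
    stop("lexicality must be 'word' or 'pseudoword'", call. = FALSE)
  if (any(!is.finite(trials$rt)) || any(trials$rt <= 0))
    stop("rt must be positive (ms)", call. = FALSE)
  if (any(!is.finite(trials$duration)) || any(trials$duration <= 0))
    stop("duration must be positive (ms)", call. = FALSE)
  if ("presentation" %in% names(trials)) {
    key <- paste(trials$participant, trials$stimulus, trials$lexicality,
                 trials$presentation)
    if (anyDuplicated(key))
      stop("duplicate (participant, stimulus, presentation) trials", call. = FALSE)
  }
  invisible(trials)
}

# accuracy column -> logical is-correct
is_correct <- function(acc) {
  if (is.logical(acc)) return(acc)
  if (is.numeric(acc)) return(acc > 0)
  acc <- as.character(acc)
  bad <- setdiff(unique(acc), c("correct", "incorrect"))
  if (length(bad))
    stop("accuracy values not understood: ", paste(bad, collapse = ", "),
         call. = FALSE)
  acc == "correct"
}

#' Exclude participants with outlying error rates
#'
#' Within each group, a participant is excluded when their error rate over
#' all their trials (words and pseudowords) exceeds the mean plus
#' `threshold_sd` standard deviations of the error rates of the *other*
#' participants of the same group (leave-one-out, one-sided high).
#'
#' @param trials a trial table (see [validate_trials()]).
#' @param threshold_sd SD multiplier (default 2.5).
#' @return A list with `trials` (the retained trials) and `report`, a list
#'   holding per-group statistics and the excluded participant ids.
#' @export
exclude_participants_by_accuracy <- function(trials, threshold_sd = 2.5) {
  validate_trials(trials)
  correct <- is_correct(trials$accuracy)
  err <- tapply(!correct, trials$participant, mean)
  grp <- tapply(as.character(trials$group), trials$participant, `[`, 1L)

  excluded <- character(0)
  stats <- list()
  for (g in unique(grp)) {
    ids <- names(grp)[grp == g]
    if (length(ids) < 3L)
      stop("group ", g, " has fewer than 3 participants; leave-one-out SD unstable",
           call. = FALSE)
    e <- err[ids]
    cut <- vapply(seq_along(ids), function(i) {
      others <- e[-i]
      mean(others) + threshold_sd * stats::sd(others)
    }, numeric(1L))
    out <- ids[e > cut]
    excluded <- c(excluded, out)
    stats[[g]] <- data.frame(participant = ids, error_rate = unname(e),
                             cutoff = cut, excluded = ids %in% out,
                             stringsAsFactors = FALSE)
  }
  keep <- !trials$participant %in% excluded
  list(
    trials = trials[keep, , drop = FALSE],
    report = list(step = "participant_exclusion",
                  threshold_sd = threshold_sd,
                  excluded_participants = excluded,
                  per_group = stats,
                  n_trials_removed = sum(!keep))
  )
}

#' Exclude word items with low accuracy in both groups
#'
#' A word is excluded when its accuracy over word trials falls below
#' `mean - threshold_sd * SD` of the item accuracies computed within *each*
#' group separately (the AND rule: the item must be an outlier in both the
#' EB and the SC group). Pseudoword trials are untouched.
#'
#' @inheritParams exclude_participants_by_accuracy
#' @return A list with `trials` and `report` (excluded item ids, per-group
#'   item statistics).
#' @export
exclude_items_by_accuracy <- function(trials, threshold_sd = 2.5) {
  validate_trials(trials)
  w <- trials$lexicality == "word"
  correct <- is_correct(trials$accuracy)

  groups <- sort(unique(as.character(trials$group)))
  low_in <- list()
  per_group <- list()
  for (g in groups) {
    sel <- w & trials$group == g
    acc <- tapply(correct[sel], trials$stimulus[sel], mean)
    cut <- mean(acc) - threshold_sd * stats::sd(acc)
    low_in[[g]] <- names(acc)[acc < cut]
    per_group[[g]] <- data.frame(stimulus = names(acc), accuracy = unname(acc),
                                 cutoff = cut, stringsAsFactors = FALSE)
  }
  excluded <- Reduce(intersect, low_in)
  keep <- !(w & trials$stimulus %in% excluded)
  list(
    trials = trials[keep, , drop = FALSE],
    report = list(step = "item_exclusion",
                  threshold_sd = threshold_sd,
                  excluded_items = excluded,
                  per_group = per_group,
                  n_trials_removed = sum(!keep))
  )
}

#' Trial-level RT filters on word trials
#'
#' Restricts to word trials (only words enter the RT model) and applies, in
#' order: (1) drop incorrect trials; (2) drop trials faster than `rt_floor`
#' ms; (3) per participant, drop trials whose RT lies strictly more than
#' `sd_window` SDs from that participant's mean RT over the trials surviving
#' steps 1-2 (raw-ms scale). Each step's percentage uses the count remaining
#' *before* that step as denominator; percentages over all pre-cleaning
#' trials (words + pseudowords) are reported alongside.
#'
#' @inheritParams exclude_participants_by_accuracy
#' @param rt_floor fast-response floor in ms (default 300).
#' @param sd_window per-participant trimming window in SDs (default 3).
#' @return A list with `trials` (clean word trials) and `report` with
#'   per-step counts and percentages.
#' @export
filter_trials <- function(trials, rt_floor = 300, sd_window = 3) {
  validate_trials(trials)
  n_all <- nrow(trials)
  words <- trials[trials$lexicality == "word", , drop = FALSE]
  n0 <- nrow(words)
  if (!n0) stop("no word trials to filter", call. = FALSE)

  # step 1: accuracy
  correct <- is_correct(words$accuracy)
  s1 <- words[correct, , drop = FALSE]
  n_inacc <- n0 - nrow(s1)

  # step 2: fast guesses
  s2 <- s1[s1$rt >= rt_floor, , drop = FALSE]
  n_fast <- nrow(s1) - nrow(s2)

  # step 3: per-participant +/- sd_window SD trimming (strict inequality)
  keep <- rep(TRUE, nrow(s2))
  skipped <- character(0)
  for (p in unique(s2$participant)) {
    idx <- which(s2$participant == p)
    if (length(idx) < 2L) {
      skipped <- c(skipped, as.character(p))
      next
    }
    m <- mean(s2$rt[idx]); s <- stats::sd(s2$rt[idx])
    keep[idx] <- abs(s2$rt[idx] - m) <= sd_window * s
  }
  if (length(skipped))
    warning("participant(s) with < 2 trials skipped by the SD filter: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  s3 <- s2[keep, , drop = FALSE]
  n_sd <- nrow(s2) - nrow(s3)

  pct <- function(n, den) if (den > 0) 100 * n / den else 0
  list(
    trials = s3,
    report = list(
      step = "trial_filters",
      rt_floor = rt_floor, sd_window = sd_window,
      n_word_trials = n0, n_all_trials = n_all,
      n_inaccurate_removed = n_inacc,
      pct_inaccurate = pct(n_inacc, n0),
      pct_inaccurate_all = pct(n_inacc, n_all),
      n_fast_removed = n_fast,
      pct_fast = pct(n_fast, nrow(s1)),
      pct_fast_all = pct(n_fast, n_all),
      n_sd_removed = n_sd,
      pct_sd = pct(n_sd, nrow(s2)),
      pct_sd_all = pct(n_sd, n_all),
      n_remaining = nrow(s3),
      participants_skipped_sd = skipped
    )
  )
}

#' Add natural-log RT and duration columns
#'
#' @param trials a trial table with positive `rt` and `duration` in ms.
#' @return the table with `log_rt` and `log_duration` columns appended;
#'   applying the transform twice is an error.
#' @export
log_transforms <- function(trials) {
  if (any(c("log_rt", "log_duration") %in% names(trials)))
    stop("log columns already present; refusing to transform twice",
         call. = FALSE)
  if (any(trials$rt <= 0) || any(trials$duration <= 0))
    stop("rt and duration must be positive for log transform", call. = FALSE)
  trials$log_rt <- log(trials$rt)
  trials$log_duration <- log(trials$duration)
  trials
}

#' Full cleaning cascade
#'
#' Participant exclusion, item exclusion, trial filters and log transforms,
#' in that order, with the step reports collected into one cleaning report.
#'
#' @inheritParams filter_trials
#' @param threshold_sd SD multiplier for participant/item exclusion.
#' @return A list with `trials` (clean, log-transformed word trials) and
#'   `report` (class `cleaning_report`).
#' @export
clean_trials <- function(trials, threshold_sd = 2.5, rt_floor = 300,
                         sd_window = 3) {
  p <- exclude_participants_by_accuracy(trials, threshold_sd)
  i <- exclude_items_by_accuracy(p$trials, threshold_sd)
  f <- filter_trials(i$trials, rt_floor, sd_window)
  out <- log_transforms(f$trials)
  report <- structure(
    list(participants = p$report, items = i$report, filters = f$report,
         n_input = nrow(trials), n_output = nrow(out)),
    class = "cleaning_report"
  )
  list(trials = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report\n")
  cat("  participants excluded:",
      if (length(x$participants$excluded_participants))
        paste(x$participants$excluded_participants, collapse = ", ")
      else "none", "\n")
  cat("  items excluded:",
      if (length(x$items$excluded_items))
        paste(x$items$excluded_items, collapse = ", ") else "none", "\n")
  f <- x$filters
  cat(sprintf("  inaccurate trials removed: %d (%.2f%% of word trials)\n",
              f$n_inaccurate_removed, f$pct_inaccurate))
  cat(sprintf("  fast (<%g ms) trials removed: %d (%.2f%%)\n",
              f$rt_floor, f$n_fast_removed, f$pct_fast))
  cat(sprintf("  +/-%g SD trials removed: %d (%.2f%%)\n",
              f$sd_window, f$n_sd_removed, f$pct_sd))
  cat("  trials in / out:", x$n_input, "/", x$n_output, "\n")
  invisible(x)
}
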