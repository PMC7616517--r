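# Fixtures are built in code; nothing is stored on disk.

# independent brute-force neighborhood-density oracle: plain loops over a
# raw matrix, no shared code with the package implementation
brute_sneigh <- function(target, target_vec, ref_words, ref_mat, k) {
  cos <- numeric(0)
  words <- character(0)
  for (i in seq_along(ref_words)) {
    if (ref_words[i] == target) next
    u <- target_vec
    v <- ref_mat[i, ]
    cos <- c(cos, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    words <- c(words, ref_words[i])
  }
  ord <- order(-cos, words, method = "radix")
  top <- ord[seq_len(k)]
  list(sneigh = mean(cos[top]), words = words[top], cosines = cos[top])
}

# a small deterministic trial table: one row per participant x stimulus x
# presentation, with overridable accuracy and RT
make_trials <- function(participants, stimuli, types = NULL,
                        presentations = 1L, rt = 600, duration = 700,
                        accuracy = "correct") {
  n_p <- length(participants)
  groups <- rep(c("EB", "SC"), length.out = n_p)
  if (is.null(types))
    types <- rep(c("abstract", "multimodal", "visual"),
                 length.out = length(stimuli))
  grid <- expand.grid(p = seq_len(n_p), s = seq_along(stimuli),
                      presentation = seq_len(presentations))
  out <- data.frame(
    participant = participants[grid$p],
    group = groups[grid$p],
    stimulus = stimuli[grid$s],
    type = types[grid$s],
    lexicality = "word",
    presentation = grid$presentation,
    accuracy = rep(accuracy, length.out = nrow(grid)),
    rt = rep(rt, length.out = nrow(grid)),
    duration = rep(duration, length.out = nrow(grid)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# random embedding space for property tests
random_space <- function(n, d, seed = NULL, prefix = "w") {
  if (!is.null(seed)) set.seed(seed)
  embedding_space(sprintf("%s%03d", prefix, seq_len(n)),
                  matrix(rnorm(n * d), nrow = n))
}

# small generative config for fast simulation tests
small_config <- function(...) {
  generative_config(
    embedding = list(n_words = 200L, dim = 20L, n_clusters = 4L),
    design = list(n_per_group = 6L, words_per_type = 8L),
    ...
  )
}
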