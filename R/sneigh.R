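#' Cosine similarity between two vectors
#'
#' `dot(u, v) / (||u|| ||v||)`, clamped to `[-1, 1]` against floating-point
#' rounding. The cosine of the angle between two embedding vectors is the
#' standard proxy for semantic relatedness in distributional models.
#'
#' @param u,v numeric vectors of equal dimension, both non-zero.
#' @return a similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v))
    stop("vectors differ in dimension (", length(u), " vs ", length(v), ")",
         call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for a zero-norm vector", call. = FALSE)
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

# all cosines between one target vector and the rows of a matrix, clamped
cosine_against <- function(target_vec, mat) {
  nt <- sqrt(sum(target_vec^2))
  if (nt == 0) stop("cosine similarity undefined for a zero-norm vector",
                    call. = FALSE)
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0))
    stop("zero-norm vector(s) in reference space: ",
         paste(utils::head(rownames(mat)[norms == 0], 5L), collapse = ", "),
         call. = FALSE)
  pmin(1, pmax(-1, drop(mat %*% target_vec) / (norms * nt)))
}

#' Semantic neighborhood density of one word
#'
#' Computes the cosine similarity between the target vector and every word of
#' the reference vocabulary except the target itself (excluded by exact
#' string identity; a different word with an identical vector is a legitimate
#' neighbor), takes the `k` largest with a deterministic tie-break (cosine
#' descending, then word lexicographically ascending), and returns their
#' arithmetic mean together with the neighbor list.
#'
#' @param target the stimulus word (used only for self-exclusion).
#' @param target_vec its embedding vector; defaults to looking `target` up in
#'   `reference` -- pass it explicitly when the stimulus is outside the
#'   reference vocabulary.
#' @param reference an [embedding_space()]; the frequency-defined reference
#'   vocabulary.
#' @param k neighbor count (the headline statistic uses `k = 5`).
#' @return A list with `word`, `sneigh` (mean cosine of the k nearest
#'   neighbors, in `[-1, 1]`) and `neighbors`, a data.frame of the k
#'   `(word, cosine)` pairs in non-increasing cosine order.
#' @export
semantic_neighborhood_density <- function(target, target_vec = NULL, reference,
                                          k = 5L) {
  stopifnot(inherits(reference, "embedding_space"))
  if (!is.numeric(k) || length(k) != 1L || k < 1L)
    stop("k must be a positive count", call. = FALSE)
  k <- as.integer(k)
  target <- stringi::stri_trans_nfc(as.character(target))
  if (is.null(target_vec)) target_vec <- drop(get_vectors(reference, target))
  if (length(target_vec) != reference$d)
    stop("target vector dimension ", length(target_vec),
         " does not match reference dimension ", reference$d, call. = FALSE)

  eligible <- reference$vocabulary != target
  if (sum(eligible) < k)
    stop("only ", sum(eligible), " eligible reference words for '", target,
         "'; k = ", k, " neighborhood undefined", call. = FALSE)
  words <- reference$vocabulary[eligible]
  cos <- cosine_against(as.numeric(target_vec),
                        reference$vectors[eligible, , drop = FALSE])
  ord <- order(-cos, words, method = "radix")[seq_len(k)]
  nb <- data.frame(word = words[ord], cosine = cos[ord],
                   stringsAsFactors = FALSE)
  list(word = target, sneigh = mean(nb$cosine), neighbors = nb)
}

#' Density table for a set of stimuli
#'
#' One row per stimulus word: its SNeigh value (mean cosine of the k closest
#' reference neighbors) and the neighbors that produced it. Stimulus vectors
#' are looked up in `space` (typically the full embedding file), while
#' neighbors are drawn from `reference` (the frequency-defined top-N set);
#' the two sets are obtained independently.
#'
#' @param stimuli character vector of stimulus words.
#' @param space an [embedding_space()] in which every stimulus must resolve;
#'   out-of-vocabulary stimuli are an error listing all missing words at
#'   once. Defaults to `reference`.
#' @param reference the reference [embedding_space()].
#' @param k neighbor count (default 5).
#' @return A data.frame of class `density_table` with columns `word`,
#'   `sneigh`, and `neighbor_i`/`cosine_i` for `i` in `1..k`.
#' @export
compute_density_table <- function(stimuli, space = reference, reference,
                                  k = 5L) {
  stimuli <- stringi::stri_trans_nfc(as.character(stimuli))
  if (anyDuplicated(stimuli))
    stop("duplicate stimulus words: ",
         paste(unique(stimuli[duplicated(stimuli)]), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(stimuli, space$vocabulary)
  if (length(missing))
    stop("stimuli without vectors (", length(missing), "): ",
         paste(missing, collapse = ", "), call. = FALSE)

  rows <- lapply(stimuli, function(w) {
    semantic_neighborhood_density(w, drop(get_vectors(space, w)), reference, k)
  })
  out <- data.frame(
    word = vapply(rows, `[[`, character(1L), "word"),
    sneigh = vapply(rows, `[[`, numeric(1L), "sneigh"),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(k)) {
    out[[paste0("neighbor_", i)]] <-
      vapply(rows, function(r) r$neighbors$word[i], character(1L))
    out[[paste0("cosine_", i)]] <-
      vapply(rows, function(r) r$neighbors$cosine[i], numeric(1L))
  }
  attr(out, "k") <- as.integer(k)
  class(out) <- c("density_table", "data.frame")
  out
}

#' Write / read a density table as TSV
#'
#' @param density a `density_table` from [compute_density_table()].
#' @param path output path.
#' @return `path` invisibly; `read_density_table()` returns the table.
#' @export
write_density_table <- function(density, path) {
  utils::write.table(density, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_table
#' @export
read_density_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("word", "sneigh") %in% names(out)))
    stop("density table must have 'word' and 'sneigh' columns", call. = FALSE)
  k <- sum(grepl("^neighbor_", names(out)))
  attr(out, "k") <- as.integer(k)
  class(out) <- c("density_table", "data.frame")
  out
}
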