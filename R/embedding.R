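#' Embedding spaces and frequency norms
#'
#' An `embedding_space` holds a vocabulary of unique word strings and one
#' real-valued vector of fixed dimension `d` per word. It is the container
#' behind all cosine-similarity and neighborhood-density computations.
#'
#' @param words character vector of unique, non-empty word strings.
#' @param vectors numeric matrix with one row per word and `d` columns.
#' @param normalize_nfc logical; apply Unicode NFC normalization to the
#'   words (default `TRUE`). Case is never folded and diacritics are never
#'   stripped: orthography is meaningful in the languages this statistic is
#'   used for.
#' @return An object of class `embedding_space`: a list with elements
#'   `vocabulary` (character), `vectors` (numeric matrix, rownames equal to
#'   the vocabulary) and `d` (integer dimension).
#' @export
embedding_space <- function(words, vectors, normalize_nfc = TRUE) {
  words <- as.character(words)
  if (isTRUE(normalize_nfc)) words <- stringi::stri_trans_nfc(words)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (length(words) != nrow(vectors))
    stop("number of words (", length(words), ") does not match number of vector rows (",
         nrow(vectors), ")", call. = FALSE)
  if (anyNA(words) || any(!nzchar(words)))
    stop("words must be non-empty strings", call. = FALSE)
  dup <- unique(words[duplicated(words)])
  if (length(dup))
    stop("duplicate words in embedding space: ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  if (!all(is.finite(vectors)))
    stop("all vector entries must be finite numbers", call. = FALSE)
  rownames(vectors) <- words
  structure(
    list(vocabulary = words, vectors = vectors, d = ncol(vectors)),
    class = "embedding_space"
  )
}

#' @export
print.embedding_space <- function(x, ...) {
  cat("<embedding_space> ", length(x$vocabulary), " words, ", x$d, " dimensions\n",
      sep = "")
  invisible(x)
}

#' @export
length.embedding_space <- function(x) length(x$vocabulary)

#' Look up word vectors, failing loudly on missing words
#'
#' @param space an [embedding_space()].
#' @param words character vector of words to retrieve.
#' @return numeric matrix with one row per requested word.
#' @export
get_vectors <- function(space, words) {
  stopifnot(inherits(space, "embedding_space"))
  words <- stringi::stri_trans_nfc(as.character(words))
  missing <- setdiff(words, space$vocabulary)
  if (length(missing))
    stop("words not present in embedding space: ",
         paste(missing, collapse = ", "), call. = FALSE)
  space$vectors[words, , drop = FALSE]
}

#' Read word vectors in word2vec text format
#'
#' Parses the plain-text dialect used to distribute pretrained vectors
#' (e.g. fastText `.vec` files): an optional header line `"<n> <d>"`
#' followed by one line per word, the token and then `d` whitespace-separated
#' decimal numbers. Words are kept in file order.
#'
#' @param path path to a `.vec`/text file.
#' @param lowercase logical; fold words to lower case before storing
#'   (default `FALSE`; exact-match semantics).
#' @param quiet suppress the row-count message.
#' @return An [embedding_space()].
#' @export
read_word2vec_text <- function(path, lowercase = FALSE, quiet = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty vector file: ", path, call. = FALSE)

  parts <- strsplit(trimws(lines), "[ \t]+")
  header <- NULL
  first <- parts[[1L]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.integer(first)))) {
    header <- as.integer(first)
    parts <- parts[-1L]
    if (!length(parts)) stop("vector file contains only a header", call. = FALSE)
  }
  lens <- lengths(parts)
  d <- lens[1L] - 1L
  if (d < 1L)
    stop("format error at line ", 1L + !is.null(header),
         ": no vector entries after the token", call. = FALSE)
  bad <- which(lens != d + 1L)
  if (length(bad))
    stop("dimension mismatch at line ", bad[1L] + as.integer(!is.null(header)),
         ": expected ", d, " values, found ", lens[bad[1L]] - 1L, call. = FALSE)

  words <- vapply(parts, `[[`, character(1L), 1L)
  if (lowercase) words <- tolower(words)
  vals <- suppressWarnings(as.numeric(unlist(lapply(parts, `[`, -1L), use.names = FALSE)))
  if (anyNA(vals)) {
    row <- ceiling(which(is.na(vals))[1L] / d)
    stop("non-numeric vector entry at data line ", row, " (word '", words[row], "')",
         call. = FALSE)
  }
  mat <- matrix(vals, ncol = d, byrow = TRUE)

  if (!is.null(header)) {
    if (header[1L] != length(words))
      stop("header declares ", header[1L], " words but file contains ",
           length(words), call. = FALSE)
    if (header[2L] != d)
      stop("header declares dimension ", header[2L], " but vectors have ", d,
           call. = FALSE)
  }
  space <- embedding_space(words, mat)
  if (!quiet)
    message("read ", length(words), " vectors of dimension ", d, " from ", path)
  space
}

#' Write an embedding space in word2vec text format
#'
#' @param space an [embedding_space()].
#' @param path output path.
#' @param header write the `"<n> <d>"` header line (default `TRUE`).
#' @param digits significant digits for vector entries.
#' @return `path`, invisibly.
#' @export
write_word2vec_text <- function(space, path, header = TRUE, digits = 8L) {
  stopifnot(inherits(space, "embedding_space"))
  body <- vapply(seq_along(space$vocabulary), function(i) {
    paste(space$vocabulary[i],
          paste(formatC(space$vectors[i, ], digits = digits, format = "g"),
                collapse = " "))
  }, character(1L))
  out <- c(if (header) paste(length(space$vocabulary), space$d), body)
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read a word-frequency list
#'
#' Reads a delimited table of corpus frequency norms (e.g. film-subtitle
#' frequencies) and returns it sorted by descending frequency with a
#' deterministic lexicographic tie-break, so that "the top N most frequent
#' words" is reproducible.
#'
#' @param path path to a TSV or CSV file.
#' @param word_column,freq_column column names holding the word and its
#'   frequency (a count or per-million rate, non-negative).
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the first line.
#' @param quiet suppress the row-count message.
#' @return A data.frame of class `frequency_list` with columns `word` and
#'   `frequency`, sorted by decreasing frequency then by word.
#' @export
read_frequency_list <- function(path, word_column = "word",
                                freq_column = "frequency", sep = NULL,
                                quiet = FALSE) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "",
                           encoding = "UTF-8")
  for (col in c(word_column, freq_column))
    if (!col %in% names(tab))
      stop("column '", col, "' not found in ", path,
           " (columns: ", paste(names(tab), collapse = ", "), ")", call. = FALSE)
  frequency_list(tab[[word_column]], tab[[freq_column]], quiet = quiet)
}

#' Construct a frequency list from vectors
#'
#' @param words character vector of words.
#' @param frequencies non-negative numeric frequencies.
#' @inheritParams read_frequency_list
#' @return see [read_frequency_list()].
#' @export
frequency_list <- function(words, frequencies, quiet = TRUE) {
  words <- stringi::stri_trans_nfc(as.character(words))
  frequencies <- as.numeric(frequencies)
  if (length(words) != length(frequencies))
    stop("words and frequencies differ in length", call. = FALSE)
  if (anyNA(frequencies) || any(frequencies < 0))
    stop("frequencies must be non-negative numbers", call. = FALSE)
  if (anyDuplicated(words)) {
    # keep the highest-frequency row per duplicated word
    ord <- order(words, -frequencies)
    keep <- !duplicated(words[ord])
    n_dropped <- sum(!keep)
    words <- words[ord][keep]
    frequencies <- frequencies[ord][keep]
    warning(n_dropped, " duplicate word row(s) dropped, keeping highest frequency",
            call. = FALSE)
  }
  ord <- order(-frequencies, words, method = "radix")
  out <- data.frame(word = words[ord], frequency = frequencies[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("frequency_list", "data.frame")
  if (!quiet) message("frequency list with ", nrow(out), " words")
  out
}

#' Build the frequency-defined reference vocabulary
#'
#' Restricts an embedding space to the `n_top` most frequent words that have
#' vectors. Words lacking vectors are skipped, not back-filled from ranks
#' beyond `n_top`: "the top N most frequent words" keeps its literal meaning,
#' so the result may be shorter than `n_top`. The skip count is reported.
#'
#' @param freq a [frequency_list()].
#' @param space an [embedding_space()] covering (most of) the list.
#' @param n_top number of top-frequency words to consider (paper-style
#'   analyses use 20000).
#' @param k if supplied, the downstream neighbor count: an error is raised
#'   when fewer than `k + 1` words resolve, since a k-neighborhood would be
#'   undefined.
#' @param quiet suppress the skip-count message.
#' @return An [embedding_space()] restricted to the resolvable top words, in
#'   descending-frequency order.
#' @export
build_reference_vocabulary <- function(freq, space, n_top, k = NULL,
                                       quiet = FALSE) {
  stopifnot(inherits(freq, "frequency_list"), inherits(space, "embedding_space"))
  if (!is.numeric(n_top) || length(n_top) != 1L || n_top < 1)
    stop("n_top must be a positive count", call. = FALSE)
  top <- utils::head(freq$word, n_top)
  have <- top %in% space$vocabulary
  n_skipped <- sum(!have)
  kept <- top[have]
  if (!is.null(k) && length(kept) < k + 1L)
    stop("only ", length(kept), " of the top-", n_top,
         " words have vectors; a ", k, "-word neighborhood is undefined",
         call. = FALSE)
  if (!quiet)
    message("reference vocabulary: ", length(kept), " of top-", n_top,
            " words resolved (", n_skipped, " skipped, no vector)")
  out <- embedding_space(kept, space$vectors[kept, , drop = FALSE],
                         normalize_nfc = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}
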