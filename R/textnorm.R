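#' Default English stopword list
#'
#' Loads the fixed English function-word list shipped with the package, or a
#' user-supplied one (one word per line, lowercase, no punctuation — the list
#' is applied to tokens after apostrophes and hyphens have been split away).
#' The list is versioned with the package so identical inputs give identical
#' results across machines.
#'
#' @param path optional path to an alternative stopword file.
#' @return character vector of stopwords.
#' @export
aop_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "aopminer")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("stopword file not found: ", path, call. = FALSE)
  }
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- trimws(words)
  words[nzchar(words)]
}

.stemmers <- c("porter")

.get_stemmer <- function(stemmer_id) {
  if (!is.character(stemmer_id) || length(stemmer_id) != 1L ||
      !(stemmer_id %in% .stemmers)) {
    stop("unsupported stemmer '", stemmer_id, "'; available: ",
         paste(.stemmers, collapse = ", "), call. = FALSE)
  }
  porter_stem
}

#' Tokenize text into lowercase word tokens
#'
#' Tokens are maximal runs of letters and digits after lowercasing; hyphens,
#' slashes and all other punctuation split tokens. Purely numeric tokens are
#' retained (they can be part of gene symbols split across punctuation).
#'
#' @param text a character scalar (NA treated as empty).
#' @return character vector of tokens, in text order.
#' @examples
#' aop_tokenize("TP53-mediated apoptosis.")
#' @export
aop_tokenize <- function(text) {
  if (length(text) != 1L) stop("text must be a single string", call. = FALSE)
  if (is.na(text) || !nzchar(text)) return(character(0))
  text <- tolower(text)
  m <- gregexpr("[\\p{L}\\p{N}]+", text, perl = TRUE)
  regmatches(text, m)[[1]]
}

# stems of the stopword list itself; outputs are filtered against these as
# well so no stem in any output can equal a stemmed stopword
.stop_stems <- function(stopwords, stem_fun) unique(stem_fun(tolower(stopwords)))

# stems are iterated to a fixed point so that normalization is idempotent:
# normalizing an already-normalized stem sequence returns it unchanged
.stem_fixpoint <- function(words, stem_fun = porter_stem) {
  stems <- stem_fun(words)
  for (i in 1:10) {
    nxt <- stem_fun(stems)
    if (identical(nxt, stems)) break
    stems <- nxt
  }
  stems
}

.norm_tokens <- function(tokens, stopwords, stem_fun, stop_stems) {
  tokens <- tokens[!(tokens %in% stopwords)]
  if (!length(tokens)) return(character(0))
  stems <- .stem_fixpoint(tokens, stem_fun)
  stems[!(stems %in% stop_stems)]
}

#' Normalize a phrase to ordered content-word stems
#'
#' The standardization pipeline applied identically to dictionary terms,
#' abstract text and annotation keys: tokenize, drop stopwords, stem the
#' remaining tokens. Stemming is applied to a fixed point, so normalization
#' is idempotent: re-normalizing the space-joined stems returns them
#' unchanged. A phrase left with no content word cannot be matched and is an
#' error.
#'
#' @param label the original phrase.
#' @param stopwords character vector of stopwords (default: shipped list).
#' @param stemmer stemming algorithm identifier; only `"porter"` is provided.
#' @return an object of class `normalized_phrase`: list with `source_label`,
#'   `stems` (ordered, may repeat) and `stem_set` (unique stems).
#' @examples
#' normalize_phrase("increased oxidative stress")
#' @export
normalize_phrase <- function(label, stopwords = aop_stopwords(),
                             stemmer = "porter") {
  stem_fun <- .get_stemmer(stemmer)
  stems <- .norm_tokens(aop_tokenize(label), stopwords, stem_fun,
                        .stop_stems(stopwords, stem_fun))
  if (!length(stems)) {
    stop("phrase has no content words after normalization: '", label, "'",
         call. = FALSE)
  }
  structure(
    list(source_label = label, stems = stems, stem_set = unique(stems)),
    class = "normalized_phrase"
  )
}

#' @export
print.normalized_phrase <- function(x, ...) {
  cat("<normalized_phrase> '", x$source_label, "' -> [",
      paste(x$stems, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

.split_sentences <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  parts <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts[nzchar(trimws(parts))]
}

#' Normalize an abstract record into per-sentence stem sets
#'
#' Concatenates title and body with a space, segments into sentences on
#' terminal punctuation (`.`, `!`, `?` followed by whitespace), and normalizes
#' each sentence to its set of content-word stems.
#'
#' @param record a list or one-row data frame with `record_id`, `title`,
#'   `abstract` fields.
#' @param stopwords,stemmer see [normalize_phrase()].
#' @return an object of class `normalized_document`: list with `record_id`,
#'   `sentence_stems` (list of unique-stem character vectors, sentence order
#'   preserved; sentences with no content words are dropped) and `all_stems`
#'   (union over sentences).
#' @export
normalize_document <- function(record, stopwords = aop_stopwords(),
                               stemmer = "porter") {
  stem_fun <- .get_stemmer(stemmer)
  .normalize_document(record, stopwords, stem_fun,
                      .stop_stems(stopwords, stem_fun))
}

.normalize_document <- function(record, stopwords, stem_fun, stop_stems) {
  title <- record$title
  body <- if (!is.null(record$abstract)) record$abstract else record$body
  if (is.null(body)) body <- ""
  if (is.na(title)) title <- ""
  if (is.na(body)) body <- ""
  text <- trimws(paste(title, body))
  sentences <- .split_sentences(text)
  stems <- lapply(sentences, function(s) {
    unique(.norm_tokens(aop_tokenize(s), stopwords, stem_fun, stop_stems))
  })
  stems <- stems[lengths(stems) > 0L]
  structure(
    list(record_id = as.character(record$record_id),
         sentence_stems = stems,
         all_stems = unique(unlist(stems, use.names = FALSE))),
    class = "normalized_document"
  )
}

#' Normalize a whole corpus
#'
#' @param corpus a corpus data frame as returned by [read_corpus_tsv()].
#' @inheritParams normalize_document
#' @return list of `normalized_document`, one per record, order preserved.
#' @export
normalize_corpus <- function(corpus, stopwords = aop_stopwords(),
                             stemmer = "porter") {
  stem_fun <- .get_stemmer(stemmer)
  stop_stems <- .stop_stems(stopwords, stem_fun)
  lapply(seq_len(nrow(corpus)), function(i) {
    .normalize_document(corpus[i, , drop = FALSE], stopwords, stem_fun,
                        stop_stems)
  })
}

#' Expand a dictionary term into normalized phrase variants
#'
#' Produces one normalized phrase for the label plus one per synonym,
#' deduplicated by stem set with the label variant kept first. A variant with
#' no content words is dropped; a term whose every variant fails is an error.
#'
#' @param term a list or one-row data frame with `term_id`, `label`,
#'   `category` and `synonyms` (character vector, possibly empty).
#' @inheritParams normalize_phrase
#' @return list of `normalized_phrase` objects.
#' @export
expand_term <- function(term, stopwords = aop_stopwords(), stemmer = "porter") {
  syn <- term$synonyms
  if (is.list(syn)) syn <- syn[[1]]
  if (is.null(syn)) syn <- character(0)
  variants <- c(term$label, syn)
  phrases <- list()
  seen <- character(0)
  for (v in variants) {
    ph <- tryCatch(normalize_phrase(v, stopwords, stemmer),
                   error = function(e) NULL)
    if (is.null(ph)) next
    key <- paste(sort(ph$stem_set), collapse = "\x1f")
    if (key %in% seen) next
    seen <- c(seen, key)
    phrases[[length(phrases) + 1L]] <- ph
  }
  if (!length(phrases)) {
    stop("term '", term$term_id,
         "' has no matchable variant after normalization", call. = FALSE)
  }
  phrases
}

#' Expand every term of a dictionary
#'
#' @param dictionary a dictionary data frame as returned by
#'   [read_dictionary()].
#' @inheritParams normalize_phrase
#' @return named list mapping `term_id` to its list of normalized phrases,
#'   with the dictionary rows attached as attribute `"dictionary"`.
#' @export
expand_dictionary <- function(dictionary, stopwords = aop_stopwords(),
                              stemmer = "porter") {
  out <- lapply(seq_len(nrow(dictionary)), function(i) {
    expand_term(dictionary[i, , drop = FALSE], stopwords, stemmer)
  })
  names(out) <- dictionary$term_id
  attr(out, "dictionary") <- dictionary
  attr(out, "stemmer") <- stemmer
  out
}
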