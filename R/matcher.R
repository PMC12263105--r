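#' Match a normalized phrase against a stem set
#'
#' The matched fraction is the number of distinct phrase stems present in
#' `stems`, divided by the number of distinct phrase stems. Partial mode
#' accepts a fraction of at least 3/4 (compared exactly as `4*j >= 3*k`,
#' no floating point); exact mode requires every stem.
#'
#' @param phrase a `normalized_phrase` (or any list with a `stem_set` field).
#' @param stems character vector of stems to search in.
#' @param mode `"partial"` (>= 3/4 of the words) or `"exact"` (all words).
#' @return list with `matched` (logical) and `fraction` (numeric in `[0,1]`).
#' @examples
#' ph <- normalize_phrase("dna double strand breaks")
#' match_phrase(ph, c("dna", "doubl", "strand"), mode = "partial")
#' @export
match_phrase <- function(phrase, stems, mode = c("partial", "exact")) {
  mode <- match.arg(mode)
  k <- length(phrase$stem_set)
  if (k < 1L) stop("phrase has no stems", call. = FALSE)
  j <- sum(phrase$stem_set %in% stems)
  matched <- if (mode == "exact") j == k else 4L * j >= 3L * k
  list(matched = matched, fraction = j / k)
}

#' Detect dictionary terms in normalized documents
#'
#' Scans every document for every term variant. With `scope = "abstract"` a
#' variant is matched against the union of stems of the whole record (title +
#' abstract); with `scope = "sentence"` it must be satisfied within a single
#' sentence's stem set. At most one hit is reported per (term, record); its
#' `best_fraction` is the maximum matched-stem fraction attained over all
#' variants (and sentences).
#'
#' @param docs list of `normalized_document` (see [normalize_corpus()]).
#' @param dictionary expanded dictionary from [expand_dictionary()].
#' @param mode `"partial"` or `"exact"` (see [match_phrase()]).
#' @param scope `"abstract"` or `"sentence"`.
#' @return data frame of hits: `term_id`, `record_id`, `best_fraction`,
#'   `mode`, ordered by (term_id, record position).
#' @export
detect_terms <- function(docs, dictionary, mode = c("partial", "exact"),
                         scope = c("abstract", "sentence")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (!length(dictionary)) stop("empty dictionary", call. = FALSE)

  rows <- vector("list", length(dictionary) * length(docs))
  n <- 0L
  for (tid in names(dictionary)) {
    variants <- dictionary[[tid]]
    for (doc in docs) {
      scopes <- if (scope == "abstract") list(doc$all_stems)
                else doc$sentence_stems
      best <- 0
      hit <- FALSE
      for (ph in variants) {
        for (ss in scopes) {
          m <- match_phrase(ph, ss, mode)
          if (m$fraction > best) best <- m$fraction
          if (m$matched) hit <- TRUE
        }
      }
      if (hit) {
        n <- n + 1L
        rows[[n]] <- data.frame(term_id = tid, record_id = doc$record_id,
                                best_fraction = best, mode = mode,
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (n == 0L) {
    return(data.frame(term_id = character(0), record_id = character(0),
                      best_fraction = numeric(0), mode = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows[seq_len(n)])
  rownames(out) <- NULL
  out
}
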