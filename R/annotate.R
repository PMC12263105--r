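#' Annotate biological events against local database extracts
#'
#' Matches each event term (with its synonyms) against the `key_term` column
#' of one or more annotation-database extracts, using the same normalization
#' pipeline as the literature search. Under `rule = "exact"` an event matches
#' a key when some variant's stem set equals the key's stem set; under
#' `rule = "partial"` when the key's stems cover at least 3/4 of a variant's
#' stems (same integer arithmetic as [match_phrase()]). Gene-category terms
#' additionally match on case-insensitive raw symbol equality, since
#' stemming can mangle gene symbols. Matches are deduplicated by
#' (source_db, annotation_id) per event.
#'
#' @param events dictionary data frame of event/gene terms (see
#'   [read_dictionary()]); must be non-empty.
#' @param db annotation data frame (see [read_annotation_db()]), possibly
#'   the row-bound union of several extracts.
#' @param stopwords,stemmer see [normalize_phrase()].
#' @param rule `"exact"` (annotation as lookup; default) or `"partial"`
#'   (recall-oriented).
#' @return object of class `event_annotations`: named list mapping each
#'   event's `term_id` to a data frame of its matched annotation records
#'   (zero rows when nothing matches — events are never omitted).
#' @export
annotate_events <- function(events, db, stopwords = aop_stopwords(),
                            stemmer = "porter",
                            rule = c("exact", "partial")) {
  rule <- match.arg(rule)
  if (is.null(events) || nrow(events) == 0L) {
    stop("empty events list", call. = FALSE)
  }
  expanded <- expand_dictionary(events, stopwords, stemmer)

  # normalize every distinct key once; keys with no content words can still
  # match genes by raw symbol
  keys <- unique(db$key_term)
  key_stems <- lapply(keys, function(k) {
    tryCatch(normalize_phrase(k, stopwords, stemmer)$stem_set,
             error = function(e) character(0))
  })
  names(key_stems) <- keys
  keys_lower <- tolower(keys)

  empty_db <- db[0, , drop = FALSE]
  sets <- lapply(events$term_id, function(tid) {
    i <- match(tid, events$term_id)
    variants <- expanded[[tid]]
    is_gene <- events$category[i] == "gene"
    raw_names <- tolower(c(events$label[i], events$synonyms[[i]]))

    key_ok <- vapply(seq_along(keys), function(ki) {
      ks <- key_stems[[ki]]
      if (length(ks)) {
        for (ph in variants) {
          hit <- if (rule == "exact") {
            setequal(ph$stem_set, ks)
          } else {
            4L * sum(ph$stem_set %in% ks) >= 3L * length(ph$stem_set)
          }
          if (hit) return(TRUE)
        }
      }
      is_gene && keys_lower[ki] %in% raw_names
    }, logical(1))

    rows <- db[db$key_term %in% keys[key_ok], , drop = FALSE]
    rows <- rows[!duplicated(paste(rows$source_db, rows$annotation_id,
                                   sep = "\x1f")), , drop = FALSE]
    ord <- order(rows$source_db, rows$annotation_id, method = "radix")
    rows <- rows[ord, , drop = FALSE]
    rownames(rows) <- NULL
    if (nrow(rows) == 0L) empty_db else rows
  })
  names(sets) <- events$term_id
  structure(sets, class = "event_annotations", rule = rule)
}

#' Per-source annotation counts
#'
#' @param sets an `event_annotations` object from [annotate_events()].
#' @return data frame `(term_id, source_db, n_annotations)`, one row per
#'   event-source combination with at least one annotation; the column sum
#'   equals the total number of (deduplicated) annotations.
#' @export
summarize_annotations <- function(sets) {
  rows <- lapply(names(sets), function(tid) {
    df <- sets[[tid]]
    if (nrow(df) == 0L) return(NULL)
    tb <- table(df$source_db)
    data.frame(term_id = tid, source_db = names(tb),
               n_annotations = as.integer(tb), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term_id = character(0), source_db = character(0),
                      n_annotations = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flatten annotation sets to one table
#'
#' @param sets an `event_annotations` object.
#' @return data frame with `term_id` followed by the annotation columns;
#'   zero rows if no event has any annotation.
#' @export
annotations_table <- function(sets) {
  rows <- lapply(names(sets), function(tid) {
    df <- sets[[tid]]
    if (nrow(df) == 0L) return(NULL)
    cbind(data.frame(term_id = tid, stringsAsFactors = FALSE), df)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term_id = character(0), source_db = character(0),
                      key_term = character(0), annotation_id = character(0),
                      annotation_label = character(0),
                      annotation_class = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.event_annotations <- function(x, ...) {
  n <- vapply(x, nrow, integer(1))
  cat("<event_annotations> ", length(x), " events, ", sum(n),
      " annotations (rule: ", attr(x, "rule"), ")\n", sep = "")
  invisible(x)
}
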