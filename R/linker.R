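#' Aggregate detection hits into co-occurrence links
#'
#' A link between two terms is supported by every record in which both terms
#' were detected. Stressor-event links pair one stressor with one event;
#' event-event links pair two distinct events. Pairs with no shared record
#' are omitted. Links are undirected: each unordered pair appears once, with
#' the stressor first (stressor-event) or the lexicographically smaller
#' term_id first (event-event).
#'
#' @param hits hit data frame from [detect_terms()].
#' @param stressor_ids character vector of stressor term ids.
#' @param event_ids character vector of event term ids.
#' @param kinds non-empty subset of `c("stressor-event", "event-event")`.
#' @return data frame of unscored links: `source_id`, `target_id`, `kind`,
#'   `count`, and a list-column `record_ids` (sorted ascending), ordered by
#'   (kind, source_id, target_id).
#' @export
extract_links <- function(hits, stressor_ids, event_ids,
                          kinds = c("stressor-event", "event-event")) {
  if (!length(kinds)) stop("kinds must be non-empty", call. = FALSE)
  bad <- setdiff(kinds, c("stressor-event", "event-event"))
  if (length(bad)) {
    stop("unknown kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  by_term <- split(hits$record_id, hits$term_id)
  pairs <- list()
  add_pairs <- function(a_ids, b_ids, kind) {
    for (a in a_ids) {
      ra <- by_term[[a]]
      if (is.null(ra)) next
      for (b in b_ids) {
        if (kind == "event-event" && b <= a) next  # each unordered pair once
        if (a == b) next
        rb <- by_term[[b]]
        if (is.null(rb)) next
        both <- sort(intersect(ra, rb), method = "radix")
        if (!length(both)) next
        pairs[[length(pairs) + 1L]] <<- list(
          source_id = a, target_id = b, kind = kind, record_ids = both
        )
      }
    }
  }
  if ("stressor-event" %in% kinds) {
    add_pairs(sort(stressor_ids, method = "radix"),
              sort(event_ids, method = "radix"), "stressor-event")
  }
  if ("event-event" %in% kinds) {
    add_pairs(sort(event_ids, method = "radix"),
              sort(event_ids, method = "radix"), "event-event")
  }
  if (!length(pairs)) {
    out <- data.frame(source_id = character(0), target_id = character(0),
                      kind = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
    out$record_ids <- list()
    return(out)
  }
  out <- data.frame(
    source_id = vapply(pairs, `[[`, character(1), "source_id"),
    target_id = vapply(pairs, `[[`, character(1), "target_id"),
    kind = vapply(pairs, `[[`, character(1), "kind"),
    count = vapply(pairs, function(p) length(p$record_ids), integer(1)),
    stringsAsFactors = FALSE
  )
  out$record_ids <- lapply(pairs, `[[`, "record_ids")
  ord <- order(out$kind, out$source_id, out$target_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the 2x2 contingency table for a term pair
#'
#' Cells count corpus records: both terms detected, first only, second only,
#' neither, against a closed-world background of `n_corpus` records.
#'
#' @param records_a,records_b record-id sets where each term was detected.
#' @param n_corpus total number of records in the analyzed corpus.
#' @return list with integer fields `n_both`, `n_a_only`, `n_b_only`,
#'   `n_neither`.
#' @export
build_contingency <- function(records_a, records_b, n_corpus) {
  records_a <- unique(records_a)
  records_b <- unique(records_b)
  n_union <- length(union(records_a, records_b))
  if (n_corpus < n_union) {
    stop("corpus size ", n_corpus, " smaller than union of record sets (",
         n_union, ")", call. = FALSE)
  }
  n_both <- length(intersect(records_a, records_b))
  list(
    n_both = n_both,
    n_a_only = length(records_a) - n_both,
    n_b_only = length(records_b) - n_both,
    n_neither = as.integer(n_corpus) - n_union
  )
}

#' One-sided Fisher exact test for co-occurrence enrichment
#'
#' Right-tail probability that the two terms co-occur in at least the
#' observed number of records under independence: `P(X >= n_both)` for `X`
#' hypergeometric with population `N` (all four cells), `n_both + n_a_only`
#' successes and `n_both + n_b_only` draws. A table with `n_both = 0` gives
#' exactly 1.
#'
#' @param tab contingency table from [build_contingency()].
#' @return p-value in `(0, 1]`.
#' @export
fisher_right_tail <- function(tab) {
  cells <- c(tab$n_both, tab$n_a_only, tab$n_b_only, tab$n_neither)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("invalid contingency cell", call. = FALSE)
  }
  if (tab$n_both == 0L) return(1)
  N <- sum(cells)
  m <- tab$n_both + tab$n_a_only
  k <- tab$n_both + tab$n_b_only
  stats::phyper(tab$n_both - 1L, m = m, n = N - m, k = k, lower.tail = FALSE)
}

#' Score links with Fisher p-values
#'
#' Computes a contingency table and a one-sided Fisher p-value for every
#' link, using each endpoint's full record set from `hits` and the corpus
#' size as background.
#'
#' @param links link data frame from [extract_links()].
#' @param hits hit data frame the links were extracted from.
#' @param n_corpus number of records in the corpus.
#' @return `links` with an added numeric `p_value` column.
#' @export
score_links <- function(links, hits, n_corpus) {
  by_term <- split(hits$record_id, hits$term_id)
  links$p_value <- vapply(seq_len(nrow(links)), function(i) {
    tab <- build_contingency(by_term[[links$source_id[i]]],
                             by_term[[links$target_id[i]]], n_corpus)
    fisher_right_tail(tab)
  }, numeric(1))
  links
}

#' Benjamini-Hochberg adjustment across links
#'
#' Step-up false-discovery-rate adjustment, computed separately within each
#' link kind (stressor-event and event-event links form different test
#' populations). With `method = "none"` no `adjusted_p` column is added.
#'
#' @param links scored link data frame (must have `p_value`).
#' @param method `"none"` or `"BH"`.
#' @return `links`, with an `adjusted_p` column when `method = "BH"`.
#' @export
adjust_pvalues <- function(links, method = c("none", "BH")) {
  method <- match.arg(method)
  if (method == "none") {
    links$adjusted_p <- NULL
    return(links)
  }
  links$adjusted_p <- NA_real_
  for (kd in unique(links$kind)) {
    idx <- which(links$kind == kd)
    links$adjusted_p[idx] <- stats::p.adjust(links$p_value[idx], method = "BH")
  }
  links
}

#' Confidence-scheme configuration
#'
#' @param alpha significance level applied to the (possibly adjusted) Fisher
#'   p-value; must lie in (0, 1).
#' @param count_moderate minimum co-occurrence count for a significant link
#'   to be rated High.
#' @param count_high minimum count for Very High (significant) or Moderate
#'   (non-significant); must be >= `count_moderate`.
#' @return list of validated parameters, class `confidence_config`.
#' @export
confidence_config <- function(alpha = 0.05, count_moderate = 5L,
                              count_high = 20L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  count_moderate <- as.integer(count_moderate)
  count_high <- as.integer(count_high)
  if (is.na(count_moderate) || is.na(count_high) || count_moderate < 1L ||
      count_high < count_moderate) {
    stop("count thresholds must satisfy 1 <= count_moderate <= count_high",
         call. = FALSE)
  }
  structure(list(alpha = alpha, count_moderate = count_moderate,
                 count_high = count_high), class = "confidence_config")
}

.confidence_levels <- c("Low", "Moderate", "High", "Very High")

#' Assign a confidence category to a link
#'
#' Combines statistical significance (`p < alpha`) with co-occurrence
#' frequency: Very High = significant and count >= `count_high`; High =
#' significant and count >= `count_moderate`; Moderate = significant with a
#' smaller count, or non-significant but count >= `count_high`; Low
#' otherwise. Category is non-decreasing in count and as p decreases.
#'
#' @param count integer co-occurrence count(s), >= 1.
#' @param p p-value(s) in `[0, 1]` (raw or adjusted, per configuration).
#' @param cfg a [confidence_config()].
#' @return character vector of categories; levels ordered
#'   Low < Moderate < High < Very High.
#' @export
assign_confidence <- function(count, p, cfg = confidence_config()) {
  stopifnot(inherits(cfg, "confidence_config"), length(count) == length(p))
  if (any(count < 1L)) stop("count must be >= 1", call. = FALSE)
  sig <- p < cfg$alpha
  out <- rep("Low", length(count))
  out[!sig & count >= cfg$count_high] <- "Moderate"
  out[sig] <- "Moderate"
  out[sig & count >= cfg$count_moderate] <- "High"
  out[sig & count >= cfg$count_high] <- "Very High"
  out
}

#' Full link-scoring pipeline
#'
#' Scores, optionally adjusts, and categorizes a set of extracted links.
#' When `p_adjust = "BH"` the confidence rule is applied to the adjusted
#' p-value; otherwise to the raw p-value.
#'
#' @inheritParams score_links
#' @inheritParams adjust_pvalues
#' @param cfg a [confidence_config()].
#' @return links with `p_value`, optional `adjusted_p`, and `confidence`.
#' @export
score_and_categorize <- function(links, hits, n_corpus,
                                 cfg = confidence_config(),
                                 method = c("none", "BH")) {
  method <- match.arg(method)
  links <- score_links(links, hits, n_corpus)
  links <- adjust_pvalues(links, method)
  p_use <- if (method == "BH") links$adjusted_p else links$p_value
  links$confidence <- if (nrow(links)) {
    assign_confidence(links$count, p_use, cfg)
  } else {
    character(0)
  }
  links
}
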