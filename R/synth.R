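# invented filler stems: never stopwords, resistant to suffix stripping, and
# checked at generation time to be disjoint from every term stem
.filler_vocab <- c(
  "zorbak", "quilmep", "fenwark", "drubnix", "clastorn", "mivrek",
  "plonduk", "sarquin", "tovmeld", "brindak", "koshnep", "velgrum",
  "darnip", "luskont", "merquat", "nivrolk", "ostrek", "pilgorn",
  "ruvnak", "selmip", "tarquem", "ulbrind", "vorshek", "wilmod",
  "yarnik", "zelquip", "halverk", "jormund", "kelpstrum", "lomirk"
)

#' Specification of a synthetic corpus with planted co-occurrences
#'
#' Defines the exact structure of a fixture corpus: which term pairs
#' co-occur in how many abstracts, how many solo mentions each term gets,
#' how many background abstracts mention no term at all, and (optionally)
#' what fraction of a pair's plants carry only `ceiling(3k/4)` of the second
#' term's `k` stems — mentions that the 3/4-threshold partial matcher must
#' find and the exact matcher must miss.
#'
#' Terms must have pairwise stem-disjoint variants (so plants cannot
#' collide) and each label word must contribute its own distinct stem (so a
#' partial mention can be composed word-wise). Pairs listed in
#' `partial_fraction_plants` must designate a second term with at least 4
#' distinct stems; for fewer, `ceiling(3k/4) = k` and a partial plant would
#' be indistinguishable from a full one.
#'
#' @param terms dictionary data frame ([read_dictionary()] layout).
#' @param pair_counts data frame `(term1, term2, count)` of planted
#'   co-mention counts; each pair must be stressor-event or event-event.
#' @param singleton_counts optional data frame `(term_id, count)` of extra
#'   solo mentions.
#' @param n_background number of abstracts mentioning no term.
#' @param partial_fraction_plants optional data frame
#'   `(term1, term2, fraction)`; `round(fraction * count)` of that pair's
#'   plants carry the reduced form of `term2`.
#' @param seed integer seed; placement randomness uses R's Mersenne-Twister
#'   generator and is recorded in the ground truth.
#' @return validated specification, class `corpus_spec`.
#' @export
corpus_spec <- function(terms, pair_counts, singleton_counts = NULL,
                        n_background = 0L, partial_fraction_plants = NULL,
                        seed = 1L) {
  stopifnot(is.data.frame(terms), is.data.frame(pair_counts))
  stopwords <- aop_stopwords()

  # per-term variant stem sets; labels additionally need one stem per word
  label_words <- list()
  variant_stems <- list()
  for (i in seq_len(nrow(terms))) {
    tid <- terms$term_id[i]
    ws <- aop_tokenize(terms$label[i])
    ws <- ws[!(ws %in% stopwords)]
    st <- .stem_fixpoint(ws)
    if (anyDuplicated(st) || length(st) == 0L) {
      stop("term '", tid, "': each label word must carry its own stem",
           call. = FALSE)
    }
    label_words[[tid]] <- ws
    vs <- lapply(expand_term(terms[i, , drop = FALSE], stopwords),
                 `[[`, "stem_set")
    variant_stems[[tid]] <- unique(unlist(vs))
  }
  ids <- terms$term_id
  for (a in seq_along(ids)) {
    for (b in seq_len(a - 1L)) {
      shared <- intersect(variant_stems[[ids[a]]], variant_stems[[ids[b]]])
      if (length(shared)) {
        stop("terms '", ids[b], "' and '", ids[a], "' share stem(s): ",
             paste(shared, collapse = ", "), call. = FALSE)
      }
    }
  }
  fillers <- .stem_fixpoint(.filler_vocab)
  clash <- intersect(fillers, unlist(variant_stems))
  if (length(clash)) {
    stop("filler vocabulary collides with term stem(s): ",
         paste(clash, collapse = ", "), call. = FALSE)
  }

  stopifnot(all(c("term1", "term2", "count") %in% names(pair_counts)))
  if (any(pair_counts$count < 0)) stop("negative pair count", call. = FALSE)
  for (i in seq_len(nrow(pair_counts))) {
    t1 <- pair_counts$term1[i]; t2 <- pair_counts$term2[i]
    if (!(t1 %in% ids) || !(t2 %in% ids) || t1 == t2) {
      stop("invalid pair (", t1, ", ", t2, ")", call. = FALSE)
    }
    cats <- terms$category[match(c(t1, t2), terms$term_id)]
    if (sum(cats == "stressor") > 1L) {
      stop("stressor-stressor pair (", t1, ", ", t2, ") not allowed",
           call. = FALSE)
    }
  }
  if (!is.null(singleton_counts)) {
    stopifnot(all(c("term_id", "count") %in% names(singleton_counts)),
              all(singleton_counts$term_id %in% ids),
              all(singleton_counts$count >= 0))
  }
  if (!is.null(partial_fraction_plants)) {
    stopifnot(all(c("term1", "term2", "fraction") %in%
                    names(partial_fraction_plants)))
    for (i in seq_len(nrow(partial_fraction_plants))) {
      t2 <- partial_fraction_plants$term2[i]
      fr <- partial_fraction_plants$fraction[i]
      if (fr < 0 || fr > 1) stop("fraction outside [0,1]", call. = FALSE)
      k <- length(label_words[[t2]])
      if (fr > 0 && k < 4L) {
        stop("partial plants for term '", t2, "' need >= 4 stems (has ", k,
             ")", call. = FALSE)
      }
    }
  }
  structure(list(terms = terms, pair_counts = pair_counts,
                 singleton_counts = singleton_counts,
                 n_background = as.integer(n_background),
                 partial_fraction_plants = partial_fraction_plants,
                 seed = as.integer(seed), label_words = label_words),
            class = "corpus_spec")
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

.filler_sentence <- function(n = 3L) {
  paste0(paste(sample(.filler_vocab, n), collapse = " "), ".")
}

#' Generate a corpus with known planted structure
#'
#' Builds one abstract per planted co-mention or solo mention plus the
#' requested background abstracts, embedding term labels (or their reduced
#' partial forms) inside filler sentences drawn from a stem-disjoint
#' nonsense vocabulary, then shuffles record order. Deterministic for a
#' fixed seed.
#'
#' @param spec a [corpus_spec()].
#' @return list with `corpus` (data frame in [read_corpus_tsv()] layout),
#'   `dictionary` (the spec's terms) and `truth`, the ground truth: per-mode
#'   expected hits, per-pair expected counts, per-term record sets,
#'   contingency tables, corpus size, seed and generator identity.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  .with_seed(spec$seed, {
    plants <- list()  # each: list(terms = c(...), partial_term = NULL/id)

    pf <- spec$partial_fraction_plants
    for (i in seq_len(nrow(spec$pair_counts))) {
      t1 <- spec$pair_counts$term1[i]
      t2 <- spec$pair_counts$term2[i]
      cnt <- spec$pair_counts$count[i]
      if (cnt == 0L) next
      n_part <- 0L
      if (!is.null(pf)) {
        j <- which(pf$term1 == t1 & pf$term2 == t2)
        if (length(j)) n_part <- as.integer(round(pf$fraction[j[1]] * cnt))
      }
      for (j in seq_len(cnt)) {
        plants[[length(plants) + 1L]] <- list(
          terms = c(t1, t2),
          partial_term = if (j <= n_part) t2 else NULL
        )
      }
    }
    if (!is.null(spec$singleton_counts)) {
      for (i in seq_len(nrow(spec$singleton_counts))) {
        tid <- spec$singleton_counts$term_id[i]
        for (j in seq_len(spec$singleton_counts$count[i])) {
          plants[[length(plants) + 1L]] <- list(terms = tid,
                                                partial_term = NULL)
        }
      }
    }
    for (i in seq_len(spec$n_background)) {
      plants[[length(plants) + 1L]] <- list(terms = character(0),
                                            partial_term = NULL)
    }
    if (!length(plants)) stop("empty corpus specification", call. = FALSE)
    plants <- plants[sample.int(length(plants))]

    term_text <- function(tid, partial) {
      ws <- spec$label_words[[tid]]
      if (partial) {
        k <- length(ws)
        ws <- ws[seq_len(ceiling(3 * k / 4))]
      }
      paste(ws, collapse = " ")
    }
    rows <- lapply(seq_along(plants), function(i) {
      p <- plants[[i]]
      mention <- vapply(p$terms, function(tid) {
        term_text(tid, identical(p$partial_term, tid))
      }, character(1))
      body_main <- if (length(mention)) {
        paste0(paste(c(mention[1],
                       sample(.filler_vocab, 2L),
                       if (length(mention) > 1L) mention[-1]),
                     collapse = " "), ".")
      } else {
        .filler_sentence(4L)
      }
      data.frame(
        record_id = sprintf("SYN%04d", i),
        year = 2000L + sample.int(25L, 1L),
        title = .filler_sentence(3L),
        abstract = paste(body_main, .filler_sentence(3L)),
        stringsAsFactors = FALSE
      )
    })
    corpus <- do.call(rbind, rows)
    rownames(corpus) <- NULL

    # ground truth ------------------------------------------------------
    rec_ids <- corpus$record_id
    full_hits <- list(); part_hits <- list()
    for (i in seq_along(plants)) {
      for (tid in plants[[i]]$terms) {
        if (identical(plants[[i]]$partial_term, tid)) {
          part_hits[[length(part_hits) + 1L]] <- c(tid, rec_ids[i])
        } else {
          full_hits[[length(full_hits) + 1L]] <- c(tid, rec_ids[i])
        }
      }
    }
    to_df <- function(lst) {
      if (!length(lst)) {
        return(data.frame(term_id = character(0), record_id = character(0),
                          stringsAsFactors = FALSE))
      }
      df <- data.frame(term_id = vapply(lst, `[`, character(1), 1L),
                       record_id = vapply(lst, `[`, character(1), 2L),
                       stringsAsFactors = FALSE)
      df[order(df$term_id, df$record_id, method = "radix"), , drop = FALSE]
    }
    hits_exact <- to_df(full_hits)
    hits_partial <- to_df(c(full_hits, part_hits))
    rownames(hits_exact) <- rownames(hits_partial) <- NULL

    recset <- function(hits) split(hits$record_id, hits$term_id)
    term_records_exact <- recset(hits_exact)
    term_records_partial <- recset(hits_partial)

    cat_of <- function(tid) {
      spec$terms$category[match(tid, spec$terms$term_id)]
    }
    pair_truth <- lapply(seq_len(nrow(spec$pair_counts)), function(i) {
      t1 <- spec$pair_counts$term1[i]; t2 <- spec$pair_counts$term2[i]
      c1 <- cat_of(t1); c2 <- cat_of(t2)
      if (c1 == "stressor" || c2 == "stressor") {
        kind <- "stressor-event"
        src <- if (c1 == "stressor") t1 else t2
        tgt <- if (c1 == "stressor") t2 else t1
      } else {
        kind <- "event-event"
        src <- min(t1, t2); tgt <- max(t1, t2)
      }
      n_exact <- length(intersect(term_records_exact[[t1]],
                                  term_records_exact[[t2]]))
      n_partial <- length(intersect(term_records_partial[[t1]],
                                    term_records_partial[[t2]]))
      data.frame(source_id = src, target_id = tgt, kind = kind,
                 count_exact = n_exact, count_partial = n_partial,
                 count_planted = spec$pair_counts$count[i],
                 stringsAsFactors = FALSE)
    })
    pair_truth <- do.call(rbind, pair_truth)
    ord <- order(pair_truth$kind, pair_truth$source_id, pair_truth$target_id,
                 method = "radix")
    pair_truth <- pair_truth[ord, , drop = FALSE]
    rownames(pair_truth) <- NULL

    n_rec <- nrow(corpus)
    tables_for <- function(recs) {
      out <- lapply(seq_len(nrow(pair_truth)), function(i) {
        build_contingency(recs[[pair_truth$source_id[i]]],
                          recs[[pair_truth$target_id[i]]], n_rec)
      })
      names(out) <- paste(pair_truth$source_id, pair_truth$target_id,
                          pair_truth$kind, sep = "|")
      out
    }

    truth <- list(
      seed = spec$seed,
      rng = "Mersenne-Twister (base R set.seed)",
      n_records = n_rec,
      hits_exact = hits_exact,
      hits_partial = hits_partial,
      term_records_exact = term_records_exact,
      term_records_partial = term_records_partial,
      pairs = pair_truth,
      contingency_exact = tables_for(term_records_exact),
      contingency_partial = tables_for(term_records_partial)
    )
    list(corpus = corpus, dictionary = spec$terms, truth = truth)
  })
}

#' Generate a planted annotation-database extract
#'
#' Emits annotation records keyed to event labels verbatim, with per-term
#' per-source counts exactly as planned, plus decoy records keyed to
#' nonsense phrases no event can match.
#'
#' @param events dictionary data frame of the events to annotate.
#' @param plan data frame `(term_id, source_db, n)`; every source must be
#'   one of the supported databases.
#' @param n_decoys number of decoy records to append.
#' @return annotation data frame ([read_annotation_db()] layout).
#' @export
generate_annotation_db <- function(events, plan, n_decoys = 5L) {
  stopifnot(all(plan$term_id %in% events$term_id),
            all(plan$source_db %in% .source_dbs), all(plan$n >= 0))
  class_of <- c("AOP-Wiki" = "AOP", "HPA" = "tissue", "KEGG" = "pathway",
                "Reactome" = "pathway", "WikiPathways" = "pathway",
                "UniProt" = "process", "DISEASES" = "disease",
                "DisGeNET" = "disease")
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    tid <- plan$term_id[i]; db <- plan$source_db[i]
    label <- events$label[match(tid, events$term_id)]
    for (j in seq_len(plan$n[i])) {
      rows[[length(rows) + 1L]] <- data.frame(
        source_db = db,
        key_term = label,
        annotation_id = sprintf("%s:%s:%03d", db, tid, j),
        annotation_label = sprintf("%s annotation %d for %s", db, j, label),
        annotation_class = unname(class_of[db]),
        stringsAsFactors = FALSE
      )
    }
  }
  for (j in seq_len(n_decoys)) {
    db <- .source_dbs[(j - 1L) %% length(.source_dbs) + 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      source_db = db,
      key_term = paste(.filler_vocab[(j - 1L) %% 28L + 1:3], collapse = " "),
      annotation_id = sprintf("%s:decoy:%03d", db, j),
      annotation_label = sprintf("decoy annotation %d", j),
      annotation_class = unname(class_of[db]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference planted-corpus conditions
#'
#' The package's standard fixture design: 12 terms (2 stressors, 9 biological
#' events, 1 gene) with stem-disjoint labels, 200 abstracts in total —
#' 16 planted pairs with co-mention counts spanning 0 to 15 (120 abstracts),
#' 30 solo mentions, and 50 background abstracts mentioning no term. With
#' `partial = TRUE`, 30% of the plants of every pair whose second term has
#' at least 4 stems carry only `ceiling(3k/4)` of its stems, so the exact
#' matcher must miss exactly those mentions while the 3/4-threshold matcher
#' finds them all.
#'
#' @param seed integer seed for [generate_corpus()].
#' @param partial add the 30% reduced-stem plants.
#' @return a [corpus_spec()].
#' @export
demo_corpus_spec <- function(seed = 1L, partial = FALSE) {
  terms <- data.frame(
    term_id = c("S1", "S2", "E1", "E2", "E3", "E4", "E5", "E6", "E7",
                "E8", "E9", "G1"),
    label = c("radon", "cadmium",
              "dna double strand breaks", "oxidative stress", "apoptosis",
              "cell cycle arrest", "inflammation",
              "genomic instability chromosome aberration",
              "mitochondrial membrane potential loss",
              "lung cancer", "neuronal degeneration", "TP53"),
    category = c("stressor", "stressor", "KE", "KE", "KE", "KE", "KE",
                 "KE", "KE", "AO", "AO", "gene"),
    stringsAsFactors = FALSE
  )
  terms$synonyms <- c(rep(list(character(0)), 11), list("p53"))

  pair_counts <- data.frame(
    term1 = c("S1", "S1", "S1", "S2", "S2", "E2", "E3", "E4", "E5", "E2",
              "E3", "E8", "E9", "E8", "E5", "S2"),
    term2 = c("E1", "E2", "E3", "E4", "E5", "E1", "E6", "E7", "E6", "E7",
              "E1", "E9", "G1", "E6", "G1", "G1"),
    count = c(15L, 12L, 8L, 10L, 5L, 14L, 9L, 7L, 11L, 6L, 13L, 4L, 3L,
              2L, 1L, 0L),
    stringsAsFactors = FALSE
  )
  singleton_counts <- data.frame(
    term_id = c("G1", "S1", "E8", "E3", "S2", "E5", "E9"),
    count = c(5L, 5L, 4L, 4L, 4L, 4L, 4L),
    stringsAsFactors = FALSE
  )
  pf <- NULL
  if (partial) {
    # every pair whose second term has >= 4 distinct stems (E1, E6, E7)
    idx <- pair_counts$term2 %in% c("E1", "E6", "E7")
    pf <- data.frame(term1 = pair_counts$term1[idx],
                     term2 = pair_counts$term2[idx],
                     fraction = 0.3, stringsAsFactors = FALSE)
  }
  corpus_spec(terms, pair_counts, singleton_counts, n_background = 50L,
              partial_fraction_plants = pf, seed = seed)
}
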