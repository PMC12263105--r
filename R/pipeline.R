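#' Configuration of a full mining run
#'
#' Validates paths and parameters for [aop_run()]. All referenced files must
#' exist at validation time.
#'
#' @param corpus path to the abstract corpus.
#' @param corpus_format `"tsv"` ([read_corpus_tsv()]) or `"medline"`
#'   ([read_medline()]).
#' @param stressors path to the stressor dictionary TSV (may be `NULL` when
#'   only event-event search is requested).
#' @param events path to the biological-event dictionary TSV.
#' @param kinds non-empty subset of `c("stressor-event", "event-event")`.
#' @param match matching mode, `"partial"` or `"exact"`.
#' @param scope `"abstract"` or `"sentence"`.
#' @param alpha,count_moderate,count_high confidence parameters
#'   ([confidence_config()]).
#' @param p_adjust `"none"` or `"BH"`.
#' @param annotate_dir optional directory of annotation TSV extracts (one
#'   file per source).
#' @param annotation_rule `"exact"` or `"partial"`.
#' @param min_count,min_confidence optional network filter
#'   ([filter_network()]); `min_confidence = NULL` disables the confidence
#'   filter.
#' @param stopword_file optional stopword list override.
#' @param stemmer stemming algorithm identifier.
#' @param out output directory (created if absent).
#' @return validated configuration, class `aop_config`.
#' @export
aop_config <- function(corpus, corpus_format = c("tsv", "medline"),
                       stressors = NULL, events,
                       kinds = c("stressor-event", "event-event"),
                       match = c("partial", "exact"),
                       scope = c("abstract", "sentence"),
                       alpha = 0.05, count_moderate = 5L, count_high = 20L,
                       p_adjust = c("none", "BH"),
                       annotate_dir = NULL,
                       annotation_rule = c("exact", "partial"),
                       min_count = 1L, min_confidence = NULL,
                       stopword_file = NULL, stemmer = "porter", out) {
  corpus_format <- match.arg(corpus_format)
  match <- match.arg(match)
  scope <- match.arg(scope)
  p_adjust <- match.arg(p_adjust)
  annotation_rule <- match.arg(annotation_rule)
  if (!length(kinds)) stop("kinds must be non-empty", call. = FALSE)
  bad <- setdiff(kinds, c("stressor-event", "event-event"))
  if (length(bad)) stop("unknown kind(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (p in c(corpus, stressors, events, stopword_file)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  if ("stressor-event" %in% kinds && is.null(stressors)) {
    stop("stressor dictionary required for stressor-event search",
         call. = FALSE)
  }
  if (!is.null(annotate_dir) && !dir.exists(annotate_dir)) {
    stop("annotation directory not found: ", annotate_dir, call. = FALSE)
  }
  cfg_conf <- confidence_config(alpha, count_moderate, count_high)
  if (!is.null(min_confidence) && !(min_confidence %in% .confidence_levels)) {
    stop("unknown confidence level '", min_confidence, "'", call. = FALSE)
  }
  structure(list(
    corpus = corpus, corpus_format = corpus_format, stressors = stressors,
    events = events, kinds = kinds, match = match, scope = scope,
    confidence = cfg_conf, p_adjust = p_adjust,
    annotate_dir = annotate_dir, annotation_rule = annotation_rule,
    min_count = as.integer(min_count), min_confidence = min_confidence,
    stopword_file = stopword_file, stemmer = stemmer, out = out
  ), class = "aop_config")
}

.log_info <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [aopminer] ", ...)
}

#' Run the full mining pipeline
#'
#' Orchestrates corpus reading, normalization, term detection, link
#' extraction and scoring, event annotation, network construction and
#' filtering, and writes `network.json`, `edges.tsv`, `nodes.tsv`,
#' `annotations.tsv` and `run_metadata.json` to the output directory.
#' Outputs are staged and only moved into place on success, so a failed run
#' leaves no partial files; identical inputs give byte-identical outputs.
#'
#' @param cfg an [aop_config()].
#' @param quiet suppress progress messages.
#' @return the filtered `aop_network`, invisibly.
#' @export
aop_run <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "aop_config"))
  say <- if (quiet) function(...) invisible() else .log_info
  t0 <- Sys.time()

  corpus <- switch(cfg$corpus_format,
                   tsv = read_corpus_tsv(cfg$corpus),
                   medline = read_medline(cfg$corpus))
  say("corpus: ", nrow(corpus), " records")

  stopwords <- aop_stopwords(cfg$stopword_file)
  events <- read_dictionary(cfg$events)
  dict <- events
  stressor_ids <- character(0)
  if (!is.null(cfg$stressors)) {
    stressors <- read_dictionary(cfg$stressors)
    overlap <- intersect(stressors$term_id, events$term_id)
    if (length(overlap)) {
      stop("term_id present in both dictionaries: ",
           paste(overlap, collapse = ", "), call. = FALSE)
    }
    stressor_ids <- stressors$term_id
    dict <- rbind(stressors, events)
  }
  event_ids <- events$term_id
  say("dictionary: ", length(stressor_ids), " stressors, ",
      length(event_ids), " events")

  expanded <- expand_dictionary(dict, stopwords, cfg$stemmer)
  docs <- normalize_corpus(corpus, stopwords, cfg$stemmer)
  hits <- detect_terms(docs, expanded, cfg$match, cfg$scope)
  say("detection: ", nrow(hits), " term-record hits (mode=", cfg$match,
      ", scope=", cfg$scope, ")")

  links <- extract_links(hits, stressor_ids, event_ids, cfg$kinds)
  links <- score_and_categorize(links, hits, nrow(corpus),
                                cfg$confidence, cfg$p_adjust)
  say("links: ", nrow(links), " (",
      paste(names(table(links$kind)), as.integer(table(links$kind)),
            sep = "=", collapse = ", "), ")")

  ann_sets <- NULL
  if (!is.null(cfg$annotate_dir)) {
    files <- sort(list.files(cfg$annotate_dir, pattern = "\\.tsv$",
                             full.names = TRUE), method = "radix")
    if (length(files)) {
      db <- do.call(rbind, lapply(files, read_annotation_db))
      ann_sets <- annotate_events(events, db, stopwords, cfg$stemmer,
                                  cfg$annotation_rule)
      say("annotation: ", sum(vapply(ann_sets, nrow, integer(1))),
          " annotations over ", length(ann_sets), " events")
    }
  }

  metadata <- list(
    alpha = cfg$confidence$alpha,
    annotation_rule = cfg$annotation_rule,
    corpus_format = cfg$corpus_format,
    count_high = cfg$confidence$count_high,
    count_moderate = cfg$confidence$count_moderate,
    kinds = cfg$kinds,
    match_mode = cfg$match,
    min_confidence = if (is.null(cfg$min_confidence)) "none"
                     else cfg$min_confidence,
    min_count = cfg$min_count,
    n_records = nrow(corpus),
    p_adjust = cfg$p_adjust,
    scope = cfg$scope,
    stemmer = cfg$stemmer,
    tool = paste0("aopminer ",
                  as.character(utils::packageVersion("aopminer")))
  )
  net <- build_network(links, dict, ann_sets, metadata)
  if (cfg$min_count > 1L || !is.null(cfg$min_confidence)) {
    net <- filter_network(net, cfg$min_count, cfg$min_confidence)
    say("filter: ", nrow(net$nodes), " nodes, ", nrow(net$edges),
        " edges retained")
  }

  stage <- tempfile("aopminer_stage_")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  write_text <- function(txt, name) {
    con <- file(file.path(stage, name), open = "wb")
    writeLines(enc2utf8(txt), con, sep = "", useBytes = TRUE)
    close(con)
  }
  write_text(to_network_json(net), "network.json")
  write_text(to_edge_table_tsv(net), "edges.tsv")
  write_text(to_node_table_tsv(net), "nodes.tsv")
  ann_df <- if (is.null(ann_sets)) annotations_table(structure(list(),
                                                     class = "event_annotations"))
            else annotations_table(ann_sets)
  write_annotation_tsv_all <- function(df, path) {
    con <- file(path, open = "wb")
    lines <- c(paste(names(df), collapse = "\t"),
               if (nrow(df)) do.call(paste, c(unname(df), sep = "\t")))
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
    close(con)
  }
  write_annotation_tsv_all(ann_df, file.path(stage, "annotations.tsv"))
  meta_json <- jsonlite::toJSON(
    metadata[order(names(metadata), method = "radix")],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_text(paste0(as.character(meta_json), "\n"), "run_metadata.json")

  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage)) {
    file.copy(file.path(stage, f), file.path(cfg$out, f), overwrite = TRUE)
  }
  say(sprintf("done in %.2fs; outputs in %s",
              as.numeric(difftime(Sys.time(), t0, units = "secs")),
              cfg$out))
  invisible(net)
}

#' Write a synthetic fixture set to a directory
#'
#' Convenience wrapper around [generate_corpus()] and
#' [generate_annotation_db()]: emits `corpus.tsv`, `dictionary.tsv`,
#' optional annotation extracts, and `ground_truth.json`.
#'
#' @param spec a [corpus_spec()].
#' @param out output directory.
#' @param annotation_plan optional plan for [generate_annotation_db()].
#' @return the ground truth list, invisibly.
#' @export
write_synth_fixtures <- function(spec, out, annotation_plan = NULL) {
  gen <- generate_corpus(spec)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_corpus_tsv(gen$corpus, file.path(out, "corpus.tsv"))
  write_dictionary_tsv(gen$dictionary, file.path(out, "dictionary.tsv"))
  if (!is.null(annotation_plan)) {
    db <- generate_annotation_db(gen$dictionary, annotation_plan)
    dir.create(file.path(out, "annotations"), showWarnings = FALSE)
    write_annotation_tsv(db, file.path(out, "annotations", "extract.tsv"))
  }
  truth_json <- jsonlite::toJSON(gen$truth, auto_unbox = TRUE, digits = NA,
                                 dataframe = "columns", pretty = TRUE)
  writeLines(as.character(truth_json), file.path(out, "ground_truth.json"),
             useBytes = TRUE)
  invisible(gen$truth)
}
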