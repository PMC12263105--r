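.conf_colors <- c("Low" = "orange", "Moderate" = "yellow",
                  "High" = "light-green", "Very High" = "dark-green")
.conf_hex <- c("orange" = "#E69F00", "yellow" = "#F0E442",
               "light-green" = "#90EE90", "dark-green" = "#006400")

.conf_rank <- function(x) match(x, .confidence_levels)

#' Build an undirected adverse outcome pathway network
#'
#' Nodes are exactly the terms incident to at least one link; each carries
#' its dictionary label, category, node type (stressor or event) and, when
#' provided, its database annotations. Edges carry the co-occurrence weight
#' (= number of supporting records), confidence category, Fisher p-value and
#' the sorted supporting record ids. The network is undirected: each
#' unordered pair appears once per kind.
#'
#' @param links scored and categorized links (see [score_and_categorize()]).
#' @param dictionary dictionary data frame covering every link endpoint.
#' @param annotations optional `event_annotations` from [annotate_events()].
#' @param metadata named list of run parameters to carry in the network
#'   (matching mode, scope, thresholds, stemmer, corpus size, ...).
#' @return object of class `aop_network`: list with `nodes`, `edges`
#'   data frames and `metadata`.
#' @export
build_network <- function(links, dictionary, annotations = NULL,
                          metadata = list()) {
  ids <- sort(unique(c(links$source_id, links$target_id)), method = "radix")
  unknown <- setdiff(ids, dictionary$term_id)
  if (length(unknown)) {
    stop("link endpoint(s) not in dictionary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  di <- match(ids, dictionary$term_id)
  ann <- lapply(ids, function(id) {
    if (is.null(annotations) || is.null(annotations[[id]])) return(character(0))
    df <- annotations[[id]]
    if (nrow(df) == 0L) return(character(0))
    sort(unique(paste(df$source_db, df$annotation_id, sep = ":")),
         method = "radix")
  })
  nodes <- data.frame(
    id = ids,
    label = dictionary$label[di],
    node_type = as.character(ifelse(dictionary$category[di] == "stressor",
                                    "stressor", "event")),
    category = dictionary$category[di],
    stringsAsFactors = FALSE
  )
  nodes$annotations <- ann

  edges <- data.frame(
    source = links$source_id,
    target = links$target_id,
    kind = links$kind,
    weight = as.integer(links$count),
    confidence = links$confidence,
    p_value = links$p_value,
    stringsAsFactors = FALSE
  )
  edges$record_ids <- lapply(links$record_ids,
                             function(r) sort(as.character(r), method = "radix"))
  ord <- order(edges$source, edges$target, edges$kind, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  if (any(edges$source == edges$target)) {
    stop("self-loop edge", call. = FALSE)
  }

  structure(list(nodes = nodes, edges = edges, metadata = metadata),
            class = "aop_network")
}

#' @export
print.aop_network <- function(x, ...) {
  cat("<aop_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  if (nrow(x$edges)) {
    tb <- table(factor(x$edges$confidence, levels = .confidence_levels))
    cat("  confidence:",
        paste(names(tb), as.integer(tb), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.aop_network <- function(object, ...) {
  list(
    n_nodes = nrow(object$nodes),
    n_edges = nrow(object$edges),
    by_kind = table(object$edges$kind),
    by_confidence = table(factor(object$edges$confidence,
                                 levels = .confidence_levels)),
    total_weight = sum(object$edges$weight)
  )
}

#' Filter a network by edge weight and confidence
#'
#' Keeps edges whose weight is at least `min_count` and whose confidence is
#' at least `min_confidence` (order Low < Moderate < High < Very High), then
#' removes nodes left without any edge. The effective cumulative filter is
#' recorded in the network metadata, so filtering twice equals filtering
#' once with the stricter thresholds.
#'
#' @param net an `aop_network`.
#' @param min_count minimum number of supporting records (>= 1).
#' @param min_confidence minimum confidence category, or `NULL` for none.
#' @return the filtered `aop_network`.
#' @export
filter_network <- function(net, min_count = 1L, min_confidence = NULL) {
  stopifnot(inherits(net, "aop_network"))
  min_count <- as.integer(min_count)
  if (is.na(min_count) || min_count < 1L) {
    stop("min_count must be >= 1", call. = FALSE)
  }
  conf_rank <- 1L
  if (!is.null(min_confidence)) {
    conf_rank <- .conf_rank(min_confidence)
    if (is.na(conf_rank)) {
      stop("unknown confidence level '", min_confidence, "'", call. = FALSE)
    }
  }
  keep <- net$edges$weight >= min_count &
    .conf_rank(net$edges$confidence) >= conf_rank
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  incident <- unique(c(edges$source, edges$target))
  nodes <- net$nodes[net$nodes$id %in% incident, , drop = FALSE]
  rownames(nodes) <- NULL

  meta <- net$metadata
  prev <- meta$filter
  eff_count <- max(min_count, if (!is.null(prev)) prev$min_count else 1L)
  prev_rank <- if (!is.null(prev) && !is.null(prev$min_confidence)) {
    .conf_rank(prev$min_confidence)
  } else 1L
  eff_rank <- max(conf_rank, prev_rank)
  meta$filter <- list(min_count = eff_count,
                      min_confidence = .confidence_levels[eff_rank])
  structure(list(nodes = nodes, edges = edges, metadata = meta),
            class = "aop_network")
}

.edge_id <- function(edges) {
  paste0(edges$source, "--", edges$target, "--", edges$kind)
}

#' Serialize a network to Cytoscape-compatible JSON
#'
#' Emits a single JSON object `{"elements": {"edges": [...], "nodes":
#' [...]}, "metadata": {...}}` where every node and edge is wrapped in a
#' `"data"` object, keys are sorted alphabetically, and output is
#' byte-stable across runs. Each edge carries its confidence category plus
#' a display color token (Low = orange, Moderate = yellow, High =
#' light-green, Very High = dark-green) and its hex default; the category
#' string is the normative field.
#'
#' @param net an `aop_network`.
#' @return JSON text (character scalar, UTF-8).
#' @export
to_network_json <- function(net) {
  stopifnot(inherits(net, "aop_network"))
  ub <- jsonlite::unbox
  node_list <- lapply(seq_len(nrow(net$nodes)), function(i) {
    n <- net$nodes[i, , drop = FALSE]
    list(data = list(
      annotations = as.character(n$annotations[[1]]),
      category = ub(n$category),
      id = ub(n$id),
      label = ub(n$label),
      node_type = ub(n$node_type)
    ))
  })
  edge_list <- lapply(seq_len(nrow(net$edges)), function(i) {
    e <- net$edges[i, , drop = FALSE]
    col <- unname(.conf_colors[[e$confidence]])
    list(data = list(
      confidence = ub(e$confidence),
      confidence_color = ub(col),
      confidence_hex = ub(unname(.conf_hex[[col]])),
      id = ub(.edge_id(e)),
      kind = ub(e$kind),
      p_value = ub(e$p_value),
      record_ids = as.character(e$record_ids[[1]]),
      source = ub(e$source),
      target = ub(e$target),
      weight = ub(e$weight)
    ))
  })
  meta <- net$metadata
  if (length(meta)) {
    meta <- meta[order(names(meta), method = "radix")]
    meta <- rapply(meta, function(x) {
      if (is.atomic(x) && length(x) == 1L) ub(x) else x
    }, how = "replace")
  }
  obj <- list(elements = list(edges = edge_list, nodes = node_list),
              metadata = meta)
  as.character(jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA,
                                null = "null", na = "null"))
}

.meta_from_json <- function(x) {
  lapply(x, function(v) {
    if (!is.list(v)) return(v)
    scalar <- vapply(v, function(e) is.atomic(e) && length(e) == 1L,
                     logical(1))
    if (length(v) && is.null(names(v)) && all(scalar)) {
      unlist(v)
    } else {
      .meta_from_json(v)
    }
  })
}

#' Parse a network back from its JSON serialization
#'
#' @param txt JSON text produced by [to_network_json()] (or a file path).
#' @return an `aop_network` equal to the serialized one (display colors are
#'   recomputed, not stored).
#' @export
read_network_json <- function(txt) {
  if (length(txt) == 1L && !grepl("^\\s*\\{", txt) && file.exists(txt)) {
    txt <- paste(readLines(txt, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
  }
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  nl <- obj$elements$nodes
  el <- obj$elements$edges
  nodes <- data.frame(
    id = vapply(nl, function(n) n$data$id, character(1)),
    label = vapply(nl, function(n) n$data$label, character(1)),
    node_type = vapply(nl, function(n) n$data$node_type, character(1)),
    category = vapply(nl, function(n) n$data$category, character(1)),
    stringsAsFactors = FALSE
  )
  nodes$annotations <- lapply(nl, function(n) {
    as.character(unlist(n$data$annotations))
  })
  edges <- data.frame(
    source = vapply(el, function(e) e$data$source, character(1)),
    target = vapply(el, function(e) e$data$target, character(1)),
    kind = vapply(el, function(e) e$data$kind, character(1)),
    weight = vapply(el, function(e) as.integer(e$data$weight), integer(1)),
    confidence = vapply(el, function(e) e$data$confidence, character(1)),
    p_value = vapply(el, function(e) as.numeric(e$data$p_value), numeric(1)),
    stringsAsFactors = FALSE
  )
  edges$record_ids <- lapply(el, function(e) {
    as.character(unlist(e$data$record_ids))
  })
  if (nrow(nodes) == 0L) nodes$annotations <- list()
  if (nrow(edges) == 0L) edges$record_ids <- list()
  meta <- if (is.null(obj$metadata)) list() else .meta_from_json(obj$metadata)
  structure(list(nodes = nodes, edges = edges, metadata = meta),
            class = "aop_network")
}

.fmt_num <- function(x) sprintf("%.17g", x)

#' Serialize network edges to a Cytoscape-readable TSV table
#'
#' Header `source, target, kind, weight, confidence, p_value, record_ids`
#' (tab-separated); record ids pipe-joined; rows sorted by (source, target,
#' kind); byte-identical across runs. P-values are printed with 17
#' significant digits so re-import reproduces them exactly.
#'
#' @param net an `aop_network`.
#' @return TSV text (character scalar, with trailing newline).
#' @export
to_edge_table_tsv <- function(net) {
  e <- net$edges
  ord <- order(e$source, e$target, e$kind, method = "radix")
  e <- e[ord, , drop = FALSE]
  lines <- c(
    "source\ttarget\tkind\tweight\tconfidence\tp_value\trecord_ids",
    if (nrow(e)) paste(e$source, e$target, e$kind, e$weight, e$confidence,
                       .fmt_num(e$p_value),
                       vapply(e$record_ids, paste, character(1),
                              collapse = "|"),
                       sep = "\t")
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Serialize network nodes to a TSV table
#'
#' Companion of [to_edge_table_tsv()]; header `id, label, node_type,
#' category, annotations` with annotations pipe-joined, rows sorted by id.
#'
#' @param net an `aop_network`.
#' @return TSV text.
#' @export
to_node_table_tsv <- function(net) {
  n <- net$nodes
  ord <- order(n$id, method = "radix")
  n <- n[ord, , drop = FALSE]
  lines <- c(
    "id\tlabel\tnode_type\tcategory\tannotations",
    if (nrow(n)) paste(n$id, n$label, n$node_type, n$category,
                       vapply(n$annotations, paste, character(1),
                              collapse = "|"),
                       sep = "\t")
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Rebuild a network from its TSV tables
#'
#' @param edge_tsv,node_tsv TSV text (or file paths) as produced by
#'   [to_edge_table_tsv()] and [to_node_table_tsv()].
#' @param metadata optional metadata list to attach.
#' @return an `aop_network`.
#' @export
network_from_tables <- function(edge_tsv, node_tsv, metadata = list()) {
  read_one <- function(x) {
    if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
      x <- paste(readLines(x, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
    }
    utils::read.delim(text = x, sep = "\t", header = TRUE, quote = "",
                      colClasses = "character", na.strings = NULL,
                      stringsAsFactors = FALSE)
  }
  e <- read_one(edge_tsv)
  n <- read_one(node_tsv)
  edges <- data.frame(
    source = e$source, target = e$target, kind = e$kind,
    weight = as.integer(e$weight), confidence = e$confidence,
    p_value = as.numeric(e$p_value), stringsAsFactors = FALSE
  )
  edges$record_ids <- lapply(strsplit(e$record_ids, "|", fixed = TRUE),
                             as.character)
  if (nrow(edges) == 0L) edges$record_ids <- list()
  nodes <- data.frame(
    id = n$id, label = n$label, node_type = n$node_type,
    category = n$category, stringsAsFactors = FALSE
  )
  nodes$annotations <- lapply(strsplit(n$annotations, "|", fixed = TRUE),
                              function(a) a[nzchar(a)])
  if (nrow(nodes) == 0L) nodes$annotations <- list()
  structure(list(nodes = nodes, edges = edges, metadata = metadata),
            class = "aop_network")
}
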