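#' @keywords internal
"_PACKAGE"

.term_categories <- c("stressor", "MIE", "KE", "AO", "gene", "event-unspecified")
.source_dbs <- c("AOP-Wiki", "HPA", "KEGG", "Reactome", "WikiPathways",
                 "UniProt", "DISEASES", "DisGeNET")
.annotation_classes <- c("AOP", "pathway", "disease", "tissue", "process")

# strict UTF-8 TSV reader; a non-UTF-8 byte is an error, never replaced
.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", encoding = "UTF-8",
                          check.names = FALSE, na.strings = NULL,
                          stringsAsFactors = FALSE)
  bad <- vapply(df, function(col) any(!validUTF8(col)), logical(1))
  if (any(bad)) {
    stop("invalid UTF-8 bytes in column(s): ",
         paste(names(df)[bad], collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  df
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(df), sep = "\t")))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Read an abstract corpus from TSV
#'
#' Expects a UTF-8 tab-separated file with header columns `record_id`, `year`,
#' `title`, `abstract`. One row per literature record; an empty `year` field
#' becomes `NA`.
#'
#' @param path path to the corpus file.
#' @return data frame with columns `record_id` (character), `year` (integer,
#'   `NA` allowed), `title`, `abstract`; row order follows the file.
#' @export
read_corpus_tsv <- function(path) {
  df <- .read_tsv(path, c("record_id", "year", "title", "abstract"))
  out <- data.frame(
    record_id = df$record_id,
    year = suppressWarnings(as.integer(ifelse(nzchar(df$year), df$year, NA))),
    title = df$title,
    abstract = df$abstract,
    stringsAsFactors = FALSE
  )
  .validate_corpus(out)
  out
}

.validate_corpus <- function(corpus) {
  dup <- unique(corpus$record_id[duplicated(corpus$record_id)])
  if (length(dup)) {
    stop("duplicate record_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(corpus$record_id))) {
    stop("empty record_id", call. = FALSE)
  }
  empty <- !nzchar(corpus$title) & !nzchar(corpus$abstract)
  if (any(empty)) {
    stop("records with both title and abstract empty: ",
         paste(corpus$record_id[empty], collapse = ", "), call. = FALSE)
  }
  invisible(corpus)
}

#' Write an abstract corpus to TSV
#'
#' Inverse of [read_corpus_tsv()]; `NA` years are written as empty fields.
#'
#' @param corpus corpus data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_corpus_tsv <- function(corpus, path) {
  df <- data.frame(
    record_id = corpus$record_id,
    year = ifelse(is.na(corpus$year), "", as.character(corpus$year)),
    title = corpus$title,
    abstract = corpus$abstract,
    stringsAsFactors = FALSE
  )
  .write_tsv(df, path)
}

#' Read a corpus in MEDLINE tagged format
#'
#' Parses the PubMed export dialect: records separated by blank lines, fields
#' tagged `PMID-`, `TI  -`, `AB  -`, `DP  -`, with continuation lines
#' indented and joined by single spaces. The year is the first 4-digit token
#' of the `DP` field.
#'
#' @param path path to the MEDLINE file.
#' @return corpus data frame as in [read_corpus_tsv()].
#' @export
read_medline <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (any(!validUTF8(lines))) stop("invalid UTF-8 in ", path, call. = FALSE)

  records <- list()
  fields <- list()
  cur_tag <- NULL
  flush <- function() {
    if (length(fields)) records[[length(records) + 1L]] <<- fields
    fields <<- list()
    cur_tag <<- NULL
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    if (grepl("^[A-Z0-9]{1,4}\\s*- ", ln)) {
      cur_tag <- sub("^([A-Z0-9]{1,4})\\s*- .*$", "\\1", ln)
      val <- sub("^[A-Z0-9]{1,4}\\s*- ", "", ln)
      fields[[cur_tag]] <- c(fields[[cur_tag]], val)
    } else if (grepl("^\\s+", ln) && !is.null(cur_tag)) {
      i <- length(fields[[cur_tag]])
      fields[[cur_tag]][i] <- paste(fields[[cur_tag]][i], trimws(ln))
    }
  }
  flush()

  if (!length(records)) {
    stop("no records found in MEDLINE file ", path, call. = FALSE)
  }
  rows <- lapply(records, function(f) {
    if (is.null(f$PMID)) stop("MEDLINE record lacks PMID", call. = FALSE)
    dp <- if (is.null(f$DP)) "" else f$DP[1]
    ym <- regmatches(dp, regexpr("\\b\\d{4}\\b", dp))
    data.frame(
      record_id = trimws(f$PMID[1]),
      year = if (length(ym)) as.integer(ym) else NA_integer_,
      title = if (is.null(f$TI)) "" else f$TI[1],
      abstract = if (is.null(f$AB)) "" else f$AB[1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .validate_corpus(out)
  out
}

#' Read a term dictionary from TSV
#'
#' Columns `term_id`, `label`, `category`, `synonyms`; synonyms are
#' pipe-separated and may be empty. Categories are restricted to
#' `stressor`, `MIE`, `KE`, `AO`, `gene`, `event-unspecified`.
#'
#' @param path path to the dictionary file.
#' @return data frame with a list-column `synonyms` (character vectors,
#'   whitespace-stripped, empty fragments dropped).
#' @export
read_dictionary <- function(path) {
  df <- .read_tsv(path, c("term_id", "label", "category", "synonyms"))
  dup <- unique(df$term_id[duplicated(df$term_id)])
  if (length(dup)) {
    stop("duplicate term_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- !(df$category %in% .term_categories)
  if (any(bad)) {
    stop("unknown category in row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(df$category[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(df$label))) {
    stop("empty label for term_id: ",
         paste(df$term_id[!nzchar(df$label)], collapse = ", "), call. = FALSE)
  }
  syn <- lapply(strsplit(df$synonyms, "|", fixed = TRUE), function(s) {
    s <- trimws(s)
    s[nzchar(s)]
  })
  out <- data.frame(term_id = df$term_id, label = df$label,
                    category = df$category, stringsAsFactors = FALSE)
  out$synonyms <- syn
  out
}

#' Write a term dictionary to TSV
#'
#' @param dictionary dictionary data frame (synonyms as a list-column).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dictionary_tsv <- function(dictionary, path) {
  df <- data.frame(
    term_id = dictionary$term_id,
    label = dictionary$label,
    category = dictionary$category,
    synonyms = vapply(dictionary$synonyms, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE
  )
  .write_tsv(df, path)
}

#' Read an annotation-database extract from TSV
#'
#' Columns `source_db`, `key_term`, `annotation_id`, `annotation_label`,
#' `annotation_class`. Sources are restricted to AOP-Wiki, HPA, KEGG,
#' Reactome, WikiPathways, UniProt, DISEASES, DisGeNET; classes to AOP,
#' pathway, disease, tissue, process.
#'
#' @param path path to the extract.
#' @return validated data frame, row order preserved.
#' @export
read_annotation_db <- function(path) {
  df <- .read_tsv(path, c("source_db", "key_term", "annotation_id",
                          "annotation_label", "annotation_class"))
  bad <- !(df$source_db %in% .source_dbs)
  if (any(bad)) {
    stop("unknown source_db: ",
         paste(unique(df$source_db[bad]), collapse = ", "), call. = FALSE)
  }
  bad <- !(df$annotation_class %in% .annotation_classes)
  if (any(bad)) {
    stop("unknown annotation_class: ",
         paste(unique(df$annotation_class[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(df$key_term))) stop("blank key_term", call. = FALSE)
  if (any(!nzchar(df$annotation_id))) stop("blank annotation_id", call. = FALSE)
  df
}

#' Write an annotation-database extract to TSV
#'
#' @param db annotation data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_annotation_tsv <- function(db, path) {
  .write_tsv(db[, c("source_db", "key_term", "annotation_id",
                    "annotation_label", "annotation_class")], path)
}
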