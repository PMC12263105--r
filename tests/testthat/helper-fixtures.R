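# shared fixtures and independent oracles

# small toy dictionary with stem-disjoint labels
toy_terms <- function() {
  t <- data.frame(
    term_id = c("S1", "E1", "E2", "G1"),
    label = c("radon", "dna double strand breaks", "oxidative stress",
              "TP53"),
    category = c("stressor", "KE", "KE", "gene"),
    stringsAsFactors = FALSE
  )
  t$synonyms <- list(character(0), character(0), "oxidant stress", "p53")
  t
}

# independent Fisher oracle: explicit summation of the hypergeometric mass
# over all outcomes at least as extreme (never calls phyper/fisher.test)
fisher_oracle <- function(n_both, n_a_only, n_b_only, n_neither) {
  N <- n_both + n_a_only + n_b_only + n_neither
  K <- n_both + n_a_only  # records containing term A
  n <- n_both + n_b_only  # records containing term B
  xs <- n_both:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# random scored-link table for network tests
random_links <- function(n_terms = 6L, p_edge = 0.5) {
  ids <- sprintf("T%02d", seq_len(n_terms))
  pairs <- t(utils::combn(ids, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  n <- nrow(pairs)
  links <- data.frame(
    source_id = pairs[, 1], target_id = pairs[, 2],
    kind = sample(c("stressor-event", "event-event"), n, replace = TRUE),
    count = sample.int(30L, n, replace = TRUE),
    p_value = stats::runif(n),
    stringsAsFactors = FALSE
  )
  links$record_ids <- lapply(links$count, function(k) {
    sort(sprintf("R%03d", sample.int(500L, k)), method = "radix")
  })
  links$count <- vapply(links$record_ids, length, integer(1))
  links$confidence <- assign_confidence(links$count, links$p_value)
  links
}

random_network <- function(n_terms = 6L, p_edge = 0.5) {
  links <- random_links(n_terms, p_edge)
  dict <- data.frame(
    term_id = sprintf("T%02d", seq_len(n_terms)),
    label = sprintf("term number %02d", seq_len(n_terms)),
    category = sample(c("stressor", "KE", "AO"), n_terms, replace = TRUE),
    stringsAsFactors = FALSE
  )
  dict$synonyms <- rep(list(character(0)), n_terms)
  build_network(links, dict,
                metadata = list(match_mode = "partial", n_records = 500L,
                                stemmer = "porter"))
}

# structural equality of networks ignoring metadata
expect_network_equal <- function(a, b) {
  expect_equal(a$nodes, b$nodes)
  expect_equal(a$edges, b$edges)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path, useBytes = TRUE)
  path
}
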