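hits_from <- function(...) {
  sets <- list(...)
  do.call(rbind, lapply(names(sets), function(tid) {
    data.frame(term_id = tid, record_id = sets[[tid]],
               best_fraction = 1, mode = "partial",
               stringsAsFactors = FALSE)
  }))
}

test_that("links are record-set intersections of the endpoints", {
  hits <- hits_from(S = c("d1", "d2"), E = c("d2", "d3"))
  links <- extract_links(hits, "S", "E", "stressor-event")
  expect_equal(nrow(links), 1L)
  expect_equal(links$record_ids[[1]], "d2")
  expect_equal(links$count, 1L)
})

test_that("disjoint record sets produce no link", {
  hits <- hits_from(E1 = c("d1", "d2"), E2 = c("d3"))
  links <- extract_links(hits, character(0), c("E1", "E2"), "event-event")
  expect_equal(nrow(links), 0L)
})

test_that("links are undirected and kinds stay category-pure", {
  hits <- hits_from(S = c("d1", "d2"), E1 = c("d1", "d3"), E2 = c("d1"))
  links <- extract_links(hits, "S", c("E1", "E2"))
  # stressor never appears in an event-event link and vice versa
  se <- links[links$kind == "stressor-event", ]
  ee <- links[links$kind == "event-event", ]
  expect_true(all(se$source_id == "S"))
  expect_false(any(ee$source_id == "S" | ee$target_id == "S"))
  # supplying ids in any order yields the identical canonical table
  hits_rev <- hits[rev(seq_len(nrow(hits))), ]
  links2 <- extract_links(hits_rev, "S", c("E2", "E1"))
  expect_equal(links, links2)
  expect_error(extract_links(hits, "S", "E1", character(0)), "non-empty")
})

test_that("contingency tables follow set arithmetic", {
  t1 <- build_contingency(c("1", "2", "3"), c("2", "3", "4"), 10)
  expect_equal(t1, list(n_both = 2L, n_a_only = 1L, n_b_only = 1L,
                        n_neither = 6L))
  a <- c("x", "y")
  expect_equal(build_contingency(a, a, 2),
               list(n_both = 2L, n_a_only = 0L, n_b_only = 0L,
                    n_neither = 0L))
  expect_equal(build_contingency(c("1"), c("2"), 5)$n_both, 0L)
  expect_error(build_contingency(c("1", "2"), c("3"), 2), "smaller")
})

test_that("right-tail Fisher test matches hand-derived values", {
  # no co-occurrence: P(X >= 0) = 1 exactly
  expect_identical(
    fisher_right_tail(list(n_both = 0L, n_a_only = 3L, n_b_only = 2L,
                           n_neither = 10L)), 1)
  # N = 4 with margins 2,2: of the C(4,2)=6 equally likely draws, 5 give
  # at least one shared record -> P(X >= 1) = 5/6 (frozen from enumeration)
  p <- fisher_right_tail(list(n_both = 1L, n_a_only = 1L, n_b_only = 1L,
                              n_neither = 1L))
  expect_equal(p, 5 / 6, tolerance = 1e-12)
})

test_that("Fisher tail agrees with exhaustive enumeration on random tables", {
  set.seed(4021)
  for (i in 1:300) {
    cells <- as.integer(stats::rmultinom(1, sample(4:40, 1), rep(1 / 4, 4)))
    tab <- list(n_both = cells[1], n_a_only = cells[2],
                n_b_only = cells[3], n_neither = cells[4])
    expect_equal(fisher_right_tail(tab),
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher tail agrees with the greater-alternative fisher.test", {
  set.seed(555)
  for (i in 1:25) {
    cells <- as.integer(stats::rmultinom(1, sample(10:60, 1), rep(1 / 4, 4)))
    tab <- list(n_both = cells[1], n_a_only = cells[2],
                n_b_only = cells[3], n_neither = cells[4])
    ft <- stats::fisher.test(matrix(cells, 2, byrow = TRUE),
                             alternative = "greater")
    expect_equal(fisher_right_tail(tab), unname(ft$p.value),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment follows the step-up rule per link kind", {
  links <- data.frame(
    source_id = c("A", "A", "B"), target_id = c("B", "C", "C"),
    kind = "event-event", count = c(3L, 2L, 1L),
    p_value = c(0.01, 0.02, 0.03), stringsAsFactors = FALSE
  )
  adj <- adjust_pvalues(links, "BH")
  expect_equal(adj$adjusted_p, c(0.03, 0.03, 0.03))

  one <- adjust_pvalues(links[1, ], "BH")
  expect_equal(one$adjusted_p, one$p_value)

  none <- adjust_pvalues(links, "none")
  expect_null(none$adjusted_p)

  # populations are adjusted separately per kind
  links$kind <- c("stressor-event", "event-event", "event-event")
  adj2 <- adjust_pvalues(links, "BH")
  expect_equal(adj2$adjusted_p[1], 0.01)
  expect_equal(adj2$adjusted_p[2:3], c(0.03, 0.03))
})

test_that("confidence categories follow the count and significance bins", {
  cfg <- confidence_config()
  expect_equal(assign_confidence(25L, 0.001, cfg), "Very High")
  expect_equal(assign_confidence(2L, 0.5, cfg), "Low")
  expect_equal(assign_confidence(2L, 0.01, cfg), "Moderate")
  expect_equal(assign_confidence(7L, 0.01, cfg), "High")
  expect_equal(assign_confidence(25L, 0.5, cfg), "Moderate")
})

test_that("invalid confidence configurations are rejected", {
  expect_error(confidence_config(alpha = 0), "alpha")
  expect_error(confidence_config(alpha = 1.2), "alpha")
  expect_error(confidence_config(count_moderate = 10, count_high = 5),
               "thresholds")
  expect_error(confidence_config(count_moderate = 0), "thresholds")
})

test_that("confidence is monotone in count and in significance", {
  set.seed(90)
  cfg <- confidence_config()
  rank <- function(x) match(x, c("Low", "Moderate", "High", "Very High"))
  count <- sample.int(40L, 1000L, replace = TRUE)
  p <- stats::runif(1000L)
  base <- rank(assign_confidence(count, p, cfg))
  more <- rank(assign_confidence(count + sample.int(10L, 1000L, TRUE), p, cfg))
  sig <- rank(assign_confidence(count, p * stats::runif(1000L), cfg))
  expect_true(all(more >= base))
  expect_true(all(sig >= base))
})

test_that("scored links conserve counts against their hit support", {
  gen <- generate_corpus(demo_corpus_spec(seed = 8))
  docs <- normalize_corpus(gen$corpus)
  dict <- expand_dictionary(gen$dictionary)
  hits <- detect_terms(docs, dict, "partial", "abstract")
  stressors <- gen$dictionary$term_id[gen$dictionary$category == "stressor"]
  events <- setdiff(gen$dictionary$term_id, stressors)
  links <- score_and_categorize(extract_links(hits, stressors, events),
                                hits, nrow(gen$corpus))
  expect_true(all(links$count == lengths(links$record_ids)))
  by_term <- split(hits$record_id, hits$term_id)
  for (i in seq_len(nrow(links))) {
    expect_true(all(links$record_ids[[i]] %in% by_term[[links$source_id[i]]]))
    expect_true(all(links$record_ids[[i]] %in% by_term[[links$target_id[i]]]))
  }
  expect_true(all(links$p_value >= 0 & links$p_value <= 1))
})
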