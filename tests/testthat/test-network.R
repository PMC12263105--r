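test_that("networks contain exactly the incident terms as nodes", {
  set.seed(21)
  links <- random_links(5, 0.4)
  dict <- data.frame(term_id = sprintf("T%02d", 1:6),
                     label = letters[1:6],
                     category = c("stressor", rep("KE", 5)),
                     stringsAsFactors = FALSE)
  dict$synonyms <- rep(list(character(0)), 6)
  net <- build_network(links, dict)
  expect_setequal(net$nodes$id, unique(c(links$source_id, links$target_id)))
  expect_equal(nrow(net$edges), nrow(links))
  expect_false("T06" %in% net$nodes$id && !("T06" %in% c(links$source_id,
                                                         links$target_id)))
  # endpoints not in the dictionary are rejected
  expect_error(build_network(links, dict[1, , drop = FALSE]),
               "not in dictionary")
})

test_that("run metadata is carried through to serialization unchanged", {
  set.seed(33)
  meta <- list(match_mode = "exact", scope = "sentence", alpha = 0.05,
               n_records = 123L, stemmer = "porter",
               kinds = c("stressor-event", "event-event"))
  links <- random_links(4, 0.7)
  dict <- data.frame(term_id = sprintf("T%02d", 1:4), label = letters[1:4],
                     category = "KE", stringsAsFactors = FALSE)
  dict$synonyms <- rep(list(character(0)), 4)
  net <- build_network(links, dict, metadata = meta)
  back <- read_network_json(to_network_json(net))
  expect_equal(back$metadata[order(names(back$metadata))],
               meta[order(names(meta))])
})

test_that("filtering equals a brute-force edge scan with isolated-node drop", {
  set.seed(101)
  levels <- c("Low", "Moderate", "High", "Very High")
  for (i in 1:100) {
    net <- random_network(sample(3:8, 1), runif(1, 0.2, 0.9))
    mc <- sample.int(25L, 1)
    lvl <- sample(c(NA, levels), 1)
    filtered <- filter_network(net, mc, if (is.na(lvl)) NULL else lvl)

    keep <- net$edges$weight >= mc
    if (!is.na(lvl)) {
      keep <- keep & match(net$edges$confidence, levels) >= match(lvl, levels)
    }
    want_edges <- net$edges[keep, , drop = FALSE]
    rownames(want_edges) <- NULL
    want_nodes <- net$nodes[net$nodes$id %in%
                              c(want_edges$source, want_edges$target), ,
                            drop = FALSE]
    rownames(want_nodes) <- NULL
    expect_equal(filtered$edges, want_edges)
    expect_equal(filtered$nodes, want_nodes)
  }
})

test_that("trivial filter is the identity on nodes and edges", {
  set.seed(7)
  net <- random_network()
  f <- filter_network(net, 1L, NULL)
  expect_network_equal(f, net)
})

test_that("raising thresholds never adds nodes or edges, and count filters compose", {
  set.seed(55)
  for (i in 1:20) {
    net <- random_network()
    a <- sample.int(10L, 1); b <- sample.int(10L, 1)
    fa <- filter_network(net, a)
    fab <- filter_network(fa, b)
    fmax <- filter_network(net, max(a, b))
    expect_equal(fab, fmax)
    expect_lte(nrow(fab$edges), nrow(fa$edges))
    expect_true(all(fab$nodes$id %in% fa$nodes$id))
    fh <- filter_network(net, 1L, "High")
    fvh <- filter_network(fh, 1L, "Very High")
    expect_true(all(fvh$edges$confidence == "Very High"))
    expect_lte(nrow(fvh$edges), nrow(fh$edges))
  }
})

test_that("JSON serialization is stable, color-annotated and round-trips", {
  set.seed(303)
  for (i in 1:50) {
    net <- random_network(sample(3:7, 1))
    js1 <- to_network_json(net)
    js2 <- to_network_json(net)
    expect_identical(js1, js2)
    expect_network_equal(read_network_json(js1), net)
  }

  # Fig-style color tokens ride along with the category
  links <- data.frame(source_id = "A", target_id = "B",
                      kind = "stressor-event", count = 25L,
                      p_value = 0.001, confidence = "Very High",
                      stringsAsFactors = FALSE)
  links$record_ids <- list(sprintf("r%02d", 1:25))
  dict <- data.frame(term_id = c("A", "B"), label = c("a", "b"),
                     category = c("stressor", "KE"),
                     stringsAsFactors = FALSE)
  dict$synonyms <- list(character(0), character(0))
  js <- to_network_json(build_network(links, dict))
  expect_match(js, '"confidence_color":"dark-green"', fixed = TRUE)
  expect_match(js, '"confidence_hex":"#006400"', fixed = TRUE)
})

test_that("empty networks serialize to empty element arrays", {
  links <- data.frame(source_id = character(0), target_id = character(0),
                      kind = character(0), count = integer(0),
                      p_value = numeric(0), confidence = character(0),
                      stringsAsFactors = FALSE)
  links$record_ids <- list()
  dict <- toy_terms()
  net <- build_network(links, dict)
  js <- to_network_json(net)
  expect_match(js, '"elements":\\{"edges":\\[\\],"nodes":\\[\\]\\}')
  expect_network_equal(read_network_json(js), net)
})

test_that("TSV tables round-trip the edge multiset and node set exactly", {
  set.seed(404)
  for (i in 1:50) {
    net <- random_network(sample(3:7, 1))
    e1 <- to_edge_table_tsv(net)
    n1 <- to_node_table_tsv(net)
    expect_identical(e1, to_edge_table_tsv(net))
    expect_identical(n1, to_node_table_tsv(net))
    back <- network_from_tables(e1, n1)
    ord_e <- order(net$edges$source, net$edges$target, net$edges$kind,
                   method = "radix")
    ord_n <- order(net$nodes$id, method = "radix")
    want <- structure(list(nodes = net$nodes[ord_n, , drop = FALSE],
                           edges = net$edges[ord_e, , drop = FALSE],
                           metadata = list()), class = "aop_network")
    rownames(want$nodes) <- rownames(want$edges) <- NULL
    expect_network_equal(back, want)
  }
})

test_that("edge tables have a header row plus one sorted row per edge", {
  set.seed(11)
  net <- random_network(5, 0.8)
  lines <- strsplit(to_edge_table_tsv(net), "\n")[[1]]
  expect_equal(lines[1],
               "source\ttarget\tkind\tweight\tconfidence\tp_value\trecord_ids")
  expect_equal(length(lines) - 1L, nrow(net$edges))
  keys <- vapply(strsplit(lines[-1], "\t"), function(x) paste(x[1], x[2]),
                 character(1))
  expect_equal(keys, sort(keys, method = "radix"))
})
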