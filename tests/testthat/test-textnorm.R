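test_that("tokenization lowercases and splits on punctuation", {
  expect_equal(aop_tokenize("DNA double-strand breaks"),
               c("dna", "double", "strand", "breaks"))
  expect_equal(aop_tokenize("TP53-mediated apoptosis."),
               c("tp53", "mediated", "apoptosis"))
  expect_equal(aop_tokenize(""), character(0))
  expect_equal(aop_tokenize("p38/MAPK 5 signaling"),
               c("p38", "mapk", "5", "signaling"))
})

# stems frozen from the Porter algorithm's published example vocabulary
test_that("Porter stemmer reproduces the algorithm's reference stems", {
  pairs <- c(
    caresses = "caress", ponies = "poni", ties = "ti", cats = "cat",
    feed = "feed", agreed = "agre", plastered = "plaster", bled = "bled",
    motoring = "motor", conflated = "conflat", troubled = "troubl",
    sized = "size", hopping = "hop", tanned = "tan", falling = "fall",
    hissing = "hiss", fizzed = "fizz", failing = "fail", filing = "file",
    happy = "happi", sky = "sky", relational = "relat",
    conditional = "condit", rational = "ration", valenci = "valenc",
    hesitanci = "hesit", digitizer = "digit", conformabli = "conform",
    radicalli = "radic", differentli = "differ", vileli = "vile",
    analogousli = "analog", vietnamization = "vietnam",
    predication = "predic", operator = "oper", feudalism = "feudal",
    decisiveness = "decis", hopefulness = "hope", callousness = "callous",
    formaliti = "formal", sensitiviti = "sensit", sensibiliti = "sensibl",
    triplicate = "triplic", formative = "form", formalize = "formal",
    electriciti = "electr", electrical = "electr", hopeful = "hope",
    goodness = "good", revival = "reviv", allowance = "allow",
    inference = "infer", airliner = "airlin", gyroscopic = "gyroscop",
    adjustable = "adjust", defensible = "defens", irritant = "irrit",
    replacement = "replac", adjustment = "adjust", dependent = "depend",
    adoption = "adopt", homologou = "homolog", communism = "commun",
    activate = "activ", angulariti = "angular", homologous = "homolog",
    effective = "effect", bowdlerize = "bowdler", probate = "probat",
    rate = "rate", cease = "ceas", controll = "control", roll = "roll"
  )
  expect_equal(porter_stem(names(pairs)), unname(pairs))
})

test_that("domain vocabulary stems as expected and short tokens pass through", {
  expect_equal(porter_stem("stressors"), "stressor")
  expect_equal(porter_stem(c("tp53", "p53", "dna", "at", "be")),
               c("tp53", "p53", "dna", "at", "be"))
})

test_that("phrase normalization drops stopwords and keeps stem order", {
  ph <- normalize_phrase("increase in oxidative stress",
                         stopwords = c("in"))
  expect_length(ph$stems, 3L)
  expect_equal(ph$stems[2:3], porter_stem(c("oxidative", "stress")))
  # stems are a fixed point of the stemmer (normalization idempotence)
  expect_equal(porter_stem(ph$stems), ph$stems)
  expect_equal(ph$stem_set, unique(ph$stems))
})

test_that("phrase of only stopwords is a validation error", {
  expect_error(normalize_phrase("the of"), "content words")
})

test_that("no output stem ever equals a stemmed stopword", {
  stop_stems <- porter_stem(aop_stopwords())
  texts <- c("being once doing further the radon exposure",
             "dna damage during cell cycle arrest",
             "having more oxidative stress than before")
  for (tx in texts) {
    ph <- normalize_phrase(tx)
    expect_length(intersect(ph$stems, stop_stems), 0L)
  }
})

test_that("document normalization segments sentences and unions stems", {
  rec <- list(record_id = "r1", title = "Radon exposure.",
              abstract = "It causes dna damage. Apoptosis follows!")
  doc <- normalize_document(rec)
  expect_s3_class(doc, "normalized_document")
  expect_length(doc$sentence_stems, 3L)
  expect_setequal(doc$all_stems,
                  unique(unlist(doc$sentence_stems)))
})

test_that("title-only records yield at least one sentence", {
  doc <- normalize_document(list(record_id = "r2",
                                 title = "Oxidative stress", abstract = ""))
  expect_gte(length(doc$sentence_stems), 1L)
  expect_true("stress" %in% doc$all_stems)
})

test_that("normalization is idempotent on reconstructed stem text", {
  set.seed(11)
  samples <- c(
    "Radon induces dna double-strand breaks in lung tissue.",
    "TP53-mediated apoptosis and the cell cycle; arrest follows.",
    "Oxidative stress, inflammation and neuronal degeneration!"
  )
  for (tx in samples) {
    ph1 <- normalize_phrase(tx)
    ph2 <- normalize_phrase(paste(ph1$stems, collapse = " "))
    expect_equal(ph2$stems, ph1$stems)
  }
})

test_that("term expansion covers synonyms and deduplicates by stem set", {
  t1 <- list(term_id = "E9", label = "oxidative stress",
             synonyms = list(c("redox imbalance", "stress oxidative")))
  ph <- expand_term(t1)
  # "stress oxidative" has the same stem set as the label; deduplicated,
  # while "redox imbalance" survives as a distinct variant
  expect_length(ph, 2L)
  expect_equal(ph[[1]]$source_label, "oxidative stress")
  # "oxidant" and "oxidative" share the stem "oxid": full dedup to one
  t2 <- list(term_id = "E9b", label = "oxidative stress",
             synonyms = list("oxidant stress"))
  expect_length(expand_term(t2), 1L)

  t2 <- list(term_id = "G7", label = "TP53", synonyms = list("p53"))
  ph2 <- expand_term(t2)
  expect_length(ph2, 2L)
  expect_equal(lengths(lapply(ph2, `[[`, "stems")), c(1L, 1L))
})

test_that("a term with no matchable variant is an error", {
  bad <- list(term_id = "X", label = "the", synonyms = list("of and"))
  expect_error(expand_term(bad), "no matchable variant")
})

test_that("unsupported stemmer identifiers are rejected", {
  expect_error(normalize_phrase("radon", stemmer = "snowball"),
               "unsupported stemmer")
})
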