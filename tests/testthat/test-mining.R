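test_that("dictionary matcher finds the documented drug-cascade mentions", {
  lex <- gene_lexicon(c("BDNF", "KCNJ11", "AP2M1", "ESR1", "APP"))
  text <- paste("glimepiride increases BDNF by binding to KCNJ11 via",
                "AP2M1 and ESR1 proteins")
  hits <- match_mentions(text, lex)
  expect_setequal(hits$symbol, c("BDNF", "KCNJ11", "AP2M1", "ESR1"))
  expect_false("APP" %in% hits$symbol)
  # surface equals the 0-based half-open slice of the searched text
  expect_equal(hits$surface,
               substring(text, hits$start + 1L, hits$end))
  expect_true(all(diff(hits$start) > 0))
})

test_that("matching respects word boundaries and hyphen contexts", {
  lex <- toy_lexicon()
  expect_equal(nrow(match_mentions("xBDNFx and BDNF2", lex)), 0L)
  h <- match_mentions("BDNF-dependent effects", lex)
  expect_equal(h$symbol, "BDNF")
  expect_equal(h$start, 0L)
  expect_equal(nrow(match_mentions("", lex)), 0L)
  expect_equal(nrow(match_mentions(NA_character_, lex)), 0L)
})

test_that("synonyms map to canonical symbols, longest match wins", {
  lex <- toy_lexicon()
  h <- match_mentions(
    "the brain-derived neurotrophic factor response", lex)
  expect_equal(h$symbol, "BDNF")
  expect_equal(nrow(h), 1L)
  expect_equal(tolower(h$surface), "brain-derived neurotrophic factor")
})

test_that("short symbols are blocked unless whitelisted; collisions resolve", {
  lex <- gene_lexicon(c("IR", "BDNF"))
  expect_equal(nrow(match_mentions("IR and BDNF", lex)), 1L)
  lex2 <- gene_lexicon(c("IR", "BDNF"), whitelist = "IR")
  expect_setequal(match_mentions("IR and BDNF", lex2)$symbol,
                  c("IR", "BDNF"))
  # one synonym claimed by two symbols: blocklisted by default
  lex3 <- gene_lexicon(c("INS", "INSR"),
                       synonyms = list("insulin", "insulin"))
  expect_equal(nrow(match_mentions("insulin signalling", lex3)), 0L)
  expect_error(
    gene_lexicon(c("INS", "INSR"), synonyms = list("insulin", "insulin"),
                 collision = "error"),
    "multiple symbols")
})

test_that("matcher agrees with the exhaustive position-by-position oracle", {
  lex <- toy_lexicon()
  vocab <- c("BDNF", "KCNJ11", "AP2M1", "ESR1", "APP", "PRKAB1",
             "xBDNFx", "BDNFAP2M1", "amyloid precursor protein",
             "brain-derived neurotrophic factor", "insulin", "cohort",
             "KCNJ11-linked", "(ESR1)", "APP,", "2APP", "T2DM")
  set.seed(7)
  for (i in 1:100) {
    text <- paste(sample(vocab, sample(3:12, 1), replace = TRUE),
                  collapse = " ")
    got <- match_mentions(text, lex)
    want <- oracle_match(text, lex)
    expect_equal(got$symbol, want$symbol, info = text)
    expect_equal(got$start, want$start, info = text)
    expect_equal(got$end, want$end, info = text)
  }
})

test_that("co-occurrence counting is per document", {
  hits <- list(d1 = c("X"), d2 = c("X"), d3 = character(), d4 = character())
  counts <- count_cooccurrence(hits, c("d2", "d3"), 4)
  expect_equal(counts$doc_count[["X"]], 2L)
  expect_equal(counts$disease_doc_count, 2L)
  expect_equal(counts$joint_count[["X"]], 1L)

  # five mentions inside one doc still contribute 1
  rep_hits <- data.frame(record_id = rep("d1", 5), symbol = rep("X", 5))
  c2 <- count_cooccurrence(rep_hits, "d1", 3)
  expect_equal(c2$doc_count[["X"]], 1L)
  expect_equal(c2$joint_count[["X"]], 1L)

  expect_error(count_cooccurrence(hits, "d1", 0), "empty corpus")
})

test_that("PMI follows log2(n_xd N / (n_x n_d)) with the zero-joint sentinel", {
  counts <- structure(list(n_docs = 100L, doc_count = c(X = 10L),
                           disease_doc_count = 10L,
                           joint_count = c(X = 10L)),
                      class = "cooccurrence_counts")
  expect_equal(compute_pmi(counts, "X")$pmi, log2(10), tolerance = 1e-12)

  # independence: n_xd = n_x n_d / N exactly -> 0
  counts$joint_count <- c(X = 1L)
  expect_equal(compute_pmi(counts, "X")$pmi, 0)

  counts$joint_count <- c(X = 0L)
  expect_identical(compute_pmi(counts, "X")$pmi, -Inf)
  expect_equal(compute_pmi(counts, "X", correction = TRUE)$pmi,
               log2(0.5 * 100 / (10 * 10)))

  expect_error(compute_pmi(counts, "Y"), "unknown symbol")
})

test_that("PMI is monotone in the joint count and symmetric in roles", {
  base <- structure(list(n_docs = 50L, doc_count = c(X = 12L),
                         disease_doc_count = 8L, joint_count = c(X = 0L)),
                    class = "cooccurrence_counts")
  pmis <- vapply(1:8, function(j) {
    base$joint_count <- c(X = as.integer(j))
    compute_pmi(base, "X")$pmi
  }, numeric(1))
  expect_true(all(diff(pmis) > 0))

  # symmetry: swap the symbol and the disease term set
  set.seed(11)
  docs <- sprintf("d%02d", 1:30)
  x_docs <- sample(docs, 12)
  d_docs <- sample(docs, 9)
  cx <- count_cooccurrence(
    stats::setNames(lapply(docs, function(d) if (d %in% x_docs) "X"
                           else character()), docs), d_docs, 30)
  cd <- count_cooccurrence(
    stats::setNames(lapply(docs, function(d) if (d %in% d_docs) "D"
                           else character()), docs), x_docs, 30)
  expect_equal(compute_pmi(cx, "X")$pmi, compute_pmi(cd, "D")$pmi)
})

test_that("repeat mentions inside documents change no count or PMI", {
  set.seed(3)
  docs <- sprintf("d%02d", 1:20)
  hits1 <- lapply(docs, function(d)
    sample(c("A", "B", "C"), sample(0:3, 1)))
  names(hits1) <- docs
  hits3 <- lapply(hits1, function(v) rep(v, 3))
  disease <- sample(docs, 7)
  c1 <- count_cooccurrence(hits1, disease, 20)
  c3 <- count_cooccurrence(hits3, disease, 20)
  expect_identical(c1, c3)
})

test_that("protein ranking applies thresholds and deterministic ties", {
  scores <- data.frame(
    symbol = c("B", "A", "C", "D", "E"),
    pmi = c(1.5, 1.5, 3.0, -Inf, 0.2),
    n_x = c(5L, 5L, 2L, 4L, 1L),
    n_xd = c(3L, 3L, 2L, 0L, 1L))
  expect_equal(rank_proteins(scores), c("C", "A", "B", "E"))
  expect_equal(rank_proteins(scores, min_pmi = 1), c("C", "A", "B"))
  expect_equal(rank_proteins(scores, min_docs = 5), c("A", "B"))
  expect_equal(rank_proteins(scores, include_zero_joint = TRUE),
               c("C", "A", "B", "E", "D"))
})

test_that("mined PMI equals the formula on independently recounted corpora", {
  at <- data.frame(symbol = c("BDNF", "APP", "ESR1"),
                   p_mention = c(0.2, 0.3, 0.1),
                   p_mention_disease = c(0.7, 0.3, 0.4))
  lex <- gene_lexicon(at$symbol)
  for (seed in 1:50) {
    sim <- simulate_corpus(corpus_spec(seed, 40, at, p_disease = 0.5))
    hits <- mine_corpus(sim$corpus, lex, fields = "body")
    disease <- find_disease_records(sim$corpus, "T2DM", fields = "body")
    counts <- count_cooccurrence(hits, disease, nrow(sim$corpus))
    # independent token-level recount straight from the text
    tokens <- strsplit(toupper(sim$corpus$body), "[^0-9A-Z]+")
    for (s in at$symbol) {
      n_x <- sum(vapply(tokens, function(tk) s %in% tk, logical(1)))
      has_d <- vapply(tokens, function(tk) "T2DM" %in% tk, logical(1))
      n_d <- sum(has_d)
      n_xd <- sum(vapply(tokens[has_d], function(tk) s %in% tk,
                         logical(1)))
      if (n_x == 0) {
        expect_false(s %in% names(counts$doc_count))
        next
      }
      got <- compute_pmi(counts, s)
      expect_equal(got$n_x, n_x)
      expect_equal(got$n_xd, n_xd)
      expected <- if (n_xd == 0) -Inf else log2(n_xd * 40 / (n_x * n_d))
      expect_equal(got$pmi, expected, tolerance = 1e-12)
    }
  }
})

test_that("strongly associated symbols outrank null symbols", {
  at <- data.frame(
    symbol = c("HIT1", "HIT2", "NUL1", "NUL2"),
    p_mention = c(0.02, 0.02, 0.5, 0.5),
    p_mention_disease = c(0.9, 0.9, 0.5, 0.5))
  lex <- gene_lexicon(at$symbol)
  recovered <- 0L
  for (seed in 1:20) {
    sim <- simulate_corpus(corpus_spec(seed + 400, 150, at,
                                       p_disease = 0.5))
    hits <- mine_corpus(sim$corpus, lex, fields = "body")
    disease <- find_disease_records(sim$corpus, "T2DM", fields = "body")
    counts <- count_cooccurrence(hits, disease, nrow(sim$corpus))
    ranked <- rank_proteins(pmi_scores(counts))
    if (all(c("HIT1", "HIT2") %in% ranked[1:2])) recovered <- recovered + 1L
  }
  expect_gte(recovered, 19L)
})
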