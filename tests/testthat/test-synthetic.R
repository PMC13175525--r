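test_that("corpus generation is deterministic and respects span invariants", {
  a <- generate_corpus(corpus_spec(n_docs = 5), seed = 7)
  b <- generate_corpus(corpus_spec(n_docs = 5), seed = 7)
  expect_identical(a$documents, b$documents)
  expect_identical(a$gold, b$gold)

  empty <- generate_corpus(corpus_spec(n_docs = 0), seed = 1)
  expect_equal(nrow(empty$documents), 0L)

  # gold gaps are >= 1 character (validate_corpus already ran inside)
  g <- dplyr::arrange(a$gold, doc_id, start)
  by_doc <- split(g, g$doc_id)
  for (d in by_doc) {
    if (nrow(d) > 1) expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
})

test_that("realized bin proportions approach their targets at large n", {
  spec <- corpus_spec(n_docs = 3400, entities_per_doc = 3)
  corpus <- generate_corpus(spec, seed = 123)
  l <- corpus$gold$end - corpus$gold$start
  expect_gt(length(l), 9000)
  props <- prop.table(table(cut_length_bin(l)))
  expect_lt(abs(props[["1-2"]] - 0.09), 0.015)
  expect_lt(abs(props[["3-6"]] - 0.35), 0.02)
})

test_that("infeasible document caps raise an error naming the document", {
  spec <- corpus_spec(n_docs = 3, entities_per_doc = 5, max_doc_length = 10)
  expect_error(generate_corpus(spec, seed = 1), "cannot fit document 'doc")
})

test_that("identity and total-miss perturbation configs behave as stated", {
  corpus <- generate_corpus(corpus_spec(n_docs = 5), seed = 2)
  idp <- perturb_predictions(corpus, perturbation_config(seed = 2))
  expect_equal(
    as.data.frame(idp),
    as.data.frame(dplyr::arrange(corpus$gold, doc_id, start))
  )
  none <- perturb_predictions(corpus, perturbation_config(miss_prob = 1, seed = 2))
  expect_equal(nrow(none), 0L)
})

test_that("perturbation is deterministic given seed and stays in bounds", {
  corpus <- generate_corpus(corpus_spec(n_docs = 6), seed = 4)
  cfg <- perturbation_config(
    miss_prob = 0.2, jitter_prob = 0.5, jitter_max = 3,
    frag_prob = 0.5, spurious_rate = 2, seed = 9
  )
  p1 <- perturb_predictions(corpus, cfg)
  p2 <- perturb_predictions(corpus, cfg)
  expect_identical(p1, p2)
  expect_silent(validate_spans(corpus$documents, p1, kind = "predicted"))
})

test_that("full fragmentation of length-10 entities gives exactly 0.9 coverage", {
  spec <- corpus_spec(
    n_docs = 340, entities_per_doc = 3,
    bin_props = c(0, 0, 1, 0, 0),
    bin_ranges = list(c(1, 2), c(3, 6), c(10, 10), c(11, 20), c(21, 35))
  )
  corpus <- generate_corpus(spec, seed = 5)
  expect_gt(nrow(corpus$gold), 900)
  cfg <- perturbation_config(frag_prob = 1, frag_k = 2, seed = 5)
  pred <- perturb_predictions(corpus, cfg)
  w <- weighted_scores(corpus$documents, corpus$gold, pred, p = c(1, 100))
  # every entity length 10, split once, one gap char dropped: coverage 9/10
  expect_equal(w$recall[w$p == 1], 0.9)
  expect_lt(w$recall[w$p == 100], 0.9)
})

test_that("no fragmentation and no jitter means p-independent scores", {
  corpus <- generate_corpus(corpus_spec(n_docs = 10), seed = 6)
  cfg <- perturbation_config(miss_prob = 0.3, spurious_rate = 1, seed = 6)
  pred <- perturb_predictions(corpus, cfg)
  w <- weighted_scores(corpus$documents, corpus$gold, pred, p = c(1, 1.5, 2, 100))
  expect_true(all(abs(w$f1 - w$f1[1]) < 1e-12))
})

test_that("generation corruption is seeded, marker-safe and rate-faithful", {
  corpus <- generate_corpus(corpus_spec(n_docs = 4), seed = 8)
  marked <- spans_to_marked_text(corpus$documents, corpus$gold)

  cfg0 <- perturbation_config(char_noise_rate = 0, seed = 8)
  expect_identical(corrupt_generation(marked, cfg0)$marked, marked$marked)

  cfg <- perturbation_config(char_noise_rate = 0.2, seed = 8)
  c1 <- corrupt_generation(marked, cfg)
  c2 <- corrupt_generation(marked, cfg)
  expect_identical(c1, c2)
  # markers survive corruption: substitution-only keeps every span
  subs <- corrupt_generation(
    marked, perturbation_config(char_noise_rate = 0.2, noise_ops = "sub", seed = 8)
  )
  p <- parse_marked_text(subs, "strict")
  expect_equal(nrow(p$spans), nrow(corpus$gold))
  # with insertions/deletions the output still parses without error
  expect_no_error(parse_marked_text(c1, "lenient"))

  # substitution-only at rate 1 changes every character
  abc <- tibble::tibble(doc_id = "d", marked = "abc")
  cs <- corrupt_generation(
    abc, perturbation_config(char_noise_rate = 1, noise_ops = "sub", seed = 1)
  )
  expect_equal(nchar(cs$marked), 3L)
  expect_true(all(strsplit(cs$marked, "")[[1]] != c("a", "b", "c")))
})

test_that("character noise produces edit distances near the expected count", {
  txt <- paste(sample(letters, 10000, replace = TRUE), collapse = "")
  marked <- tibble::tibble(doc_id = "d", marked = txt)
  cfg <- perturbation_config(char_noise_rate = 0.01, seed = 21)
  out <- corrupt_generation(marked, cfg)
  dist <- edit_distance(txt, out$marked)
  expect_gt(dist, 50) # Poisson(100), 5 sigma
  expect_lt(dist, 150)
})

test_that("exact match rate decreases monotonically with character noise", {
  corpus <- generate_corpus(corpus_spec(n_docs = 40), seed = 10)
  marked <- spans_to_marked_text(corpus$documents, corpus$gold)
  rates <- c(0, 0.005, 0.05, 0.5)
  emr <- vapply(rates, function(r) {
    cfg <- perturbation_config(char_noise_rate = r, seed = 10)
    out <- corrupt_generation(marked, cfg)
    p <- parse_marked_text(out, "lenient")
    fidelity_audit(corpus$documents, p$documents)$exact_match_rate
  }, numeric(1))
  expect_equal(emr[1], 1)
  expect_true(all(diff(emr) <= 0))
  expect_lt(emr[4], emr[1])
})
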