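test_that("entity soft score matches hand-derived values and handles limits", {
  expect_equal(entity_soft_score(10, 10, 2), 1.0)
  expect_equal(entity_soft_score(10, 4, 7), 0.4) # single fragment, any p
  expect_equal(entity_soft_score(10, c(5, 5), 1), 1.0)
  expect_equal(entity_soft_score(10, c(5, 5), 2), sqrt(0.5), tolerance = 1e-12)
  expect_equal(entity_soft_score(10, c(5, 5), Inf), 0.5)
  expect_equal(entity_soft_score(8, c(2, 2, 2), 2), sqrt(3) / 4, tolerance = 1e-12)
  expect_equal(entity_soft_score(10, integer(), 2), 0)
  expect_error(entity_soft_score(10, 5, 0.5), "p must be >= 1")
})

test_that("max-factoring keeps large penalties out of the underflow regime", {
  # a naive (0.01)^100 underflows; the factored form must not
  s <- entity_soft_score(100, c(1, 1), 100)
  expect_gt(s, 0)
  expect_equal(s, 0.01 * 2^(1 / 100), tolerance = 1e-12)
})

test_that("fragment decomposition distinguishes marker and mask semantics", {
  g <- spans("d", 0, 10)
  d1 <- decompose_fragments(g, spans(c("d", "d"), c(2, 7), c(5, 9)))
  expect_equal(d1$fragments[[1]], c(3L, 2L))
  expect_equal(d1$l, 10L)

  d2 <- decompose_fragments(g, spans("d", 8, 15))
  expect_equal(d2$fragments[[1]], 2L)

  adj <- spans(c("d", "d"), c(0, 5), c(5, 10))
  expect_equal(decompose_fragments(g, adj, "marker")$fragments[[1]], c(5L, 5L))
  expect_equal(decompose_fragments(g, adj, "mask")$fragments[[1]], 10L)
})

test_that("weighted scores on a hand-enumerated fixture match the char mask", {
  d <- documents("d", "abcde")
  g <- spans("d", 0, 2)
  pr <- spans("d", 1, 3)
  w <- weighted_scores(d, g, pr, p = 1)
  expect_equal(w$tp_mass, 1)
  expect_equal(w$fn_mass, 1)
  expect_equal(w$fp_mass, 1)
  expect_equal(w$precision, 0.5)
  expect_equal(w$recall, 0.5)
  expect_equal(w$f1, 0.5)
})

test_that("zero-denominator policy: both empty is perfect, one-sided is flagged", {
  d <- documents("d", "abcdef")
  both <- weighted_scores(d, spans(), spans(), p = c(1, 2))
  expect_true(all(both$f1 == 1))
  expect_true(all(both$note == "both_empty"))

  nopred <- weighted_scores(d, spans("d", 0, 3), spans(), p = 1)
  expect_equal(nopred$recall, 0)
  expect_equal(nopred$f1, 0)
  expect_equal(nopred$note, "no_predictions")

  nogold <- weighted_scores(d, spans(), spans("d", 0, 3), p = 1)
  expect_equal(nogold$precision, 0)
  expect_equal(nogold$note, "no_gold")
})

test_that("marker scores count each entity as one regardless of length", {
  d <- documents("d", strrep("x", 60))
  g <- spans(c("d", "d"), c(0, 10), c(2, 30)) # lengths 2 and 20
  pr <- spans("d", 10, 30) # only the long one, in one piece
  mk <- marker_scores(d, g, pr, p = c(1, 2, 100))
  expect_true(all(mk$recall == 0.5))
  w <- weighted_scores(d, g, pr, p = 1)
  expect_equal(w$recall, 20 / 22)

  # fully missed + fully extracted: recall 0.5 at every p
  pr2 <- spans("d", 0, 2)
  mk2 <- marker_scores(d, g, pr2, p = c(1, 1.5, 2, 100))
  expect_true(all(mk2$recall == 0.5))
})

test_that("spurious spans count one marker-mode FP only when fully disjoint", {
  d <- documents("d", strrep("x", 30))
  g <- spans("d", 0, 10)
  pr <- spans(c("d", "d", "d"), c(5, 15, 25), c(12, 20, 28))
  mk <- marker_scores(d, g, pr, p = 1)
  expect_equal(mk$fp_mass, 2) # the two spans not touching the entity
})

test_that("character scores match enumeration and flag degenerate cases", {
  d <- documents("d", "abcde")
  cs <- char_scores(d, spans("d", 0, 2), spans("d", 1, 3))
  expect_equal(cs$tp_mass, 1)
  expect_equal(cs$fp_mass, 1)
  expect_equal(cs$fn_mass, 1)
  expect_equal(cs$f1, 0.5)
  expect_equal(char_scores(d, spans("d", 1, 3), spans("d", 1, 3))$f1, 1)
  expect_equal(char_scores(d, spans("d", 1, 3), spans())$recall, 0)
})

test_that("token scores apply the any-overlap projection before counting", {
  d <- documents("d", "abcdef")
  seg <- spans(c("d", "d"), c(0, 4), c(4, 6))
  g <- spans("d", 0, 3)
  pr <- spans("d", 0, 5) # straddles into the second token
  ts <- token_scores(d, g, pr, seg)
  expect_equal(ts$precision, 0.5)
  expect_equal(ts$recall, 1)
  expect_equal(ts$f1, 2 / 3)
  expect_error(token_scores(d, g, pr), "segmentation")

  # aligned boundaries reduce to char scoring of collapsed labels
  seg2 <- spans(c("d", "d"), c(0, 3), c(3, 6))
  ts2 <- token_scores(d, g, spans("d", 0, 3), seg2)
  expect_equal(ts2$f1, 1)
})

test_that("both precision rules coincide at p = 1 and stay in [0, 1]", {
  for (seed in 1:10) {
    rc <- random_case(seed)
    m <- weighted_scores(rc$corpus$documents, rc$corpus$gold, rc$predicted,
      p = c(1, 2, 100), precision_rule = "mass"
    )
    s <- weighted_scores(rc$corpus$documents, rc$corpus$gold, rc$predicted,
      p = c(1, 2, 100), precision_rule = "symmetric"
    )
    expect_equal(m$precision[m$p == 1], s$precision[s$p == 1], tolerance = 1e-12)
    expect_true(all(s$precision >= 0 & s$precision <= 1))
    expect_true(all(m$precision >= 0 & m$precision <= 1))
  }
})

test_that("splitting a fragment strictly lowers the score for p > 1", {
  set.seed(7)
  for (i in 1:200) {
    l <- sample(4:40, 1)
    a <- sample(2:l, 1)
    a1 <- sample(seq_len(a - 1), 1)
    p <- sample(c(1.5, 2, 5, 100), 1)
    whole <- entity_soft_score(l, a, p)
    split <- entity_soft_score(l, c(a1, a - a1), p)
    expect_lt(split, whole)
    # and p = 1 is indifferent to the split
    expect_equal(
      entity_soft_score(l, a, 1), entity_soft_score(l, c(a1, a - a1), 1)
    )
  }
})

test_that("a span straddling two gold entities feeds both and adds no FP inside gold", {
  d <- documents("d", strrep("x", 20))
  g <- spans(c("d", "d"), c(0, 6), c(5, 12))
  pr <- spans("d", 3, 14) # covers tail of e1, all of e2, 2 chars beyond
  dec <- decompose_fragments(g, pr)
  expect_equal(dec$fragments[[1]], 2L)
  expect_equal(dec$fragments[[2]], 6L)
  w <- weighted_scores(d, g, pr, p = 1)
  expect_equal(w$fp_mass, 3) # offset 5 (gap) + offsets 12,13
  expect_equal(w$tp_mass, 8)
})

test_that("tidy, glance and autoplot work on score reports", {
  d <- documents("d", "abcdef")
  w <- weighted_scores(d, spans("d", 0, 3), spans("d", 0, 3))
  expect_s3_class(tidy(w), "tbl_df")
  expect_false(inherits(tidy(w), "score_report"))
  g <- glance(w)
  expect_equal(g$f1_max, 1)
  expect_s3_class(autoplot(w), "ggplot")
})
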