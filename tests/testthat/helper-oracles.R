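# Independent oracles: deliberately naive implementations used only to
# cross-check the package's optimized paths.

# textbook dynamic-programming Levenshtein distance over code points
dp_edit_distance <- function(a, b) {
  ca <- if (nchar(a)) strsplit(a, "")[[1]] else character()
  cb <- if (nchar(b)) strsplit(b, "")[[1]] else character()
  n <- length(ca)
  m <- length(cb)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

# per-character fragment enumeration: walk every character of the entity,
# record which merged predicted span covers it, fragments = maximal runs of
# the same covering span (marker semantics) or of coverage (mask semantics)
brute_decompose <- function(entity_start, entity_end, pred_starts, pred_ends,
                            semantics = "marker") {
  ids <- integer(entity_end - entity_start)
  for (c in entity_start:(entity_end - 1L)) {
    hit <- which(pred_starts <= c & c < pred_ends)
    ids[c - entity_start + 1L] <- if (length(hit)) hit[1] else 0L
  }
  if (semantics == "mask") ids[ids > 0L] <- 1L
  r <- rle(ids)
  as.integer(r$lengths[r$values > 0L])
}

# direct (no max-factoring) Hoelder score
brute_score <- function(l, a, p) {
  if (length(a) == 0) return(0)
  if (is.infinite(p)) return(max(a) / l)
  sum((a / l)^p)^(1 / p)
}

# full corpus weighted scores by character/fragment enumeration
brute_weighted <- function(docs, gold, predicted, p) {
  pred <- spanscore::normalize_spans(predicted)
  tp <- 0
  gold_mass <- 0
  covered <- 0
  for (i in seq_len(nrow(gold))) {
    ps <- pred[pred$doc_id == gold$doc_id[i], , drop = FALSE]
    a <- brute_decompose(gold$start[i], gold$end[i], ps$start, ps$end)
    l <- gold$end[i] - gold$start[i]
    tp <- tp + l * brute_score(l, a, p)
    gold_mass <- gold_mass + l
    covered <- covered + sum(a)
  }
  pred_mass <- sum(pred$end - pred$start)
  fp <- pred_mass - covered
  fn <- gold_mass - tp
  rec <- if (gold_mass == 0) 0 else tp / (tp + fn)
  prec <- if (pred_mass == 0) 0 else tp / (tp + fp)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}

# a small randomly perturbed corpus exercising every error mode
random_case <- function(seed, n_docs = 3, entities_per_doc = 3) {
  spec <- corpus_spec(n_docs = n_docs, entities_per_doc = entities_per_doc)
  corpus <- generate_corpus(spec, seed = seed)
  cfg <- perturbation_config(
    miss_prob = 0.15, jitter_prob = 0.3, jitter_max = 2,
    frag_prob = 0.4, frag_k = 2, spurious_rate = 1, seed = seed
  )
  list(corpus = corpus, predicted = perturb_predictions(corpus, cfg))
}

# random fragment decomposition: entity length and fragments fitting in it
random_decomposition <- function() {
  l <- sample(1:40, 1)
  m <- sample(0:min(4, l), 1)
  if (m == 0) return(list(l = l, a = integer()))
  # m fragment lengths >= 1 with sum <= l
  budget <- sample(m:l, 1)
  a <- rep(1L, m)
  extra <- budget - m
  if (extra > 0) a <- a + tabulate(sample.int(m, extra, replace = TRUE), m)
  list(l = l, a = a)
}
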