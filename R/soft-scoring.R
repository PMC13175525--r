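#' Hoelder-mean soft score of one extraction target
#'
#' The per-entity score underlying the weighted soft matching metric. For a
#' gold entity of length `l` characters extracted as `m` fragments of
#' lengths `a_1..a_m`, the score is
#' \deqn{s_p = \left(\sum_{i=1}^m (a_i/l)^p\right)^{1/p},}
#' an \eqn{\ell^p}-norm of the per-fragment coverage ratios. `p >= 1` sets
#' the fragmentation penalty: `p = 1` is plain character coverage
#' (`sum(a)/l`), larger `p` discounts split extractions, and `p = Inf` is
#' the longest-fragment ratio `max(a)/l`. A single full-coverage fragment
#' scores 1 at every `p`; no fragments score 0.
#'
#' Computed with max-factoring, `s = x_max * (sum((x/x_max)^p))^(1/p)` with
#' `x = a/l`, so that large penalties such as `p = 100` do not underflow
#' (`0.01^100` is below the double-precision range without it).
#'
#' @param l Entity length in characters (scalar, `>= 1`).
#' @param fragments Integer vector of fragment lengths, each `>= 1`,
#'   `sum(fragments) <= l`. May be empty (entity missed entirely).
#' @param p Numeric vector of penalties, each `>= 1` or `Inf`.
#' @return Numeric vector of scores in `[0, 1]`, one per `p`.
#' @export
#' @examples
#' entity_soft_score(10, c(5, 5), c(1, 2, 100, Inf))
entity_soft_score <- function(l, fragments, p) {
  if (any(p < 1)) stop("penalty p must be >= 1 (got ", min(p), ")")
  m <- length(fragments)
  if (m == 0) return(rep(0, length(p)))
  stopifnot(l >= 1, all(fragments >= 1), sum(fragments) <= l)
  x <- fragments / l
  xmax <- max(x)
  vapply(p, function(pp) {
    if (is.infinite(pp)) return(xmax)
    if (pp == 1) return(sum(x))
    if (m == 1) return(xmax) # single fragment is p-independent
    xmax * sum((x / xmax)^pp)^(1 / pp)
  }, numeric(1))
}

#' Fragment decomposition of gold entities under a prediction
#'
#' For every gold entity, finds the predicted fragments lying inside it:
#' the nonempty intersections of the (overlap-merged) predicted spans with
#' the entity, in text order. Under the default `"marker"` semantics,
#' predicted spans that touch without overlapping stay separate fragments --
#' they are distinct extraction markers. Under `"mask"` semantics only the
#' predicted character mask matters: contiguous fragments are merged, as is
#' appropriate for token-classification output.
#'
#' @param gold Gold span table (disjoint).
#' @param predicted Predicted span table.
#' @param semantics `"marker"` or `"mask"`.
#' @return Tibble with one row per gold entity: `doc_id`, `start`, `end`,
#'   `l`, list-column `fragments` (integer lengths), and `m`.
#' @export
#' @examples
#' g <- spans("d", 0, 10)
#' decompose_fragments(g, spans(c("d", "d"), c(0, 5), c(5, 10)))
decompose_fragments <- function(gold, predicted, semantics = c("marker", "mask")) {
  semantics <- match.arg(semantics)
  pred <- normalize_spans(predicted)
  frag <- purrr::map(seq_len(nrow(gold)), function(i) {
    ps <- pred[pred$doc_id == gold$doc_id[i], , drop = FALSE]
    s <- pmax(ps$start, gold$start[i])
    e <- pmin(ps$end, gold$end[i])
    keep <- e > s
    s <- s[keep]
    e <- e[keep]
    if (semantics == "mask" && length(s) > 1) {
      # merge fragments made contiguous by clipping or adjacency
      j <- 1L
      for (k in 2:length(s)) {
        if (s[k] == e[j]) {
          e[j] <- e[k]
        } else {
          j <- j + 1L
          s[j] <- s[k]
          e[j] <- e[k]
        }
      }
      s <- s[1:j]
      e <- e[1:j]
    }
    as.integer(e - s)
  })
  tibble::tibble(
    doc_id = gold$doc_id, start = gold$start, end = gold$end,
    l = as.integer(gold$end - gold$start),
    fragments = frag,
    m = lengths(frag)
  )
}

# one report row; applies the zero-denominator policy
prf_row <- function(mode, p, tp, fp, fn, gold_mass, pred_mass, n_gold, n_pred) {
  note <- NA_character_
  if (gold_mass == 0 && pred_mass == 0) {
    prec <- rec <- f1 <- 1
    note <- "both_empty"
  } else {
    rec <- if (gold_mass == 0) 0 else tp / (tp + fn)
    prec <- if (pred_mass == 0) 0 else tp / (tp + fp)
    if (gold_mass == 0) note <- "no_gold"
    if (pred_mass == 0) note <- "no_predictions"
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  tibble::tibble(
    mode = mode, p = p, precision = prec, recall = rec, f1 = f1,
    tp_mass = tp, fp_mass = fp, fn_mass = fn,
    n_gold = n_gold, n_pred = n_pred, note = note
  )
}

new_score_report <- function(x) {
  class(x) <- c("score_report", class(tibble::tibble()))
  x
}

#' Corpus-level soft matching scores
#'
#' Aggregates per-entity Hoelder scores into precision/recall/F1 for each
#' requested penalty `p`, under two aggregation rules:
#'
#' * `mode = "weighted"` -- length-weighted soft matching. Soft true-positive
#'   mass is `sum(l_e * s_e(p))` over gold entities, so long targets carry
#'   weight proportional to their length; false-negative mass is the
#'   uncovered remainder `sum(l_e) - TP`; false-positive mass is the count
#'   of predicted characters outside every gold entity. At `p = 1` this is
#'   exactly character-level evaluation.
#' * `mode = "marker"` -- each entity counts 1 regardless of length:
#'   `TP = sum(s_e(p))`, `FN = n_gold - TP`, and each predicted span fully
#'   disjoint from the gold counts 1 false positive.
#'
#' True negatives are never counted: characters outside every gold and
#' predicted span play no role. When gold and predictions are both empty all
#' metrics are 1; when exactly one side is empty the affected metric is 0
#' and the row is flagged in `note`.
#'
#' @param docs Document table.
#' @param gold Gold span table.
#' @param predicted Predicted span table.
#' @param p Numeric vector of penalties (`>= 1`, `Inf` allowed).
#' @param mode `"weighted"` or `"marker"`.
#' @param precision_rule For `mode = "weighted"`, how false-positive mass is
#'   charged: `"mass"` (default; FP = predicted characters outside gold) or
#'   `"symmetric"` (predicted spans scored by their gold-covered fragments
#'   with the same Hoelder formula, length-weighted by predicted length).
#'   Both coincide with character-level precision at `p = 1`.
#' @param semantics Fragment identity rule, see [decompose_fragments()].
#' @return A `score_report` tibble, one row per `p`.
#' @export
soft_scores <- function(docs, gold, predicted, p = c(1, 1.5, 2, 100),
                        mode = c("weighted", "marker"),
                        precision_rule = c("mass", "symmetric"),
                        semantics = c("marker", "mask")) {
  mode <- match.arg(mode)
  precision_rule <- match.arg(precision_rule)
  semantics <- match.arg(semantics)
  if (any(p < 1)) stop("penalty p must be >= 1")
  gold <- validate_spans(docs, gold, kind = "gold")
  predicted <- validate_spans(docs, predicted, kind = "predicted")
  pred <- normalize_spans(predicted)
  d <- decompose_fragments(gold, pred, semantics = semantics)

  gold_mass <- sum(d$l)
  pred_mass <- sum(pred$end - pred$start)
  cov <- vapply(d$fragments, function(a) sum(a), numeric(1)) # chars covered per entity
  n_gold <- nrow(gold)
  n_pred <- nrow(pred)

  rows <- purrr::map(p, function(pp) {
    s <- vapply(
      seq_len(nrow(d)),
      function(i) entity_soft_score(d$l[i], d$fragments[[i]], pp),
      numeric(1)
    )
    if (mode == "weighted") {
      # p = 1: integer covered-character count, the exact char-level TP mass
      tp <- if (pp == 1) sum(cov) else sum(d$l * s)
      fn <- gold_mass - tp
      if (precision_rule == "mass") {
        fp <- pred_mass - sum(cov)
        row <- prf_row("weighted", pp, tp, fp, fn, gold_mass, pred_mass, n_gold, n_pred)
      } else {
        pr <- symmetric_precision(gold, pred, pp)
        fp <- pred_mass - pr$tp
        row <- prf_row("weighted", pp, tp, fp, fn, gold_mass, pred_mass, n_gold, n_pred)
        if (pred_mass > 0 && !(gold_mass == 0 && pred_mass == 0)) {
          row$precision <- pr$tp / pred_mass
          row$f1 <- if (row$precision + row$recall > 0) {
            2 * row$precision * row$recall / (row$precision + row$recall)
          } else 0
        }
      }
      row
    } else {
      tp <- sum(s)
      fn <- n_gold - tp
      fp <- n_spurious(gold, pred)
      prf_row("marker", pp, tp, fp, fn, n_gold, n_pred, n_gold, n_pred)
    }
  })
  new_score_report(dplyr::bind_rows(rows))
}

# predicted spans with zero overlap against every gold entity
n_spurious <- function(gold, pred) {
  if (nrow(pred) == 0) return(0L)
  sum(vapply(seq_len(nrow(pred)), function(i) {
    g <- gold[gold$doc_id == pred$doc_id[i], , drop = FALSE]
    all(intersect_length(pred$start[i], pred$end[i], g$start, g$end) == 0L)
  }, logical(1)))
}

# role-swapped Hoelder precision: score each predicted span by its
# gold-covered fragments, weight by predicted length
symmetric_precision <- function(gold, pred, pp) {
  if (nrow(pred) == 0) return(list(tp = 0))
  tp <- sum(vapply(seq_len(nrow(pred)), function(i) {
    g <- gold[gold$doc_id == pred$doc_id[i], , drop = FALSE]
    a <- intersect_length(pred$start[i], pred$end[i], g$start, g$end)
    a <- a[a > 0]
    len <- pred$end[i] - pred$start[i]
    if (pp == 1) sum(a) else len * entity_soft_score(len, a, pp)
  }, numeric(1)))
  list(tp = tp)
}

#' Length-weighted soft matching report
#'
#' Convenience wrapper for [soft_scores()] with `mode = "weighted"`.
#' @inheritParams soft_scores
#' @return A `score_report` tibble.
#' @export
weighted_scores <- function(docs, gold, predicted, p = c(1, 1.5, 2, 100),
                            precision_rule = c("mass", "symmetric"),
                            semantics = c("marker", "mask")) {
  soft_scores(docs, gold, predicted, p,
    mode = "weighted",
    precision_rule = precision_rule, semantics = semantics
  )
}

#' Marker matching report (each entity counts 1)
#'
#' Convenience wrapper for [soft_scores()] with `mode = "marker"`: a simple
#' average that does not account for target length, so frequent short terms
#' weigh as much as long clinical phrases.
#' @inheritParams soft_scores
#' @return A `score_report` tibble.
#' @export
marker_scores <- function(docs, gold, predicted, p = c(1, 1.5, 2, 100),
                          semantics = c("marker", "mask")) {
  soft_scores(docs, gold, predicted, p, mode = "marker", semantics = semantics)
}

#' Character-level binary classification report
#'
#' Per-character precision/recall/F1 on the label-1 class, with no true
#' negatives. Identical to [weighted_scores()] at `p = 1`.
#'
#' @inheritParams soft_scores
#' @return A `score_report` tibble with one row, `mode = "char"`.
#' @export
char_scores <- function(docs, gold, predicted) {
  gold <- validate_spans(docs, gold, kind = "gold")
  predicted <- validate_spans(docs, predicted, kind = "predicted")
  gm <- to_char_mask(docs, gold)
  pm <- to_char_mask(docs, predicted)
  tp <- fp <- fn <- 0L
  for (i in seq_len(nrow(docs))) {
    g <- gm$mask[[i]]
    q <- pm$mask[[i]]
    tp <- tp + sum(g == 1L & q == 1L)
    fp <- fp + sum(g == 0L & q == 1L)
    fn <- fn + sum(g == 1L & q == 0L)
  }
  new_score_report(prf_row(
    "char", NA_real_, tp, fp, fn,
    gold_mass = tp + fn, pred_mass = tp + fp,
    n_gold = nrow(gold), n_pred = nrow(predicted)
  ))
}

#' Token-level binary classification report
#'
#' Projects gold and predicted character masks onto a supplied token
#' segmentation (see [project_to_tokens()]) and scores per-token binary
#' precision/recall/F1 on the label-1 class. Reported for completeness:
#' token-level numbers depend on the tokenizer, which is why the weighted
#' soft matching score operates on characters.
#'
#' @inheritParams soft_scores
#' @param segmentation Token segmentation span table (required).
#' @param rule Token labeling rule, `"any"` (default) or `"all"`.
#' @return A `score_report` tibble with one row, `mode = "token"`.
#' @export
token_scores <- function(docs, gold, predicted, segmentation,
                         rule = c("any", "all")) {
  if (missing(segmentation) || is.null(segmentation)) {
    stop("token_scores requires a token segmentation")
  }
  rule <- match.arg(rule)
  gold <- validate_spans(docs, gold, kind = "gold")
  predicted <- validate_spans(docs, predicted, kind = "predicted")
  segmentation <- validate_segmentation(docs, segmentation)
  gl <- project_to_tokens(to_char_mask(docs, gold), segmentation, rule = rule)
  pl <- project_to_tokens(to_char_mask(docs, predicted), segmentation, rule = rule)
  tp <- sum(gl$label == 1L & pl$label == 1L)
  fp <- sum(gl$label == 0L & pl$label == 1L)
  fn <- sum(gl$label == 1L & pl$label == 0L)
  new_score_report(prf_row(
    "token", NA_real_, tp, fp, fn,
    gold_mass = tp + fn, pred_mass = tp + fp,
    n_gold = nrow(gold), n_pred = nrow(predicted)
  ))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.score_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.score_report <- function(x, ...) {
  tibble::tibble(
    modes = paste(unique(x$mode), collapse = ","),
    n_p = length(unique(x$p[!is.na(x$p)])),
    f1_min = min(x$f1),
    f1_max = max(x$f1),
    n_gold = x$n_gold[1],
    n_pred = x$n_pred[1]
  )
}

#' Plot a score report across penalties
#'
#' Precision, recall and F1 against the fragmentation penalty `p`, one line
#' per metric, faceted by mode. Rows without a penalty (char/token modes)
#' are drawn as horizontal reference lines.
#'
#' @param object A `score_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_report <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
      names_to = "metric", values_to = "value"
    )
  withp <- dplyr::filter(long, !is.na(.data$p))
  nop <- dplyr::filter(long, is.na(.data$p))
  gg <- ggplot2::ggplot(
    withp,
    ggplot2::aes(x = .data$p, y = .data$value, colour = .data$metric)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(
      x = "fragmentation penalty p (log scale)", y = "score",
      title = "Soft matching scores by fragmentation penalty"
    ) +
    ggplot2::ylim(0, 1)
  if (nrow(nop) > 0) {
    gg <- gg + ggplot2::geom_hline(
      data = nop,
      ggplot2::aes(yintercept = .data$value, colour = .data$metric),
      linetype = "dashed", alpha = 0.5
    )
  }
  gg
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
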