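# default code-point pool: hiragana, katakana, a CJK block slice, ASCII
# letters/digits -- multi-byte and single-byte text without clinical content.
# Marker/escape characters (@ # \) are deliberately absent.
default_alphabet <- function() {
  c(
    vapply(0x3042:0x3093, intToUtf8, character(1)), # hiragana
    vapply(0x30A2:0x30F3, intToUtf8, character(1)), # katakana
    vapply(0x4E00:0x4E80, intToUtf8, character(1)), # CJK ideographs
    letters, LETTERS, as.character(0:9)
  )
}

#' Specification of a synthetic annotated corpus
#'
#' Describes the statistical shape of a corpus of documents with
#' non-overlapping gold spans: how many documents, how many entities each,
#' the entity length distribution over the five length bins, and the gaps
#' separating entities. Defaults place 9% of entities in the 1-2 character
#' bin -- the minority share such short spans hold in clinical concept
#' annotation -- with the remainder spread over the longer bins.
#'
#' @param n_docs Number of documents.
#' @param entities_per_doc Mean of the entity count per document; counts are
#'   drawn as `1 + Poisson(entities_per_doc - 1)`.
#' @param bin_props Numeric vector of length 5, proportions of entities in
#'   the bins 1-2, 3-6, 7-10, 11-20, >=21 (normalized internally).
#' @param bin_ranges List of 5 length ranges `c(lo, hi)` to draw uniformly
#'   within each bin.
#' @param gap_range Range `c(lo, hi)` of unannotated gap lengths between
#'   consecutive entities (and at the document edges); `lo >= 1` keeps gold
#'   spans separated.
#' @param alphabet Character vector of code points to draw text from.
#' @param max_doc_length Optional cap; a document whose entities and gaps
#'   cannot fit raises an error naming the document.
#' @return A `corpus_spec` object.
#' @export
corpus_spec <- function(n_docs = 100,
                        entities_per_doc = 3,
                        bin_props = c(0.09, 0.35, 0.25, 0.21, 0.10),
                        bin_ranges = list(
                          c(1, 2), c(3, 6), c(7, 10), c(11, 20), c(21, 35)
                        ),
                        gap_range = c(1, 8),
                        alphabet = default_alphabet(),
                        max_doc_length = NULL) {
  stopifnot(
    n_docs >= 0, entities_per_doc >= 1,
    length(bin_props) == length(bin_ranges),
    all(bin_props >= 0), sum(bin_props) > 0,
    gap_range[1] >= 1, gap_range[2] >= gap_range[1]
  )
  structure(
    list(
      n_docs = as.integer(n_docs),
      entities_per_doc = entities_per_doc,
      bin_props = bin_props / sum(bin_props),
      bin_ranges = bin_ranges,
      gap_range = as.integer(gap_range),
      alphabet = alphabet,
      max_doc_length = max_doc_length
    ),
    class = "corpus_spec"
  )
}

#' Rates governing synthetic prediction and generation corruption
#'
#' Encodes the error modes an extraction system exhibits: missing an entity
#' outright, deviating at the boundaries, splitting one target into several
#' fragments, emitting spurious spans in unannotated text, and -- for
#' generative output -- character-level corruption of the reproduced text.
#'
#' @param miss_prob Probability an entity is dropped entirely.
#' @param jitter_prob Per-end probability a boundary is shifted.
#' @param jitter_max Maximum absolute boundary shift in characters.
#' @param frag_prob Probability an (un-missed) entity is split into
#'   fragments.
#' @param frag_k Number of fragments per split (`>= 2`); fragments are
#'   separated by 1 dropped character each, so splitting needs length
#'   `>= 2 * frag_k - 1`.
#' @param spurious_rate Expected spurious spans per document (Poisson).
#' @param char_noise_rate Per-character corruption probability for
#'   generated text.
#' @param noise_ops Subset of `c("sub", "ins", "del")` drawn equiprobably
#'   per corrupted character.
#' @param seed Integer seed; identical seed and config give identical
#'   output. Sub-streams for corpus generation, perturbation and corruption
#'   are derived from it by fixed labels, so changing one stage's settings
#'   does not disturb the others.
#' @return A `perturbation_config` object.
#' @export
perturbation_config <- function(miss_prob = 0,
                                jitter_prob = 0, jitter_max = 2,
                                frag_prob = 0, frag_k = 2,
                                spurious_rate = 0,
                                char_noise_rate = 0,
                                noise_ops = c("sub", "ins", "del"),
                                seed = 1L) {
  probs <- c(miss_prob, jitter_prob, frag_prob, char_noise_rate)
  stopifnot(
    all(probs >= 0 & probs <= 1), jitter_max >= 1, frag_k >= 2,
    spurious_rate >= 0, all(noise_ops %in% c("sub", "ins", "del"))
  )
  structure(
    list(
      miss_prob = miss_prob, jitter_prob = jitter_prob,
      jitter_max = as.integer(jitter_max),
      frag_prob = frag_prob, frag_k = as.integer(frag_k),
      spurious_rate = spurious_rate,
      char_noise_rate = char_noise_rate,
      noise_ops = noise_ops,
      seed = as.integer(seed)
    ),
    class = "perturbation_config"
  )
}

# uniform draw from lo:hi that is safe when lo == hi (sample() would
# otherwise treat the scalar as 1:lo)
sample_range <- function(lo, hi, n = 1L) {
  lo <- as.integer(lo)
  as.integer(lo + sample.int(as.integer(hi) - lo + 1L, n, replace = TRUE) - 1L)
}

# deterministic sub-stream seed from a run seed and a stage label,
# kept below 2^31 (R integer range)
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  x <- (abs(as.numeric(seed)) + h) %% 2147483647
  as.integer((x * 48271) %% 2147483647)
}

#' Generate a synthetic annotated corpus
#'
#' Builds documents as alternating unannotated gaps and gold entities, so
#' every gold invariant (bounds, disjointness, >= 1-character separation)
#' holds by construction and realized bin proportions approach the spec's
#' targets as the entity count grows. Deterministic given `seed`.
#'
#' @param spec A [corpus_spec()].
#' @param seed Integer seed.
#' @return A validated `span_corpus` (list of `documents` and `gold`).
#' @export
#' @examples
#' generate_corpus(corpus_spec(n_docs = 2), seed = 7)
generate_corpus <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "corpus_spec"))
  withr::with_seed(derive_seed(seed, "corpus"), {
    docs <- vector("list", spec$n_docs)
    gold <- vector("list", spec$n_docs)
    for (i in seq_len(spec$n_docs)) {
      id <- sprintf("doc%05d", i)
      n_e <- 1L + stats::rpois(1, spec$entities_per_doc - 1)
      bin <- sample.int(length(spec$bin_props), n_e,
        replace = TRUE, prob = spec$bin_props
      )
      lens <- vapply(bin, function(b) {
        r <- spec$bin_ranges[[b]]
        sample_range(r[1], r[2])
      }, integer(1))
      gaps <- sample_range(spec$gap_range[1], spec$gap_range[2], n_e + 1L)
      total <- sum(lens) + sum(gaps)
      if (!is.null(spec$max_doc_length) && total > spec$max_doc_length) {
        stop(sprintf(
          "entities cannot fit document '%s': need %d characters, cap %d",
          id, total, spec$max_doc_length
        ))
      }
      pos <- 0L
      starts <- integer(n_e)
      for (j in seq_len(n_e)) {
        pos <- pos + gaps[j]
        starts[j] <- pos
        pos <- pos + lens[j]
      }
      pos <- pos + gaps[n_e + 1L]
      txt <- paste(sample(spec$alphabet, pos, replace = TRUE), collapse = "")
      docs[[i]] <- tibble::tibble(doc_id = id, text = txt)
      gold[[i]] <- tibble::tibble(doc_id = id, start = starts, end = starts + lens)
    }
    documents <- if (spec$n_docs == 0) documents(character(), character()) else dplyr::bind_rows(docs)
    gold_tbl <- if (spec$n_docs == 0) spans() else dplyr::bind_rows(gold)
    validate_corpus(documents, gold_tbl)
  })
}

#' Derive perturbed predictions from gold annotations
#'
#' Applies the error model of a [perturbation_config()] to each gold
#' entity: drop with `miss_prob`; otherwise jitter each boundary with
#' `jitter_prob` (clipped to the text, minimum length 1); additionally,
#' with `frag_prob`, split the span into `frag_k` fragments separated by
#' one dropped character each (total coverage shrinks by `frag_k - 1`
#' characters). Spurious spans are placed uniformly in unannotated regions
#' at `spurious_rate` per document. Deterministic given the seed.
#'
#' @param corpus A `span_corpus` from [generate_corpus()] or
#'   [validate_corpus()].
#' @param config A [perturbation_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Predicted span table.
#' @export
perturb_predictions <- function(corpus, config, seed = config$seed) {
  stopifnot(inherits(corpus, "span_corpus"), inherits(config, "perturbation_config"))
  docs <- corpus$documents
  gold <- corpus$gold
  len <- stats::setNames(nchar(docs$text, type = "chars"), docs$doc_id)
  withr::with_seed(derive_seed(seed, "perturb"), {
    out <- vector("list", nrow(docs))
    for (di in seq_len(nrow(docs))) {
      id <- docs$doc_id[di]
      n <- len[[id]]
      g <- gold[gold$doc_id == id, , drop = FALSE]
      ps <- integer(0)
      pe <- integer(0)
      for (i in seq_len(nrow(g))) {
        if (stats::runif(1) < config$miss_prob) next
        s <- g$start[i]
        e <- g$end[i]
        if (config$jitter_prob > 0) {
          shifts <- c(-(config$jitter_max:1), 1:config$jitter_max)
          if (stats::runif(1) < config$jitter_prob) {
            s <- s + sample(shifts, 1L)
          }
          if (stats::runif(1) < config$jitter_prob) {
            e <- e + sample(shifts, 1L)
          }
          s <- max(0L, min(s, n - 1L))
          e <- max(s + 1L, min(e, n))
        }
        k <- config$frag_k
        if (config$frag_prob > 0 && (e - s) >= 2L * k - 1L &&
          stats::runif(1) < config$frag_prob) {
          L <- e - s
          extra <- L - (k - 1L) - k # coverage chars beyond the minimum 1 each
          f <- rep(1L, k)
          if (extra > 0) {
            f <- f + tabulate(sample.int(k, extra, replace = TRUE), k)
          }
          fs <- s + c(0L, cumsum(f[-k] + 1L)) # 1-char dropped gap per split
          ps <- c(ps, fs)
          pe <- c(pe, fs + f)
        } else {
          ps <- c(ps, s)
          pe <- c(pe, e)
        }
      }
      # spurious spans in unannotated regions
      n_sp <- stats::rpois(1, config$spurious_rate)
      if (n_sp > 0 && n > 0) {
        free <- complement_regions(g, n)
        for (j in seq_len(n_sp)) {
          sl <- sample(1:5, 1L)
          cand <- free[free$end - free$start >= sl, , drop = FALSE]
          if (nrow(cand) == 0) next
          w <- (cand$end - cand$start) - sl + 1L
          r <- cand[sample.int(nrow(cand), 1L, prob = w), ]
          at <- r$start + sample.int(r$end - r$start - sl + 1L, 1L) - 1L
          ps <- c(ps, at)
          pe <- c(pe, at + sl)
        }
      }
      out[[di]] <- if (length(ps)) {
        tibble::tibble(doc_id = id, start = ps, end = pe)
      } else NULL
    }
    res <- dplyr::bind_rows(out)
    if (nrow(res) == 0) spans() else dplyr::arrange(res, .data$doc_id, .data$start)
  })
}

# unannotated intervals of a document of length n, given disjoint spans
complement_regions <- function(span_tbl, n) {
  s <- span_tbl[order(span_tbl$start), , drop = FALSE]
  bounds <- c(0L, rbind(s$start, s$end), n)
  starts <- bounds[seq(1, length(bounds), by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  keep <- ends > starts
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' Corrupt generated marker text at the character level
#'
#' Emulates imperfect text reproduction by a generative model: each payload
#' character is, with probability `char_noise_rate`, substituted, deleted,
#' or followed by an inserted character (operations drawn equiprobably from
#' `config$noise_ops`). Marker literals are never touched, so the corrupted
#' text still parses. Deterministic given the seed.
#'
#' @param marked_tbl Tibble with `doc_id`, `marked` (strict-parseable).
#' @param config A [perturbation_config()] (uses `char_noise_rate`,
#'   `noise_ops`, `seed`).
#' @param seed Integer seed; defaults to `config$seed`.
#' @param markers Length-2 marker literals.
#' @param alphabet Replacement/insertion character pool.
#' @return Tibble with `doc_id`, `marked` corrupted.
#' @export
corrupt_generation <- function(marked_tbl, config, seed = config$seed,
                               markers = c("@@", "##"),
                               alphabet = default_alphabet()) {
  stopifnot(inherits(config, "perturbation_config"))
  rate <- config$char_noise_rate
  ops <- config$noise_ops
  withr::with_seed(derive_seed(seed, "corrupt"), {
    corrupted <- purrr::map_chr(marked_tbl$marked, function(m) {
      ch <- chars_of(m)
      op_lit <- chars_of(markers[1])
      cl_lit <- chars_of(markers[2])
      out <- character(0)
      i <- 1L
      n <- length(ch)
      while (i <= n) {
        lit <- NULL
        if (i + length(op_lit) - 1L <= n &&
          all(ch[i:(i + length(op_lit) - 1L)] == op_lit)) {
          lit <- op_lit
        } else if (i + length(cl_lit) - 1L <= n &&
          all(ch[i:(i + length(cl_lit) - 1L)] == cl_lit)) {
          lit <- cl_lit
        }
        if (!is.null(lit)) {
          out <- c(out, lit)
          i <- i + length(lit)
          next
        }
        if (rate > 0 && stats::runif(1) < rate) {
          op <- if (length(ops) == 1) ops else sample(ops, 1L)
          if (op == "sub") {
            repl <- sample(alphabet, 1L)
            while (repl == ch[i]) repl <- sample(alphabet, 1L)
            out <- c(out, repl)
          } else if (op == "ins") {
            out <- c(out, ch[i], sample(alphabet, 1L))
          } # "del": emit nothing
        } else {
          out <- c(out, ch[i])
        }
        i <- i + 1L
      }
      paste(out, collapse = "")
    })
    tibble::tibble(doc_id = marked_tbl$doc_id, marked = corrupted)
  })
}
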