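#' Build a document table
#'
#' Documents are the unit of text over which spans are defined. Offsets are
#' counted in Unicode code points, never bytes, so Japanese clinical text and
#' ASCII behave identically.
#'
#' @param doc_id Character vector of unique document identifiers.
#' @param text Character vector of document texts (will be marked as UTF-8).
#' @return A tibble with columns `doc_id` and `text`.
#' @export
#' @examples
#' documents("d1", "abcdef")
documents <- function(doc_id, text) {
  doc_id <- as.character(doc_id)
  if (anyDuplicated(doc_id)) {
    stop("duplicated doc_id: ", paste(unique(doc_id[duplicated(doc_id)]), collapse = ", "))
  }
  tibble::tibble(doc_id = doc_id, text = enc2utf8(as.character(text)))
}

#' Build a span table
#'
#' Spans are character-offset intervals, 0-based and half-open `[start, end)`,
#' the standoff-annotation convention. Empty spans are rejected.
#'
#' @param doc_id Character vector, one entry per span.
#' @param start,end Integer offsets, `0 <= start < end`.
#' @return A tibble with columns `doc_id`, `start`, `end`.
#' @export
spans <- function(doc_id = character(), start = integer(), end = integer()) {
  tibble::tibble(
    doc_id = as.character(doc_id),
    start = as.integer(start),
    end = as.integer(end)
  )
}

#' Validate spans against their documents
#'
#' Checks bounds (`0 <= start < end <= nchar(text)`) and, for gold spans,
#' pairwise disjointness. Errors name the offending document and offsets.
#'
#' @param docs Document table (see [documents()]).
#' @param span_tbl Span table (see [spans()]).
#' @param kind `"gold"` (disjointness enforced) or `"predicted"` (stored as
#'   given; use [normalize_spans()] for the overlap-merged view).
#' @return The span table, invisibly, sorted by `doc_id` then `start`.
#' @export
validate_spans <- function(docs, span_tbl, kind = c("gold", "predicted")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(docs), is.data.frame(span_tbl))
  unknown <- setdiff(span_tbl$doc_id, docs$doc_id)
  if (length(unknown) > 0) {
    stop("spans reference unknown doc_id: ", paste(unknown, collapse = ", "))
  }
  len <- stats::setNames(nchar(docs$text, type = "chars"), docs$doc_id)
  s <- span_tbl
  bad <- s$start < 0L | s$end <= s$start | s$end > len[s$doc_id]
  if (any(bad)) {
    b <- s[which(bad)[1], ]
    stop(sprintf(
      "span exceeds text length or is empty: doc '%s' [%d,%d) with text length %d",
      b$doc_id, b$start, b$end, len[[b$doc_id]]
    ))
  }
  s <- dplyr::arrange(s, .data$doc_id, .data$start, .data$end)
  if (kind == "gold" && nrow(s) > 1) {
    ov <- s |>
      dplyr::group_by(.data$doc_id) |>
      dplyr::filter(dplyr::row_number() > 1 &
        .data$start < dplyr::lag(.data$end)) |>
      dplyr::ungroup()
    if (nrow(ov) > 0) {
      b <- ov[1, ]
      stop(sprintf(
        "overlapping gold spans in doc '%s' at [%d,%d)", b$doc_id, b$start, b$end
      ))
    }
  }
  invisible(s)
}

#' Validate a corpus of documents and gold annotations
#'
#' @param docs Document table.
#' @param gold Gold span table; must reference existing documents, stay in
#'   bounds, and be pairwise disjoint per document.
#' @return A `span_corpus` object: a list with validated `documents` and
#'   `gold` tibbles.
#' @export
validate_corpus <- function(docs, gold) {
  if (anyDuplicated(docs$doc_id)) {
    stop("duplicated doc_id: ", paste(
      unique(docs$doc_id[duplicated(docs$doc_id)]),
      collapse = ", "
    ))
  }
  gold <- validate_spans(docs, gold, kind = "gold")
  structure(
    list(documents = tibble::as_tibble(docs), gold = gold),
    class = "span_corpus"
  )
}

#' @export
print.span_corpus <- function(x, ...) {
  cat(sprintf(
    "<span_corpus> %d documents, %d gold spans\n",
    nrow(x$documents), nrow(x$gold)
  ))
  invisible(x)
}

#' Normalized view of a span table
#'
#' Sorts spans by start and merges spans that overlap by at least one
#' character. Adjacent-but-touching spans are kept distinct: they correspond
#' to distinct extraction markers, and fragment counting treats them as
#' separate fragments.
#'
#' @param span_tbl Span table.
#' @return Span table, sorted, with overlapping spans merged per document.
#' @export
normalize_spans <- function(span_tbl) {
  if (nrow(span_tbl) == 0) return(span_tbl)
  span_tbl |>
    dplyr::arrange(.data$doc_id, .data$start, .data$end) |>
    dplyr::group_by(.data$doc_id) |>
    dplyr::group_modify(~ merge_overlapping(.x)) |>
    dplyr::ungroup()
}

# merge strictly overlapping intervals within one document (assumed sorted)
merge_overlapping <- function(df) {
  if (nrow(df) <= 1) return(df)
  start <- df$start
  end <- df$end
  out_s <- start[1]
  out_e <- end[1]
  k <- 1L
  for (i in 2:length(start)) {
    if (start[i] < out_e[k]) { # strict overlap only; adjacency kept distinct
      out_e[k] <- max(out_e[k], end[i])
    } else {
      k <- k + 1L
      out_s[k] <- start[i]
      out_e[k] <- end[i]
    }
  }
  tibble::tibble(start = out_s[1:k], end = out_e[1:k])
}

#' Convert spans to per-character binary masks
#'
#' One mask per document: `mask[i] = 1` iff character `i` (1-based position,
#' offset `i - 1`) lies inside some span.
#'
#' @param docs Document table.
#' @param span_tbl Span table (validated against `docs`).
#' @return Tibble with `doc_id` and a list-column `mask` of integer vectors,
#'   one value per character.
#' @export
#' @examples
#' d <- documents("d1", "abcdef")
#' to_char_mask(d, spans("d1", 1, 3))
to_char_mask <- function(docs, span_tbl) {
  masks <- purrr::map(seq_len(nrow(docs)), function(i) {
    n <- nchar(docs$text[i], type = "chars")
    m <- integer(n)
    ss <- span_tbl[span_tbl$doc_id == docs$doc_id[i], , drop = FALSE]
    for (j in seq_len(nrow(ss))) {
      m[(ss$start[j] + 1L):ss$end[j]] <- 1L
    }
    m
  })
  tibble::tibble(doc_id = docs$doc_id, mask = masks)
}

#' Recover spans from binary character masks
#'
#' Maximal runs of 1s become spans; the inverse of [to_char_mask()] whenever
#' the original spans had no two adjacent or overlapping spans.
#'
#' @param mask_tbl Tibble with `doc_id` and list-column `mask` (0/1 integer
#'   vectors), as produced by [to_char_mask()].
#' @return Span table.
#' @export
char_labels_to_spans <- function(mask_tbl) {
  res <- purrr::map2(mask_tbl$doc_id, mask_tbl$mask, function(id, m) {
    r <- mask_runs(m)
    if (nrow(r) == 0) return(NULL)
    tibble::tibble(doc_id = id, start = r$start, end = r$end)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) spans() else out
}

# maximal runs of 1 in a 0/1 vector, as 0-based half-open intervals
mask_runs <- function(m) {
  if (length(m) == 0 || !any(m == 1L)) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  r <- rle(as.integer(m))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  tibble::tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Overlap length of two half-open intervals
#'
#' Vectorized over all four arguments.
#'
#' @param start1,end1,start2,end2 Integer offsets of the two intervals.
#' @return Non-negative integer vector, `max(0, min(end) - max(start))`.
#' @export
#' @examples
#' intersect_length(0, 10, 8, 15) # 2
intersect_length <- function(start1, end1, start2, end2) {
  pmax(0L, pmin(end1, end2) - pmax(start1, start2))
}

# split a UTF-8 string into code points
chars_of <- function(text) {
  if (nchar(text, type = "chars") == 0) return(character())
  strsplit(enc2utf8(text), "", fixed = FALSE)[[1]]
}

# substring by 0-based half-open offsets, in code points
substr0 <- function(text, start, end) {
  if (end <= start) return("")
  substr(text, start + 1L, end)
}
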