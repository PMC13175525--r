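#' Wrap annotated spans in inline markers
#'
#' Produces the instruction-tuning target representation: each annotated
#' span is enclosed by an opening and a closing marker (by default `@@` and
#' `##`), in source order. Occurrences of the marker literals (and of the
#' escape character `\\`) inside the text itself are backslash-escaped so
#' that parsing is unambiguous; [parse_marked_text()] reverses the escaping.
#'
#' @param docs Document table.
#' @param span_tbl Disjoint span table (validated against `docs`).
#' @param markers Length-2 character vector: opening and closing literal.
#' @return Tibble with `doc_id` and `marked`.
#' @export
#' @examples
#' spans_to_marked_text(documents("d", "abcdef"), spans("d", 1, 3))
spans_to_marked_text <- function(docs, span_tbl, markers = c("@@", "##")) {
  span_tbl <- validate_spans(docs, span_tbl, kind = "gold")
  marked <- purrr::map_chr(seq_len(nrow(docs)), function(i) {
    txt <- docs$text[i]
    ss <- span_tbl[span_tbl$doc_id == docs$doc_id[i], , drop = FALSE]
    bounds <- sort(unique(c(0L, ss$start, ss$end, nchar(txt, type = "chars"))))
    pieces <- character(0)
    for (j in seq_len(length(bounds) - 1L)) {
      seg <- escape_markers(substr0(txt, bounds[j], bounds[j + 1L]), markers)
      if (any(ss$start == bounds[j])) {
        seg <- paste0(markers[1], seg, markers[2])
      }
      pieces <- c(pieces, seg)
    }
    paste(pieces, collapse = "")
  })
  tibble::tibble(doc_id = docs$doc_id, marked = marked)
}

escape_markers <- function(text, markers) {
  text <- gsub("\\", "\\\\", text, fixed = TRUE)
  text <- gsub(markers[1], paste0("\\", markers[1]), text, fixed = TRUE)
  gsub(markers[2], paste0("\\", markers[2]), text, fixed = TRUE)
}

#' Parse marker-annotated text back into payload and spans
#'
#' Inverse of [spans_to_marked_text()]. In `strict` mode, unbalanced or
#' nested markers are errors (used for gold files, which must be clean). In
#' `lenient` mode -- the default for model output -- unmatched openers and
#' closers and empty `@@##` pairs are dropped, each producing a logged
#' warning record rather than a failure.
#'
#' @param marked_tbl Tibble with `doc_id` and `marked` columns.
#' @param mode `"lenient"` or `"strict"`.
#' @param markers Length-2 character vector of marker literals.
#' @return List with `documents` (tibble `doc_id`, `text` -- the payload with
#'   markers removed and escapes undone), `spans` (payload coordinates), and
#'   `log` (tibble `doc_id`, `message` of lenient-mode salvage events).
#' @export
parse_marked_text <- function(marked_tbl, mode = c("lenient", "strict"),
                              markers = c("@@", "##")) {
  mode <- match.arg(mode)
  parsed <- purrr::map2(
    marked_tbl$doc_id, marked_tbl$marked,
    function(id, m) parse_marked_one(id, m, mode, markers)
  )
  list(
    documents = tibble::tibble(
      doc_id = marked_tbl$doc_id,
      text = purrr::map_chr(parsed, "payload")
    ),
    spans = dplyr::bind_rows(purrr::map(parsed, "spans")) |>
      (\(x) if (nrow(x) == 0) spans() else x)(),
    log = dplyr::bind_rows(purrr::map(parsed, "log"))
  )
}

parse_marked_one <- function(doc_id, marked, mode, markers) {
  ch <- chars_of(marked)
  op <- chars_of(markers[1])
  cl <- chars_of(markers[2])
  n <- length(ch)
  payload <- character(n) # over-allocated
  np <- 0L
  open_at <- NA_integer_ # payload offset where current span started
  starts <- integer(0)
  ends <- integer(0)
  log <- character(0)
  i <- 1L
  lit_at <- function(i, lit) {
    length(lit) > 0 && i + length(lit) - 1L <= n &&
      all(ch[i:(i + length(lit) - 1L)] == lit)
  }
  while (i <= n) {
    if (ch[i] == "\\" && i < n) {
      # escape: \\, \@@ or \## introduce literal payload characters
      if (ch[i + 1L] == "\\") {
        np <- np + 1L; payload[np] <- "\\"; i <- i + 2L; next
      }
      if (lit_at(i + 1L, op)) {
        payload[(np + 1L):(np + length(op))] <- op
        np <- np + length(op); i <- i + 1L + length(op); next
      }
      if (lit_at(i + 1L, cl)) {
        payload[(np + 1L):(np + length(cl))] <- cl
        np <- np + length(cl); i <- i + 1L + length(cl); next
      }
    }
    if (lit_at(i, op)) {
      if (!is.na(open_at)) {
        if (mode == "strict") stop("nested marker in doc '", doc_id, "'")
        log <- c(log, "dropped unmatched opening marker (re-opened)")
      }
      open_at <- np
      i <- i + length(op)
      next
    }
    if (lit_at(i, cl)) {
      if (is.na(open_at)) {
        if (mode == "strict") stop("unmatched closing marker in doc '", doc_id, "'")
        log <- c(log, "dropped unmatched closing marker")
      } else if (np == open_at) {
        log <- c(log, "dropped empty marked region")
        open_at <- NA_integer_
      } else {
        starts <- c(starts, open_at)
        ends <- c(ends, np)
        open_at <- NA_integer_
      }
      i <- i + length(cl)
      next
    }
    np <- np + 1L
    payload[np] <- ch[i]
    i <- i + 1L
  }
  if (!is.na(open_at)) {
    if (mode == "strict") stop("unclosed marker in doc '", doc_id, "'")
    log <- c(log, "dropped unclosed opening marker")
  }
  list(
    payload = paste(payload[seq_len(np)], collapse = ""),
    spans = if (length(starts)) {
      tibble::tibble(doc_id = doc_id, start = starts, end = ends)
    } else NULL,
    log = if (length(log)) tibble::tibble(doc_id = doc_id, message = log) else NULL
  )
}

#' Align generated text to its source by minimum edit distance
#'
#' Generative extraction models are asked to reproduce the input sentence
#' with markers inserted; occasionally the reproduction drifts by a few
#' characters. This computes a global unit-cost (Levenshtein) alignment and
#' returns the pairs of positions holding equal characters, so that spans
#' found in generated coordinates can be projected back onto the source.
#' When `generated` equals `source` the map is the identity.
#'
#' @param source,generated Single strings.
#' @return Tibble with 0-based columns `gen_pos`, `src_pos`, monotone
#'   increasing, one row per matched (equal) character pair.
#' @export
align_generated_to_source <- function(source, generated) {
  source <- enc2utf8(source)
  generated <- enc2utf8(generated)
  if (identical(source, generated)) {
    n <- nchar(source, type = "chars")
    return(tibble::tibble(gen_pos = seq_len(n) - 1L, src_pos = seq_len(n) - 1L))
  }
  d <- utils::adist(generated, source, counts = TRUE)
  ops <- chars_of(attr(d, "trafos")[1, 1])
  gi <- 0L # generated cursor
  si <- 0L # source cursor
  gen_pos <- integer(0)
  src_pos <- integer(0)
  for (o in ops) {
    if (o == "M") {
      gen_pos <- c(gen_pos, gi)
      src_pos <- c(src_pos, si)
      gi <- gi + 1L
      si <- si + 1L
    } else if (o == "S") {
      gi <- gi + 1L
      si <- si + 1L
    } else if (o == "D") { # present in generated only
      gi <- gi + 1L
    } else { # "I": present in source only
      si <- si + 1L
    }
  }
  tibble::tibble(gen_pos = gen_pos, src_pos = src_pos)
}

#' Project generated-coordinate spans onto the source text
#'
#' Each span's characters are mapped through the alignment; the projected
#' span is the covering interval of their source images. Characters with no
#' source image are dropped; a span none of whose characters map is
#' unprojectable and returned with `NA` offsets.
#'
#' @param alignment Alignment tibble from [align_generated_to_source()].
#' @param start,end Integer vectors of generated-coordinate spans.
#' @return Tibble with `start`, `end` (source coordinates, `NA` when
#'   unprojectable) and `n_unmapped` (span characters with no source image).
#' @export
project_spans_to_source <- function(alignment, start, end) {
  purrr::map2(start, end, function(s, e) {
    hit <- alignment$gen_pos >= s & alignment$gen_pos < e
    img <- alignment$src_pos[hit]
    tibble::tibble(
      start = if (length(img)) min(img) else NA_integer_,
      end = if (length(img)) max(img) + 1L else NA_integer_,
      n_unmapped = (e - s) - sum(hit)
    )
  }) |> dplyr::bind_rows()
}

#' Validate a token segmentation
#'
#' Tokens are spans covering a document without overlap (gaps allowed, e.g.
#' for whitespace a tokenizer discards).
#'
#' @param docs Document table.
#' @param seg_tbl Span table of tokens.
#' @return The segmentation, invisibly, sorted.
#' @export
validate_segmentation <- function(docs, seg_tbl) {
  validate_spans(docs, seg_tbl, kind = "gold") # disjoint + bounds
}

#' Project character masks to binary token labels
#'
#' A token is labeled 1 under the default `"any"` rule iff at least one of
#' its characters is labeled 1; the stricter `"all"` rule requires every
#' character. The any-overlap rule preserves recall for tokens straddling a
#' span boundary.
#'
#' @param mask_tbl Mask tibble from [to_char_mask()].
#' @param seg_tbl Token segmentation span table.
#' @param rule `"any"` or `"all"`.
#' @return Tibble `doc_id`, `start`, `end`, `label`.
#' @export
project_to_tokens <- function(mask_tbl, seg_tbl, rule = c("any", "all")) {
  rule <- match.arg(rule)
  seg_tbl |>
    dplyr::left_join(mask_tbl, by = "doc_id") |>
    dplyr::mutate(
      label = purrr::pmap_int(
        list(.data$mask, .data$start, .data$end),
        function(m, s, e) {
          if (is.null(m) || e > length(m)) stop("segmentation out of bounds")
          v <- m[(s + 1L):e] == 1L
          as.integer(if (rule == "any") any(v) else all(v))
        }
      )
    ) |>
    dplyr::select("doc_id", "start", "end", "label")
}
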