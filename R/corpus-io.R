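# brat standoff reading/writing and sentence segmentation with offset
# remapping. All coordinates are 0-based, half-open character offsets.

normalize_newlines <- function(x) gsub("\r\n?", "\n", x)

#' Read a document in brat standoff format
#'
#' Parses an abstract plus its standoff annotation content into a document
#' object. Only entity lines (`T` identifiers) whose type belongs to the
#' eight-type vocabulary are kept; relation, attribute and note lines, and
#' entity lines with unknown types, are skipped with a counted warning.
#' Discontinuous spans (`start end;start end`) have no representation in the
#' layered BIO scheme and are rejected.
#'
#' @param text_content The abstract text (UTF-8).
#' @param ann_content The standoff annotation content (may be `""`).
#' @param doc_id Document identifier.
#' @param lenient If `TRUE`, a surface string that disagrees with the text
#'   slice warns and the offsets are trusted; the default (strict) errors.
#' @return A `ner_document`: a list with `doc_id`, `text` and a span tibble
#'   `spans`.
#' @examples
#' doc <- read_standoff_document("Chronic hypertension persists.",
#'                               "T1\tDISO 8 20\thypertension")
#' doc$spans
#' @export
read_standoff_document <- function(text_content, ann_content, doc_id = "doc",
                                   lenient = FALSE) {
  text <- normalize_newlines(text_content)
  lines <- strsplit(normalize_newlines(ann_content), "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  skipped <- 0L
  rows <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (!grepl("^T", parts[[1]])) {
      skipped <- skipped + 1L
      next
    }
    if (length(parts) < 2L) {
      stop("malformed annotation line: ", ln, call. = FALSE)
    }
    if (grepl(";", parts[[2]], fixed = TRUE)) {
      stop("discontinuous span is not representable in layered BIO tagging: ",
           ln, call. = FALSE)
    }
    fields <- strsplit(trimws(parts[[2]]), "\\s+")[[1]]
    if (length(fields) != 3L || anyNA(suppressWarnings(as.integer(fields[2:3])))) {
      stop("malformed annotation line: ", ln, call. = FALSE)
    }
    etype <- fields[[1]]
    if (!etype %in% entity_types()) {
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = parts[[1]], etype = etype,
      start = as.integer(fields[[2]]), end = as.integer(fields[[3]]),
      surface = if (length(parts) >= 3L) parts[[3]] else NA_character_
    )
  }
  if (skipped > 0L) {
    warning(skipped, " non-entity or unknown-type annotation line(s) skipped",
            call. = FALSE)
  }
  spans <- if (length(rows)) dplyr::bind_rows(rows) else empty_spans()
  if (anyDuplicated(spans$id)) {
    stop("duplicate annotation ids in document ", doc_id, call. = FALSE)
  }
  spans <- validate_spans(spans, text, lenient = lenient)
  structure(list(doc_id = doc_id, text = text, spans = spans),
            class = "ner_document")
}

#' @export
print.ner_document <- function(x, ...) {
  cat("<ner_document> ", x$doc_id, ": ", nchar(x$text), " chars, ",
      nrow(x$spans), " spans\n", sep = "")
  invisible(x)
}

#' Write entity spans as brat standoff annotation
#'
#' Emits one entity line per span with fresh sequential identifiers
#' (`T1`, `T2`, ...). Reading the output back with
#' [read_standoff_document()] recovers the same typed offsets.
#'
#' @param spans A span tibble.
#' @param text Host text; spans are validated against it before any output.
#' @return The annotation content as a single string (possibly `""`).
#' @export
write_standoff <- function(spans, text) {
  if (nrow(spans) == 0) return("")
  spans <- validate_spans(spans, text)
  paste0(sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(spans)), spans$etype,
                 spans$start, spans$end, spans$surface),
         collapse = "\n")
}

# Candidate sentence boundaries: sentence-final punctuation followed by
# whitespace and a capitalized (or numeric) continuation. Returns the doc
# offsets (0-based) at which a new sentence starts.
candidate_breaks <- function(text) {
  m <- gregexpr("[.!?]+[\"')\\]]*\\s+(?=[A-Z0-9])", text, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer())
  as.integer(m) + attr(m, "match.length") - 1L
}

#' Split a document into sentences, remapping annotations
#'
#' Segments the text with a rule-based splitter (sentence-final punctuation
#' followed by a capitalized continuation) and attaches each entity span to
#' the sentence containing it, converting offsets to sentence-local
#' coordinates. Whenever a span crosses a proposed boundary the two
#' sentences are merged, so annotation mapping never depends on splitter
#' quality.
#'
#' @param doc A `ner_document`.
#' @return A tibble with columns `doc_id`, `sent_index`, `text`,
#'   `doc_start` and a list-column `spans` of sentence-local span tibbles.
#' @export
segment_sentences <- function(doc) {
  text <- doc$text
  breaks <- candidate_breaks(text)
  starts <- c(0L, breaks)
  ends <- c(breaks, nchar(text))
  keep <- starts < ends
  starts <- starts[keep]; ends <- ends[keep]

  # merge sentences joined by a boundary-crossing span
  if (nrow(doc$spans) > 0 && length(starts) > 1L) {
    repeat {
      crossing <- FALSE
      for (k in seq_len(length(starts) - 1L)) {
        b <- ends[k]
        if (any(doc$spans$start < b & doc$spans$end > b)) {
          starts <- starts[-(k + 1L)]
          ends <- ends[-k]
          crossing <- TRUE
          break
        }
      }
      if (!crossing) break
    }
  }

  out <- purrr::map2(starts, ends, function(s, e) {
    raw <- substr(text, s + 1L, e)
    lead <- nchar(raw) - nchar(sub("^\\s+", "", raw))
    trail <- nchar(raw) - nchar(sub("\\s+$", "", raw))
    s2 <- s + lead
    e2 <- e - trail
    stext <- substr(text, s2 + 1L, e2)
    inside <- doc$spans$start >= s2 & doc$spans$end <= e2
    local <- doc$spans[inside, , drop = FALSE]
    local$start <- local$start - s2
    local$end <- local$end - s2
    list(text = stext, doc_start = s2, spans = local)
  })
  out <- out[vapply(out, function(x) nzchar(x$text), logical(1))]
  if (!length(out)) {
    out <- list(list(text = text, doc_start = 0L, spans = doc$spans))
  }
  tibble::tibble(
    doc_id = doc$doc_id,
    sent_index = seq_along(out),
    text = purrr::map_chr(out, "text"),
    doc_start = purrr::map_int(out, ~as.integer(.x$doc_start)),
    spans = purrr::map(out, "spans")
  )
}

#' Map sentence-local spans back to document coordinates
#'
#' The inverse of the remapping done by [segment_sentences()]: shifts each
#' sentence's spans by its `doc_start` and binds them into one document-level
#' span tibble.
#'
#' @param sentences A sentence tibble as returned by [segment_sentences()].
#' @return A span tibble in document coordinates.
#' @export
sentences_to_doc_spans <- function(sentences) {
  rows <- purrr::map2(sentences$spans, sentences$doc_start, function(sp, off) {
    sp$start <- sp$start + off
    sp$end <- sp$end + off
    sp
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty_spans() else out
}

#' Read a directory of standoff `.txt`/`.ann` pairs
#'
#' @param dir Directory containing matched `<id>.txt` and `<id>.ann` files.
#' @param lenient Passed to [read_standoff_document()].
#' @return A list of `ner_document` objects, ordered by file name.
#' @export
read_standoff_dir <- function(dir, lenient = FALSE) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(txts)) stop("no .txt files found in ", dir, call. = FALSE)
  purrr::map(txts, function(tf) {
    af <- sub("\\.txt$", ".ann", tf)
    ann <- if (file.exists(af)) paste(readLines(af, warn = FALSE), collapse = "\n") else ""
    read_standoff_document(paste(readLines(tf, warn = FALSE), collapse = "\n"),
                           ann, doc_id = sub("\\.txt$", "", basename(tf)),
                           lenient = lenient)
  })
}

#' Write documents as standoff `.txt`/`.ann` pairs
#'
#' @param docs A list of `ner_document` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_standoff_dir <- function(docs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in docs) {
    writeLines(doc$text, file.path(dir, paste0(doc$doc_id, ".txt")))
    ann <- write_standoff(doc$spans, doc$text)
    writeLines(if (nzchar(ann)) ann else character(),
               file.path(dir, paste0(doc$doc_id, ".ann")))
  }
  invisible(dir)
}

#' Serialize a sentence corpus as JSON Lines
#'
#' One sentence per line with fields `doc_id`, `sent_index`, `text`,
#' `doc_start` and `spans` (sentence-local coordinates) — the on-disk
#' format used for reproducible train/validation splits.
#'
#' @param sentences A sentence tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sentences_jsonl <- function(sentences, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(sentences))) {
    rec <- list(doc_id = sentences$doc_id[i],
                sent_index = sentences$sent_index[i],
                text = sentences$text[i],
                doc_start = sentences$doc_start[i],
                spans = sentences$spans[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"), con)
  }
  invisible(path)
}

#' Read a JSON Lines sentence corpus
#'
#' @param path File written by [write_sentences_jsonl()].
#' @return A sentence tibble.
#' @export
read_sentences_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- purrr::map(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyDataFrame = TRUE)
    sp <- if (length(rec$spans)) {
      tibble::as_tibble(rec$spans)
    } else {
      empty_spans()
    }
    sp$start <- as.integer(sp$start); sp$end <- as.integer(sp$end)
    tibble::tibble(doc_id = rec$doc_id,
                   sent_index = as.integer(rec$sent_index),
                   text = rec$text, doc_start = as.integer(rec$doc_start),
                   spans = list(sp))
  })
  dplyr::bind_rows(rows)
}
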