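#' Entity type vocabulary
#'
#' The eight biomedical entity classes handled throughout the package:
#' disorders (`DISO`), anatomical structures (`ANATOMY`), chemicals (`CHEM`),
#' clinical findings (`FINDING`), physiological processes (`PHYS`),
#' laboratory procedures (`LABPROC`), injuries/poisonings
#' (`INJURY_POISONING`) and medical devices (`DEVICE`).
#'
#' @format A character vector of length 8.
#' @export
entity_types <- function() {
  c("DISO", "ANATOMY", "CHEM", "FINDING", "PHYS",
    "LABPROC", "INJURY_POISONING", "DEVICE")
}

#' BIO label vocabulary
#'
#' The full per-token label space: `B-TYPE` and `I-TYPE` for each of the
#' eight entity types plus the outside label `O` — 17 labels in total. Every
#' classification head of the multilayer model predicts over exactly this
#' vocabulary.
#'
#' @return A character vector of length 17; `O` is the first element.
#' @examples
#' bio_labels()
#' length(bio_labels())
#' @export
bio_labels <- function() {
  types <- entity_types()
  c("O", as.vector(rbind(paste0("B-", types), paste0("I-", types))))
}

#' Construct a tibble of entity spans
#'
#' An entity span is one typed annotation with 0-based half-open character
#' offsets, the atom of both gold and predicted output. Spans live in
#' tibbles with columns `id`, `etype`, `start`, `end`, `surface`.
#'
#' @param etype Character vector of entity types (see [entity_types()]).
#' @param start,end Integer character offsets, 0-based, half-open.
#' @param surface Character vector of annotated surface strings (optional;
#'   filled from `text` when supplied).
#' @param id Annotation identifiers; defaults to `T1`, `T2`, ...
#' @param text Optional host text used to fill `surface` and validate.
#' @return A tibble with one row per span.
#' @export
entity_spans <- function(etype = character(), start = integer(),
                         end = integer(), surface = NULL, id = NULL,
                         text = NULL) {
  n <- length(etype)
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.null(id)) id <- if (n) paste0("T", seq_len(n)) else character()
  if (is.null(surface)) {
    surface <- if (!is.null(text)) {
      substr(rep(text, n), start + 1L, end)
    } else {
      rep(NA_character_, n)
    }
  }
  out <- tibble::tibble(id = as.character(id), etype = as.character(etype),
                        start = start, end = end,
                        surface = as.character(surface))
  if (!is.null(text)) validate_spans(out, text)
  out
}

empty_spans <- function() {
  tibble::tibble(id = character(), etype = character(), start = integer(),
                 end = integer(), surface = character())
}

#' Validate entity spans against their host text
#'
#' Checks the span invariants: offsets within `[0, nchar(text)]` and
#' `start < end`, entity type in the eight-type vocabulary, and (unless
#' `lenient`) that the recorded surface equals the text slice.
#'
#' @param spans A span tibble (see [entity_spans()]).
#' @param text The host text the offsets refer to.
#' @param lenient If `TRUE`, surface mismatches warn instead of erroring
#'   (offsets are trusted); malformed offsets always error.
#' @return `spans`, invisibly, with `surface` filled from the text where it
#'   was `NA`.
#' @export
validate_spans <- function(spans, text, lenient = FALSE) {
  if (nrow(spans) == 0) return(invisible(spans))
  n <- nchar(text)
  bad <- spans$start < 0L | spans$end > n | spans$start >= spans$end
  if (any(bad)) {
    stop("malformed annotation: offsets out of range for span(s) ",
         paste(spans$id[bad], collapse = ", "), call. = FALSE)
  }
  bad_type <- !spans$etype %in% entity_types()
  if (any(bad_type)) {
    stop("unknown entity type for span(s) ",
         paste(spans$id[bad_type], collapse = ", "), call. = FALSE)
  }
  slice <- substr(rep(text, nrow(spans)), spans$start + 1L, spans$end)
  known <- !is.na(spans$surface)
  mism <- known & spans$surface != slice
  if (any(mism)) {
    msg <- paste0("surface mismatch for span(s) ",
                  paste(spans$id[mism], collapse = ", "),
                  ": annotation does not equal the text slice")
    if (lenient) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  spans$surface[!known] <- slice[!known]
  invisible(spans)
}

dedup_spans <- function(spans) {
  dplyr::distinct(spans, .data$etype, .data$start, .data$end,
                  .keep_all = TRUE)
}

span_key <- function(spans) {
  paste(spans$etype, spans$start, spans$end)
}
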