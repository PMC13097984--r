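# Per-entity-type term dictionaries from MRCONSO.RRF-format concept files,
# longest-match term scanning, and merging of dictionary spans with model
# predictions.
#
# MRCONSO.RRF is pipe-delimited; the columns used here are CUI (field 1),
# LAT (field 2, language) and STR (field 15, term string).

MRCONSO_CUI <- 1L
MRCONSO_LAT <- 2L
MRCONSO_STR <- 15L

#' Construct a concept map
#'
#' Maps each entity type to the concept identifier (CUI) governing it,
#' optionally with the coarse semantic-group label — the layout used to
#' tie UMLS-style concept vocabularies to the eight-type task.
#'
#' @param entity_type Character vector of entity types.
#' @param concept_id Character vector of CUIs (`C` followed by digits).
#' @param semantic_group Optional semantic-group labels.
#' @return A `concept_map` tibble.
#' @export
concept_map <- function(entity_type, concept_id, semantic_group = NA) {
  bad <- !grepl("^C[0-9]+$", concept_id)
  if (any(bad)) {
    stop("invalid concept id(s): ", paste(concept_id[bad], collapse = ", "),
         call. = FALSE)
  }
  bad_ty <- !entity_type %in% entity_types()
  if (any(bad_ty)) {
    stop("unknown entity type(s): ",
         paste(entity_type[bad_ty], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(entity_type = entity_type, concept_id = concept_id,
                        semantic_group = semantic_group)
  class(out) <- c("concept_map", class(out))
  out
}

#' Read a concept map from CSV
#'
#' Expects columns `entity_type`, `concept_id` and optionally
#' `semantic_group`.
#'
#' @param path CSV file path.
#' @return A `concept_map` tibble.
#' @export
read_concept_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  concept_map(df$entity_type, df$concept_id,
              if ("semantic_group" %in% names(df)) df$semantic_group else NA)
}

normalize_term <- function(x) {
  stringr::str_squish(tolower(x))
}

# transitive closure: all descendants (including self) of each seed CUI
descendant_closure <- function(seeds, parent, child) {
  out <- lapply(seeds, function(s) {
    seen <- s
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(child[parent %in% frontier])
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  })
  names(out) <- seeds
  out
}

#' Build typed term dictionaries from MRCONSO-format content
#'
#' Collects the term strings of every concept whose CUI is governed by a
#' concept-map entry, expanded to descendant concepts via the transitive
#' closure of an optional parent-to-child relation table. Only
#' English-language rows are used. Terms are normalized (case-folded,
#' whitespace-collapsed) exactly as [match_terms()] expects.
#'
#' @param rrf_content MRCONSO.RRF-format text (pipe-delimited, CUI in
#'   field 1, language in field 2, term in field 15).
#' @param cmap A [concept_map()].
#' @param relations_content Optional pipe-delimited `parent|child` CUI
#'   pairs enabling descendant expansion.
#' @return A `typed_dictionary`: a named list of term-string sets per
#'   entity type, with a `counts` attribute recording provenance.
#' @export
parse_mrconso <- function(rrf_content, cmap, relations_content = NULL) {
  lines <- strsplit(normalize_newlines(rrf_content), "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "|", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= MRCONSO_STR
  if (any(!ok)) {
    warning(sum(!ok), " malformed MRCONSO row(s) skipped", call. = FALSE)
    fields <- fields[ok]
  }
  cui <- vapply(fields, `[[`, character(1), MRCONSO_CUI)
  lat <- vapply(fields, `[[`, character(1), MRCONSO_LAT)
  str <- vapply(fields, `[[`, character(1), MRCONSO_STR)
  eng <- lat == "ENG"
  cui <- cui[eng]; str <- str[eng]

  closure <- if (!is.null(relations_content)) {
    rl <- strsplit(normalize_newlines(relations_content), "\n",
                   fixed = TRUE)[[1]]
    rl <- rl[nzchar(trimws(rl))]
    rp <- strsplit(rl, "|", fixed = TRUE)
    descendant_closure(cmap$concept_id,
                       vapply(rp, `[[`, character(1), 1L),
                       vapply(rp, `[[`, character(1), 2L))
  } else {
    stats::setNames(as.list(cmap$concept_id), cmap$concept_id)
  }

  terms <- stats::setNames(rep(list(character()), length(entity_types())),
                           entity_types())
  for (i in seq_len(nrow(cmap))) {
    ty <- cmap$entity_type[i]
    cuis <- closure[[cmap$concept_id[i]]]
    tm <- normalize_term(str[cui %in% cuis])
    tm <- unique(tm[nzchar(tm)])
    terms[[ty]] <- sort(unique(c(terms[[ty]], tm)))
  }
  empty <- vapply(terms, function(x) length(x) == 0L, logical(1))
  if (any(empty)) {
    warning("empty dictionary for type(s): ",
            paste(names(terms)[empty], collapse = ", "), call. = FALSE)
  }
  counts <- tibble::tibble(entity_type = names(terms),
                           n_terms = vapply(terms, length, integer(1)))
  structure(terms, counts = counts, class = "typed_dictionary")
}

#' @export
print.typed_dictionary <- function(x, ...) {
  cat("<typed_dictionary>\n")
  print(attr(x, "counts"))
  invisible(x)
}

#' Write a typed dictionary as one-term-per-line files
#'
#' @param dict A `typed_dictionary`.
#' @param dir Output directory; one `<TYPE>.txt` per entity type.
#' @return `dir`, invisibly.
#' @export
write_dictionary <- function(dict, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ty in names(dict)) {
    writeLines(as.character(dict[[ty]]), file.path(dir, paste0(ty, ".txt")))
  }
  invisible(dir)
}

#' Read a typed dictionary from one-term-per-line files
#'
#' @param dir Directory of `<TYPE>.txt` files as written by
#'   [write_dictionary()].
#' @return A `typed_dictionary`.
#' @export
read_dictionary <- function(dir) {
  terms <- stats::setNames(vector("list", length(entity_types())),
                           entity_types())
  for (ty in entity_types()) {
    f <- file.path(dir, paste0(ty, ".txt"))
    if (file.exists(f)) {
      tm <- normalize_term(readLines(f, warn = FALSE))
      terms[[ty]] <- sort(unique(tm[nzchar(tm)]))
    } else {
      terms[[ty]] <- character()
    }
  }
  counts <- tibble::tibble(entity_type = names(terms),
                           n_terms = vapply(terms, length, integer(1)))
  structure(terms, counts = counts, class = "typed_dictionary")
}

is_word_char <- function(ch) grepl("[[:alnum:]]", ch)

# all word-boundary occurrences of a fixed term in lowercased text
term_occurrences <- function(text_lower, term, n) {
  m <- gregexpr(term, text_lower, fixed = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  start <- as.integer(m) - 1L
  end <- start + nchar(term)
  keep <- vapply(seq_along(start), function(i) {
    before_ok <- start[i] == 0L ||
      !is_word_char(substr(text_lower, start[i], start[i]))
    after_ok <- end[i] == n ||
      !is_word_char(substr(text_lower, end[i] + 1L, end[i] + 1L))
    before_ok && after_ok
  }, logical(1))
  if (!any(keep)) return(NULL)
  cbind(start = start[keep], end = end[keep])
}

#' Match dictionary terms in text
#'
#' Case-insensitive scan at word boundaries. Overlapping candidate matches
#' of the same entity type are resolved longest-first, then leftmost;
#' matches of different types may overlap (nesting is legitimate). Terms
#' shorter than `min_chars` characters are never matched.
#'
#' @param text Text to scan (document or sentence coordinates — the output
#'   uses the same frame).
#' @param dict A `typed_dictionary`.
#' @param min_chars Minimum term length in characters (default 3).
#' @return A span tibble.
#' @export
match_terms <- function(text, dict, min_chars = 3L) {
  text_lower <- tolower(text)
  n <- nchar(text)
  rows <- list()
  for (ty in names(dict)) {
    terms <- dict[[ty]]
    terms <- terms[nchar(terms) >= min_chars]
    if (!length(terms)) next
    cand <- do.call(rbind, lapply(terms, term_occurrences,
                                  text_lower = text_lower, n = n))
    if (is.null(cand)) next
    cand <- cand[order(-(cand[, "end"] - cand[, "start"]),
                       cand[, "start"]), , drop = FALSE]
    kept_end <- integer(0)
    kept_start <- integer(0)
    for (i in seq_len(nrow(cand))) {
      s <- cand[i, "start"]; e <- cand[i, "end"]
      if (!any(kept_start < e & kept_end > s)) {
        kept_start <- c(kept_start, s)
        kept_end <- c(kept_end, e)
        rows[[length(rows) + 1L]] <- list(etype = ty, start = s, end = e)
      }
    }
  }
  if (!length(rows)) return(empty_spans())
  out <- tibble::tibble(etype = purrr::map_chr(rows, "etype"),
                        start = purrr::map_int(rows, ~as.integer(.x$start)),
                        end = purrr::map_int(rows, ~as.integer(.x$end)))
  out <- dplyr::arrange(out, .data$start, dplyr::desc(.data$end), .data$etype)
  out$id <- paste0("T", seq_len(nrow(out)))
  out$surface <- substring(text, out$start + 1L, out$end)
  out[, c("id", "etype", "start", "end", "surface")]
}

#' Merge model predictions with dictionary matches
#'
#' Deduplicated union on (`etype`, `start`, `end`) with model precedence:
#' a dictionary span overlapping a model span of the same type without
#' being identical is dropped, preserving the trained model's boundary
#' decisions. Cross-type overlaps (nesting) are kept. Every model span
#' survives, so merging can only add recall.
#'
#' @param model_spans,dict_spans Span tibbles in the same coordinate frame.
#' @return A deduplicated span tibble.
#' @export
merge_predictions <- function(model_spans, dict_spans) {
  model_spans <- dedup_spans(model_spans)
  dict_spans <- dedup_spans(dict_spans)
  mkey <- span_key(model_spans)
  keep <- vapply(seq_len(nrow(dict_spans)), function(i) {
    k <- paste(dict_spans$etype[i], dict_spans$start[i], dict_spans$end[i])
    if (k %in% mkey) return(FALSE)  # identical: model copy already present
    same <- model_spans$etype == dict_spans$etype[i] &
      model_spans$start < dict_spans$end[i] &
      model_spans$end > dict_spans$start[i]
    !any(same)
  }, logical(1))
  out <- dplyr::bind_rows(model_spans, dict_spans[keep, , drop = FALSE])
  if (nrow(out) == 0) return(empty_spans())
  out <- dplyr::arrange(out, .data$start, dplyr::desc(.data$end), .data$etype)
  out$id <- paste0("T", seq_len(nrow(out)))
  out
}
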