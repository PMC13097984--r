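# Layered BIO codec: assign nested/overlapping spans to up to six
# non-overlapping layers, encode each layer as token-level BIO tags, and
# decode tags back to spans.

#' Tokenize a sentence into word tokens with offsets
#'
#' Word-level pre-tokenization preceding subword handling: maximal
#' alphanumeric runs and single punctuation characters become tokens, so
#' `"interleukin-2"` yields three tokens. Offsets are sentence-local,
#' 0-based, half-open.
#'
#' @param text Sentence text.
#' @return A tibble with columns `text`, `start`, `end`, ordered by `start`.
#' @examples
#' tokenize_sentence("serum level.")
#' @export
tokenize_sentence <- function(text) {
  if (!nzchar(text)) {
    return(tibble::tibble(text = character(), start = integer(),
                          end = integer()))
  }
  m <- gregexpr("[[:alnum:]]+|[^[:alnum:][:space:]]", text)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(text = character(), start = integer(),
                          end = integer()))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  tibble::tibble(text = substring(text, start + 1L, end), start = start,
                 end = end)
}

#' Assign nested spans to non-overlapping layers
#'
#' Deterministic greedy placement: spans are sorted by start ascending,
#' length descending, then entity type lexicographically, and each span is
#' placed in the lowest-index layer where it overlaps nothing already
#' placed. An outer span therefore precedes its nested inner spans, so the
#' outermost entities populate layer 1. Within a layer no two spans overlap.
#'
#' @param spans A sentence-local span tibble.
#' @param max_layers Maximum nesting depth supported (default 6).
#' @param lenient If `TRUE`, spans that cannot be placed within
#'   `max_layers` layers are dropped with a warning; the default errors,
#'   listing the unplaceable spans.
#' @return The span tibble with an integer `layer` column, sorted in
#'   placement order.
#' @export
assign_layers <- function(spans, max_layers = 6L, lenient = FALSE) {
  if (nrow(spans) == 0) {
    spans$layer <- integer()
    return(spans)
  }
  ord <- order(spans$start, -(spans$end - spans$start), spans$etype)
  spans <- spans[ord, , drop = FALSE]
  # per layer, rightmost end placed so far (spans arrive sorted by start)
  layer_end <- rep(-1L, max_layers)
  layer <- integer(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    placed <- FALSE
    for (k in seq_len(max_layers)) {
      if (spans$start[i] >= layer_end[k]) {
        layer[i] <- k
        layer_end[k] <- spans$end[i]
        placed <- TRUE
        break
      }
    }
    if (!placed) layer[i] <- NA_integer_
  }
  if (anyNA(layer)) {
    bad <- spans[is.na(layer), , drop = FALSE]
    msg <- paste0("span set requires more than ", max_layers,
                  " layers; unplaceable: ",
                  paste(sprintf("%s(%s %d-%d)", bad$id, bad$etype, bad$start,
                                bad$end), collapse = ", "))
    if (!lenient) stop(msg, call. = FALSE)
    warning(msg, " (dropped)", call. = FALSE)
    spans <- spans[!is.na(layer), , drop = FALSE]
    layer <- layer[!is.na(layer)]
  }
  spans$layer <- layer
  spans
}

# Snap a span outward to the boundaries of the tokens it overlaps.
snap_to_tokens <- function(start, end, tokens) {
  hit <- which(tokens$start < end & tokens$end > start)
  if (!length(hit)) return(NULL)
  c(tokens$start[min(hit)], tokens$end[max(hit)])
}

#' Encode layered spans as six BIO tag sequences
#'
#' For each layer, tokens inside a span receive `B-TYPE` (first token) and
#' `I-TYPE` (subsequent tokens); all other tokens receive `O`. Exactly
#' `n_layers` sequences are always emitted, unused layers padded all-`O`,
#' keeping the model's head count static. A span boundary falling inside a
#' token is snapped outward to the enclosing token boundaries with a
#' counted warning.
#'
#' @param tokens A token tibble from [tokenize_sentence()].
#' @param layered A span tibble with a `layer` column from
#'   [assign_layers()].
#' @param n_layers Number of tag sequences to emit (default 6).
#' @return A character matrix with `n_layers` rows and one column per
#'   token, values drawn from [bio_labels()].
#' @export
encode_bio <- function(tokens, layered, n_layers = 6L) {
  nt <- nrow(tokens)
  tags <- matrix("O", nrow = n_layers, ncol = nt,
                 dimnames = list(paste0("layer", seq_len(n_layers)), NULL))
  if (nrow(layered) > 0 && max(layered$layer) > n_layers) {
    stop("layer index exceeds n_layers", call. = FALSE)
  }
  snapped <- 0L
  for (i in seq_len(nrow(layered))) {
    if (nt == 0L) stop("span present but sentence has no tokens", call. = FALSE)
    bounds <- snap_to_tokens(layered$start[i], layered$end[i], tokens)
    if (is.null(bounds)) {
      stop("span [", layered$start[i], ",", layered$end[i],
           ") overlaps no token", call. = FALSE)
    }
    if (bounds[1] != layered$start[i] || bounds[2] != layered$end[i]) {
      snapped <- snapped + 1L
    }
    idx <- which(tokens$start >= bounds[1] & tokens$end <= bounds[2])
    k <- layered$layer[i]
    tags[k, idx[1]] <- paste0("B-", layered$etype[i])
    if (length(idx) > 1L) {
      tags[k, idx[-1]] <- paste0("I-", layered$etype[i])
    }
  }
  if (snapped > 0L) {
    warning(snapped, " span boundary(ies) snapped to token boundaries",
            call. = FALSE)
  }
  tags
}

#' Decode BIO tag sequences back to entity spans
#'
#' Contiguous `B`/`I` runs become spans from the first token's start to the
#' last token's end. Invalid sequences are repaired conservatively: an
#' `I-TYPE` following `O` or a different type is treated as `B-TYPE`.
#' Output is the union over layers, deduplicated on
#' (`etype`, `start`, `end`); decoding is total.
#'
#' @param tokens A token tibble.
#' @param tags A tag matrix as produced by [encode_bio()] (layers in rows).
#' @param text Optional sentence text used to fill span surfaces.
#' @return A span tibble in sentence-local coordinates.
#' @export
decode_bio <- function(tokens, tags, text = NULL) {
  stopifnot(ncol(tags) == nrow(tokens))
  rows <- list()
  for (k in seq_len(nrow(tags))) {
    cur_type <- NA_character_
    cur_first <- NA_integer_
    flush <- function(last) {
      if (!is.na(cur_type)) {
        rows[[length(rows) + 1L]] <<- list(etype = cur_type,
                                           start = tokens$start[cur_first],
                                           end = tokens$end[last])
      }
    }
    for (j in seq_len(ncol(tags))) {
      tag <- tags[k, j]
      if (tag == "O") {
        flush(j - 1L); cur_type <- NA_character_
      } else {
        prefix <- substr(tag, 1, 1)
        ty <- substring(tag, 3)
        if (prefix == "B" || is.na(cur_type) || ty != cur_type) {
          flush(j - 1L)  # I after O or type switch: repaired as B
          cur_type <- ty
          cur_first <- j
        }
      }
    }
    flush(ncol(tags))
  }
  if (!length(rows)) return(empty_spans())
  out <- tibble::tibble(
    etype = purrr::map_chr(rows, "etype"),
    start = purrr::map_int(rows, ~as.integer(.x$start)),
    end = purrr::map_int(rows, ~as.integer(.x$end))
  )
  out <- dplyr::distinct(out)
  out <- dplyr::arrange(out, .data$start, dplyr::desc(.data$end), .data$etype)
  out$id <- paste0("T", seq_len(nrow(out)))
  out$surface <- if (!is.null(text)) {
    substring(text, out$start + 1L, out$end)
  } else {
    NA_character_
  }
  out[, c("id", "etype", "start", "end", "surface")]
}

#' Tokenize and BIO-encode a sentence corpus
#'
#' Convenience wrapper running [tokenize_sentence()], [assign_layers()] and
#' [encode_bio()] over every sentence of a corpus tibble.
#'
#' @param sentences A sentence tibble from [segment_sentences()].
#' @param n_layers Number of BIO layers (default 6).
#' @param lenient Passed to [assign_layers()].
#' @return The tibble with list-columns `tokens` and `tags` added.
#' @export
encode_sentences <- function(sentences, n_layers = 6L, lenient = FALSE) {
  sentences$tokens <- purrr::map(sentences$text, tokenize_sentence)
  sentences$tags <- purrr::pmap(
    list(sentences$tokens, sentences$spans),
    function(tok, sp) {
      encode_bio(tok, assign_layers(sp, max_layers = n_layers,
                                    lenient = lenient),
                 n_layers = n_layers)
    })
  sentences
}

#' Human-readable vertical dump of a tagged sentence
#'
#' One token per row with its six layer tags in columns — the inspection
#' format for tagged corpora.
#'
#' @param tokens A token tibble.
#' @param tags A tag matrix (layers in rows).
#' @return A tibble with columns `token` and `layer1` ... `layerN`.
#' @export
tagged_sentence_table <- function(tokens, tags) {
  out <- tibble::tibble(token = tokens$text)
  for (k in seq_len(nrow(tags))) out[[paste0("layer", k)]] <- tags[k, ]
  out
}

#' Serialize tagged sentences as JSON Lines
#'
#' One sentence per line with token texts, offsets and the six tag
#' sequences — the on-disk training-set format.
#'
#' @param encoded A tibble from [encode_sentences()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tagged_jsonl <- function(encoded, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(encoded))) {
    tg <- encoded$tags[[i]]
    rec <- list(doc_id = encoded$doc_id[i],
                sent_index = encoded$sent_index[i],
                text = encoded$text[i],
                tokens = encoded$tokens[[i]],
                tags = lapply(seq_len(nrow(tg)), function(k) unname(tg[k, ])))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows"), con)
  }
  invisible(path)
}

#' Read tagged sentences from JSON Lines
#'
#' @param path File written by [write_tagged_jsonl()].
#' @return A tibble with `doc_id`, `sent_index`, `text`, `tokens`, `tags`.
#' @export
read_tagged_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- purrr::map(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyDataFrame = TRUE)
    tok <- tibble::as_tibble(rec$tokens)
    tok$start <- as.integer(tok$start); tok$end <- as.integer(tok$end)
    tg <- rec$tags
    if (!is.matrix(tg)) {
      tg <- if (is.list(tg)) do.call(rbind, tg) else matrix(tg, ncol = 1L)
    }
    rownames(tg) <- paste0("layer", seq_len(nrow(tg)))
    tibble::tibble(doc_id = rec$doc_id,
                   sent_index = as.integer(rec$sent_index), text = rec$text,
                   tokens = list(tok), tags = list(tg))
  })
  dplyr::bind_rows(rows)
}
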