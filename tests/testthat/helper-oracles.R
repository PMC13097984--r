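# Independent brute-force oracles and fixture builders used across tests.

# exact-match confusion tally by explicit pairwise comparison
brute_confusion <- function(gold, pred) {
  gold <- dplyr::distinct(gold, etype, start, end)
  pred <- dplyr::distinct(pred, etype, start, end)
  purrr::map_dfr(entity_types(), function(ty) {
    g <- gold[gold$etype == ty, ]
    p <- pred[pred$etype == ty, ]
    matched_g <- rep(FALSE, nrow(g))
    matched_p <- rep(FALSE, nrow(p))
    for (i in seq_len(nrow(p))) {
      for (j in seq_len(nrow(g))) {
        if (!matched_g[j] && p$start[i] == g$start[j] &&
            p$end[i] == g$end[j]) {
          matched_p[i] <- TRUE
          matched_g[j] <- TRUE
          break
        }
      }
    }
    tibble::tibble(etype = ty, tp = sum(matched_p), fp = sum(!matched_p),
                   fn = sum(!matched_g))
  })
}

# dictionary matching by scanning every substring of the text
brute_match <- function(text, dict, min_chars = 3L) {
  lower <- tolower(text)
  n <- nchar(text)
  wordish <- function(i) i >= 1 && i <= n &&
    grepl("[[:alnum:]]", substr(lower, i, i))
  rows <- list()
  for (ty in names(dict)) {
    terms <- dict[[ty]][nchar(dict[[ty]]) >= min_chars]
    if (!length(terms)) next
    cand <- list()
    for (s in 0:(n - 1)) {
      for (e in (s + 1):n) {
        if (substr(lower, s + 1, e) %in% terms &&
            !wordish(s) && !wordish(e + 1)) {
          cand[[length(cand) + 1L]] <- c(as.integer(s), as.integer(e))
        }
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-(cand[, 2] - cand[, 1]), cand[, 1]), , drop = FALSE]
    kept <- matrix(integer(), ncol = 2)
    for (i in seq_len(nrow(cand))) {
      s <- cand[i, 1]; e <- cand[i, 2]
      if (!any(kept[, 1] < e & kept[, 2] > s)) {
        kept <- rbind(kept, c(s, e))
        rows[[length(rows) + 1L]] <- tibble::tibble(etype = ty, start = s,
                                                    end = e)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(etype = character(), start = integer(),
                          end = integer()))
  }
  dplyr::arrange(out, start, dplyr::desc(end), etype)
}

# random typed span set over a virtual text of length text_len
random_spans <- function(n, text_len = 100L) {
  if (n == 0) {
    return(tibble::tibble(etype = character(), start = integer(),
                          end = integer()))
  }
  start <- sample.int(text_len - 2L, n, replace = TRUE) - 1L
  len <- sample.int(10L, n, replace = TRUE)
  tibble::tibble(etype = sample(entity_types(), n, replace = TRUE),
                 start = start,
                 end = pmin(start + len, text_len))
}

span_keys <- function(sp) sort(paste(sp$etype, sp$start, sp$end))

# a small encoded synthetic corpus for model tests
make_encoded_corpus <- function(n_documents = 5, seed = 11, max_depth = 3,
                                sentences_per_doc = c(4, 4)) {
  spec <- corpus_spec(n_documents = n_documents,
                      sentences_per_doc = sentences_per_doc,
                      seed = seed, max_depth = max_depth)
  docs <- generate_corpus(spec)
  encode_sentences(dplyr::bind_rows(purrr::map(docs, segment_sentences)))
}

# span-level micro F1 of per-sentence predictions against per-sentence gold
sentence_micro_f1 <- function(gold_list, pred_list) {
  counts <- purrr::map2_dfr(gold_list, pred_list, confusion_counts)
  counts <- dplyr::summarise(dplyr::group_by(counts, etype),
                             tp = sum(tp), fp = sum(fp), fn = sum(fn),
                             .groups = "drop")
  score(counts)$micro$f1
}
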