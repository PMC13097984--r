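# Pipeline stages wiring the modules end to end over on-disk artifacts:
# simulate -> preprocess (tag + split) -> train -> predict -> dict-match ->
# merge -> evaluate. A thin command-line front-end over these functions
# ships in inst/cli/nestedner.R.
#
# One global seed fans out to per-stage seeds by fixed offsets so stages
# are reproducible without seed collisions.

SEED_SPLIT_OFFSET <- 101L
SEED_MODEL_OFFSET <- 202L

#' Seeded 80:20 sentence-level split
#'
#' Shuffles sentences with the given seed and assigns the first
#' `round(prop * n)` to the training split, the rest to the development
#' split. Sizes are exact and the assignment is reproducible.
#'
#' @param sentences A sentence tibble.
#' @param prop Training proportion (default 0.8).
#' @param seed Shuffle seed.
#' @return The tibble with a `split` column (`"train"` / `"dev"`).
#' @export
split_sentences <- function(sentences, prop = 0.8, seed = 1L) {
  n <- nrow(sentences)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- round(prop * n)
  split <- character(n)
  split[ord[seq_len(n_train)]] <- "train"
  split[ord[setdiff(seq_len(n), seq_len(n_train))]] <- "dev"
  sentences$split <- split
  sentences
}

#' Generate a synthetic corpus on disk
#'
#' @param out_dir Output directory for `.txt`/`.ann` pairs.
#' @param spec A [corpus_spec()]; its seed controls generation.
#' @return The document list, invisibly.
#' @export
run_simulate <- function(out_dir, spec = corpus_spec()) {
  docs <- generate_corpus(spec)
  write_standoff_dir(docs, out_dir)
  jsonlite::write_json(list(seed = spec$seed, n_documents = spec$n_documents),
                       file.path(out_dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(docs)
}

#' Preprocess a standoff corpus into tagged, split sentence files
#'
#' Reads `.txt`/`.ann` pairs, segments into sentences with annotation
#' remapping, encodes six-layer BIO tags, performs the seeded 80:20
#' sentence split, and writes `train.jsonl`, `dev.jsonl` and a split
#' manifest recording the seed.
#'
#' @param corpus_dir Directory of standoff pairs.
#' @param out_dir Output directory.
#' @param seed Global seed; the split uses a fixed offset from it.
#' @param prop Training proportion.
#' @param lenient Passed to the reader and layer assignment.
#' @return The split sentence tibble, invisibly.
#' @export
run_preprocess <- function(corpus_dir, out_dir, seed = 1L, prop = 0.8,
                           lenient = FALSE) {
  docs <- read_standoff_dir(corpus_dir, lenient = lenient)
  sentences <- dplyr::bind_rows(purrr::map(docs, segment_sentences))
  encoded <- encode_sentences(sentences, lenient = lenient)
  encoded <- split_sentences(encoded, prop = prop,
                             seed = seed + SEED_SPLIT_OFFSET)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tagged_jsonl(encoded[encoded$split == "train", ],
                     file.path(out_dir, "train.jsonl"))
  write_tagged_jsonl(encoded[encoded$split == "dev", ],
                     file.path(out_dir, "dev.jsonl"))
  manifest <- list(seed = seed, split_seed = seed + SEED_SPLIT_OFFSET,
                   prop = prop,
                   train = encoded[encoded$split == "train",
                                   c("doc_id", "sent_index")],
                   dev = encoded[encoded$split == "dev",
                                 c("doc_id", "sent_index")])
  jsonlite::write_json(manifest, file.path(out_dir, "split_manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(encoded)
}

#' Train the multilayer model from preprocessed files
#'
#' @param data_dir Directory with `train.jsonl` (and optionally
#'   `dev.jsonl`) from [run_preprocess()].
#' @param model_dir Output checkpoint directory.
#' @param config A [ner_config()]; its seed is offset from the global
#'   seed by the caller or defaults to the config value.
#' @param merge_splits If `TRUE`, train on train+dev combined (the final
#'   retraining mode after hyperparameter selection).
#' @param verbose Print per-epoch losses.
#' @return The trained model, invisibly.
#' @export
run_train <- function(data_dir, model_dir, config = ner_config(),
                      merge_splits = FALSE, verbose = FALSE) {
  train_path <- file.path(data_dir, "train.jsonl")
  if (!file.exists(train_path)) {
    stop("missing ", train_path, "; run the preprocess stage first",
         call. = FALSE)
  }
  train_data <- read_tagged_jsonl(train_path)
  dev_path <- file.path(data_dir, "dev.jsonl")
  dev_data <- if (file.exists(dev_path)) read_tagged_jsonl(dev_path)
  if (merge_splits && !is.null(dev_data)) {
    train_data <- dplyr::bind_rows(train_data, dev_data)
    dev_data <- NULL
  }
  vocab <- build_vocab(train_data, piece_len = config$piece_len)
  model <- build_model(config, vocab)
  model <- train_ner(model, train_data, val_data = dev_data,
                     verbose = verbose)
  save_model(model, model_dir)
  utils::write.csv(model$history, file.path(model_dir, "metrics.csv"),
                   row.names = FALSE)
  invisible(model)
}

# read docs, predict per sentence, remap to document coordinates
predict_documents <- function(model, docs) {
  purrr::map(docs, function(doc) {
    sentences <- segment_sentences(doc)
    sentences$spans <- purrr::map(sentences$text,
                                  function(tx) predict_spans(model, tx))
    spans <- dedup_spans(sentences_to_doc_spans(sentences))
    if (nrow(spans)) {
      spans$id <- paste0("T", seq_len(nrow(spans)))
      spans$surface <- substring(doc$text, spans$start + 1L, spans$end)
    }
    structure(list(doc_id = doc$doc_id, text = doc$text, spans = spans),
              class = "ner_document")
  })
}

#' Predict standoff annotations for a corpus with a trained model
#'
#' @param model_dir Checkpoint directory from [run_train()].
#' @param corpus_dir Directory of `.txt` files (annotations, if present,
#'   are ignored).
#' @param out_dir Output directory for predicted `.txt`/`.ann` pairs.
#' @return The predicted document list, invisibly.
#' @export
run_predict <- function(model_dir, corpus_dir, out_dir) {
  if (!file.exists(file.path(model_dir, "params.json"))) {
    stop("no model checkpoint in ", model_dir,
         "; run the train stage first", call. = FALSE)
  }
  model <- load_model(model_dir)
  docs <- read_standoff_dir(corpus_dir, lenient = TRUE)
  preds <- predict_documents(model, docs)
  write_standoff_dir(preds, out_dir)
  invisible(preds)
}

#' Dictionary-match a corpus into standoff annotations
#'
#' Builds (or loads) the typed dictionary and scans every document text,
#' writing the matches as standoff pairs.
#'
#' @param corpus_dir Directory of `.txt` files.
#' @param out_dir Output directory.
#' @param dict_dir Directory of per-type term files ([read_dictionary()]),
#'   or `NULL` when building from MRCONSO-format inputs.
#' @param mrconso_path,concept_map_path,relations_path MRCONSO-format
#'   file, concept-map CSV and optional parent-child relation file used
#'   when `dict_dir` is `NULL`.
#' @param min_chars Minimum term length for matching.
#' @return The matched document list, invisibly.
#' @export
run_dict_match <- function(corpus_dir, out_dir, dict_dir = NULL,
                           mrconso_path = NULL, concept_map_path = NULL,
                           relations_path = NULL, min_chars = 3L) {
  dict <- if (!is.null(dict_dir)) {
    read_dictionary(dict_dir)
  } else {
    if (is.null(mrconso_path) || is.null(concept_map_path)) {
      stop("supply dict_dir, or mrconso_path plus concept_map_path",
           call. = FALSE)
    }
    rel <- if (!is.null(relations_path)) {
      paste(readLines(relations_path, warn = FALSE), collapse = "\n")
    }
    parse_mrconso(paste(readLines(mrconso_path, warn = FALSE),
                        collapse = "\n"),
                  read_concept_map(concept_map_path), rel)
  }
  docs <- read_standoff_dir(corpus_dir, lenient = TRUE)
  matched <- purrr::map(docs, function(doc) {
    spans <- match_terms(doc$text, dict, min_chars = min_chars)
    structure(list(doc_id = doc$doc_id, text = doc$text, spans = spans),
              class = "ner_document")
  })
  write_standoff_dir(matched, out_dir)
  invisible(matched)
}

#' Merge model and dictionary standoff predictions
#'
#' Document-by-document union with model precedence on same-type overlap.
#' With no dictionary directory the output equals the model predictions.
#'
#' @param model_pred_dir Standoff directory of model predictions.
#' @param out_dir Output directory.
#' @param dict_pred_dir Optional standoff directory of dictionary matches.
#' @return The merged document list, invisibly.
#' @export
run_merge <- function(model_pred_dir, out_dir, dict_pred_dir = NULL) {
  mdocs <- read_standoff_dir(model_pred_dir, lenient = TRUE)
  ddocs <- if (!is.null(dict_pred_dir)) {
    dd <- read_standoff_dir(dict_pred_dir, lenient = TRUE)
    stats::setNames(dd, purrr::map_chr(dd, "doc_id"))
  }
  merged <- purrr::map(mdocs, function(doc) {
    dspans <- if (!is.null(ddocs) && doc$doc_id %in% names(ddocs)) {
      ddocs[[doc$doc_id]]$spans
    } else {
      empty_spans()
    }
    spans <- merge_predictions(doc$spans, dspans)
    if (nrow(spans)) {
      spans$surface <- substring(doc$text, spans$start + 1L, spans$end)
    }
    structure(list(doc_id = doc$doc_id, text = doc$text, spans = spans),
              class = "ner_document")
  })
  write_standoff_dir(merged, out_dir)
  invisible(merged)
}

#' Evaluate predicted standoff annotations against gold
#'
#' Pools exact-match confusion counts over all documents (matched by
#' document id) and scores them; optionally writes the report as JSON.
#'
#' @param gold_dir Directory of gold `.txt`/`.ann` pairs.
#' @param pred_dir Directory of predicted pairs.
#' @param out_path Optional JSON output path.
#' @return An `eval_report`.
#' @export
run_evaluate <- function(gold_dir, pred_dir, out_path = NULL) {
  gold <- read_standoff_dir(gold_dir)
  preds <- read_standoff_dir(pred_dir, lenient = TRUE)
  pmap <- stats::setNames(preds, purrr::map_chr(preds, "doc_id"))
  counts <- purrr::map_dfr(gold, function(doc) {
    pd <- if (doc$doc_id %in% names(pmap)) pmap[[doc$doc_id]]$spans else
      empty_spans()
    confusion_counts(doc$spans, pd)
  })
  counts <- dplyr::summarise(dplyr::group_by(counts, .data$etype),
                             tp = sum(.data$tp), fp = sum(.data$fp),
                             fn = sum(.data$fn), .groups = "drop")
  counts <- counts[match(entity_types(), counts$etype), ]
  report <- score(counts)
  if (!is.null(out_path)) write_eval_report(report, out_path)
  report
}
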