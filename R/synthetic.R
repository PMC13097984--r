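# Seeded synthetic corpus generator: sentence-structured abstracts with
# nested standoff annotations emulating the statistical structure of
# nested biomedical NER data (eight skewed entity types, nesting up to six
# levels, valid offsets), so every module is testable without licensed
# data.
#
# Entities are realized as phrases drawn from type-specific word pools, so
# a compact model can genuinely learn the word-to-type mapping; this is
# what the overfit and learnability tests rely on.

default_type_weights <- function() {
  # relative frequency shape: disorders and anatomy dominate, devices rare
  c(DISO = 1200, ANATOMY = 911, CHEM = 579, FINDING = 456, PHYS = 397,
    LABPROC = 190, INJURY_POISONING = 90, DEVICE = 20)
}

default_vocabulary <- function() {
  list(
    pools = list(
      DISO = c("hypertension", "sepsis", "anemia", "fibrosis", "migraine",
               "asthma", "dermatitis", "nephritis", "colitis", "edema"),
      ANATOMY = c("serum", "liver", "kidney", "cortex", "plasma", "mucosa",
                  "artery", "retina", "thyroid", "alveoli"),
      CHEM = c("interleukin", "cortisol", "glucose", "insulin", "dopamine",
               "heparin", "creatinine", "albumin", "ferritin", "cytokine"),
      FINDING = c("decrease", "elevation", "deficit", "response",
                  "abnormality", "reduction", "increase", "impairment",
                  "accumulation", "depletion"),
      PHYS = c("metabolism", "secretion", "perfusion", "absorption",
               "clearance", "motility", "respiration", "glycolysis",
               "homeostasis", "diuresis"),
      LABPROC = c("assay", "biopsy", "screening", "titration", "staining",
                  "sequencing", "centrifugation", "culturing", "imaging",
                  "electrophoresis"),
      INJURY_POISONING = c("fracture", "poisoning", "contusion",
                           "laceration", "overdose", "burns", "trauma",
                           "sprain", "concussion", "intoxication"),
      DEVICE = c("catheter", "stent", "pacemaker", "ventilator", "implant",
                 "prosthesis", "electrode", "cannula", "forceps", "syringe")
    ),
    filler = c("patients", "with", "showed", "during", "treatment", "after",
               "study", "observed", "were", "significantly", "compared",
               "controls", "baseline", "therapy", "group", "analysis",
               "results", "clinical", "measured", "daily", "associated",
               "reported", "among", "adults", "cohort", "outcomes"),
    starters = c("The", "Patients", "Results", "Analysis", "Clinical",
                 "Moreover", "However", "Overall")
  )
}

#' Specification for a synthetic nested-NER corpus
#'
#' @param n_documents Number of abstracts to generate.
#' @param sentences_per_doc Integer range `c(min, max)` of sentences per
#'   abstract.
#' @param type_weights Named non-negative relative frequencies over the
#'   eight entity types; the default follows the skewed shape typical of
#'   clinical abstract annotation (disorders and anatomy dominant, devices
#'   rarest).
#' @param nesting_probability Probability, at each nesting step, of
#'   wrapping an entity in a containing entity (default 0.35).
#' @param max_depth Maximum nesting depth, at most 6.
#' @param entity_probability Probability that a sentence slot holds an
#'   entity phrase rather than a filler word.
#' @param vocabulary Word lists: per-type `pools`, `filler`, `starters`.
#' @param seed Seed making generation fully reproducible.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_documents = 20L, sentences_per_doc = c(3L, 6L),
                        type_weights = default_type_weights(),
                        nesting_probability = 0.35, max_depth = 6L,
                        entity_probability = 0.45,
                        vocabulary = default_vocabulary(), seed = 1L) {
  stopifnot(max_depth <= 6L, max_depth >= 1L,
            nesting_probability >= 0, nesting_probability <= 1,
            all(type_weights >= 0), any(type_weights > 0))
  missing_types <- setdiff(names(type_weights), entity_types())
  if (length(missing_types)) {
    stop("unknown entity type(s) in weights: ",
         paste(missing_types, collapse = ", "), call. = FALSE)
  }
  pool_sizes <- vapply(vocabulary$pools, length, integer(1))
  if (any(pool_sizes < 2L) || length(vocabulary$filler) < 5L ||
      length(vocabulary$starters) < 1L) {
    stop("vocabulary too small to realize the corpus spec", call. = FALSE)
  }
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 type_weights = type_weights,
                 nesting_probability = nesting_probability,
                 max_depth = as.integer(max_depth),
                 entity_probability = entity_probability,
                 vocabulary = vocabulary, seed = as.integer(seed)),
            class = "corpus_spec")
}

sample_type <- function(weights) {
  sample(names(weights), 1L, prob = weights)
}

# Build one (possibly nested) entity phrase. Returns text plus spans with
# offsets relative to the phrase start; the full phrase is always the
# outermost span.
build_entity_phrase <- function(spec) {
  w <- spec$type_weights[spec$type_weights > 0]
  depth <- 1L
  while (depth < spec$max_depth &&
         stats::runif(1) < spec$nesting_probability) {
    depth <- depth + 1L
  }
  ty <- sample_type(w)
  pool <- spec$vocabulary$pools[[ty]]
  words <- sample(pool, sample(1:2, 1L))
  text <- paste(words, collapse = " ")
  spans <- tibble::tibble(etype = ty, start = 0L, end = nchar(text))
  for (level in seq_len(depth - 1L)) {
    ty <- sample_type(w)
    pool <- spec$vocabulary$pools[[ty]]
    n_left <- sample(0:1, 1L)
    n_right <- if (n_left == 0L) sample(1:2, 1L) else sample(0:1, 1L)
    left <- if (n_left) sample(pool, n_left) else character()
    right <- if (n_right) sample(pool, n_right) else character()
    left_text <- paste(left, collapse = " ")
    shift <- if (n_left) nchar(left_text) + 1L else 0L
    text <- paste(c(left, text, right), collapse = " ")
    spans$start <- spans$start + shift
    spans$end <- spans$end + shift
    spans <- dplyr::bind_rows(
      tibble::tibble(etype = ty, start = 0L, end = nchar(text)), spans)
  }
  list(text = text, spans = spans)
}

build_sentence <- function(spec) {
  voc <- spec$vocabulary
  words <- sample(voc$starters, 1L)
  spans <- list()
  offset <- nchar(words)
  n_slots <- sample(2:5, 1L)
  for (s in seq_len(n_slots)) {
    if (stats::runif(1) < spec$entity_probability) {
      ph <- build_entity_phrase(spec)
      start <- offset + 1L  # +1 for the joining space
      ph$spans$start <- ph$spans$start + start
      ph$spans$end <- ph$spans$end + start
      spans[[length(spans) + 1L]] <- ph$spans
      words <- c(words, ph$text)
      offset <- start + nchar(ph$text)
    } else {
      wd <- sample(voc$filler, 1L)
      words <- c(words, wd)
      offset <- offset + 1L + nchar(wd)
    }
  }
  text <- paste0(paste(words, collapse = " "), ".")
  sp <- if (length(spans)) dplyr::bind_rows(spans) else
    tibble::tibble(etype = character(), start = integer(), end = integer())
  list(text = text, spans = sp)
}

#' Generate a synthetic annotated corpus
#'
#' Emits sentence-structured abstracts with nested entity annotations:
#' entities are type-specific vocabulary phrases placed at token
#' boundaries; a span is wrapped in a containing entity with probability
#' `nesting_probability` per level, up to `max_depth`. Empirical type
#' frequencies converge to the spec weights as counts grow, and generation
#' is byte-identical given the seed.
#'
#' @param spec A [corpus_spec()].
#' @return A list of `ner_document` objects.
#' @export
generate_corpus <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  rng <- spec$sentences_per_doc
  purrr::map(seq_len(spec$n_documents), function(d) {
    n_sent <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
    sents <- purrr::map(seq_len(n_sent), function(i) build_sentence(spec))
    text <- paste(purrr::map_chr(sents, "text"), collapse = " ")
    offsets <- cumsum(c(0L, utils::head(nchar(purrr::map_chr(sents, "text")) +
                                          1L, -1L)))
    spans <- dplyr::bind_rows(purrr::map2(sents, offsets, function(s, off) {
      s$spans$start <- s$spans$start + off
      s$spans$end <- s$spans$end + off
      s$spans
    }))
    if (nrow(spans) == 0) {
      spans <- empty_spans()
    } else {
      spans$id <- paste0("T", seq_len(nrow(spans)))
      spans$surface <- substring(text, spans$start + 1L, spans$end)
      spans <- spans[, c("id", "etype", "start", "end", "surface")]
    }
    structure(list(doc_id = sprintf("doc%04d", d), text = text,
                   spans = spans),
              class = "ner_document")
  })
}

#' Tally BIO tag frequencies over a corpus
#'
#' Segments, tokenizes and BIO-encodes every document, then counts each
#' `B-`/`I-` label per layer. The outside label `O` is excluded from the
#' tally, as it is not a target class.
#'
#' @param docs A list of `ner_document` objects (e.g. from
#'   [generate_corpus()]).
#' @param n_layers Number of BIO layers (default 6).
#' @return A tibble with columns `layer`, `label`, `n`, one row per
#'   observed non-`O` label per layer.
#' @export
tabulate_tags <- function(docs, n_layers = 6L) {
  encoded <- dplyr::bind_rows(purrr::map(docs, function(doc) {
    encode_sentences(segment_sentences(doc), n_layers = n_layers)
  }))
  rows <- purrr::map(encoded$tags, function(tg) {
    idx <- which(tg != "O", arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    tibble::tibble(layer = idx[, "row"], label = tg[idx])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(layer = integer(), label = character(),
                          n = integer()))
  }
  dplyr::count(out, .data$layer, .data$label, name = "n")
}
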