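# Multilayer nested-NER model: a contextual encoder backbone with six
# parallel per-token classification heads (17 labels each), masked
# cross-entropy loss summed over heads, Adam training, and span prediction.
#
# The backbone is pluggable through a registry. The bundled "tiny_conv"
# backbone is a compact trainable encoder (subword-piece embeddings plus
# windowed tanh convolution layers) so the full pipeline trains and tests
# on a single CPU with no external weights.

#' Model configuration
#'
#' Holds the architecture and optimization hyperparameters of the
#' multilayer model. Defaults follow the reference setting: batch size 64,
#' learning rate 1e-4, 40 epochs, maximum sequence length 512 subword
#' pieces, Adam optimizer, 6 heads over a 17-label space.
#'
#' @param backbone Name of a registered backbone (see
#'   [register_backbone()]); default `"tiny_conv"`.
#' @param n_heads Number of classification heads, one per nesting layer.
#' @param n_labels Output classes per head; must equal
#'   `2 * n_types + 1` for BIO over `n_types` entity types.
#' @param batch_size,learning_rate,epochs,max_sequence_length,optimizer
#'   Optimization hyperparameters.
#' @param hidden_size Encoder hidden width.
#' @param n_enc_layers Number of encoder layers.
#' @param window Half-width of the convolution context window per layer.
#' @param piece_len Maximum subword-piece length in characters.
#' @param seed Seed controlling parameter initialization and batching.
#' @return A `ner_config` list.
#' @export
ner_config <- function(backbone = "tiny_conv", n_heads = 6L, n_labels = 17L,
                       batch_size = 64L, learning_rate = 1e-4, epochs = 40L,
                       max_sequence_length = 512L, optimizer = "adam",
                       hidden_size = 32L, n_enc_layers = 2L, window = 2L,
                       piece_len = 6L, seed = 42L) {
  stopifnot(n_labels == 2L * length(entity_types()) + 1L)
  if (!identical(tolower(optimizer), "adam")) {
    stop("only the Adam optimizer is supported", call. = FALSE)
  }
  structure(list(backbone = backbone, n_heads = as.integer(n_heads),
                 n_labels = as.integer(n_labels),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 max_sequence_length = as.integer(max_sequence_length),
                 optimizer = "adam", hidden_size = as.integer(hidden_size),
                 n_enc_layers = as.integer(n_enc_layers),
                 window = as.integer(window),
                 piece_len = as.integer(piece_len), seed = as.integer(seed)),
            class = "ner_config")
}

# ---- backbone registry -----------------------------------------------------

backbone_registry <- new.env(parent = emptyenv())

#' Register an encoder backbone
#'
#' The multilayer model is backbone-agnostic: any encoder mapping a subword
#' piece sequence to per-piece hidden states can stand under the six heads.
#' A backbone is a list of three functions: `init(config, vocab_size)`
#' returning a named list of parameter matrices, `forward(params, ids,
#' config)` returning `list(H, cache)` with `H` an `L x hidden` matrix, and
#' `backward(params, cache, dH, config)` returning gradients shaped like
#' the parameters.
#'
#' @param name Backbone identifier used in [ner_config()].
#' @param backbone A list with elements `init`, `forward`, `backward`.
#' @return `name`, invisibly.
#' @export
register_backbone <- function(name, backbone) {
  stopifnot(is.list(backbone),
            all(c("init", "forward", "backward") %in% names(backbone)))
  assign(name, backbone, envir = backbone_registry)
  invisible(name)
}

get_backbone <- function(name) {
  if (!exists(name, envir = backbone_registry, inherits = FALSE)) {
    stop("unknown backbone '", name, "'; registered: ",
         paste(ls(backbone_registry), collapse = ", "), call. = FALSE)
  }
  get(name, envir = backbone_registry, inherits = FALSE)
}

# shift matrix rows by k, zero-padding: row i of result is row i+k of x
shift_rows <- function(x, k) {
  L <- nrow(x)
  out <- matrix(0, L, ncol(x))
  if (k >= 0) {
    if (L > k) out[seq_len(L - k), ] <- x[(k + 1):L, , drop = FALSE]
  } else {
    if (L > -k) out[(-k + 1):L, ] <- x[seq_len(L + k), , drop = FALSE]
  }
  out
}

tiny_conv_backbone <- function() {
  list(
    init = function(config, vocab_size) {
      h <- config$hidden_size
      w <- config$window
      params <- list(E = matrix(stats::runif(vocab_size * h, -0.5, 0.5) /
                                  sqrt(h), vocab_size, h))
      for (l in seq_len(config$n_enc_layers)) {
        fan_in <- (2L * w + 1L) * h
        params[[paste0("W", l)]] <-
          matrix(stats::runif(fan_in * h, -1, 1) * sqrt(6 / (fan_in + h)),
                 fan_in, h)
        params[[paste0("b", l)]] <- matrix(0, 1, h)
      }
      params
    },
    forward = function(params, ids, config) {
      w <- config$window
      X <- params$E[ids, , drop = FALSE]
      cache <- list(ids = ids, X = list(X))
      A <- X
      for (l in seq_len(config$n_enc_layers)) {
        Xcat <- do.call(cbind, lapply(seq(-w, w), function(k) shift_rows(A, k)))
        Z <- Xcat %*% params[[paste0("W", l)]]
        Z <- sweep(Z, 2, params[[paste0("b", l)]], "+")
        Tl <- tanh(Z)
        A <- Tl + A  # residual connection keeps word identity available
        cache$Xcat[[l]] <- Xcat
        cache$T[[l]] <- Tl
      }
      list(H = A, cache = cache)
    },
    backward = function(params, cache, dH, config) {
      w <- config$window
      h <- config$hidden_size
      grads <- list()
      dA <- dH
      for (l in rev(seq_len(config$n_enc_layers))) {
        Tl <- cache$T[[l]]
        dZ <- dA * (1 - Tl * Tl)
        grads[[paste0("W", l)]] <- crossprod(cache$Xcat[[l]], dZ)
        grads[[paste0("b", l)]] <- matrix(colSums(dZ), 1, h)
        dXcat <- dZ %*% t(params[[paste0("W", l)]])
        dprev <- dA  # residual path
        for (j in seq_along(seq(-w, w))) {
          k <- seq(-w, w)[j]
          block <- dXcat[, ((j - 1L) * h + 1L):(j * h), drop = FALSE]
          dprev <- dprev + shift_rows(block, -k)
        }
        dA <- dprev
      }
      dE <- matrix(0, nrow(params$E), h)
      for (i in seq_along(cache$ids)) {
        dE[cache$ids[i], ] <- dE[cache$ids[i], ] + dA[i, ]
      }
      grads$E <- dE
      grads
    }
  )
}

register_backbone("tiny_conv", tiny_conv_backbone())

# ---- subword pieces and vocabulary -----------------------------------------

split_pieces <- function(word, piece_len) {
  n <- nchar(word)
  if (n <= piece_len) return(word)
  starts <- seq(1L, n, by = piece_len)
  substring(word, starts, pmin(starts + piece_len - 1L, n))
}

#' Build a subword-piece vocabulary from an encoded corpus
#'
#' Word tokens are split into fixed-length character chunks (subword
#' pieces); the vocabulary is the set of pieces seen in training plus an
#' unknown-piece entry.
#'
#' @param encoded A tibble from [encode_sentences()] (uses the `tokens`
#'   list-column).
#' @param piece_len Maximum piece length in characters.
#' @return A `ner_vocab`: named integer vector mapping piece to id, with
#'   the piece length as an attribute.
#' @export
build_vocab <- function(encoded, piece_len = 6L) {
  words <- unlist(purrr::map(encoded$tokens, "text"))
  pieces <- unique(unlist(lapply(tolower(words), split_pieces, piece_len)))
  v <- seq_along(pieces) + 1L
  names(v) <- pieces
  v <- c("<unk>" = 1L, v)
  structure(v, piece_len = as.integer(piece_len), class = "ner_vocab")
}

# Map word tokens to piece ids plus the first-subword alignment: every word
# maps to >= 1 contiguous pieces and exactly one supervised piece (the
# first), the standard token-classification convention.
align_subtokens <- function(words, vocab) {
  plen <- attr(vocab, "piece_len")
  ids <- integer(0)
  first <- integer(length(words))
  for (i in seq_along(words)) {
    p <- split_pieces(tolower(words[i]), plen)
    pid <- unname(vocab[p])
    pid[is.na(pid)] <- 1L
    first[i] <- length(ids) + 1L
    ids <- c(ids, pid)
  }
  mask <- rep(FALSE, length(ids))
  mask[first] <- TRUE
  list(ids = ids, first_piece = first, mask = mask)
}

# ---- model construction ----------------------------------------------------

#' Build a multilayer nested-NER model
#'
#' Instantiates the configured backbone and stacks `n_heads` parallel
#' linear classification heads on its hidden states, one head per nesting
#' layer, each predicting over the 17-label BIO space. Initialization is
#' fully determined by `config$seed`.
#'
#' @param config A [ner_config()].
#' @param vocab A [build_vocab()] vocabulary.
#' @return A `multilayer_ner_model` (untrained).
#' @export
build_model <- function(config, vocab) {
  bb <- get_backbone(config$backbone)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- list(backbone = bb$init(config, length(vocab)))
  h <- config$hidden_size
  params$heads <- lapply(seq_len(config$n_heads), function(k) {
    list(W = matrix(stats::runif(h * config$n_labels, -1, 1) *
                      sqrt(6 / (h + config$n_labels)), h, config$n_labels),
         b = matrix(0, 1, config$n_labels))
  })
  structure(list(config = config, vocab = vocab, params = params,
                 history = NULL, trained = FALSE),
            class = "multilayer_ner_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.multilayer_ner_model <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, identity, how = "unlist"), length,
                   integer(1)))
  cat("<multilayer_ner_model> backbone:", x$config$backbone,
      "| heads:", x$config$n_heads, "x", x$config$n_labels,
      "labels |", if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

model_forward <- function(model, ids) {
  bb <- get_backbone(model$config$backbone)
  fw <- bb$forward(model$params$backbone, ids, model$config)
  logits <- lapply(model$params$heads, function(hd) {
    sweep(fw$H %*% hd$W, 2, hd$b, "+")
  })
  list(H = fw$H, logits = logits, cache = fw$cache)
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Multi-head masked cross-entropy loss
#'
#' The training objective: the unweighted sum over heads of the mean
#' cross-entropy at supervised subword positions. Positions outside the
#' supervision mask contribute nothing; with an all-masked input the loss
#' is defined as zero (with a warning).
#'
#' @param logits A list of `n_heads` matrices, each `L x n_labels`.
#' @param gold An `n_heads x L` integer matrix of gold label indices into
#'   [bio_labels()]; entries at unsupervised positions are ignored.
#' @param mask Logical vector of length `L` marking supervised positions.
#' @return A non-negative scalar.
#' @export
compute_loss <- function(logits, gold, mask) {
  stopifnot(length(logits) == nrow(gold), ncol(gold) == length(mask),
            nrow(logits[[1]]) == length(mask))
  pos <- which(mask)
  if (!length(pos)) {
    warning("all positions masked; loss defined as zero", call. = FALSE)
    return(0)
  }
  total <- 0
  for (h in seq_along(logits)) {
    p <- softmax_rows(logits[[h]][pos, , drop = FALSE])
    idx <- cbind(seq_along(pos), gold[h, pos])
    total <- total + mean(-log(pmax(p[idx], 1e-300)))
  }
  total
}

# loss + gradients for one prepared example
example_grad <- function(model, ex) {
  fw <- model_forward(model, ex$ids)
  pos <- which(ex$mask)
  L <- length(ex$ids)
  n_sup <- length(pos)
  loss <- 0
  dH <- matrix(0, L, model$config$hidden_size)
  head_grads <- vector("list", model$config$n_heads)
  for (h in seq_len(model$config$n_heads)) {
    logit <- fw$logits[[h]]
    p <- softmax_rows(logit[pos, , drop = FALSE])
    idx <- cbind(seq_along(pos), ex$gold[h, pos])
    loss <- loss + mean(-log(pmax(p[idx], 1e-300)))
    dlog <- p
    dlog[idx] <- dlog[idx] - 1
    dlog <- dlog / n_sup
    dfull <- matrix(0, L, model$config$n_labels)
    dfull[pos, ] <- dlog
    hd <- model$params$heads[[h]]
    head_grads[[h]] <- list(W = crossprod(fw$H, dfull),
                            b = matrix(colSums(dfull), 1))
    dH <- dH + dfull %*% t(hd$W)
  }
  bb <- get_backbone(model$config$backbone)
  bb_grads <- bb$backward(model$params$backbone, fw$cache, dH, model$config)
  list(loss = loss, grads = list(backbone = bb_grads, heads = head_grads))
}

# ---- Adam ------------------------------------------------------------------

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    full <- paste0(prefix, nm)
    if (is.list(p[[nm]])) {
      out <- c(out, flatten_params(p[[nm]], paste0(full, ".")))
    } else {
      out[[full]] <- p[[nm]]
    }
  }
  out
}

# lists of heads are unnamed; give them stable names first
name_tree <- function(p) {
  if (is.list(p) && is.null(names(p))) names(p) <- paste0("i", seq_along(p))
  if (is.list(p)) p <- lapply(p, name_tree)
  p
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0), v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

unflatten_params <- function(flat, template, prefix = "") {
  for (nm in names(template)) {
    full <- paste0(prefix, nm)
    if (is.list(template[[nm]])) {
      template[[nm]] <- unflatten_params(flat, template[[nm]],
                                         paste0(full, "."))
    } else {
      template[[nm]] <- flat[[full]]
    }
  }
  template
}

# ---- training --------------------------------------------------------------

prepare_example <- function(tokens, tags, vocab, config) {
  al <- align_subtokens(tokens$text, vocab)
  labels <- bio_labels()
  truncated <- FALSE
  if (length(al$ids) > config$max_sequence_length) {
    keep_words <- which(al$first_piece <= config$max_sequence_length)
    al$ids <- al$ids[seq_len(config$max_sequence_length)]
    al$mask <- al$mask[seq_len(config$max_sequence_length)]
    al$first_piece <- al$first_piece[keep_words]
    tags <- tags[, keep_words, drop = FALSE]
    truncated <- TRUE
  }
  gold <- matrix(1L, config$n_heads, length(al$ids))
  for (h in seq_len(min(config$n_heads, nrow(tags)))) {
    gold[h, al$first_piece] <- match(tags[h, ], labels)
  }
  list(ids = al$ids, mask = al$mask, first_piece = al$first_piece,
       gold = gold, truncated = truncated)
}

#' Train the multilayer model
#'
#' Runs minibatch Adam on the summed per-head masked cross-entropy over a
#' BIO-encoded sentence corpus, logging per-epoch training (and optional
#' validation) loss. Training is deterministic given the configuration
#' seed. Sentences longer than `max_sequence_length` subword pieces are
#' truncated with a counted warning.
#'
#' @param model An untrained (or previously trained) model from
#'   [build_model()].
#' @param train_data A tibble from [encode_sentences()] with `tokens` and
#'   `tags` list-columns.
#' @param val_data Optional held-out tibble of the same shape.
#' @param epochs,learning_rate,batch_size Optional overrides of the model
#'   configuration.
#' @param verbose Print per-epoch losses.
#' @return The model with updated parameters, `trained = TRUE`, and a
#'   `history` tibble (`epoch`, `train_loss`, `val_loss`).
#' @export
train_ner <- function(model, train_data, val_data = NULL, epochs = NULL,
                      learning_rate = NULL, batch_size = NULL,
                      verbose = FALSE) {
  if (nrow(train_data) == 0) stop("empty training set", call. = FALSE)
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  lr <- learning_rate %||% cfg$learning_rate
  bs <- batch_size %||% cfg$batch_size

  prep <- function(dat) purrr::map2(dat$tokens, dat$tags, prepare_example,
                                    vocab = model$vocab, config = cfg)
  train_ex <- prep(train_data)
  n_trunc <- sum(purrr::map_lgl(train_ex, "truncated"))
  if (n_trunc > 0) {
    warning(n_trunc, " sentence(s) truncated to max_sequence_length",
            call. = FALSE)
  }
  val_ex <- if (!is.null(val_data)) prep(val_data)

  params <- name_tree(model$params)
  flat <- flatten_params(params)
  state <- adam_init(flat)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)

  history <- vector("list", epochs)
  n <- length(train_ex)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    ep_loss <- 0
    for (batch in batches) {
      acc <- NULL
      bloss <- 0
      model$params <- unflatten_params(flat, params)
      for (i in batch) {
        eg <- example_grad(model, train_ex[[i]])
        g <- flatten_params(name_tree(eg$grads))
        if (is.null(acc)) {
          acc <- g
        } else {
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g[[nm]]
        }
        bloss <- bloss + eg$loss
      }
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(batch)
      upd <- adam_step(flat, acc, state, lr)
      flat <- upd$flat
      state <- upd$state
      ep_loss <- ep_loss + bloss
    }
    model$params <- unflatten_params(flat, params)
    vloss <- if (!is.null(val_ex)) {
      mean(purrr::map_dbl(val_ex, function(ex) {
        fw <- model_forward(model, ex$ids)
        compute_loss(fw$logits, ex$gold, ex$mask)
      }))
    } else NA_real_
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / n,
                                    val_loss = vloss)
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %s", ep, ep_loss / n,
                      ifelse(is.na(vloss), "-", sprintf("%.4f", vloss))))
    }
  }
  model$history <- dplyr::bind_rows(history)
  model$trained <- TRUE
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- prediction ------------------------------------------------------------

#' Predict nested entity spans for a sentence
#'
#' Tokenizes, subword-encodes, takes the per-head argmax at supervised
#' positions, decodes the six BIO sequences (with conservative repair) and
#' returns the deduplicated span union in sentence-local coordinates.
#'
#' @param model A trained `multilayer_ner_model`.
#' @param text Sentence text.
#' @return A span tibble.
#' @export
predict_spans <- function(model, text) {
  tokens <- tokenize_sentence(text)
  if (nrow(tokens) == 0) return(empty_spans())
  al <- align_subtokens(tokens$text, model$vocab)
  n_words <- length(al$first_piece)
  if (length(al$ids) > model$config$max_sequence_length) {
    keep <- which(al$first_piece <= model$config$max_sequence_length)
    al$ids <- al$ids[seq_len(model$config$max_sequence_length)]
    al$first_piece <- al$first_piece[keep]
    n_words <- length(keep)
    warning("sentence truncated to max_sequence_length", call. = FALSE)
  }
  fw <- model_forward(model, al$ids)
  labels <- bio_labels()
  tags <- matrix("O", model$config$n_heads, n_words)
  for (h in seq_len(model$config$n_heads)) {
    pred <- max.col(fw$logits[[h]][al$first_piece, , drop = FALSE],
                    ties.method = "first")
    tags[h, ] <- labels[pred]
  }
  decode_bio(tokens[seq_len(n_words), , drop = FALSE], tags, text = text)
}

#' Predict spans for every sentence of a corpus tibble
#'
#' @param model A trained model.
#' @param sentences A sentence tibble (needs `text`).
#' @return The tibble with a `pred_spans` list-column added.
#' @export
predict_sentences <- function(model, sentences) {
  sentences$pred_spans <- purrr::map(sentences$text,
                                     function(tx) predict_spans(model, tx))
  sentences
}

# ---- broom-style methods ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted model
#'
#' @param x A `multilayer_ner_model`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.multilayer_ner_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), train_loss = double(),
                          val_loss = double()))
  }
  x$history
}

#' One-row summary of a fitted model
#'
#' @param x A `multilayer_ner_model`.
#' @param ... Unused.
#' @return A one-row tibble: backbone, head/label counts, parameter count,
#'   epochs trained and final losses.
#' @export
glance.multilayer_ner_model <- function(x, ...) {
  flat <- flatten_params(name_tree(x$params))
  tibble::tibble(
    backbone = x$config$backbone,
    n_heads = x$config$n_heads,
    n_labels = x$config$n_labels,
    n_parameters = sum(vapply(flat, length, integer(1))),
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_train_loss = if (is.null(x$history)) NA_real_ else
      utils::tail(x$history$train_loss, 1),
    final_val_loss = if (is.null(x$history)) NA_real_ else
      utils::tail(x$history$val_loss, 1)
  )
}

# ---- checkpointing ---------------------------------------------------------

#' Save a model as plain-text JSON checkpoints
#'
#' Writes the configuration, vocabulary and all parameter matrices to a
#' directory as JSON — a text-only checkpoint layout.
#'
#' @param model A `multilayer_ner_model`.
#' @param dir Checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(model$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(list(pieces = names(model$vocab),
                            ids = unname(unclass(model$vocab)),
                            piece_len = attr(model$vocab, "piece_len")),
                       file.path(dir, "vocab.json"), digits = NA)
  flat <- flatten_params(name_tree(model$params))
  jsonlite::write_json(lapply(flat, function(m) {
    list(dim = dim(m), data = as.vector(m))
  }), file.path(dir, "params.json"), digits = NA)
  jsonlite::write_json(list(trained = model$trained,
                            history = model$history),
                       file.path(dir, "state.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a model from a JSON checkpoint directory
#'
#' @param dir Directory written by [save_model()].
#' @return A `multilayer_ner_model`.
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- do.call(ner_config, cfg[setdiff(names(cfg), character())])
  vj <- jsonlite::read_json(file.path(dir, "vocab.json"),
                            simplifyVector = TRUE)
  vocab <- structure(as.integer(vj$ids), names = vj$pieces,
                     piece_len = as.integer(vj$piece_len),
                     class = "ner_vocab")
  model <- build_model(config, vocab)
  pj <- jsonlite::read_json(file.path(dir, "params.json"),
                            simplifyVector = TRUE)
  flat <- lapply(pj, function(p) matrix(p$data, p$dim[1], p$dim[2]))
  model$params <- unflatten_params(flat, name_tree(model$params))
  st <- jsonlite::read_json(file.path(dir, "state.json"),
                            simplifyVector = TRUE)
  model$trained <- isTRUE(st$trained)
  if (!is.null(st$history) && length(st$history)) {
    hist <- tibble::as_tibble(st$history)
    # an all-NA validation column serializes to JSON nulls and is dropped
    if (!"val_loss" %in% names(hist)) hist$val_loss <- NA_real_
    model$history <- hist[, c("epoch", "train_loss", "val_loss")]
  }
  model
}
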