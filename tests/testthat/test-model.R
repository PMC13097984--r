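tiny_cfg <- function(seed = 3, ...) {
  ner_config(seed = seed, hidden_size = 16, n_enc_layers = 2, window = 2,
             batch_size = 8, learning_rate = 0.02, ...)
}

test_that("the model maps L subwords to six 17-label logit grids", {
  enc <- make_encoded_corpus(n_documents = 2, seed = 41)
  cfg <- tiny_cfg()
  model <- build_model(cfg, build_vocab(enc, cfg$piece_len))
  ids <- rep_len(seq_along(model$vocab), 10)
  fw <- nestedner:::model_forward(model, ids)
  expect_length(fw$logits, 6L)
  for (lg in fw$logits) expect_equal(dim(lg), c(10L, 17L))
  expect_length(model$params$heads, 6L)
})

test_that("identical seeds give bitwise-identical initial parameters", {
  enc <- make_encoded_corpus(n_documents = 2, seed = 41)
  cfg <- tiny_cfg(seed = 123)
  vocab <- build_vocab(enc, cfg$piece_len)
  m1 <- build_model(cfg, vocab)
  m2 <- build_model(cfg, vocab)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_cfg(seed = 124), vocab)
  expect_false(identical(m1$params$backbone$E, m3$params$backbone$E))
})

test_that("unknown backbones are rejected and custom ones accepted", {
  enc <- make_encoded_corpus(n_documents = 1, seed = 2)
  cfg <- ner_config(backbone = "no_such_model")
  expect_error(build_model(cfg, build_vocab(enc, cfg$piece_len)),
               "unknown backbone")
})

test_that("the loss has its closed-form values at the limits", {
  L <- 5L
  gold <- matrix(sample.int(17, 6 * L, replace = TRUE), 6, L)
  mask <- rep(TRUE, L)

  # probability ~1 on every gold label -> loss ~0
  sharp <- lapply(1:6, function(h) {
    lg <- matrix(-50, L, 17)
    lg[cbind(seq_len(L), gold[h, ])] <- 50
    lg
  })
  expect_lt(compute_loss(sharp, gold, mask), 1e-6)

  # uniform logits: per-position cross-entropy log(17), summed over heads
  unif <- lapply(1:6, function(h) matrix(0, L, 17))
  expect_equal(compute_loss(unif, gold, mask), 6 * log(17),
               tolerance = 1e-10)

  # all-masked input is defined as zero with a warning
  expect_warning(z <- compute_loss(unif, gold, rep(FALSE, L)), "masked")
  expect_equal(z, 0)
})

test_that("the loss decomposes into the sum of single-head losses", {
  set.seed(8)
  L <- 7L
  gold <- matrix(sample.int(17, 6 * L, replace = TRUE), 6, L)
  mask <- sample(c(TRUE, FALSE), L, replace = TRUE, prob = c(0.7, 0.3))
  mask[1] <- TRUE
  logits <- lapply(1:6, function(h) matrix(rnorm(L * 17), L, 17))
  total <- compute_loss(logits, gold, mask)
  parts <- vapply(1:6, function(h) {
    compute_loss(logits[h], gold[h, , drop = FALSE], mask)
  }, double(1))
  expect_equal(total, sum(parts), tolerance = 1e-12)

  # masking a position changes the loss iff its gold/logits matter
  mask2 <- mask
  on <- which(mask)
  mask2[on[1]] <- FALSE
  expect_false(isTRUE(all.equal(compute_loss(logits, gold, mask2), total)))
})

test_that("analytic gradients match finite differences", {
  enc <- make_encoded_corpus(n_documents = 1, seed = 6)
  cfg <- tiny_cfg(seed = 5)
  model <- build_model(cfg, build_vocab(enc, cfg$piece_len))
  ex <- nestedner:::prepare_example(enc$tokens[[1]], enc$tags[[1]],
                                    model$vocab, cfg)
  eg <- nestedner:::example_grad(model, ex)
  loss_at <- function(m) {
    fw <- nestedner:::model_forward(m, ex$ids)
    compute_loss(fw$logits, ex$gold, ex$mask)
  }
  eps <- 1e-5
  set.seed(1)
  # a few entries in each parameter class
  probes <- list(
    list(get = function(m) m$params$backbone$E,
         set = function(m, v) { m$params$backbone$E <- v; m },
         grad = eg$grads$backbone$E),
    list(get = function(m) m$params$backbone$W1,
         set = function(m, v) { m$params$backbone$W1 <- v; m },
         grad = eg$grads$backbone$W1),
    list(get = function(m) m$params$heads[[4]]$W,
         set = function(m, v) { m$params$heads[[4]]$W <- v; m },
         grad = eg$grads$heads[[4]]$W)
  )
  for (pr in probes) {
    mat <- pr$get(model)
    for (k in 1:4) {
      i <- sample.int(nrow(mat), 1); j <- sample.int(ncol(mat), 1)
      up <- mat; up[i, j] <- up[i, j] + eps
      dn <- mat; dn[i, j] <- dn[i, j] - eps
      fd <- (loss_at(pr$set(model, up)) - loss_at(pr$set(model, dn))) /
        (2 * eps)
      expect_equal(pr$grad[i, j], fd, tolerance = 1e-4)
    }
  }
})

test_that("each head controls exactly its own layer's tags", {
  enc <- make_encoded_corpus(n_documents = 2, seed = 19)
  cfg <- tiny_cfg(seed = 2)
  model <- build_model(cfg, build_vocab(enc, cfg$piece_len))
  al <- nestedner:::align_subtokens(enc$tokens[[1]]$text, model$vocab)
  layer_tags <- function(m) {
    fw <- nestedner:::model_forward(m, al$ids)
    t(vapply(fw$logits, function(lg) {
      bio_labels()[max.col(lg[al$first_piece, , drop = FALSE],
                           ties.method = "first")]
    }, character(length(al$first_piece))))
  }
  base <- layer_tags(model)
  pert <- model
  set.seed(30)
  pert$params$heads[[3]]$W <- pert$params$heads[[3]]$W +
    matrix(rnorm(length(pert$params$heads[[3]]$W), sd = 5),
           nrow(pert$params$heads[[3]]$W))
  after <- layer_tags(pert)
  expect_false(identical(base[3, ], after[3, ]))
  expect_identical(base[-3, ], after[-3, ])
})

test_that("training descends, is seed-deterministic, and rejects empty input", {
  enc <- make_encoded_corpus(n_documents = 2, seed = 55)
  cfg <- tiny_cfg(seed = 9)
  vocab <- build_vocab(enc, cfg$piece_len)
  m1 <- train_ner(build_model(cfg, vocab), enc, epochs = 15)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- train_ner(build_model(cfg, vocab), enc, epochs = 15)
  expect_identical(m1$history, m2$history)
  expect_error(train_ner(build_model(cfg, vocab), enc[0, ]), "empty")
})

test_that("prediction handles empty text, trailing padding, and truncation", {
  enc <- make_encoded_corpus(n_documents = 2, seed = 71)
  cfg <- tiny_cfg(seed = 4)
  model <- train_ner(build_model(cfg, build_vocab(enc, cfg$piece_len)),
                     enc, epochs = 30)
  expect_equal(nrow(predict_spans(model, "")), 0L)

  txt <- enc$text[1]
  base <- predict_spans(model, txt)
  padded <- predict_spans(model, paste0(txt, "   "))
  expect_equal(span_keys(padded), span_keys(base))

  short <- model
  short$config$max_sequence_length <- 4L
  expect_warning(tr <- predict_spans(short, txt), "truncated")
  expect_true(all(tr$end <= short$config$max_sequence_length * 50))
})

test_that("checkpoints round-trip through the JSON layout", {
  enc <- make_encoded_corpus(n_documents = 2, seed = 91)
  cfg <- tiny_cfg(seed = 12)
  model <- train_ner(build_model(cfg, build_vocab(enc, cfg$piece_len)),
                     enc, epochs = 10)
  dir <- withr::local_tempdir()
  save_model(model, dir)
  back <- load_model(dir)
  for (tx in enc$text[1:3]) {
    expect_equal(predict_spans(back, tx), predict_spans(model, tx))
  }
  expect_equal(nrow(tidy(back)), 10L)
  expect_equal(glance(back)$n_parameters, glance(model)$n_parameters)
})

test_that("the 80:20 sentence split is exact, disjoint and seed-deterministic", {
  sentences <- tibble::tibble(doc_id = rep("d", 100),
                              sent_index = 1:100,
                              text = paste("sentence", 1:100))
  s1 <- split_sentences(sentences, prop = 0.8, seed = 42)
  expect_equal(sum(s1$split == "train"), 80L)
  expect_equal(sum(s1$split == "dev"), 20L)
  s2 <- split_sentences(sentences, prop = 0.8, seed = 42)
  expect_identical(s1$split, s2$split)
  s3 <- split_sentences(sentences, prop = 0.8, seed = 43)
  expect_false(identical(s1$split, s3$split))
})
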