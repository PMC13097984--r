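test_that("tokenizer splits on whitespace and punctuation with offsets", {
  tok <- tokenize_sentence("serum level.")
  expect_equal(tok$text, c("serum", "level", "."))
  expect_equal(tok$start, c(0L, 6L, 11L))
  expect_equal(tok$end, c(5L, 11L, 12L))

  expect_equal(nrow(tokenize_sentence("")), 0L)

  tok2 <- tokenize_sentence("interleukin-2")
  expect_equal(tok2$text, c("interleukin", "-", "2"))
  expect_equal(tok2$start, c(0L, 11L, 12L))

  # concatenating token slices recovers the non-whitespace text
  txt <- "Decrease in serum level of soluble interleukin-2 receptor."
  tok3 <- tokenize_sentence(txt)
  expect_equal(paste(tok3$text, collapse = ""), gsub("\\s", "", txt))
})

test_that("layer assignment is outermost-first, deterministic, and errors at capacity", {
  # disjoint spans all land in layer 1
  sp <- entity_spans(c("DISO", "CHEM"), c(0, 10), c(5, 15))
  la <- assign_layers(sp)
  expect_equal(sort(unique(la$layer)), 1L)

  # hand-executed sort-and-place: outer FINDING first, nested ANATOMY and
  # CHEM both fit in layer 2
  sp2 <- entity_spans(c("FINDING", "ANATOMY", "CHEM"),
                      c(0, 12, 26), c(46, 17, 37))
  la2 <- assign_layers(sp2)
  expect_equal(la2$layer[la2$etype == "FINDING"], 1L)
  expect_equal(la2$layer[la2$etype == "ANATOMY"], 2L)
  expect_equal(la2$layer[la2$etype == "CHEM"], 2L)

  # seven pairwise-nested spans cannot fit six layers
  sp3 <- entity_spans(rep("DISO", 7), 0:6, 14:8)
  expect_error(assign_layers(sp3), "more than 6 layers")
  expect_warning(la3 <- assign_layers(sp3, lenient = TRUE), "dropped")
  expect_equal(nrow(la3), 6L)

  # determinism: shuffled input yields the same assignment
  set.seed(9)
  sp4 <- sp2[sample.int(3), ]
  expect_equal(assign_layers(sp4), la2)
})

test_that("BIO encoding emits six layers with B/I/O semantics", {
  tok <- tokenize_sentence("serum level")
  one <- assign_layers(entity_spans("ANATOMY", 0, 5))
  tags <- encode_bio(tok, one)
  expect_equal(dim(tags), c(6L, 2L))
  expect_equal(tags[1, ], c("B-ANATOMY", "O"))
  expect_true(all(tags[2:6, ] == "O"))

  both <- assign_layers(entity_spans("PHYS", 0, 11))
  expect_equal(encode_bio(tok, both)[1, ], c("B-PHYS", "I-PHYS"))

  none <- encode_bio(tok, assign_layers(entity_spans()))
  expect_true(all(none == "O"))
})

test_that("span boundaries inside tokens snap outward with a warning", {
  tok <- tokenize_sentence("serum level")
  mid <- assign_layers(entity_spans("ANATOMY", 2, 8))
  expect_warning(tags <- encode_bio(tok, mid), "snapped")
  expect_equal(tags[1, ], c("B-ANATOMY", "I-ANATOMY"))
})

test_that("decoding inverts encoding and repairs illegal sequences", {
  tok <- tokenize_sentence("low serum level")
  tags <- matrix("O", 6, 3)
  tags[1, ] <- c("B-DISO", "I-DISO", "O")
  dec <- decode_bio(tok, tags)
  expect_equal(dec$etype, "DISO")
  expect_equal(dec$start, 0L)
  expect_equal(dec$end, 9L)

  # I after O is promoted to B (conservative repair)
  bad <- matrix("O", 6, 3)
  bad[1, ] <- c("O", "I-CHEM", "O")
  dec2 <- decode_bio(tok, bad)
  expect_equal(dec2$etype, "CHEM")
  expect_equal(dec2$start, 4L)
  expect_equal(dec2$end, 9L)

  # I with a type switch starts a new span
  sw <- matrix("O", 6, 3)
  sw[1, ] <- c("B-DISO", "I-CHEM", "I-CHEM")
  dec3 <- decode_bio(tok, sw)
  expect_equal(span_keys(dec3), span_keys(tibble::tibble(
    etype = c("DISO", "CHEM"), start = c(0L, 4L), end = c(3L, 15L))))
})

test_that("every emitted tag is one of the 17 labels and layer 1 is complete for flat spans", {
  spec <- corpus_spec(n_documents = 10, seed = 31, nesting_probability = 0)
  docs <- generate_corpus(spec)
  for (doc in docs[1:5]) {
    enc <- encode_sentences(segment_sentences(doc))
    for (i in seq_len(nrow(enc))) {
      tg <- enc$tags[[i]]
      expect_true(all(tg %in% bio_labels()))
      expect_true(all(tg[2:6, ] == "O"))  # flat corpus: layers 2-6 empty
      n_b <- sum(startsWith(tg[1, ], "B-"))
      expect_equal(n_b, nrow(enc$spans[[i]]))
    }
  }
})

test_that("codec round trip recovers the exact span multiset on nested corpora", {
  spec <- corpus_spec(n_documents = 30, seed = 77)
  docs <- generate_corpus(spec)
  n_checked <- 0L
  for (doc in docs) {
    enc <- encode_sentences(segment_sentences(doc))
    for (i in seq_len(nrow(enc))) {
      dec <- decode_bio(enc$tokens[[i]], enc$tags[[i]], text = enc$text[i])
      expect_equal(span_keys(dec), span_keys(enc$spans[[i]]))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 50L)
})

test_that("tagged sentences round-trip through JSON Lines and the vertical dump aligns", {
  enc <- make_encoded_corpus(n_documents = 2, seed = 13)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_tagged_jsonl(enc, path)
  back <- read_tagged_jsonl(path)
  expect_equal(nrow(back), nrow(enc))
  for (i in seq_len(nrow(enc))) {
    expect_equal(back$tags[[i]], enc$tags[[i]])
    expect_equal(back$tokens[[i]]$start, enc$tokens[[i]]$start)
  }
  tab <- tagged_sentence_table(enc$tokens[[1]], enc$tags[[1]])
  expect_equal(names(tab), c("token", paste0("layer", 1:6)))
  expect_equal(tab$layer1, unname(enc$tags[[1]][1, ]))
})
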