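mini_map <- function() {
  concept_map(c("ANATOMY", "DISO"), c("C1268086", "C0677042"))
}

rrf_row <- function(cui, str, lat = "ENG") {
  # 18-column MRCONSO layout; only CUI, LAT and STR matter here
  f <- rep("", 18)
  f[1] <- cui; f[2] <- lat; f[15] <- str
  paste(f, collapse = "|")
}

test_that("concept maps validate CUI pattern and entity types", {
  expect_s3_class(mini_map(), "concept_map")
  expect_error(concept_map("ANATOMY", "X123"), "invalid concept id")
  expect_error(concept_map("TISSUE", "C1"), "unknown entity type")
})

test_that("MRCONSO parsing filters by concept, language and well-formedness", {
  rrf <- paste(rrf_row("C1268086", "Body structure"),
               rrf_row("C1268086", "serum"),
               rrf_row("C1268086", "Struktur", lat = "GER"),
               rrf_row("C0999999", "unrelated term"),
               "C1268086|ENG|broken",
               sep = "\n")
  expect_warning(
    expect_warning(dict <- parse_mrconso(rrf, mini_map()), "malformed"),
    "empty dictionary")
  expect_setequal(dict$ANATOMY, c("body structure", "serum"))
  expect_length(dict$DISO, 0L)

  expect_warning(empty <- parse_mrconso("", mini_map()),
                 "empty dictionary")
  expect_true(all(vapply(empty, length, integer(1)) == 0L))
  expect_equal(nrow(attr(empty, "counts")), 8L)
})

test_that("descendant terms are included iff relations are supplied", {
  rrf <- paste(rrf_row("C0677042", "pathologic process"),
               rrf_row("C0011111", "nephritis"),
               rrf_row("C0022222", "lupus nephritis"),
               sep = "\n")
  rels <- "C0677042|C0011111\nC0011111|C0022222"
  suppressWarnings({
    without <- parse_mrconso(rrf, mini_map())
    with_rel <- parse_mrconso(rrf, mini_map(), rels)
  })
  expect_equal(without$DISO, "pathologic process")
  # transitive closure reaches the grandchild concept
  expect_setequal(with_rel$DISO,
                  c("pathologic process", "nephritis", "lupus nephritis"))
})

test_that("dictionaries round-trip through per-type term files", {
  rrf <- paste(rrf_row("C1268086", "Serum  Level"),
               rrf_row("C1268086", "liver"), sep = "\n")
  suppressWarnings(dict <- parse_mrconso(rrf, mini_map()))
  expect_true("serum level" %in% dict$ANATOMY)  # normalized
  dir <- withr::local_tempdir()
  write_dictionary(dict, dir)
  back <- read_dictionary(dir)
  expect_equal(back$ANATOMY, dict$ANATOMY)
})

test_that("term matching is case-insensitive, word-bounded and longest-first", {
  dict <- structure(list(ANATOMY = c("serum", "serum levels"),
                         CHEM = c("insulin")),
                    class = "typed_dictionary")
  m1 <- match_terms("Serum levels rose.", dict)
  # longest match wins within a type
  expect_equal(m1$etype, "ANATOMY")
  expect_equal(m1$start, 0L)
  expect_equal(m1$end, 12L)

  expect_equal(nrow(match_terms("biserum rose", dict)), 0L)
  expect_equal(nrow(match_terms("serums rose", dict)), 0L)

  # matches below the length threshold are dropped
  short <- structure(list(CHEM = "il"), class = "typed_dictionary")
  expect_equal(nrow(match_terms("il rose", short)), 0L)
  expect_equal(nrow(match_terms("il rose", short, min_chars = 2)), 1L)

  # different types may overlap (nesting)
  both <- structure(list(ANATOMY = "serum insulin", CHEM = "insulin"),
                    class = "typed_dictionary")
  m2 <- match_terms("high serum insulin today", both)
  expect_equal(nrow(m2), 2L)

  # insertion order of terms does not matter
  rev_dict <- structure(list(ANATOMY = rev(dict$ANATOMY),
                             CHEM = dict$CHEM),
                        class = "typed_dictionary")
  expect_equal(match_terms("Serum levels rose.", rev_dict), m1)
})

test_that("matching equals the brute-force all-substrings oracle", {
  set.seed(202)
  words <- c("serum", "liver", "insulin", "glucose", "edema", "rose",
             "with", "acute", "renal", "level", "levels", "se")
  for (rep in 1:100) {
    text <- paste(sample(words, sample(3:12, 1), replace = TRUE),
                  collapse = " ")
    terms <- unique(c(
      sample(words, sample(1:6, 1)),
      replicate(3, paste(sample(words, 2), collapse = " "))))
    dict <- structure(
      list(ANATOMY = sort(sample(terms, sample(seq_along(terms), 1))),
           CHEM = sort(sample(terms, sample(seq_along(terms), 1)))),
      class = "typed_dictionary")
    got <- match_terms(text, dict)
    want <- brute_match(text, dict)
    expect_equal(got[, c("etype", "start", "end")], want,
                 ignore_attr = TRUE)
  }
})

test_that("merging keeps every model span and applies same-type precedence", {
  # disjoint sets: plain union
  m <- entity_spans(c("DISO", "CHEM", "PHYS"), c(0, 10, 20), c(5, 15, 25))
  d <- entity_spans(c("ANATOMY", "LABPROC"), c(30, 40), c(35, 45))
  expect_equal(nrow(merge_predictions(m, d)), 5L)

  # identical span present in both appears once
  d2 <- entity_spans("DISO", 0, 5)
  expect_equal(nrow(merge_predictions(m, d2)), 3L)

  # same-type overlap: the model span wins; cross-type overlap is kept
  m3 <- entity_spans("DISO", 10, 25)
  d3 <- entity_spans(c("DISO", "CHEM"), c(10, 12), c(20, 18))
  out <- merge_predictions(m3, d3)
  expect_equal(span_keys(out), span_keys(tibble::tibble(
    etype = c("DISO", "CHEM"), start = c(10L, 12L), end = c(25L, 18L))))
})

test_that("every model span survives merging over randomized pairs", {
  set.seed(77)
  for (rep in 1:50) {
    m <- dplyr::distinct(random_spans(sample(0:12, 1)), etype, start, end,
                         .keep_all = TRUE)
    d <- dplyr::distinct(random_spans(sample(0:12, 1)), etype, start, end,
                         .keep_all = TRUE)
    out <- merge_predictions(m, d)
    expect_true(all(span_keys(m) %in% paste(out$etype, out$start, out$end)))
    expect_gte(nrow(out), nrow(m))
    expect_equal(anyDuplicated(paste(out$etype, out$start, out$end)), 0L)
  }
})
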