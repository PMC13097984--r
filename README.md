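# nestedner

Nested named entity recognition for biomedical text with layered BIO
tagging, in R.

Biomedical abstracts routinely contain entities nested inside other
entities: an anatomical term (`serum`) and a chemical (`interleukin`) can
sit inside a longer clinical finding (`decrease in serum interleukin`).
Flat sequence taggers cannot represent this, because one token would need
two labels at once. `nestedner` implements the layered approach: the
nested annotation of each sentence is decomposed into up to **six parallel
BIO sequences**, each internally non-overlapping, and a token-classification
model with **six parallel softmax heads** over a shared contextual encoder
predicts all layers at once. Each head predicts over the same 17-label
space — `B-TYPE` and `I-TYPE` for each of the eight entity classes
(`DISO`, `ANATOMY`, `CHEM`, `FINDING`, `PHYS`, `LABPROC`,
`INJURY_POISONING`, `DEVICE`) plus `O`.

The package is aimed at text-mining practitioners who need a complete,
testable nested-NER pipeline: brat standoff I/O, sentence segmentation
with annotation remapping, the layered codec, model training and
prediction, dictionary matching against MRCONSO.RRF-format concept
vocabularies with model/dictionary merging, span-level exact-match
evaluation, and a seeded synthetic corpus generator so everything runs
without licensed data.

## The method

**Layer assignment.** Spans are sorted by start (ascending), length
(descending), then type, and each is placed greedily in the lowest layer
where it overlaps nothing — so outermost entities populate layer 1 and
inner entities fall to deeper layers. Encoding and decoding are exact
inverses for any span set that fits in six layers.

**Model.** Word tokens are split into fixed-length subword pieces; a
compact trainable encoder (piece embeddings plus windowed tanh
convolution layers with residual connections) produces per-piece hidden
states `h_i`; head *k* computes `softmax(W_k h_i + b_k)` over the 17
labels for layer *k*. Supervision and decoding use the first piece of
each word. The loss is the unweighted sum over the six heads of the mean
cross-entropy at supervised positions, optimized with Adam (defaults:
batch size 64, learning rate 1e-4, 40 epochs, maximum sequence length
512). The backbone is pluggable via `register_backbone()`.

**Evaluation.** A prediction is correct only if entity type and both
character boundaries match a gold span exactly, pooling all nesting
levels. Per class: `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
`F1 = 2PR/(P+R)`; micro scores pool counts over classes and the macro F1
is the unweighted mean of the eight per-class F1 values (a zero
denominator yields 0).

**Dictionary matching.** Terms extracted per entity type from an
MRCONSO.RRF-format file (filtered by concept identifier, optionally
expanded to descendant concepts through a parent–child relation table)
are matched case-insensitively at word boundaries, longest match first.
Dictionary spans are merged into model output with model precedence on
same-type overlap, so merging can only add recall.

## Worked example

```r
library(nestedner)

doc <- read_standoff_document(
  "Patients showed decrease in serum interleukin levels.",
  paste("T1\tFINDING 16 45\tdecrease in serum interleukin",
        "T2\tANATOMY 28 33\tserum",
        "T3\tCHEM 34 45\tinterleukin", sep = "\n"))
enc <- encode_sentences(segment_sentences(doc))
tagged_sentence_table(enc$tokens[[1]], enc$tags[[1]])[, 1:4]
#> # A tibble: 8 × 4
#>   token       layer1    layer2    layer3
#>   <chr>       <chr>     <chr>     <chr>
#> 1 Patients    O         O         O
#> 2 showed      O         O         O
#> 3 decrease    B-FINDING O         O
#> 4 in          I-FINDING O         O
#> 5 serum       I-FINDING B-ANATOMY O
#> 6 interleukin I-FINDING B-CHEM    O
#> 7 levels      O         O         O
#> 8 .           O         O         O
```

The outer finding occupies layer 1; the anatomical and chemical entities
nested inside it land in layer 2. Training the six-head model on a small
synthetic corpus and scoring it on its own training sentences:

```r
spec  <- corpus_spec(n_documents = 5, sentences_per_doc = c(4, 4),
                     seed = 11, max_depth = 3)
train <- encode_sentences(
  dplyr::bind_rows(purrr::map(generate_corpus(spec), segment_sentences)))
cfg   <- ner_config(seed = 3, hidden_size = 64, batch_size = 8,
                    learning_rate = 0.02, epochs = 200)
model <- train_ner(build_model(cfg, build_vocab(train, cfg$piece_len)),
                   train)
glance(model)
#> # A tibble: 1 × 7
#>   backbone  n_heads n_labels n_parameters epochs_trained final_train_loss
#> 1 tiny_conv       6       17        54118            200         0.000550

pred   <- predict_sentences(model, train)
counts <- purrr::map2_dfr(train$spans, pred$pred_spans, confusion_counts) |>
  dplyr::group_by(etype) |>
  dplyr::summarise(dplyr::across(c(tp, fp, fn), sum), .groups = "drop")
format_eval_table(score(counts))
#> # A tibble: 1 × 4
#>   `Precision (%)` `Recall (%)` `F1 Score (%)` `Macro F1 Score (%)`
#> 1 100.00          100.00       100.00         75.00
```

The model memorizes the 20 training sentences exactly (micro F1 100);
the macro F1 is 75.00 because two of the eight classes never occur in
this tiny corpus and absent classes contribute an F1 of 0 to the macro
average.

A command-line front-end over the same pipeline (subcommands `simulate`,
`preprocess`, `train`, `predict`, `dict-match`, `merge`, `evaluate`)
ships at `inst/cli/nestedner.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "nestedner.R", package = "nestedner"))') \
  simulate --out corpus --seed 9
```

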