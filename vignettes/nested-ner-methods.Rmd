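---
title: "Layered nested NER: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered nested NER: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestedner)
```

## The problem and the representation

Nested named entity recognition must assign labels to entities that
contain other entities. The layered BIO representation resolves the
conflict by decomposing each sentence's span set into up to six parallel
BIO sequences, each internally non-overlapping. The codec in this
package makes that decomposition a *bijection* for any span set that
fits in six layers with token-aligned boundaries:

* **Layer assignment** sorts spans by start ascending, length
  descending, then entity type lexicographically, and places each span
  in the lowest-index layer where it overlaps nothing already placed.
  An outer span always precedes its nested inner spans in this order,
  so outermost entities populate layer 1 and each additional nesting
  level falls one layer deeper. Whether layer 1 should hold the
  outermost or the innermost entities is a genuine convention choice —
  both give a valid bijection — and we fix outermost-first because it
  makes layer 1 a complete flat annotation whenever no nesting is
  present. Models trained under a different convention are
  incompatible, which is why the convention is stated here prominently.
* **Ties** on identical (start, length) are broken lexicographically on
  entity type: arbitrary, but deterministic, which the round-trip
  property requires.
* **Encoding** always emits exactly six layers, padding unused layers
  with all-`O`, so the model's head count is static regardless of the
  observed nesting depth.
* **Decoding** is total: an `I-TYPE` tag following `O` or a different
  type is treated as `B-TYPE` (conservative repair). Dropping such runs
  instead would silently lose entities predicted with a slightly
  malformed prefix.
* A span set needing more than six layers raises a capacity error by
  default (the spec of the data format promises at most six levels);
  a lenient mode drops the unplaceable spans with a warning instead.

Two degenerate-input rules are worth stating: a span whose boundary
falls strictly inside a token is snapped *outward* to the enclosing
token boundaries with a counted warning (preserving recall under
tokenizer mismatches), and a sentence-boundary candidate that would cut
through an annotated span forces the two sentences to merge, so the
correctness of annotation remapping never depends on the quality of the
rule-based splitter.

## The multilayer model

The model is a token classifier with six parallel linear heads over a
shared contextual encoder. Words are split into subword pieces of at
most `piece_len` (default 6) characters; the bundled `tiny_conv`
backbone embeds pieces and applies `n_enc_layers` (default 2) windowed
tanh convolution layers with residual connections, each mixing a
`window = 2` neighborhood, giving an effective receptive field of ±4
pieces. Head *k* maps each hidden state to 17 logits (`B-`/`I-` for
eight types plus `O`) for nesting layer *k*.

Several aspects are deliberate design choices where reasonable
alternatives exist:

* **Supervision at the first subword piece only.** Remaining pieces are
  masked from the loss and skipped at decoding — the standard
  token-classification convention; supervising all pieces would
  over-weight long words.
* **Loss = unweighted sum over heads** of the mean cross-entropy at
  supervised positions. No per-layer weighting: the heads are
  independent classifiers of equal standing. The empty-mask edge case
  is defined as zero loss with a warning.
* **Residual connections** in the encoder. The per-layer tag of a token
  depends strongly on the token's own identity; letting embeddings
  bypass the convolutions keeps that signal undiluted and, in our
  training experiments, is the difference between reliable and erratic
  convergence of the memorization tests.
* **No class re-weighting.** Tag frequencies are heavily skewed (the
  `O` class dominates, and rare entity types contribute few tags), but
  plain cross-entropy is used; imbalance handling is left to the
  evaluation's macro averaging, which exposes rare-class performance
  rather than hiding it.
* **Determinism.** Parameter initialization and batch shuffling are
  driven entirely by the configuration seed; two runs with the same
  seed produce identical loss logs and parameters. The RNG state of the
  caller is saved and restored around every seeded operation.

Default optimization settings are batch size 64, learning rate 1e-4,
40 epochs, Adam, maximum sequence length 512 subword pieces (sentences
are the unit of processing, so truncation is rare and counted). For the
compact from-scratch backbone used in the tests, those defaults are
overridden locally (hidden size 64, batch size 8, learning rate 0.02,
up to 200 epochs): a randomly initialized encoder needs a larger step
size than fine-tuning a pretrained one. The backbone registry accepts
any encoder exposing `init`/`forward`/`backward`, so a stronger
pretrained backbone can stand under the same heads without touching the
training loop.

## Dictionary matching and merging

Typed term dictionaries are distilled from an MRCONSO.RRF-format file:
English rows whose concept identifier is governed by the concept map,
optionally expanded through the transitive closure of an explicit
parent→child relation table. We use an explicit relation file rather
than traversing a full Metathesaurus hierarchy: it keeps the licensed
resource optional and the closure logic testable on three-node
fixtures.

Matching is case-insensitive, at word boundaries, with same-type
conflicts resolved longest-first then leftmost; different types may
produce overlapping (nested) matches. Terms shorter than three
characters are never matched — uncurated vocabularies are full of short
ambiguous strings that flood precision; three characters is the chosen
cutoff in the absence of a principled one. Merging applies **model
precedence**: a dictionary span overlapping a same-type model span
without being identical is dropped, preserving the trained model's
boundary decisions; everything else is a deduplicated union. Two
consequences are guaranteed by construction and verified by tests:
every model span survives merging, and merged recall is never below
model-only recall.

## Evaluation

Scoring is span-level exact match — entity type and both character
boundaries — with all nesting levels pooled, the usual convention for
layered nested NER. Micro metrics pool TP/FP/FN over the eight classes;
macro F1 is their unweighted mean F1, *including* classes absent from
gold and prediction, which score 0 by the zero-denominator convention.
This makes the macro average a deliberately harsh statistic on small or
skewed corpora: a class that never occurs still drags the mean down.
The worked consequences (a single-class corpus caps macro F1 at 1/8 of
its micro F1) are computed in the tests, not assumed.

## The synthetic corpus generator

The generator emulates the statistical structure the pipeline must
handle, not biomedical language. Each sentence is a capitalized starter
word, a few filler words and entity phrases, and a final period.
Entities are phrases drawn from disjoint type-specific word pools, so a
token's type is genuinely learnable; nesting is created by wrapping an
existing entity in a containing one with probability
`nesting_probability` (default 0.35) per level, up to `max_depth`
(default 6), with at least one extra word per wrap so containment is
strict. Default type weights follow the skewed shape typical of
clinical-abstract annotation — disorders and anatomy dominant, devices
rarest — because that ordering, not any exact count, is the structure
under test. All offsets are valid by construction: every generated
document passes the strict standoff reader, and every span set fits in
six layers.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: real token/annotation boundary mismatches,
abbreviations and punctuation inside entity names, discontinuous
entities, annotation noise, and genuinely contextual type ambiguity
(the same surface form annotated differently in different contexts).
Results on it measure the correctness of the machinery, never expected
performance on clinical text.

## Problem sizes and budgets in the test suite

The suite exercises the codec round trip on a 250-document corpus
(1,100+ sentences, nesting to depth 6), evaluator and matcher behavior
against brute-force oracles on hundreds of randomized fixtures, and
model learnability as an overfit test: the compact backbone with six
heads must reach exact-match span F1 of 1.0 on a 20-sentence corpus
with nesting depth ≤ 3 within 200 epochs. These sizes were chosen as
the smallest that still make each property meaningful; the whole suite
runs in about a minute on one CPU.

## Known limitations

* No discontinuous spans: the layered BIO scheme cannot represent them
  and the standoff reader rejects them explicitly.
* No BILOU/BMES tag variants and no relaxed-boundary or partial-overlap
  scoring modes.
* The bundled backbone is a compact encoder suitable for CPU training
  on small corpora; reproducing competitive benchmark scores requires a
  large pretrained biomedical encoder plugged into the backbone
  registry, licensed annotated data, and accelerator-scale training —
  all outside this package's scope.
* Dictionary matching is exact (after case folding and whitespace
  collapse); no fuzzy or approximate matching.
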