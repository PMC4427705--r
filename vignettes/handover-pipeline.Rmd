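---
title: "Methods: scoring, phonetics, and CRF extraction for nursing handover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, phonetics, and CRF extraction for nursing handover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handoverNLP)
```

This vignette is the package's account of its methods: the models and
procedures, their assumptions, the tunable parameters, and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## The task

A nursing shift-change handover is a short single-speaker monologue about
one patient. A cascaded documentation system (i) converts the speech to
text and (ii) classifies every word of the text into a structured handover
form so the nurse only proofs and signs off. The package implements the
measurement stack for both stages plus a synthetic data generator that
makes the whole cascade testable offline.

## The handover form

The form has six headings — HANDOVER NURSE, PATIENT INTRODUCTION, MY SHIFT,
APPOINTMENTS, MEDICATION, FUTURE CARE — holding respectively 5, 18, 8, 12,
3 and 3 mutually exclusive categories (subheadings, some with
subsubheadings such as Year/Month/Day under Date of birth), plus one NA
category for text relevant to no slot: 50 categories in total. Annotation
is token-wise: every token carries exactly one category id; spans are
reconstructed as maximal runs of equal labels, which is what released
token-per-line data supports (adjacent same-category entities are therefore
indistinguishable — a known representational limit of run-encoding without
a BIO scheme).

Only part of the category names are attested verbatim in the study prose;
the complete listing exists only in a published figure. The packaged
default schema (`inst/extdata/handover_form_schema.tsv`) reproduces the
attested names exactly, satisfies the per-heading counts, and fills the
remaining slots with plausible nursing-handover names; it is documented as
a synthetic reconstruction, and `load_schema()` accepts any conforming
replacement file.

Heading-level abstraction (`abstract_labels()`) maps each category to its
heading (NA stays NA), giving a 7-value label set; the operation is
idempotent.

## Speech-recognition scoring

`normalize_for_scoring()` lowercases, splits on whitespace and strips
leading/trailing punctuation; word-internal apostrophes, hyphens and
decimal points survive, and digit strings are kept verbatim — "0" vs
"zero" remains a scoring error, because digit/word mismatches are a real,
systematic SR error class that normalization would hide.

`align_words()` computes a unit-cost minimum-edit alignment (match cost 0;
substitution, insertion, deletion cost 1). Among co-optimal alignments the
counts are *not* unique (for `ref = a b`, `hyp = b a`, two substitutions
and a deletion-match-insertion script both cost 2), so the implementation
selects, among minimum-cost alignments, the one with the most matches.
This makes C/S/I/D canonical, and symmetric under swapping reference and
hypothesis (I and D exchange; C and S are preserved) — the convention of
word-error-rate scoring. `corpus_correctness()` reports per-document mean,
SD, min, median and max word correctness and the pooled ratio of total
correct words to total reference words.

## Phonetic similarity

The Double Metaphone encoder maps a word to a consonant-skeleton code in
which similar sounds share symbols ("b" and "p" both yield `P`; theta is
written `0`), with an alternate code where pronunciation is ambiguous. The
algorithm tolerates accented English — the reason it was chosen for this
domain. Codes are truncated at the conventional four symbols. Because the
algorithm encodes one word at a time, a multi-word sequence is encoded
word-by-word and the codes concatenated.

The PS percentage between two sequences is
`100 * (1 - editdist(ref_code, hyp_code) / max(nchar(ref_code), nchar(hyp_code)))`
under unweighted edit distance. No formula is published for the original
measure; max-length normalization is the standard normalized edit
similarity and reproduces the published "above 75" semantics. When primary
codes differ, the maximum over primary/alternate combinations is taken.
Degenerate words whose codes are empty (all-vowel words, digit strings)
compare as 100 when the lowercased surfaces are equal and 0 otherwise.

`classify_substitutions()` merges maximal runs of adjacent substitution
ops into multi-word units (matching the distinction between single-word
and multi-word errors, e.g. "doctors signed" vs "dr san") and flags:
homophone (PS = 100), high similarity (PS > 75), short word (every
reference word under 4 characters), spelling-variant candidate (surface
edit distance 1 with PS = 100, like "Johnson"/"Johnsson"), number form
and abbreviation expansion (lexicon-driven, configurable — the error
classes are attested but no detection rule is published). A record is a
correction candidate when homophone or high-similarity. Uniqueness in
`error_profile()` is over lowercased (reference, hypothesis) pairs after
multi-word merging; since "unique error" has no published precise
definition, this policy is documented rather than claimed to reproduce any
particular published tally.

## Features and the template

Feature files follow the CRF++ column convention: one token per line, tab
separated columns (token surface first, label last when annotated), blank
line between documents; `"_"` is the placeholder for absent values and
multi-valued cells are `|`-joined. The reader/writer round-trips its own
output byte-identically.

Statistical features implemented directly:

* **Location** (`location_decile()`): `ceiling(10 * i / n)` — position on a
  ten-point scale; the first word of a document maps to 1 and the last to
  10 for any document of at least ten words, which every document in this
  domain is (the endpoints-only published definition does not constrain
  shorter documents, and this formula is monotone with near-equal blocks).
* **Normalized term frequency** (`normalized_tf()`): term count divided by
  the maximum term count in the document (excluded from the default best
  system, as published).
* **Medication score** (`medication_score()`): 1 for an exact
  (case-insensitive) match of a lexicon ingredient term, 0.5 when the
  phrase occurs at word boundaries inside some term or some term inside the
  phrase, else 0 — strict 1 > 0.5 > 0 precedence. The packaged lexicon is a
  small synthetic stand-in for the ATC ingredient list and is replaceable.

Syntactic/semantic columns (lemma, POS, NER, parse path, dependents,
governors, phrase, concept candidates, top mapping) come from a pluggable
provider. The reference configuration ingests precomputed columns (as
released data provides), so the package has no dependency on external
annotators; `rule_provider()` is a small deterministic annotator (table
lemmatizer, regex/word-list taggers, window-based context columns) that
lets the full pipeline run on synthetic text.

The template (`default_template()`) expands, per token: each feature of the
current, previous and next location alone; pairwise previous/current and
current/next conjunctions per feature; the conjunction of all current
features (six unigram groups); and, in the bigram part, each current
feature conjoined with the previous predicted label. Out-of-document
offsets use `_B-1`/`_B+1` sentinels. `read_template()` parses the CRF++
`U*/B*` macro syntax and `verify_template()` checks a file encodes exactly
these seven groups.

## The sequence labeler

The linear-chain CRF scores a label sequence by summing unigram weights
(feature string × label) and bigram weights (feature string × label pair)
and normalizes globally. Training maximizes the L2-penalized conditional
log-likelihood — penalty `0.5 * l2 * ||w||^2`, default `l2 = 1`, feature
cut-off 1, mirroring documented CRF++ defaults since the original
hyperparameters are unstated — with exact forward-backward gradients and
L-BFGS (`stats::optim`, default `factr = 1e8`, `max_iter = 200`). The
objective is convex, so training is deterministic given inputs and
configuration.

Numerics: the forward-backward pass runs in the linear domain with
per-step normalization. A token's transition matrix is the sum of a
handful of feature blocks, so `exp()` of each bigram block is cached once
per evaluation (shifted by the block maximum) and per-token matrices are
elementwise products of cached blocks; emission scores are exponentiated
with a per-token max shift. Marginals are renormalized per position, which
makes the gradient immune to scale bookkeeping. Viterbi decoding works on
the raw scores, so prediction assigns exactly one category per token and
is total even when every feature is unseen.

Baselines: the majority baseline labels every token with the most frequent
non-NA training label; the random baseline draws uniformly over all 50
schema categories (the full schema, not only attested ones — the published
description does not say which, and the full schema is the conservative
reading) under a fixed seed, reproducibly per document.

## Evaluation protocol

`conll_eval()` scores at segment granularity (exact boundary and label
match of maximal non-NA runs), the convention of the CoNLL-2000 chunking
evaluator, because token-level scores overstate performance on long spans.
Per-category precision/recall/F1 come from segment counts; the macro
average is the unweighted mean over categories with nonzero gold support,
excluding NA and recomputed per corpus (never hard-coded to an attested
category count); micro averages are emitted at both segment and token
granularity, labeled, since the published micro-averaging granularity is
unstated. NA — the dominating filler category — is scored separately at
token granularity, the granularity its tallies are conventionally quoted
at, and overall token accuracy (NA included) is reported alongside.

Drivers: `loo_cv()` (each document predicted by a model trained on the
rest), `learning_curve()` (a fixed `test_n`-document split sampled without
replacement, then independent training subsamples per size under one seed;
when a size equals the whole remainder, the remainder is used),
`leave_feature_out()` (one LOO run per dropped feature type; deltas of
macro F1, NA F1, and mean per-category F1 over attested categories;
dropping the token column is refused), `confusion_matrix()` (token-level,
gold in rows), and `compare_abstraction()` (fine-trained-then-abstracted
vs heading-trained, identical features, template and folds, both scored at
heading level).

LOO folds are warm-started from the all-document optimum, with the weight
blocks of features absent from a fold's training data reset to zero (at
the fold optimum those weights are exactly zero, so the reset removes any
information flow from the held-out document). Since the penalized
likelihood is strictly convex, warm starting changes only the optimization
path, not the fold estimates.

## Synthetic data: what it emulates and what it does not

`generate_corpus()` builds monologues from a template grammar over four
balanced patient types (cardiovascular, neurological, renal, respiratory),
assembling sentence segments (patient introduction, admission, status,
vitals, medications, appointments, future care, …) whose content tokens
come from per-category trigger vocabularies; connective tokens are NA.
Every token is labeled by construction, so generated corpora carry an
exact reference standard for every seed. The default document length range
is 100–300 words (the nominal instruction under which the emulated
documents were written); the experiments in this package use
`length_range = c(30, 120)`, chosen to mirror the attested real document
lengths (range 19–209, mean ≈ 71). The label-recovery experiments use 100
documents, the attested corpus size.

Trigger vocabularies are pairwise disjoint and disjoint from the NA
vocabulary. This makes the corpus *separable*: a correct learner should
recover the labels almost perfectly, which is what the label-recovery
tests assert (LOO macro F1 and NA F1 at least 0.90). Passing them
validates the learner and the evaluation stack — it says nothing about
performance on real clinical text, where vocabularies overlap, spans are
ambiguous and annotation is noisy. The generator's feature matrix (token,
lexicon-cue column standing in for semantic lookups, location decile) is
deliberately simple for the same reason.

`corrupt_transcript()` injects sound-alike substitutions (drawn from a
confusion table built by perturbing words under the constraint
`PS >= 75`, mostly exact homophones), filler insertions and short
function-word deletions, recording each site in a ledger. Replacements and
fillers must differ from their neighbors, and sites are kept at least
three positions apart: one matched token between a deletion and an
insertion is not enough, because the two-substitution alignment then ties
in cost and the tie-break is not contract-bearing. Under these guarantees
the aligner recovers the injected S/I/D counts exactly — the end-to-end
oracle the tests rely on. The guarantee caps corruption density at one
site per three tokens, so default rates (0.15/0.08/0.05) realize word
correctness near 0.9 rather than the attested 0.725; heavier corruption is
available by disabling the guarantee, at the price of exact count
recovery.

## Problem sizes and runtimes

The test suite exercises the alignment oracle on 500 random pairs, the
phonetic laws on 1,000 random pairs, the CoNLL scorer against an
independent reference implementation on 20 randomized documents, LOO CV
label recovery on a 100-document 50-category corpus, and exact corruption
recovery on 100 documents. The 100-document LOO run (101 CRF trainings
over roughly 9,000 tokens with ~1.4 million active weights) is the
dominant cost, a few minutes on one CPU thanks to the warm start.

## Known limitations

* The default schema's unattested category names are a reconstruction.
* Run-encoded annotation cannot represent adjacent same-category entities.
* The rule-based annotation provider is a stand-in adequate for synthetic
  text; real deployments should ingest precomputed columns from a full
  NLP stack.
* PS normalization and the uniqueness policy for error counting are
  documented choices; published values depending on unpublished policies
  are not claimed to be reproduced exactly.
* The synthetic corpus is separable by design; results on it bound what
  the code does, not what real handover data yields.
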