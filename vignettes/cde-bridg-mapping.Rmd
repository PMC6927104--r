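---
title: "Mapping Common Data Elements to BRIDG classes: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping Common Data Elements to BRIDG classes: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdemapr)
```

## The problem

ISO 11179 Common Data Elements (CDEs), as registered in the NCI's caDSR,
define clinical data points through a conceptual part (an Object Class and
a Property, together the Data Element Concept) and a representational part
(a Value Domain with a Representation Term). The BRIDG domain model
describes protocol-driven biomedical research as UML classes. Mapping each
CDE to the BRIDG class it belongs to is what lets CDE-encoded data flow
into other standards (CDASH, SDTM), but by hand it is slow, subjective
work for committees of domain experts.

`cdemapr` implements a semi-automated recommender: given a corpus of CDEs
with known BRIDG class mappings, it learns how much each of six CDE text
attributes matters for class membership, and then ranks candidate classes
for new CDEs so an expert only has to confirm a short list.

## The similarity model

Every comparison between two CDEs runs over six attributes, in fixed
order: CDE Long Name, Object Class, Property, Value Domain Long Name,
Representation Term, Question Text. For one attribute pair:

1. Both phrases are tokenized: lowercased, punctuation stripped, split on
   whitespace.
2. Every word pair gets a similarity $s_{word} = 1 - d/l$, with $d$ the
   Levenshtein edit distance and $l$ the longer word's length.
3. The word-similarity matrix is reduced greedily: the global maximum is
   extracted into a list, its row and column are deleted, and the process
   repeats until one phrase is exhausted. The list therefore has
   $\min(|a|,|b|)$ non-increasing entries.
4. The attribute similarity $s_i$ is the fraction of list entries at or
   above the word-similarity threshold (compared with $\ge$; the
   threshold is fixed for the life of a model, default 0.8).

The overall similarity is the single-layer network's output
$s = \sum_{i=1}^{6} w_i s_i$ with the weights $w_i \ge 0$,
$\sum_i w_i = 1$.

```{r worked}
q_a <- "What was the classification of the acute myelogenous leukemia?"
q_b <- "What was the classification of the chronic myelogenous leukemia?"
greedy_similarity_list(tokenize(q_a), tokenize(q_b))
attribute_similarity(q_a, q_b, threshold = 0.9)
```

Eight of the nine word pairs match exactly; the leftover pair
(*acute*/*chronic*) has edit distance 7 over length 7, similarity 0, so
the attribute similarity is $8/9$.

## Weight learning

Weights start uniform at $1/6$. For an anchor CDE in class $C$:

* $s_{avg}$ — its mean overall similarity to the other members of $C$;
* $s_{avg\_other\_cls}$ — its mean overall similarity to every record
  outside $C$;
* the error is $E = \tfrac12 (s_{max} - s_{avg})^2$ with
  $s_{max} = \max(s_{avg}, s_{avg\_other\_cls})$, i.e. zero exactly when
  the anchor already sits closer to its own class.

When the error is positive each weight receives
$\Delta w_i = \eta\,(s_{max} - s_{avg})\,\bar{s}_i$, where $\bar{s}_i$ is
the mean attribute-similarity vector over the anchor's within-class
pairs, and the weights are renormalized onto the simplex. Classes are
traversed from smallest to largest (ties by name); by default every class
member serves as anchor once per pass (`anchor_mode = "all"`; the
single-anchor reading, `"first"`, is available for comparison). Training
runs for at most 50 passes at $\eta = 0.05$ and stops early once the
total error changes by less than 1% between passes.

Design choices worth stating explicitly:

* **Renormalization after every update.** The simplex constraint must be
  maintained under the purely additive update; dividing by the weight sum
  keeps it exact while preserving the update's relative effect. (Whether
  the constraint is restored per update or once at the end is not
  determined by the update rule itself; per-update is the choice here.)
* **Mean rather than sum over within-class pairs.** Using the average
  attribute vector makes the step size independent of class size; the
  summed form is recovered by scaling $\eta$.
* **Early stop at 1% relative error change**, reflecting the observed
  fluctuation band at the 50-pass cap.
* The training-time comparisons and the recommendation-time class score
  share one construction: a class's score for a query is the mean overall
  similarity between the query and the class's stored members (a
  max-over-members mode exists behind `score_mode` for sensitivity
  analysis). Ranking ties break lexicographically by class name so every
  run is deterministic.

## Recommendation and evaluation

`recommend()` scores every class of a trained model for a query CDE and
returns the top $k$ (default 10). `match_rate()` reports the percentage
of labeled queries whose true class appears in the top $n$; by
construction this is non-decreasing in $n$. `sweep_parameters()` re-runs
split/cap/train/evaluate over a grid of training ratios (0.75, 0.9),
thresholds (0.6–1.0) and per-class training caps (4–10), the parameter
ranges relevant to this task. `dec_concept_overlap()` computes the
semantic-similarity statistic between corpora: the percentage of distinct
DEC concept identifiers of a testing set that also occur in the training
set.

Corpus preparation follows the same order as the original study: filter
classes below the minimum size (default 10) first, then split the
remainder into training and verification parts. Splitting is stratified
per class by default so small classes never vanish from training; a
non-stratified mode is provided. The per-class cap is applied to the
training split by seeded subsampling, which makes it affect both training
cost and the stored members used at recommendation time.

## The synthetic corpus generator

Real caDSR corpora cannot be redistributed with the package, so every
claim is exercised on generated corpora that emulate their structure.
Each synthetic class has a fixed two-word Object Class phrase — mirroring
real mappings, where the CDEs of one BRIDG class typically share an
object class — plus a class vocabulary of property/representation words.
Per record, the Long Name is the concatenation of Object Class, Property
and Representation Term; the Value Domain Long Name is templated from the
representation term; the Question Text is the sentence
`"what was the <property> of the <object class>"`. `dec_concepts` carries
the record's canonical content words, so DEC-overlap statistics have
exact expected values.

Content words come from a collision-controlled lexicon: pronounceable
CV-syllable words, rejection-sampled so every pair of lexicon words has
word similarity below 0.7. Cross-class edit-distance matches are
therefore designed (via the overlap dial), never accidental.

Two dials control difficulty:

* `overlap_fraction` — the fraction of each class vocabulary drawn from a
  pool shared by all classes. At 0 the class vocabularies are pairwise
  disjoint and a trained model retrieves held-out members perfectly; at 1
  all classes draw from one small pool and differ only in which words
  recur.
* `typo_rate` — the probability that each content word of a record
  receives one random single-character edit, pushing word similarities
  toward the threshold.

The default configuration (19 classes × 12 members, overlap 0, typo 0)
matches the scale of the real training material (19 classes after
filtering) in its fully separable regime. The difficulty calibration used
in the tests defines *moderate noise* as full vocabulary sharing
(`overlap_fraction = 1`) with `typo_rate = 0.3`: on 12 classes × 10
members this lands top-1 accuracy in the 40–80% band with a steeply
rising top-$n$ curve — the regime in which the largest single accuracy
gain comes from returning two candidates instead of one — whereas milder
settings leave the task saturated at 100%.

With `informative_attribute = i`, only attribute $i$ is built from class
vocabulary; all other attributes draw their content words from a small
background pool shared by every class. The background pool is
deliberately small (the size of one class vocabulary) so that the
non-informative attributes resemble each other across classes and the
uniform-weight network actually misclassifies — otherwise the corpus is
already separable and training is a zero-error fixed point that never
moves the weights.

### What parameter recovery can and cannot show

The recovery suite demonstrates that when only the Question Text carries
class structure, its weight $w_6$ is learned strictly maximal on every
seed. The analogous claim does **not** hold for a bare single-word
attribute such as Property, and this is a property of the update rule,
not of the implementation: $\Delta w_i$ is proportional to the *mean
within-class similarity* of attribute $i$, so the rule reinforces
whatever is consistently similar within a class. Templated multi-word
attributes (value domain long name, question text) have structurally high
within-class similarity and always out-gain a single word that matches
only occasionally; conversely, if the single word is made class-constant,
the corpus becomes separable under uniform weights and no update ever
fires. The question-text attribute — a full sentence — is exactly the
attribute reported to earn the highest trained weight on the real
corpora, and it is the one this package's recovery suite pins down.

What passing these tests shows about real data is limited in the usual
ways: synthetic vocabularies are cleaner than curated metadata (no
synonyms, no abbreviations, no shared English carrier words beyond the
templates), class sizes are balanced, and typo noise is uniform. The
harness accepts real caDSR-style corpora through the canonical CSV/JSON
schema (and a best-effort CDE Browser XML reader) when those are
available.

## Numerical and degenerate-input choices

* Greedy ties (equal matrix maxima) resolve to the smallest row index,
  then the smallest column index; the implementation's sorted single scan
  is provably equivalent to literal repeated rescans and is tested
  against a rescan oracle.
* Word-pair similarity of two empty words is an error; an attribute in
  which either phrase tokenizes to nothing contributes similarity 0
  (absent text is no evidence of a match).
* Threshold comparisons use $\ge$, and thresholds live in $(0, 1]$.
* Weight-sum tolerance is $10^{-9}$; models whose persisted weights
  violate it are refused at load time.
* A corpus in which every anchor already satisfies
  $s_{avg} \ge s_{avg\_other\_cls}$ is a fixed point: training returns
  uniform weights and an all-zero error trace.
* Training requires at least two classes and two members per class;
  stratified splitting refuses one-member classes; a query whose true
  class is absent from a model counts as unmatched at every $n$.

## Problem sizes used in the shipped tests

The test suite and acceptance checks run entirely on generated corpora:
up to 19 classes × 12 members (228 records) for the end-to-end
separability check, 12 × 10 for the accuracy-curve shape, 6 × 8 over five
seeds for parameter recovery, and 10–60 record fixtures for the unit
tests. All record-pair attribute similarities are precomputed once per
training corpus (they do not depend on the weights), which is what keeps
the 50-pass training loop to dot products.

## Known limitations

* No synonym expansion, stemming, or NCI Thesaurus semantics; matching is
  purely lexical, so semantically equivalent but lexically disjoint CDEs
  score 0.
* The greedy similarity list has length $\min(|a|,|b|)$, so a phrase
  scores 1.0 against any superset phrase ("subset inflation").
* The delta rule only learns from misclassified anchors; on separable
  corpora the weights stay uniform.
* Gradient descent is batch with a fixed learning rate — no momentum,
  minibatching, validation-loss early stopping, or alternative losses.
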