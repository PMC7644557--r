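---
title: "Scoring rigor and transparency in biomedical methods sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring rigor and transparency in biomedical methods sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtindex)
```

## The problem and the model

Reporting guidelines converge on a small set of study-design items whose
absence is repeatedly linked to irreproducible results: ethics oversight
(IRB/consent for human work, IACUC for vertebrate work), randomization of
subjects into groups, blinding of experimenters or analysts, a power
analysis justifying the sample size, reporting the sex of subjects, and —
for cell-line work — authentication (e.g. STR profiling) and mycoplasma
contamination checks. A second family of items concerns *key biological
resources*: whether the antibodies, organisms, cell lines, plasmids,
oligonucleotides and software tools a study used can be uniquely identified
from the text (vendor plus catalog number, or better, a Research Resource
Identifier, RRID).

`rtindex` screens the methods section — the one part of an article that
states facts about how the work was done — sentence by sentence, and
condenses the findings into a per-paper composite score on a 0–10 scale:

* **Rigor component (5 points).** The nine detected criteria collapse into
  scoring *blocks*: ethics (IRB, consent, IACUC — any one satisfies it, so a
  purely human or purely animal study is not penalized for lacking the other
  approval type), randomization, blinding, power, sex, and cell-line
  authentication (authentication or contamination check; *applicable only
  when a cell line is detected*). The component is
  `5 × addressed/applicable` over applicable blocks, optionally weighted.
* **Resource component (5 points).** For each *scoreable* type detected
  (antibody, organism, cell line, software) compute the fraction of
  de-duplicated mentions that are identifiable; the component is 5 times the
  mean of those per-type fractions. Plasmids are recorded but not scored;
  oligonucleotides never affect the score. With no scoreable resource
  detected the component is 0.
* A paper in which nothing at all is found is flagged *not applicable* and
  scores 0; such papers are excluded from journal averages but counted.

The **Rigor and Transparency Index** of a journal in a year is the mean
composite score of its scored papers. Trend tables aggregate by year, and
`compare_with_jif()` relates the RTI to the Journal Impact Factor by
Spearman rank correlation, pairing the impact factor of year *y* with scores
of papers from years *y−2* and *y−1* (the window the citation metric itself
summarizes; configurable).

### Design choices where the aggregation was open

The published score defines only the two 5-point section caps and the 0 and
10 endpoints, not a per-block weight split. We default to equal block
weights with rescaling to the caps, and expose `block_weights` and
`type_weights` in `score_config()` for sensitivity analysis. Averaging the
resource component over *types* rather than over mentions prevents one
abundant type (typically software) from dominating. Scores are kept
continuous; `score_config(rounding = TRUE)` gives half-up integer rounding
for league-table style reporting. Two ethics readings are implemented:
`"merged"` (default, one ethics block) and `"strict"` (human ethics and
IACUC as separate blocks) — the stricter reading penalizes single-domain
studies and is retained for comparability experiments.

## Detection

The default engine is deliberately *deterministic*: per-criterion
keyword/phrase lexicons with proximity constraints, shipped as an editable
JSON config (`default_lexicons()`). Three mechanisms control false
positives:

* **Context terms.** Blinding terms ("blinded", "unaware", "masked") count
  only alongside an investigator/analysis/assessment term in the same
  sentence.
* **Exclusions.** Exclusion patterns mask their matches (a gene name like
  *Sex-lethal* cannot satisfy the sex criterion; "blind-ended" is not
  blinding) and disable the weaker contextual patterns for that sentence
  (an "approved by the … Animal Care and Use Committee" sentence is not read
  as IRB approval).
* **Word boundaries.** "doublesex" never matches the sex terms.

The sex lexicon includes relational terms such as "mother", which mark the
sex of subjects in observational phrasing; this is a deliberate recall
choice and a known false-positive source (e.g. chemistry's "mother liquor").

Resource mentions are found by shape patterns (e.g. `X antibody`, `anti-X`,
strain-before-species for organisms, letter–digit tokens before cell nouns,
`pXyz` tokens in cloning contexts, runs of nucleotide letters, a known-tool
registry for software). Vendor names come from a configurable list; catalog
numbers from cue-anchored patterns (`#62988`, `ab37144`, `number TIB-67`,
`Cat. No. X`), with RRID spans masked first so an accession is never read as
a catalog number. The RRID grammar accepts both the spaced and unspaced
dialects and nested-colon accessions (`RRID:IMSR_JAX:000664`); parsing is
purely syntactic — resolving identifiers against live registries is a
documented extension point, not a dependency.

**Relaxed second pass.** An RRID is near-certain evidence a resource is
described, so any RRID not carried by a first-pass mention either augments a
same-sentence mention of the matching type or creates a new mention, typed
by its authority (AB → antibody, CVCL → cell line, SCR → software, Addgene →
plasmid, stock centers → organism) and named by the nearest preceding
resource-like token. The exact relaxation used by production systems is not
published; nearest-preceding-token naming is our reconstruction, and the
pass is constrained to be monotone: it never removes a mention and never
lowers identifiability.

**Identifiability rules.** Antibody: catalog number or RRID (vendor alone is
not enough; a clone ID plus vendor counts only under
`clone_with_vendor = TRUE`, the laxer reading). Organism, cell line,
plasmid: RRID, or vendor *and* catalog number. Software: RRID, URL, or a
name in the known-tool registry — the registry ships with common tools and
is editable; recall on unlisted tools is a stated limitation, consistent
with the observation that most software mentions concentrate on few tools.
Oligonucleotides are reported as identifiable but never scored.

**Counting.** Detected/identifiable counts are over *entities*: mentions are
de-duplicated per document on (type, normalized name, catalog-or-RRID), so
restating a reagent does not inflate the denominator.

An optional trainable tagger (`train_tagger()`, IOB2 labels, CoNLL-style
two-column files) preserves the sequence-labeling architecture used by
production systems without their proprietary training corpus. It is a
deterministic token/shape majority-label model — adequate for the template
distributions it is tested on, and *off by default*; the pattern engine is
the reference path.

## The synthetic corpus

Because the full open-access corpus cannot ship with a package, every claim
is exercised on a generated corpus with known ground truth
(`corpus_spec()` + `generate_corpus()`). Documents are assembled from
slot-filled templates of realistic criterion sentences, resource sentences
with or without identifying metadata, and hard-negative distractors
("blind-ended duct", "doublesex gene"), shuffled per document.

Defaults emulate recently reported corpus rates: criterion prevalences
randomization 0.303, blinding 0.087, power 0.096, sex 0.375, IACUC 0.246;
identifiability probabilities antibody 0.433, organism 0.22, cell line
0.393, software 0.867. IRB (0.25) and consent (0.20) prevalences are not
separately published; we chose values comparable to the IACUC share.
Authentication/contamination sentences are planted only in documents that
received a cell-line mention, matching the conditional scoring rule, with
conditional prevalences 0.40/0.30. Mention counts per type are
`floor(m) + Bernoulli(m - floor(m))`, so the configured mean is exact and a
mean of 1 guarantees a mention — which is what makes the all-ones endpoint
(every document scores exactly 10) a deterministic property rather than a
probabilistic one.

What the generator does *not* emulate: paraphrase diversity beyond the
template pools, OCR noise, non-English text, methods split across
supplements, or reagent descriptions spanning sentences. Passing the
recovery tests therefore demonstrates internal consistency of the pipeline
(detection, identifiability, scoring, aggregation) at realistic prevalence
levels — not field performance on arbitrary prose, which for any rule-based
engine depends on lexicon coverage.

Problem sizes used in the checks: golden-fixture suites run on single
sentences; property suites on 5–60 documents; parameter recovery on
400–500-document corpora, where each configured rate must be recovered
within three binomial standard errors; the planted-count check uses 1,000
documents against a 99% binomial interval.

## Numerical and procedural conventions

* Character offsets are 0-based, half-open, everywhere (sentences, RRID
  spans, mention anchors); one convention avoids off-by-one drift.
* The sentence splitter is rule-based and deterministic: boundaries at
  `.!?` followed by whitespace and an upper-case/digit/open-bracket start,
  suppressed after a whitelist of abbreviations ("Fig.", "et al.", "i.m."),
  after single initials, and inside decimal numbers; `RRID:` tokens are
  never split. Spans cover all non-whitespace, so the original text is
  reconstructible from spans plus inter-span whitespace.
* Ranks use average ties throughout (Spearman, percentiles); with no ties
  Spearman equals `1 − 6Σd²/(n(n²−1))`. Zero variance is signalled as a
  degenerate condition (`NA` coefficient), not silently returned.
* League-table percentages round half-up (92.5 → 93); score rates are
  reported to one decimal. Quartile labels put the *top* quartile at Q1.
* Journal-year summaries require `min_n` scored papers (default 10, echoing
  published inclusion practice for league tables); zero-score papers are
  excluded from means but reported as `n_zero`.
* Degenerate inputs are signalled with typed conditions: missing methods
  section (`rtindex_methods_missing` — the document is retained, scores 0,
  counted unscorable), zero denominators (`rtindex_no_denominator`),
  correlation contract violations (`rtindex_cor_*`).

## Known limitations

* Rule-based recall is bounded by the lexicons; phrasings far from the
  shipped patterns (or non-English methods) are missed. The lexicons are
  JSON and user-extensible.
* Software identifiability depends on the registry; the 80/20 concentration
  of tool usage makes a modest registry effective but long-tail tools will
  be read as non-identifiable.
* Catalog-number syntax is only validated, not verified against vendors.
* The per-block weight split and the production second-pass relaxation are
  reconstructions; both are isolated behind configuration so alternative
  readings are one argument away.
* Methods sections embedded in supplementary PDFs are invisible to text
  mining; such articles enter the pipeline as unscorable.
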