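---
title: "Detecting a complex medication error in case narratives: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a complex medication error in case narratives: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icsrminer)
```

## The detection problem

An individual case safety report (ICSR) couples structured fields — MedDRA®
preferred-term (PT) codes, a product list, a source tag — with a free-text
narrative, often split into named sections.  The target event here, the
extraction of insulin from a prefilled pen or cartridge by a syringe
(EIPPCS), has no dedicated PT: it must be recognised from how reporters
phrase it ("withdrew insulin out of the pen with a regular syringe",
"intentionally mixed in the one syringe", "taking insulin with syringe").
`icsrminer` implements three detectors over a shared text engine and a
shared evaluation protocol, so that their retrieval behaviour can be
compared on one corpus with per-record rule traces.

All three detectors are deliberately **rule-based**.  In a regulated
setting every retrieval decision must be explainable and modifications must
behave predictably; a trace that says "excluded at the negation rule" is
worth more than a marginally better black-box score, and a rare event
(about 1.7% of even a pre-filtered corpus) offers little training signal
for statistical classifiers anyway.

## The text engine

**Normalisation.** Narrative text is NFKC-normalised on ingest and
trademark glyphs (®, ™) are stripped, because real narratives contain
branded device names while rule dictionaries hold plain words.  All
matching is case-insensitive via a single folding routine (NFKC + lower
case).

**Sentence segmentation** is rule-based and deterministic: a run of
`.`, `!`, `?` followed by whitespace and an upper-case letter or digit ends
a sentence, unless the token ending at the terminator is a listed
abbreviation ("e.g.", "i.e.", "Dr.", …, with leading punctuation ignored,
so "(e.g." is still recognised).  Safety narratives are template-like
translated prose; a statistical splitter would add a dependency and
non-determinism without obvious benefit here.

**Tokenisation** splits on whitespace and separates punctuation into its
own tokens; internal hyphens and apostrophes stay inside word tokens
("re-injected" is one word).  Tokens carry 0-based half-open character
offsets and concatenating their surfaces reconstructs the non-whitespace
input — an invariant the tests assert.  Word tokens are numbered separately
from punctuation tokens; dictionary phrases match over the word-token
sequence.

**Tagging** finds all maximal dictionary matches: at each position the
longest matching phrase wins ("insulin syringe" beats "insulin") and
matching resumes after the matched span, so spans from one lexicon never
overlap.  Tagging is checked against a naive enumerate-every-window oracle
on randomly generated corpora.

**Proximity.** Two spans pair when they share a sentence and at most
`max_gap` *word* tokens lie strictly between their nearest edges; adjacent
or overlapping spans have gap 0.  The phrase "equal or less than 8 words
separated" admits several readings; counting intervening word tokens (not
punctuation, not the matched words themselves) is the strictest defensible
one, and `max_gap` is an explicit parameter (default 8) rather than a
constant.  No stemming is applied anywhere: the shipped lexicons list
surface inflections explicitly ("syringe", "syringes"; "withdrew",
"withdrawn", …), which keeps matching transparent and lets a reviewer see
exactly which form fired.

## The three detectors

**SSA** (keyword + PT filter): a record passes if (1) some narrative token
has folded prefix `"syringe"` — prefix matching covers the plural; an
exact-token mode is available — and (2) the record carries at least one of
twelve curated PTs, matched by *name* through the hierarchy table,
case-insensitively with internal whitespace collapsed.  PT identity is by
name because curated filter lists are published as names; codes are carried
for bookkeeping.

**CPR** (dictionary tagging + proximity), per record: isolate sections
(dropping names that contain "analysis", so wording confined to a returned
product analysis cannot drive detection); require an anchor tag in retained
text; disqualify on a negation cue sharing a sentence with an anchor or
positive span; disqualify on inhaled-insulin-trial vocabulary anywhere in
retained text or on "prefilled" within 2 word tokens before an anchor
(covering "prefilled syringes" and "prefilled insulin syringes" — prefilled
syringes are a product, not the error); finally require an
anchor/EIPPCS-dictionary pair within the proximity window.  Negation is a
sentence-scoped cue list ("did not", "never", "denied", …), not full scope
resolution — adequate for narratives that state plainly that the error did
not occur, and cheap to audit.

**I2E-style cascade**: an ordered set of `pattern_rule` objects — verb +
anchor same-sentence co-occurrence, anchor presence, product mention
(narrative text or the structured product field), inhaled-vocabulary
exclusion — combined as "all includes pass, no exclude fires".  The cascade
runs on the raw (un-sectioned) narrative by default; `exclude_section`
rules are available.  The exact box-level contents of the original
commercial query are not public, so the default ruleset is an explicit
reconstruction that reproduces each documented behaviour, including the
documented product-coverage miss: the product lexicon deliberately omits
the FlexTouch-like brands, so a record mentioning only such a product fails
the product rule.

Two dictionary decisions deserve a note.  The action-verb list includes
inflections of *take* alongside *inject*, *administer*, *use*, *withdraw*,
*extract*, *draw* and *mix*: phrasings like "taking insulin with syringe"
are canonical for this error and the published verb list is explicitly
non-exhaustive ("e.g.").  The EIPPCS phrase dictionary likewise includes
*inject* inflections, because re-injection clauses ("… and then injected it
back …") are how several canonical narratives bring the cue within the
8-word window of the anchor.

Rule identifiers (`cpr_rule_1..5`, `i2e_rule_1..4`) mirror the numbering
conventions used in published miss-cause tables, but the mapping of numbers
to boxes is itself a reconstruction; the trace semantics, not the labels,
are the contract.

## Evaluation protocol

`confusion()` partitions an annotated universe into TP/FP/FN/TN;
`recall()` is `tp/(tp+fn)`.  Precision is computed under **two
conventions**, reported side by side: `precision_testset()` is the textbook
PPV `tp/(tp+fp)` within the annotated universe, while `precision_paper()`
divides confirmed test-set true positives by the method's total retrieval
from the *full* corpus.  The second is the only arithmetic consistent with
headline figures of the form 37/1104; the package surfaces the discrepancy
rather than silently picking one.  Published one-decimal percentages mix
half-up rounding (88.1 from 37/42) and truncation (90.4 from 38/42);
`format_percent()` takes the convention as an argument so each printed
value can be pinned with its matching rule.

`cohens_kappa()` uses the closed form over marginal frequencies, with the
degenerate both-raters-constant-and-equal case defined as 1.
`overlap_analysis()` enumerates all non-empty method subsets plus a
captured-by-none bucket; counts sum to the gold-positive total.
`pt_frequency()` counts multi-PT records once under "Composite PTs" and
merges PTs below a threshold (default 10) into a "PTs < N" bucket.
`fp_only_terms()` mines word n-grams (1–5, stop words kept — published
FP-only term lists contain stop-word-bearing phrases) occurring in a
method's FP pool and never in its TP pool, ranked by FP count with
lexicographic tie-break.

## The synthetic corpus generator

Real pharmacovigilance corpora are proprietary, so the generator is a
first-class, tested module, not a fixture.  What it emulates:

* **Prevalence**: gold positives are exactly
  `round_half_up(prevalence * n)` at a default 1.7% — the observed rarity
  of the event among device/medication-error coded reports.  Half-up
  rounding is used for every sample-size computation in the package
  (10% of 25,328 is 2533).
* **Positive phrasing**: template families paraphrase the published
  example narratives (intentional mixing in one syringe; withdrawing from
  a pen with a regular syringe and re-injecting; taking insulin with a
  syringe after a device fault), with randomised brands and fillers.
* **Designed misses**, labelled positive by template semantics: a long-gap
  family (cue ~21 words from the anchor, beyond any sensible window); an
  "analysis results"-only family (error wording confined to the excluded
  section, mirroring a real missed case); a no-"syringe" family (missed by
  all three methods, as the absence of the keyword defeats them all); and
  a FlexTouch-analogue family (fictional brand "Flexitra", absent from the
  cascade's product dictionary).  Because gold labels come from templates,
  measured recall of the deterministic pipeline equals exactly one minus
  the designed-miss fraction — the parameter-recovery property the
  acceptance tests assert at n = 5000.
* **False-positive drivers**: a nurse drawing a dose from a *vial* with a
  syringe (correct use, not EIPPCS — retrieved by all three methods);
  prefilled-insulin-syringe product mentions (retrieved by the cascade,
  filtered by the tagging pipeline's prefilled rule — which is why
  "prefilled insulin syringes" shows up only in the cascade's FP-only term
  list); negated errors; inhaled-insulin trials; plain device complaints.
* **Coding**: PTs are drawn per template family (error PTs for positives,
  device PTs for device complaints, off-scope PTs for plain adverse
  events, which the HLGT pre-filter then removes), with `coding_noise`
  replacing a record's PT set by in-scope but off-filter terms
  ("Medication error", "Needle issue") — the mechanism behind
  keyword-method misses of correctly narrated cases.
* **Determinism**: all draws run under a seed-isolated RNG
  (`withr::with_seed`), so a configuration yields a byte-identical corpus
  and the global RNG state is untouched.

What it does **not** emulate: real clinical language variability,
translation artifacts, narrative length distributions (unknown for
proprietary data), multi-axial MedDRA coding (the mock hierarchy is
single-path, so HLGT collapsing has a unique answer by construction), or
realistic product portfolios (brands are fictional; the packaged
hierarchy is synthetic and miniature).  Green tests on synthetic data
therefore demonstrate correctness of the *mechanisms* — filtering,
tagging, proximity, tracing, accounting — not field performance on real
narratives.

## Problem sizes and numerical choices

The test suite exercises the text engine against brute-force oracles on
over a thousand randomly generated cases, and the end-to-end
parameter-recovery check runs at n = 5000 with 85 planted positives; unit
fixtures are hand-enumerable (≤ 40 records).  These sizes were chosen so
the whole suite runs in about two minutes while still covering every rule
interaction; the generator scales linearly if larger corpora are wanted.

Degenerate inputs are defined, not accidental: empty corpora filter to
empty corpora; empty text segments to zero sentences; a lexicon that
parses to zero phrases is an error (a detector with an empty dictionary is
meaningless); recall and precision raise a typed error when their
denominator is empty; unknown PT codes are skipped by default (synthetic
coding noise produces them deliberately) and raise in strict mode.
Ties in term mining break lexicographically; largest-remainder
apportionment of template counts breaks ties by template order.

## Known limitations

* Negation handling is cue-based and sentence-scoped; "the patient denied
  X but later admitted it" would be over-excluded.
* The proximity gap definition is one of several defensible readings of
  "N words separated"; alternatives (counting punctuation, counting
  matched words) are not implemented, only a different `max_gap`.
* The pattern cascade is a reconstruction of a commercial query's
  described behaviour, not of its internals.
* Inter-annotator κ can be validated only against closed-form oracles:
  the disagreement table behind any particular published κ is not
  recoverable from its summary value.
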