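---
title: "Methods: location surveillance of vaping-related posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: location surveillance of vaping-related posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vapescope)
```

## The surveillance question and the estimator

Given a keyword-collected stream of vaping-related posts, we want the share
of analyzable posts that reference each of eleven location categories. The
estimand is a per-post multi-label prevalence: for category $c$,

$$\hat p_c = \frac{n_c}{N}, \qquad n_c = \#\{\text{analytic posts matching } c\},$$

where $N$ is the analytic sample — posts that survive the hygiene cascade,
contain at least one vaping gate term, and match at least one location
keyword. Because a post may name several locations, $\sum_c n_c \ge N$ and
percentages may sum above 100. Each $\hat p_c$ carries a Wilson 95% score
interval; the interval is an addition of this implementation (the
conventional reports carry none) and is flagged as such in rendered output.

The estimator is deliberately rule-based: every assignment is reproducible
from the post text and the published dictionaries, which is what makes the
numbers auditable in a regulatory context. The cost is no sense
disambiguation — "court" counts as *Correctional facility* even in a
basketball post — and no recall beyond the dictionary.

## The exclusion cascade

Six filters run in fixed order; each is a contraction (output ⊆ input) and
each emits an attrition row, so the whole chain telescopes:
$n_{\mathrm{in}}^{(1)} = n_{\mathrm{out}}^{(6)} + \sum_k n_{\mathrm{removed}}^{(k)}$.

| stage | rule | tunables (default) |
|---|---|---|
| retweet | `is_retweet` flag, else leading `"RT @"` | — |
| language | stream `lang` tag in allow-list; unknown tags fall back to a stopword-bank detector | `allowed_langs` (`"en"`) |
| bot | account rate ≥ threshold | `bot_rate_threshold` (50 posts/day); pluggable scorer |
| high-frequency | account rate > mean + k·SD | `high_freq_multiplier` (k = 2) |
| duplicate | identical whitespace-normalized text; earliest copy kept (ties by post id) | — |
| promotional | whole-word marker term, plus URL | `promo_terms`, `promo_requires_url` (TRUE) |

Design notes, where the design was genuinely open:

* **Bot detection.** Published bot classifiers for this task are
  proprietary; we ship a transparent posting-rate heuristic instead and
  expose a `bot_scorer` hook so a real classifier can be injected without
  touching the cascade. 50 posts/day is a conservative burst threshold: a
  human account sustaining it for its full active span is implausible,
  while the heuristic stays far above ordinary heavy users (a few
  posts/day).
* **"Higher than normal frequency"** is not quantified in the surveillance
  literature we follow; we use rate > mean + 2·SD over per-account daily
  rates with the *population* SD, computed after excluding accounts already
  at bot rates (otherwise bots inflate the scale and mask heavy posters).
  The inequality is strict, so a degenerate corpus where every account
  posts at the same rate flags nobody. One caveat is inherent to any
  outlier rule: it is a statistical cutoff, not a labeled property, so its
  exactness on synthetic data is a designed-in feature of the generator
  (below), not a general guarantee; and re-applying the filter to its own
  output can in principle flag new accounts as the scale shrinks. In the
  generated study conditions the separation is roughly two orders of
  magnitude, so neither effect occurs.
* **Duplicates** are text-exact after whitespace collapsing, not fuzzy
  hashing — the simplest rule consistent with "duplicate posts", and the
  only one whose recovery can be verified exactly.
* **Account activity span** is the inclusive calendar-day distance between
  an account's first and last post, clamped to ≥ 1 day, so a single-day
  burst of $m$ posts is a rate of $m$/day.

## Normalization

`strip_artifacts()` NFKC-normalizes, removes URLs (`http(s)://`, `www.`,
`t.co/`), hashtags, and @-mentions, and replaces every remaining
non-alphanumeric character (emoji included) with a space. Hashtags are
dropped *whole* (marker and word) by default — the literal reading of
"hashtags were removed" — with `keep_hashtag_words = TRUE` available because
the other reading (drop only the `#`) is also plausible; the choice
measurably changes recall, since `#school` only fires the School category
under the permissive setting.

Lemmatization is a bundled exception table (TSV, user-extensible) plus
suffix rules: regular plurals (`-ies → -y`, `-(ss|x|ch|sh|z)es → ·`,
`-s → ·`), and `-ing`/`-ed` with final-consonant dedoubling. Irregulars that
matter to the bundled dictionaries (`vaping → vape`, `drove → drive`,
`buses → bus`) live in the exception table. Rules iterate to a fixpoint,
which makes the whole pipeline idempotent — normalizing a re-joined token
sequence returns the same tokens. We chose a rule lemmatizer over a
model-based one for determinism: byte-identical reruns are a stated contract
of the pipeline, and classification only needs the closed vocabulary of the
dictionaries to normalize correctly, which the exception table pins down.

## Dictionaries and matching

The location dictionary has eleven categories in fixed order; keywords are
stored lowercase in lemma form. Matching is **whole-token**: a single-word
keyword fires only on an exact lemma-token match (so `car` never fires on
`care` or `carpet`), and a multi-word keyword fires only as a contiguous
lemma sequence (`e cigarette` matches "my e-cigarettes", not "e … cigarette"
at a distance). Substring matching was rejected because the dictionary is
full of short common words.

The vaping gate is a 26-term dictionary. Only a handful of gate terms are
fixed by the surveillance literature (vape, e-cigarette(s), juul); the
bundled list is a reconstruction from field-standard terminology and is
fully overridable via `load_lexicon()` — the lexicon file format is plain
text, designed for hand curation.

*Miscellaneous* is an ordinary category with its own keywords (place, town,
downtown, neighborhood), not a fallback bucket. Multi-label assignment is
the default because single-label assignment cannot produce category shares
summing above 100%, which location-prevalence tables in this literature do;
`first_match` mode (first matching category in dictionary order) is provided
for sensitivity analysis, and its percentages sum to ≤ 100 by construction.

## The synthetic corpus generator

`generate_corpus()` exists so that every stage has exact ground truth. Each
post receives exactly one kind: clean, or one of six contaminant kinds
resolved in priority order retweet > non-English > bot > high-frequency >
duplicate > promotional. Real streams overlap these populations;
exclusivity here is a deliberate trade of realism for exact stage-wise
recovery testing. Defaults: 10% retweets, 10% non-English, 5% each for the
other four kinds, and a clean remainder following an 11-category mixture
proportional to the prevalences reported in this surveillance literature,
with a 10.6% double-label rate (the rate implied by category shares that
sum to 110.6%).

What makes recovery exact by construction:

* Clean text = filler words from a vocabulary verified at generation time
  to share no lemma with either dictionary, plus one vaping-term surface
  and one keyword surface per planted category, every surface validated to
  normalize back to its dictionary entry. Matched categories therefore
  equal planted categories, exactly.
* Clean and low-rate contaminant posts are pooled into accounts of ~20
  posts whose first/last posts are pinned to the period endpoints, so every
  such account spans the whole year at the same low rate (~0.05 posts/day);
  remainders spill into strictly smaller accounts, keeping the maximum rate
  the majority value, which the mean + 2·SD rule can never flag.
* Bot accounts burst ~60 posts within one calendar day (≥ the 50/day
  threshold); high-frequency accounts post ~25 posts over two days
  (~12/day: above mean + 2·SD, below the bot threshold).
* Duplicates are exact copies of clean posts, one hour later, under fresh
  ids, spread round-robin over time-sorted sources so duplicate accounts
  also span most of the year.
* Non-English posts draw from small Spanish/French/German word banks and
  are tagged accordingly; promotional posts carry a marker phrase plus a
  URL; retweets carry the `RT @` prefix and flag.

What the generator does **not** emulate: linguistic realism (grammar,
slang, emoji, misspellings), overlapping contaminant kinds, near-duplicate
spam, adversarial bots with human-like rates, or keyword mentions in
negated or figurative contexts. Passing the recovery tests therefore
demonstrates that the *mechanics* of the pipeline are correct — not that
the heuristics would achieve precision/recall of 1 on real streams, where
thresholds are genuinely uncertain. One concrete corner: when heavy
accounts are absent but duplicates/promotions are present at unusual
mixtures, the mean + 2·SD rule can flag a low-rate pooled account, so exact
stage recovery is guaranteed under the documented study conditions rather
than for every conceivable spec.

## Numerical and degenerate-input choices

* Percentages render at one decimal, round-half-even.
* Wilson intervals use $z = \Phi^{-1}(0.975)$; at $n = 1$ the interval is
  [2.5%, 100%] for an observed 100%.
* Duplicate ties (identical text, identical timestamp) break by post id.
* Empty corpora: filters pass them through with zero-removal reports;
  `compute_prevalence()` errors on an empty analytic sample (there is no
  denominator), while `mixture_truth()` returns an empty table for a corpus
  with no clean posts.
* `flag_high_frequency_accounts()` requires ≥ 2 accounts (SD undefined
  otherwise); `flag_bot_accounts()` rejects empty stats.
* Timestamps are whole seconds (ISO-8601 UTC) so JSONL round-trips are
  byte-faithful; all generator randomness flows from a single integer seed,
  and identical specs yield byte-identical corpora.

## Problem sizes in the test suite

The suite validates recovery on corpora of 10,000 posts across 10 seeds
(filter cascade), matcher-vs-brute-force equality on 100 corpora of 1,000
posts, mixture recovery at n = 20,000 with and without contamination,
multi-label arithmetic at n = 5,000, and normalization idempotence on
10,000 random strings — sizes chosen to give stable statistics while
keeping a full run in a few minutes on one CPU.

## Known limitations

* Keyword prevalence is mention prevalence: a post about *not* vaping at
  school still counts toward School.
* The language fallback detector is a small stopword scorer (en/es/fr/de)
  meant for sparsely missing tags, not a general language identifier.
* The lemmatizer over-stems rare words outside the dictionaries' closed
  vocabulary (harmless to matching, visible in token output).
* Thresholds for bot and heavy-poster detection are reproducible stand-ins,
  configurable but not validated against labeled bot data.
* Real-stream prevalence tables cannot be reproduced here: the underlying
  streams are not redistributable, so all quantitative guarantees are
  stated — and tested — on synthetic ground truth.
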