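# vapescope

Lexicon-based surveillance of the locations people mention in
vaping-related social-media posts.

## The problem

Smoke-free-air policies increasingly cover e-cigarettes, but enforcement
and new policy need evidence about *where* people actually vape — schools,
workplaces, cars, bars, multi-unit housing. Public social-media streams
carry that evidence at scale: posts collected on vaping keywords routinely
mention the place where the vaping happened. Turning a raw stream into a
defensible prevalence estimate, however, requires careful hygiene (retweets,
bots, spam and duplicates dominate raw keyword streams) and a transparent,
auditable classification rule.

`vapescope` implements that workflow for tobacco-control researchers and
infodemiology practitioners, as a tested R package:

1. **Exclusion cascade** — six deterministic filters applied in fixed
   order: retweets; non-English posts (stream language tag, with a
   stopword-bank fallback detector); bot accounts (posting-rate heuristic,
   default ≥ 50 posts/day, pluggable); abnormally high-frequency accounts
   (rate > mean + k·SD over per-account daily rates, population SD computed
   after excluding bot-rate accounts, default k = 2); exact duplicate texts
   (earliest copy kept); promotional posts (marker term + URL). Every stage
   emits an attrition report (`n_in`, `n_removed`, `n_out`).
2. **Normalization** — NFKC, removal of URLs, hashtags, mentions,
   punctuation and other special characters; lowercasing; whitespace
   tokenization; deterministic rule-based lemmatization
   (`cars → car`, `vaping → vape`, `parties → party`).
3. **Rule-based classification** — a post enters the analytic sample if it
   contains at least one of 26 vaping gate terms; it is then assigned every
   location category for which at least one dictionary keyword matches a
   whole lemma token (phrases match contiguously). Eleven categories:
   social venues, living space, stores, modes of transportation, school,
   workplace, healthcare offices, eateries, correctional facility,
   religious institutions, miscellaneous.
4. **Prevalence report** — per-category share of the analytic sample,

   percent(c) = 100 · n_c / N,

   with a Wilson 95% score interval per category. Assignment is multi-label
   by default, so percentages may sum above 100; a `first_match` mode is
   available.
5. **Synthetic corpus generator** — plants labeled retweets, non-English
   posts, bot/high-frequency accounts, duplicates and promotional posts
   around clean posts drawn from a known category mixture, with a filler
   vocabulary disjoint from every lexicon. Every claim the pipeline makes
   can therefore be checked against exact ground truth.

## Worked example

```r
library(vapescope)

spec    <- corpus_spec(n_posts = 3000, seed = 7)   # 10% retweets, 10% non-English,
corpus  <- generate_corpus(spec)                   # 5% each bot/heavy/dup/promo
cascade <- run_filter_cascade(corpus)
cascade$reports
#>   stage           n_in n_removed n_out
#> 1 retweet         3000       300  2700
#> 2 language        2700       300  2400
#> 3 bot             2400       150  2250
#> 4 high_frequency  2250       150  2100
#> 5 duplicate       2100       150  1950
#> 6 promotional     1950       150  1800

prevalence <- compute_prevalence(classify_corpus(cascade$records))
prevalence
#> Analytic sample: 1800 posts from 90 users
#>    category                n_posts percent ci_low ci_high top_keywords
#>  1 Living space                333  18.5   16.8    20.4   hotel, bedroom, home
#>  2 Social venues               314  17.4   15.8    19.3   party, club, game
#>  3 Modes of transportation     286  15.9   14.3    17.7   subway, car, train
#>  4 Stores                      278  15.4   13.8    17.2   store, shop, mall
#>  5 School                      255  14.2   12.6    15.9   college, school, campus
#>  6 Workplace                   202  11.2    9.85   12.8   job, work, workplace
#>  7 Healthcare offices           37   2.06   1.49    2.82  doctor, hospital, dentist
#>  8 Eateries                     30   1.67   1.17    2.37  boba, café, diner
#>  9 Correctional facility        14   0.778  0.464   1.30  court, prison, jail
#> 10 Religious institutions        7   0.389  0.189   0.801 chapel, church, temple
#> 11 Miscellaneous               243  13.5   12.0    15.2   town, neighborhood, downtown
```

Reading the output: the cascade removed exactly the planted 1,200
contaminated posts, leaving the 1,800 clean ones; every clean post carries a
vaping term and its planted location keywords, so the analytic sample is the
full clean set. Each row gives the number and share of analytic-sample posts
mentioning that location, with its Wilson 95% interval; counts sum above
1,800 because a post naming two locations counts in both categories.
`render_report()` emits the table as Markdown/CSV/JSON, and `run_pipeline()`
drives the whole flow from a JSONL corpus file to report files plus an
attrition log.

A thin CLI wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "vapescope.R", package = "vapescope"))') \
    run --input corpus.jsonl --output-dir out/
```

## What this is not

No live stream collection or OAuth (the pipeline reads JSON-lines files),
no machine-learned classification or word-sense disambiguation ("court"
matches as a correctional facility even in a basketball context), no
geolocation, no trend analysis. See the methods vignette
(`vignettes/vaping-location-surveillance.Rmd`) for the modeling choices,
parameter defaults and known limitations.
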