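---
title: "Mining substance co-mention networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining substance co-mention networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ppminet` turns a dump of forum posts into a clustered network of
co-mentioned substances. This vignette explains the statistical model
behind each stage, the tunable parameters and their defaults, what the
synthetic corpus generator does and does not emulate, and the design
decisions that were genuinely open.

## The unit of analysis

The post is the unit everywhere. Co-occurrence means "two substances
mentioned in the same post", duplicates within a post are collapsed so
that long, repetitive posts do not carry extra weight, and the corpus
size `N` used in the PMI denominators is the number of **analyzed**
posts, including those that mention no substance at all. Substance-free
posts are informative: they shrink the marginal probabilities
`p(x) = c_x / N` and therefore raise every PMI symmetrically, which is
harmless because all downstream filters (positivity, mean-weight) are
relative. Input order is preserved throughout; no timestamp sorting is
applied.

Posts are excluded only by flair: tags on a configurable exclusion list
(default `article`, `research article`, `humor`) and untagged posts.
Matching is case-insensitive after trimming — forums are inconsistent
about capitalisation, and a filter this blunt should not depend on it.

## Entity extraction

Extraction is a deterministic dictionary matcher rather than a trained
model, which makes every downstream number reproducible from the shipped
lexicon alone. The matcher scans tokens left to right, trying the longest
n-gram (n ≤ 4) first, so multi-word surfaces ("cetirizine hydrochloride",
"vitamin d") win over their heads, and hyphenated compounds
("anti-histamines") survive as single tokens — the classical failure mode
where a matcher extracts "histamines" from "anti histamines" and inverts
the meaning is avoided for the hyphenated form. Matched stop terms
("ethanol") are consumed but never emitted.

Tokens with no exact match are linked fuzzily when they are alphabetic
and at least 4 characters long (shorter tokens produce too many false
positives). A surface links to the concept with the highest synonym
similarity, provided it reaches the threshold (default **0.85**); ties
break to the lexicographically smallest concept id for determinism.

**Similarity metric.** The default is Jaro-Winkler. The requirement that
drives this choice is behavioural, not aesthetic: at threshold 0.85,
single-typo variants of drug names must link (`ceterizine` ↔
`cetirizine`, `zyrtex` ↔ `zyrtec`) while unrelated drug names
(`famotidine` / `loratadine`) and slang abbreviations (`benzos` /
`benzodiazepine`) must not. Jaro-Winkler satisfies all four contracts;
character-3-gram Jaccard, the other classical candidate (available as
`method = "trigram_jaccard"`), scores one-substitution variants of
10-letter names around 0.5–0.6 and cannot satisfy the first two at any
threshold that still rejects the others. The metric is one swappable
function, so a different choice is a one-argument change.

**Brand normalisation.** Brand surfaces are mapped to their active
ingredient through an Orange-Book-style two-column table, with the same
fuzzy threshold. The operation is idempotent: concept ids are not brand
surfaces, so a second application is the identity.

**Negation.** Negex-style trigger rules: a mention is negated if a
pre-trigger ("no", "not", "never", "without", "stopped taking", ...)
occurs within `scope_window` tokens before it with no intervening
sentence boundary, or a post-trigger ("free") within the window after it.
Pseudo-triggers ("not only", "no increase") suppress the match. The
window defaults to 5 tokens, the classical Negex convention. Negated
mentions are excluded from all counting but written to an audit file.

**Evaluation.** `evaluate_ner()` scores micro-averaged precision, recall
and F1 over exact (span, concept) matches — the strict convention; an
overlap-based relaxation would only raise scores. Undefined ratios fall
back to 0. Intercoder reliability is Cohen's kappa over binary
substance/not-substance decisions per candidate unit; kappa is the
standard chance-corrected choice when no coefficient is otherwise
specified.

## From mentions to a network

With `c_x` the number of posts containing `x` and `c_xy` the pair count,

$$\mathrm{PMI}(x,y) = \log_2 \frac{c_{xy}\,N}{c_x\,c_y}.$$

Log base 2 is a display convention: the base rescales all weights by one
constant, and both downstream filters (positivity, relative mean) are
invariant to it. Counts are not smoothed; a pair that never co-occurs is
simply absent.

Filters apply in a fixed order: (1) substances in fewer than
`min_count = 10` posts are dropped; (2) PMI is computed among the
survivors; (3) pairs with PMI ≤ 0 are dropped (positive PMI keeps only
associations above the independence expectation); (4) pairs below the
arithmetic mean of the remaining weights are dropped, with ties at the
mean kept so a constant-weight matrix passes unchanged. The order
matters — the mean depends on which weights are still present — so it is
fixed and documented rather than left to chance. Frequency is counted at
post level (presence), consistent with the dedup rationale.

The graph keeps only nodes incident to a surviving edge, minus an
optional manual exclusion list for known false-positive nodes (the
"chlorine" problem: real chemicals that are not treatments).

## Community detection

Communities are found by an implementation of the Leiden algorithm under
weighted modularity with resolution γ:

$$Q_\gamma = \sum_c \left[ \frac{w_c}{m} - \gamma\left(\frac{d_c}{2m}\right)^{\!2} \right]$$

with `w_c` the intra-community weight, `d_c` the community strength and
`m` the total edge weight. The three phases are queue-based local moving,
refinement (each community is re-partitioned from singletons, lone nodes
merging randomly into positive-gain neighbouring refined communities,
which keeps every refined community connected), and aggregation of the
refined partition initialised with the unrefined one. Levels repeat until
nothing merges. Three robustness measures are built in, because greedy
moving alone can lodge in local optima on small graphs: the refinement
merge target is drawn uniformly among positive-gain candidates; each run
iterates the whole procedure from its own result until the objective
stops improving; and `n_restarts = 25` seeded restarts are kept, the
first from the singleton partition and the rest from random initial
partitions (the escape needed when two strongly tied nodes belong on
opposite sides of the optimal cut). Communities that still end up
disconnected are split into components, which can only raise modularity
for γ > 0. All randomness flows from one seed (default 42), so identical
inputs give identical partitions, and the caller's RNG state is never
touched.

`brute_force_best_partition()` enumerates all set partitions (up to 10
nodes) as an independent oracle; the test suite checks the implementation
against it on batches of random small graphs, and against
`igraph::modularity()` / `igraph::cluster_leiden()` as cross-checks.

**Reported modularity.** `leiden()` returns both the γ-scaled objective it
maximized (`quality`) and the same partition scored at γ = 1
(`modularity`). Summaries and manifests report the latter: the familiar
"Q ≥ 0.3 indicates meaningful structure" rule of thumb is defined on the
standard scale, and at γ = 0.6 the scaled objective of even a trivial
one-community partition is already 1 − γ = 0.4, which would make such a
threshold meaningless. The resolution only steers detection granularity.

**Resolution.** Default γ = 0.6, exposed as a knob, with
`resolution_sweep()` reporting community count and quality per γ so the
user can run the iterative selection themselves; the package does not
choose for them. Degree centrality (the reported importance measure) is
the unweighted edge count, and the clustering coefficient is the
unweighted local coefficient averaged over nodes with 0 for degree < 2.
Community labels are relabelled 0, 1, 2, ... by decreasing size for
stable reporting; top-k lists break degree ties by weighted degree, then
lexicographically.

## The synthetic corpus generator

`generate_corpus()` emulates the statistical skeleton of a
condition-specific subreddit dump: each post draws one of K latent
medication strategies and mentions each of that cluster's substances
independently with probability `p_in`, every other substance with
`p_out`. Mentions are rendered as canonical names, synonyms, brands, or
out-of-lexicon slang; a configurable fraction is wrapped in negation
triggers; posts get filler sentences (Poisson length), flair tags (some
excludable, some missing) and removable text noise (links, tabs, blank
lines) that `clean_text()` provably undoes. Gold span annotations are
emitted for posts that survive the default flair filter, split into
in-lexicon mentions, slang mentions (guaranteed recall failures —
corruption is re-drawn until the matcher genuinely finds nothing) and
negated mentions.

The reference conditions used throughout validation are 5000 posts, K = 3
clusters of 15 substances, `p_in = 0.25`, `p_out = 0.01`: roughly 4
substances per post and per-substance post frequencies in the hundreds,
comfortably above the `min_count = 10` cut, with within-cluster PMI near
+1.4 bits and between-cluster PMI negative — separations the pipeline
should recover exactly, and does in the acceptance checks (3 communities,
ARI = 1, Q ≈ 0.65). The matching null sets `p_out = p_in = 0.25`, under
which every joint probability factorizes and surviving edges are pure
sampling noise (acceptance requires Q < 0.3 there). Default author count
(640 users per 5000 posts) mirrors the posts-per-user ratio of real
condition-specific forums.

Deliberate idealisations — what passing these tests does **not** show
about real data:

* Generated substance names are single-token and mutually dissimilar
  (enforced at generation), so the generator cannot produce the
  cross-concept fuzzy collisions real drug names allow ("...
  hydrochloride" suffix families); multi-word matching is exercised by
  the packaged real-name lexicon and fixtures instead.
* Filler text is drawn from a fixed neutral vocabulary with no lexicon
  collisions, so NER precision on synthetic corpora is 1 by construction;
  real text contains lookalike words (the package's own fixture
  originally contained one: "timeline" fuzzily links to "thiamine").
* Cluster membership is uniform and mention draws independent; real
  medication strategies overlap, and prevalence is skewed.
* No temporal dynamics, no user-level behaviour, no free-text grammar —
  negations always directly precede the mention, so the scope window is
  never stressed at its boundary.

One consequence worth knowing: with background (cluster-free) substances
enabled, a single chance co-occurrence between two rare background
substances can carry PMI above the mean filter (c_xy = 1 against c_x ≈
40 gives ≈ +1.4 bits) and surface as a small extra community. That is
the method faithfully amplifying a rare coincidence — the mean-weight
filter bounds but does not eliminate it — and it is why the recovery
validation uses the background-free reference configuration.

## Numerical and degenerate-input choices

* Probabilities are plain count ratios; no smoothing anywhere.
* `c_xy > min(c_x, c_y)` is a fatal inconsistency, not a warning.
* Empty corpora, empty mention tables, empty PPMI matrices and empty
  graphs all flow through; the pipeline writes zero-count reports rather
  than failing.
* Tie-breaks are total and documented: lexicographic concept ids in
  linking, lexicographic pair names in top-pair ranking, smallest
  community label in local moving, size-then-smallest-member in
  partition relabelling. Exports sort nodes and edges by id. Two runs
  with the same config and seed are byte-identical.
* Floating-point comparisons in the optimizer use a 1e-12 slack so gain
  ties cannot oscillate.

## Problem sizes used in validation

The shipped tests and the acceptance script run the reference recovery at
5000 posts (5 generator seeds in the test suite), NER round-trips at 1500
posts, oracle comparisons on 100 random mention tables (N ≤ 200, ≤ 30
concepts) and 50 random graphs of ≤ 8 nodes per batch, and determinism on
a 400-post pipeline run — sizes chosen so the entire validation completes
in a few minutes on one CPU while keeping every binomial band (e.g.
recall within ±0.05 of 1 − oov_rate) statistically comfortable.

## Known limitations

* The dictionary matcher cannot find what the lexicon does not name; the
  packaged lexicon (~55 concepts) covers the substances most discussed in
  long-COVID self-medication but is a starting point, not a census. The
  extractor sits behind a small interface, so a model-based NER can be
  slotted in.
* The 0.85 threshold was inherited from an entity-linking score that is
  not numerically comparable to any classical string similarity; under
  Jaro-Winkler it behaves as intended on drug-name typos, but it is a
  config knob, not a law.
* PMI is variance-hungry for rare pairs (see the background-substance
  note above); `min_count` is the only guard.
* Degree centrality and unweighted clustering ignore edge weights by
  design, following the convention of the reporting they imitate.
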