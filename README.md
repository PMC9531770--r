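# ppminet

Mining substance co-mention networks from social-media self-reports.

When patients face a condition with no approved treatment — long-COVID is
the motivating case — they experiment with medications and supplements and
discuss the results in online forums. Those discussions are a passive
crowdsourcing signal for drug-repurposing hypothesis generation: substances
that patients systematically use *together* form medication strategies that
frequency counts alone cannot reveal. `ppminet` implements the full mining
pipeline for researchers in pharmacovigilance and drug repurposing who want
to run this analysis on forum post dumps, and to validate every stage of it
without any proprietary data.

## The method

1. **Ingestion & filtering.** Posts arrive as JSONL (Pushshift-style
   subreddit dumps). Posts tagged with excludable flairs (articles, humor)
   and untagged posts are removed; hyperlinks, tabs and blank lines are
   stripped from the text.
2. **Substance NER.** A deterministic dictionary matcher finds substance
   mentions by greedy longest n-gram match over a packaged lexicon
   (synonyms, brand names, stop terms). Unmatched tokens are linked
   fuzzily: a mention links to the concept with maximal string similarity
   provided it reaches the threshold *s* ≥ 0.85 (Jaro-Winkler by default),
   so `ceterizine` links to cetirizine while `benzos` is discarded. Brand
   surfaces are normalised to their active ingredient (`zyrtec` →
   cetirizine hydrochloride). Negated mentions (`"never took famotidine"`)
   are excluded by Negex-style trigger rules with a sentence-bounded scope
   window.
3. **Co-occurrence & PPMI.** With per-post duplicates collapsed, the
   pointwise mutual information of substances x, y over N analyzed posts is

   PMI(x, y) = log2( c_xy · N / (c_x · c_y) )

   where c_x is the number of posts mentioning x and c_xy the number
   mentioning both. Substances seen in fewer than 10 posts are dropped,
   only positive PMI pairs are kept (co-occurrence above the independence
   expectation), and pairs below the mean PPMI weight are pruned.
4. **Community detection.** The surviving weighted graph is clustered with
   an implementation of the Leiden algorithm (local moving, randomized
   refinement, aggregation) maximising modularity

   Q = (1/2m) Σ_ij \[A_ij − γ k_i k_j / 2m\] δ(c_i, c_j)

   at resolution γ (default 0.6). Reported Q is the standard (γ = 1) value,
   on whose scale Q ≥ 0.3 conventionally indicates meaningful structure.
   Communities are summarised by node share and top-k substances by degree
   centrality — the Table-of-clusters view used for repurposing hypothesis
   reading.
5. **Synthetic validation.** A generator plants K substance clusters in a
   Reddit-like corpus (per-post mention probabilities p_in within the
   post's cluster, p_out elsewhere; brand/synonym/slang surface rendering;
   negations; flair and text noise) together with gold annotations, so NER
   accuracy, filter arithmetic and cluster recovery are all measurable.

## Worked example

Everything below runs offline on a generated corpus with 3 planted
clusters of 15 substances (2000 posts):

```r
library(ppminet)

cfg  <- generator_config(seed = 11, n_posts = 2000, n_users = 300,
                         n_background = 0)
lex  <- generate_lexicon(cfg)
syn  <- generate_corpus(cfg, lex)
kept <- filter_by_flair(syn$corpus)

fit <- substance_network(kept, lex, min_count = 10, resolution = 0.6,
                         seed = 42)
print(fit)
#> Substance co-mention network
#>   posts analyzed: 1573 (1557 with substances)
#>   mentions: 6389 (317 negated, excluded)
#>   network: 45 nodes, 171 edges after PPMI filters
#>   communities: 3, Q = 0.666 (detected at gamma = 0.6)
```

1573 of the 2000 posts survive the flair filter; 6389 substance mentions
are extracted, of which 317 are negated and excluded. After the frequency,
positive-PMI and mean-weight filters, 45 substances remain connected by
171 edges, and Leiden at γ = 0.6 finds exactly the 3 planted communities
with standard modularity 0.666 — well above the 0.3 threshold for
non-random structure. The per-cluster report mirrors a cluster
characteristics table (shares of nodes, top substances by degree
centrality):

```r
summary(fit)
#> <network_summary> 45 nodes, 171 edges, Q = 0.666 (gamma = 0.6), avg clustering = 0.588
#>   community 0: 15 nodes (33.33%): s02_tanomo, s07_rupevi, s04_fifogifo, ...
#>   community 1: 15 nodes (33.33%): s18_zuteko, s30_zodare, s19_ninegudebo, ...
#>   community 2: 15 nodes (33.33%): s40_moketotu, s44_zokerosote, s45_vakidanu, ...
```

Extraction is exact against the generator's gold annotations when every
surface is in-lexicon:

```r
men <- fit$mentions[!fit$mentions$negated, ]
evaluate_ner(men[, c("post_id", "start", "end", "concept_id")],
             syn$gold_mentions)[1:3]
#> $precision [1] 1   $recall [1] 1   $f1 [1] 1
```

For file-based runs, `run_pipeline(pipeline_config(corpus = "posts.jsonl",
out_dir = "out"))` executes the same analysis end to end and writes
frequency/pair CSVs, a cluster summary (CSV + JSON), GEXF/GraphML graph
exports for Gephi, a negated-mention audit and a manifest with every stage
count. `inst/cli/ppminet` wraps this as a shell command with `synth`,
`run`, `sweep` and `eval-ner` subcommands.

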