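Hand computations for toy_posts.jsonl (the worked micro-corpus)
================================================================

Flair filter (excluded = {article, research article, humor}, drop untagged):
  p09 (Humor) excluded, p10 (no flair) dropped -> N = 8 analyzed posts.

Extraction (default lexicon, default negation rules), per-post sets:
  p01  {cetirizine_hydrochloride, famotidine, magnesium}   (famotidine deduped)
  p02  {cetirizine_hydrochloride, famotidine, magnesium}   (zyrtec -> brand map;
                                                            magnesium glycinate -> synonym)
  p03  {cetirizine_hydrochloride, famotidine, magnesium}   (ceterizine -> typo synonym)
  p04  {cetirizine_hydrochloride, famotidine, magnesium}   (2-token synonym match)
  p05  {melatonin}                 ("never took famotidine" -> negated, excluded)
  p06  {}                          (URL and tab removed by cleaning)
  p07  {}
  p08  {}                          (ethanol is a stop term)

Frequencies (posts containing the concept):
  c_cet = 4, c_fam = 4, c_mag = 4, c_mel = 1

Frequency filter at min_count = 2: melatonin dropped, retained {cet, fam, mag}.

Pair counts (per-post unordered pairs):
  cet-fam = 4, cet-mag = 4, fam-mag = 4

PMI with N = 8:  log2(c_xy * N / (c_x * c_y)) = log2(4*8 / 16) = log2(2) = 1.0
  (the c_x = c_y = c_xy = 4, N = 8 reference case)

Mean-weight filter: all weights equal 1.0 = mean -> all three edges kept.

Graph: triangle on {cet, fam, mag}
  degree = 2 for every node; local clustering = 1 for every node
  -> average clustering coefficient = 1.0.

Leiden at gamma = 1: single community (any split has negative modularity);
  standard modularity of the one-community triangle partition = 0.
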