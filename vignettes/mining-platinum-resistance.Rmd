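---
title: "Mining platinum-resistance genes from ovarian-cancer abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining platinum-resistance genes from ovarian-cancer abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platmine)
```

## The problem

Roughly half of ovarian-cancer patients who initially respond to
platinum-based chemotherapy (cisplatin, carboplatin) eventually relapse
with platinum-resistant disease. The genes implicated in that resistance
are scattered across thousands of abstracts, each study typically
examining a handful of candidates. `platmine` aggregates that literature
quantitatively: it treats the *sentence* as the unit of evidence and asks,
for every gene in a user-supplied lexicon, in how many sentences the gene
co-appears with both a platinum-drug term and a resistance term.

The pipeline has five stages, each usable on its own:

1. **Corpus ingest** — MEDLINE flat files are parsed into titled
   abstracts and segmented into sentences.
2. **Co-occurrence mining** — dictionary-based gene recognition plus
   fixed drug/resistance keyword sets produce a gene frequency table,
   and the same rule against subtype keywords (serous, mucinous,
   endometrioid, clear cell/OCCC) produces a gene-by-subtype count
   matrix.
3. **Enrichment** — annotation-term over-representation of the mined
   gene set under a Bonferroni-corrected hypergeometric test.
4. **Network** — the protein-interaction subnetwork induced *just among*
   frequently mined genes, ranked by degree.
5. **Clustering** — per-subtype min-max normalisation followed by
   complete-linkage agglomeration of gene profiles under the Chebyshev
   metric.

## The counting model

For each sentence $s$ and gene $g$, define the indicator

$$ X_{g,s} = \mathbf{1}\{g \text{ mentioned in } s\}\cdot
   \mathbf{1}\{\text{drug term in } s\}\cdot
   \mathbf{1}\{\text{resistance term in } s\}, $$

and the gene's count as $c_g = \sum_s X_{g,s}$. A gene mentioned several
times in one sentence contributes once; the three indicators must be
satisfied by the *same* sentence, never pooled across sentences. The drug
dictionary is `platinum, platin, cisplatin, DDP, carboplatin, CBP`; the
resistance dictionary is `resistance, resistant`. Because token
boundaries include hyphens, a single token like *cisplatin-resistant*
satisfies both dictionaries at once — a deliberate decision, since much
of the literature writes the phenotype that way.

Negation is not modelled: "TP53 did **not** confer cisplatin resistance"
counts. The count is a measure of *discussion intensity*, not of effect
direction.

### Sentence segmentation

The splitter is rule-based and deterministic: a sentence ends at `. ! ?`
followed by whitespace and an uppercase letter or digit, unless the text
ends in a known abbreviation (`vs.`, `et al.`, `Fig.`, `e.g.`, `i.e.`,
…). A trained segmenter would gain marginal recall on edge cases but
would make every downstream count depend on a model artifact;
determinism was preferred. Titles are mined along with bodies by default
(`include_title = FALSE` turns this off) — a title is part of the
retrieved record and frequently carries the study's core claim. Text is
NFKC-normalised, with typographic quotes and dashes folded to ASCII, so
typography cannot defeat whole-word matching.

### Gene recognition

Recognition is dictionary matching against a lexicon of
`gene_id / symbol / synonyms`, replacing trained NER: since mined output
must in any case be verified against a curated gene catalogue, matching
directly against that catalogue makes every count reproducible. Three
matching rules matter:

* matching is case-insensitive, **except** for all-uppercase keys of at
  most 3 characters (`CBP`, `DDP`-like symbols), which match only
  case-sensitively — otherwise such keys fire inside ordinary words and
  lowercase prose;
* word boundaries are transitions between alphanumeric and
  non-alphanumeric characters (Greek letters count as alphanumeric), so
  `p53-pathway` contains `p53` but `atp53x` contains nothing;
* overlapping candidate matches are resolved longest-first, then
  leftmost, so a key `BRCA1-associated` beats `BRCA1` on its own span.

A synonym claimed by two gene identifiers is rejected at load time;
ambiguity policy belongs in the lexicon, not in the matcher.

## Enrichment

For a query of $n$ mined genes inside a background of $N$ annotated
genes, a term annotating $K$ background genes with overlap $k$ is scored
with the one-sided hypergeometric upper tail $P(X \ge k)$, evaluated via
the log-space-stable distribution function in `stats`. Correction is
Bonferroni — $p_{\mathrm{corr}} = \min(1, m\,p)$ — with $m$ counting the
terms actually tested (those with $k \ge 1$); `m_all = TRUE` switches to
correcting over every term in the map. The background defaults to the
annotation universe rather than the genome: the union of annotated genes
is the largest set for which the draw-without-replacement model is
honest when no explicit background is supplied.

## Network stage

Interaction evidence arrives as offline edge files (2-column TSV or
PSI-MI-TAB-like with database prefixes stripped), merged as *undirected*
unordered pairs with per-file source tags, so provenance-restricted
reruns stay possible. Induction applies three filters in order: genes
mined fewer than `min_count = 3` times are excluded; only edges with
*both* endpoints among the remaining genes are kept (input nodes only,
never their neighbours); self-loops and then isolated nodes are deleted.
Degree is the only centrality computed, and the hub table uses a strict
cut (`degree > 20` by default).

## Clustering stage

Each subtype column of the gene-by-subtype matrix is min-max scaled,
$v' = (v - \min)/(\max - \min)$, so subtypes with very different
literature volumes become comparable; a constant column carries no
contrast and maps to zeros. "Maximum distance" is implemented as the
Chebyshev metric $d(u,v) = \max_i |u_i - v_i|$ and "maximum linkage" as
complete linkage — the distance between clusters is the maximum
cross-pair distance. Note the asymmetry of vocabulary in parts of this
literature: *similarity metric of maximum distance* conflates similarity
and distance; here both are distances throughout.

The agglomerator is written in the package rather than delegated to
`stats::hclust` for one reason: reproducibility requires a documented
tie-break, and `hclust`'s behaviour under exactly tied merge distances
is an implementation detail. Here, among minimum-distance cluster pairs
the pair whose (smallest-leaf, smallest-leaf) label pair sorts
lexicographically first is merged; the test suite verifies agreement
with `hclust` heights on tie-free inputs and with a naive
recompute-from-raw-vectors reference on tied ones. Leaf display order is
equally deterministic (smallest-label child left). Only genes are
clustered; subtype columns stay in fixed order.

## The synthetic corpus generator

No public corpus snapshot ships with the package, so testing rests on a
generator with planted, known structure. Per sentence and per gene,
independent Bernoulli draws decide whether the sentence carries a
gene + drug + resistance event (default rates: one strong gene at 0.3,
several intermediate genes at 0.04–0.08, decoys at 0.01); sentences
without an event may instead carry exactly one (gene, subtype) mention
pair; everything else becomes a decoy sentence that deliberately
exercises the counting rule's negatives — gene without drug, drug
without resistance, resistance alone — and the splitter's abbreviation
traps (`vs.`, `et al.`, `Fig. 3`). Default scale is 300 abstracts of 3–8
sentences; at those sizes the whole pipeline runs in about two seconds,
so calibration loops over dozens of seeds stay cheap.

One generator decision deserves emphasis: a subtype sentence carries
exactly **one** gene and **one** subtype term. Under the counting rule,
every gene in a sentence pairs with every subtype term in it, so
multi-pair sentences would smear the planted per-pair rates across
subtypes and blur the very cluster structure the defaults are meant to
plant. Likewise, the two planted subtype-specific groups
(BCL2/AKT1/STAT3 on endometrioid; ERBB2/AGR3/TNF on mucinous) have a
zero rate on the other subtypes: min-max scaling of a sparse column
turns even one or two stray counts into coordinates of several tenths,
which is exactly the noise that breaks group monophyly.

What the generator does **not** emulate: real linguistic variation
(anaphora, coordination ellipsis, novel abbreviations), ambiguous gene
symbols shared with common English words, and the long-tailed topic mix
of a real retrieval. Passing the planted-recovery tests therefore
demonstrates that the *counting machinery* is exact and that the planted
effect sizes are recoverable — not that dictionary recall on real prose
matches trained NER.

Deterministic mode plants exact counts instead of Bernoulli draws and is
used for exact assertions; stochastic mode is used for calibration-style
tests. A single seed fixes every emitted file byte-for-byte.

## Numerical and degenerate-input choices

* Merge heights are compared exactly for ties (no epsilon): tied
  distances arise from identical arithmetic on identical inputs, and the
  lexicographic rule resolves them.
* An empty mined-event set, an empty induced network, a subtype matrix
  with fewer than two rows and a corpus with no subtype words are all
  legal and propagate as empty results (the pipeline skips clustering
  below two profiles).
* `filter_by_count` keeps `count >= threshold` (the frequency-table
  convention) while `top_nodes` keeps `degree > threshold` (the hub
  table convention) — the asymmetry is intentional and documented on
  both functions.
* Query genes outside the enrichment background are dropped, with a
  message, before the query size enters the test.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_count_table` | 15 | frequency-table inclusion cut (count ≥ 15) |
| `network_min_count` | 3 | minimum count to enter the network stage |
| `min_degree` | 20 | strict hub cut (degree > 20) |
| `alpha` | 0.05 | corrected-p significance level |
| `include_title` | TRUE | mine titles along with bodies |
| `subtype_scope` | sentence | gene-subtype co-occurrence unit |

The subtype co-occurrence scope is configurable (`"sentence"` or
`"abstract"`) because either reading is defensible; sentence scope is
the default for symmetry with the drug-resistance rule.

## A worked run

```{r worked, eval = FALSE}
cfg <- synthetic_config(seed = 1)
b <- generate_bundle(cfg, "bundle")
res <- run_pipeline(pipeline_config(
  corpus = b$paths$corpus, lexicon = b$paths$lexicon,
  annotations = b$paths$annotations, edges = b$paths$edges,
  out_dir = "out"))
head(res$counts)          # gene frequency table
head(res$enrichment)      # Bonferroni-corrected term table
head(res$degrees)         # induced-subnetwork degrees
plot(as.hclust(res$dendrogram))
```

## Known limitations

* Dictionary recognition cannot find genes absent from the lexicon, and
  recall on free text is bounded by the synonym list.
* No negation, speculation or species handling; counts measure
  discussion, not direction of effect.
* Enrichment results depend entirely on the supplied annotation map and
  background; with a biased background the hypergeometric model is
  biased too.
* The interaction stage trusts the supplied edge files; no evidence-type
  filtering happens beyond what the user pre-filters.
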