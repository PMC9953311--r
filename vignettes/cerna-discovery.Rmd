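---
title: "ceRNA network discovery: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ceRNA network discovery: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The problem

Circular RNAs can act as competing endogenous RNAs (ceRNAs): by carrying
miRNA response elements they sequester ("sponge") miRNAs and thereby
de-repress the miRNAs' mRNA targets. A sponge axis therefore has a
characteristic signature in case/control expression data — the circRNA and
the mRNA move together while the shared miRNA moves the other way — and a
characteristic structural signature in target-prediction tables: the
circRNA→miRNA link and the miRNA→mRNA link must both be predicted.

`cernet` implements the standard discovery chain used in small-cohort
disease transcriptomics (the motivating application is thoracic aortic
dissection, with cohorts of 3v3 circRNA, 6v5 miRNA and 7v5 mRNA samples):

1. per-layer differential expression on log2 intensities,
2. Venn-style intersection of differentially expressed RNAs with predicted
   targets (co-miRNAs, co-mRNAs), with a multi-database support rule,
3. exhaustive enumeration of circRNA–miRNA–mRNA triplets,
4. MCODE molecular-complex detection and degree-based hub ranking on a
   protein–protein interaction (PPI) graph of the implicated mRNAs,
5. hypergeometric over-representation of the hub/module genes, and
6. single-gene ROC diagnostics of candidate markers.

Every stage is file-based (TSV / SIF / GMT / GraphML / JSON); no web
services are queried.

## Differential expression

Inputs are assumed already log2 scale, so the effect is
`logFC = mean(case) − mean(control)`. Two tests are offered:

* **Welch t** with Satterthwaite degrees of freedom — the plain two-sample
  choice.
* **Moderated t** (the default): per-feature pooled variances are shrunk
  toward a scaled inverse-chi-square prior,
  `s²_post = (d0·s0² + d·s²) / (d0 + d)`, with the statistic referred to
  `d0 + d` degrees of freedom. The prior parameters `(d0, s0²)` are fit by
  method of moments on the log variances (the mean and variance of
  `log s²` identify `s0²` and `d0` through digamma/trigamma relations; the
  trigamma is inverted by Newton iteration). This is the limma-style
  empirical-Bayes construction; with 3–7 samples per group the shrinkage
  is what makes the test usable at all. When the observed log-variances
  are *less* dispersed than a chi-square with the residual df would allow,
  the prior df is taken as infinite and all features share the common
  variance. `prior_df = 0` disables shrinkage and recovers the ordinary
  pooled t — a limiting case the tests exercise against `t.test`.

Features with zero variance in both groups but differing means have an
infinite t; they are flagged and reported with `p = 0` plus a warning
rather than dropped, since on fixed-precision array data exact ties do
occur.

The DEG gate is **strict**: `p < p_threshold` and `|logFC| >
lfc_threshold` (defaults 0.05 and 1.0). The gate uses the nominal p by
default; gating on the Benjamini–Hochberg adjusted p is a flag
(`use_adjusted_p`), because screening conventions differ and the package
does not guess which one a given study used. BH adjustment is the usual
step-up with a cumulative-minimum monotonicity pass.

## ceRNA assembly

Target tables carry `(source_id, target_id, database)` rows.
Two conventions are built in as defaults:

* circRNA→miRNA predictions from the two circRNA resources are merged by
  **union** (`min_databases = 1`) — these resources enumerate MREs rather
  than vote;
* miRNA→mRNA pairs must be reported by **all three** prediction databases
  (`min_databases = 3`, counting *distinct* database tags), the
  established false-positive control for sequence-based target prediction.

Co-sets are plain intersections: co-miRNAs = DEG miRNAs ∩ targets of DEG
circRNAs; co-mRNAs = DEG mRNAs ∩ supported targets of co-miRNAs. Triplets
are enumerated exhaustively over the filtered relations — there is no
triplet score or ranking, because none is defined for this construction —
and the ce-node sets are derived from the triplets only, so every reported
node participates in at least one complete axis.

ID matching is case-sensitive and exact by default. A normalization hook
(`normalize_mirna_id`: trimming plus `miR`/`mir` case folding) exists but
is off, because silent identifier munging is a classic source of
irreproducibility; turn it on only when you know your tables disagree in
exactly that way.

The **direction-consistency filter** (circRNA and mRNA same sign, miRNA
opposite) is available but off by default: the construction above is
direction-agnostic, and the pattern is how one *selects a headline axis*,
not how the network is defined. With the filter on, decoy triplets whose
directions are random are removed at ~75% rate while true sponge axes
survive, which is what drives the precision acceptance criterion.

One upstream study step is deliberately **not** automated: selecting a
subset of DEG circRNAs "for further study" has no stated rule, so the
pipeline accepts an optional user-supplied `circ_whitelist` instead of
guessing one.

## MCODE

`find_complexes()` reimplements the published MCODE procedure, since only
its parameters are conventionally reported:

* **vertex weight** = `k · density` of the highest k-core of the closed
  neighbourhood (vertices below `degree_cutoff = 2` weigh 0);
* **seeded expansion** in decreasing weight order; a neighbour joins while
  its weight ≥ `(1 − node_score_cutoff) · seed weight`
  (`node_score_cutoff = 0.2`), breadth-first to `max_depth = 100` (vacuous
  on small graphs, retained for fidelity); vertices are globally assigned
  at most once, so modules are vertex-disjoint;
* **post-processing**: optional fluff (off by default) runs before the
  haircut, as in the original description; the haircut is a single pass
  removing members with fewer than two in-module connections; each module
  must contain a nonempty 2-core (`k_core = 2`, the standard reading of a
  "k-score of 2"); **module score** = density × size, kept when strictly
  `> 5`.

Ties are broken deterministically everywhere (weight, then vertex name;
score, then size, then seed name), so output is reproducible by
construction. Correctness is established against exhaustive subset
enumeration on all random graphs of ≤ 8 vertices and hand-computed
K5/star/K6 cases, plus `igraph::coreness` as an independent k-core oracle.

Hub genes are ranked by plain degree with a lexicographic tie-break. In
the pipeline the ranking is taken **within the top module** (falling back
to the whole graph when no module passes), matching the practice of
reading hubs off the top module rather than the full network.

## Enrichment

Over-representation uses the upper-tail hypergeometric
`P(X ≥ k)` for `X ~ Hypergeom(N, K, n)`, summed in log space
(`lchoose` + log-sum-exp) so that large universes do not underflow; the
suite checks agreement with plain-space summation to 1e−10 up to
`N = 1000`. The universe defaults to the union of the collection's genes
and is explicit and configurable — reproducing any particular study's
printed p-values would require that study's annotation-era universe, which
is out of scope. Only terms with overlap `k ≥ min_count` (default 2) are
tested and enter the BH family; results are sorted by p.

## ROC diagnostics

AUC is computed through the Mann–Whitney identity (ties ½). Orientation is
auto-selected so AUC ≥ 0.5 and reported (`case_high`/`case_low`): a marker
that is *down* in cases is as usable diagnostically as one that is up, and
the motivating marker is down-regulated. Significance against AUC = 0.5 is
two-sided under the permutation null; it is computed **exactly** by
enumerating all `choose(n, n_case)` label assignments when that count is
≤ 2·10⁵ — which covers the small cohorts this targets (7v5 → 792
assignments), where the normal approximation is poor — and otherwise falls
back to the tie-corrected normal approximation. Full enumeration is
infeasible for, say, 100v100 even though `n_case · n_control` is only
10⁴, which is why the cut is on the combination count rather than on the
pair count.

## The synthetic world

`generate_dataset()` emulates the shape of the motivating data so the
whole chain is testable offline; it is a stated world, not a tuning knob:

| parameter | default | why |
|---|---|---|
| cohort sizes | 3v3 / 6v5 / 7v5 | the motivating studies' shapes |
| features | 1000 / 500 / 2000 | small-array orders of magnitude |
| baseline | mean 8, SD 0.3 (log2) | typical array log-intensity scale |
| effect size | 2 log2 units | the "clear DEG" regime the thresholds imply |
| planted DEGs | 20 / 20 / 40 | a few percent of each layer |
| planted axes | 5 | small, fully checkable truth |
| `db_overlap_prob` | 0.5 | a decoy pair passes the all-three rule with p³ = 0.125 |
| `decoy_pair_rate` | 0.01 | sparse background targetome |

Noise is i.i.d. Gaussian on the log2 scale — the simplest model consistent
with the t-tests downstream. Planted axes follow the sponge pattern
(circRNA down, miRNA up, mRNA down) and have their links forced into the
target tables (the miRNA→mRNA link into all three databases), which makes
the support rule discriminative by construction. The PPI fixture wires the
planted mRNAs into a clique of ≥ 8 (a clique of c nodes scores c under
MCODE, so ≥ 8 clears the score > 5 gate even after edge losses) over a
sparse Erdős–Rényi background; one gene set is enriched for the planted
mRNAs. `effect_size = 0` is explicitly legal and gives the global-null
world used for type-I calibration.

What the generator does **not** model: probe-level artifacts,
normalization, batch effects, correlated noise, or sequence-based MRE
prediction. A green end-to-end test therefore establishes that the
*algorithms* recover planted structure under clean assumptions — not that
any particular biological dataset will behave as nicely.

## Worked example

```{r example, eval = FALSE}
sim <- generate_dataset(simulation_config(seed = 7, decoy_pair_rate = 0))
dir <- tempfile()
write_fixture_bundle(sim, dir)
report <- run_pipeline(pipeline_config_for_bundle(dir, seed = 7))
report$counts$triplets      # 5: the planted axes, exactly
report$hubs                 # members of the planted clique
```

The same run is available from the shell:

```sh
Rscript inst/cli/cernet simulate --out fx --seed 7 --decoy-rate 0
Rscript inst/cli/cernet run-all --fixture-dir fx --seed 7
```

## Numerical and degenerate-input choices

* Thresholds are strict (`<`, `>`) exactly as printed conventions state
  them; a feature at `|logFC| = 1.0` is *not* a DEG.
* Zero-variance features: `t = 0, p = 1` when the groups are identical,
  `t = ±Inf, p = 0` with a warning flag otherwise.
* Empty layers propagate: an empty DEG list yields empty co-sets, an empty
  network and a complete report full of zeros rather than an error.
* Density of a single-vertex graph is defined as 0.
* The run report is audited against the emitted tables (row counts must
  match) before it is written.

## Known limitations

* Correlation-based sponge scoring (sensitivity correlation etc.) is out
  of scope; triplets are structural claims, not quantitative ones.
* The moderated test assumes exchangeable variances across features on the
  log scale; heavy probe-level artifacts violate this.
* Real GEO series matrices can be read (`read_series_matrix`), but group
  labels must be supplied by the user — GEO metadata encodes them too
  inconsistently to parse them blindly.
* MCODE's fluff stage can add vertices already assigned to other modules
  in the original tool; here fluff respects single assignment (and is off
  by default).
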