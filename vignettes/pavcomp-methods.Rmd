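---
title: "pavcomp: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pavcomp: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavcomp)
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and what the validation does and does not show.

## Presence/absence from coverage breadth

The core inference treats a gene as *present* in an unannotated query
genome when its shotgun reads blanket homologous reference coding
sequences, and *lost* when they leave them essentially untouched. The
statistic is horizontal coverage — breadth, never depth: a CDS covered end
to end by single reads scores 100 even if no base is covered twice, and a
CDS with one deeply piled-up exon-sized island scores only that island's
share. Breadth is the right statistic here because gene loss removes the
template entirely, whereas depth fluctuations reflect library and mapping
artefacts.

`union_covered_bases()` computes the size of the union of hit subject
intervals (1-based inclusive, clipped to the CDS) by a sort-and-sweep; it
is exact, and order- and duplication-independent. `horizontal_coverage()`
composes it per CDS, emitting explicit zero records for CDSs without hits
so that downstream averages are never silently truncated.

### Averaging across references and the NA policy

Per orthologue group, each reference species contributes the mean breadth
of its member genes (single-copy in the panels this is built for; with
multiple members the within-species mean is used). The group mean is then
taken **over species that have a member**: a species lacking an orthologue
says nothing about the query and counting it as 0 would conflate reference
incompleteness with query loss. Because the alternative reading (absent
reference = zero coverage) is defensible when the panel is known to be
complete, `group_mean_coverage(na_species = "zero")` switches to it; the
default is `"exclude"`.

### Thresholds and the indeterminate band

`classify_pav()` uses strict inequalities: mean < 2 % is LOST, mean > 50 %
is CONSERVED. Values in [2, 50] — including exact ties at the bounds — are
reported as INDETERMINATE rather than silently binned into either class;
the band is where partial hits (conserved domains of otherwise diverged
genes, paralogous cross-mapping) live, and surfacing it keeps the two
confident classes honest. Groups whose every species is NA become NO_DATA.
Both thresholds are arguments; the defaults are the field's published
operating point for ~40× read sets against diverged references.

## The naive mapper

`naive_map()` is a fully specified, deterministic stand-in for an external
read aligner at desk scale: exact k-mer seeds at every read offset on both
strands, ungapped full-read placement per seeded diagonal (the read must
lie wholly inside the subject), and a reported hit wherever the matched
fraction reaches `min_match_fraction`. Every passing placement is reported;
there is no best-hit selection, because the coverage union is insensitive
to redundant placements and the published pipeline describes no such
filter.

Defaults `k = 16`, `min_match_fraction = 0.8` come from divergence
arithmetic, not tuning: reads simulated from a query ~5 % diverged from the
panel ancestor, mapped against references themselves ~5 % diverged, differ
from the subject at ≈ 10 % of sites (plus 1 % sequencing error), i.e. ≈ 15
mismatches in a 150 bp read — a matched fraction around 0.9, safely above
0.8, while a 16-mer exact seed survives with high probability when
mismatches land every ~9 bp on average. Random 16-mer collisions against a
megabase-scale catalogue are rare and the extension step removes them. The
mapper is ungapped by design (the mutation model is substitution-only);
real indel-rich data needs a real aligner, whose tabular output
`read_tabular_hits()` ingests directly.

## Orthologue clustering

`build_similarity_graph()` converts all-vs-all protein hits into an
undirected graph weighted by −log10(e-value), merging reciprocal hits at
the maximum weight, dropping self-hits, and capping e-value 0 at 1e−200
(weight 200) — the conventional cap, configurable. `mcl_cluster()` is
standard Markov clustering: self-loops at each node's maximum incident
weight, column normalization, then alternating expansion (matrix square)
and inflation (elementwise power + renormalize) with pruning of entries
below 1e−5, until the matrix moves less than 1e−8. Attractor rows (positive
diagonal mass) seed clusters; overlapping attractor sets merge; any stray
node follows its largest flow. Node ids are processed in lexicographic
order, so the clustering is invariant to input permutation.

Plain MCL is used rather than the species-pair weight normalization some
orthology pipelines add on top: the downstream analyses consume the cluster
memberships, not the normalization, and the simpler algorithm is exactly
testable (disconnected components provably never merge; planted partitions
are recovered with ARI ≥ 0.95). The inflation default 1.5 follows common
orthology practice and is exposed — no published value exists for the
motivating study, so granularity must remain the caller's choice.
`select_lineage_specific()` then keeps clusters with ≥ 1 member in every
target species and none in any outgroup.

## Cross-species comparison

`build_pav_matrix()` merges computed calls for the focal species with
imported statuses for others into a rectangular group × species matrix
(missing cells NO_DATA; conflicting duplicates are an error, agreeing ones
collapse). `venn_categories()` classifies the rows where the focal species
holds the status of interest: shared by both others, shared with exactly
one (the other holding the *opposite definite* status — LOST vs CONSERVED),
unique to the focal species, and an `others_only` count for the reverse
pattern. Rows where a non-focal cell is NO_DATA or INDETERMINATE count
toward the focal total but toward none of the three sharing categories, and
are reported explicitly as `unresolved`. This is deliberate: published
lost-gene partitions of this kind do not sum to their totals, which is the
expected footprint of indeterminate cells in the non-focal species, and the
package surfaces the shortfall rather than forcing rows into categories.
"Opposite definite status" mirrors the binary lost/conserved language of
the underlying analyses — merely *not conserved* (indeterminate) never
certifies uniqueness.

`compare_domain_sets()` reduces protein-domain comparison to set identity
over opaque domain ids: IDENTICAL (equal, non-empty), NO_DOMAINS (focal
empty), DIFFERENT otherwise.

## Term enrichment

Annotations are propagated by the true-path rule along `is_a` edges only
(`propagate_annotations()`); other relation types are out of scope because
no relation policy exists for the motivating analyses and `is_a` is the
safe core. The per-term test is the exact upper-tail hypergeometric
`P(X ≥ k)` with `X ~ Hypergeom(N, K, n)` (`fisher_term_test()`, via
`stats::phyper`; the test suite checks it against direct tail summation to
1e−12 and its empirical null type-I error against binomial bounds).

`go_enrichment()` offers two modes. *Classic* tests every term
independently. *Elim* processes terms children-before-parents (reverse
topological order) and, whenever a term is significant at `elim_alpha`
(default 0.01), removes its annotated genes from all ancestors before they
are tested — decorrelating the inheritance-driven redundancy of DAG
enrichment. Raw p-values are the primary output, matching how such tables
are published; a Benjamini–Hochberg q-value column is emitted alongside but
never gates anything. Terms below `min_count` background annotations
(default 1) are skipped.

## Convergent substitution scan

`scan_convergent_columns()` calls an alignment column when (a) the
background has a strict-majority consensus residue at or above
`bg_conservation_min` (default 1.0 — full conservation; a tied majority is
*no* consensus at any threshold), (b) all foreground taxa agree
(`fg_unanimity = TRUE`; a majority-vote option exists), and (c) the
foreground residue differs from the background consensus. Gap handling is
explicit: by default any gap rejects the column; with `allow_gaps = TRUE`
gapped taxa are excluded from the fractions instead. Columns are reported
in original alignment coordinates, gaps included, so calls can be located
in the published alignment figure style directly. Partition membership
(which taxa are foreground, background, or ignored) is entirely
caller-specified — outgroups can be included in the conservation assessment
or dropped without touching the scan. The strict defaults encode the
conservative reading of a "conserved in all non-focal taxa" criterion;
relaxation is monotone (lowering `bg_conservation_min` only ever adds
calls), which the suite checks.

## The synthetic data generator

The generator produces every input the pipeline consumes, seeded and with
recorded ground truth (`sim_truth`): reference panels with single-copy
orthologue structure, query genomes with planted loss, paired-end reads,
alignments with planted convergent columns, and annotation sets with
planted term enrichment.

Model choices, fixed once:

* **Mutation**: i.i.d. per-site substitution to a uniformly chosen
  different symbol; no indels. Divergence stays analytically interpretable
  (two copies at divergence *d* from a common ancestor mismatch at
  `2d(1−d) + (2/3)d²` of sites) and coverage truth stays exact.
* **Reads**: pair count is exactly `ceiling(depth × G / (2 × read_length))`;
  fragment starts uniform over fully contained placements; constant insert
  (`insert_sd = 0`) by default so depth arithmetic is exact, normal option
  available; mate 2 reverse-complemented; constant placeholder qualities —
  nothing downstream reads qualities.
* **Intergenic spacers**: i.i.d. uniform nucleotides, lengths uniform in
  [0.5×, 1.5×] of `intergenic_length` (default 200 bp, a compact-genome
  figure chosen for desk-scale genomes; spacers exist only to separate
  genes, not to model real intergenic content).
* **Planted MSAs**: planted columns are exactly background-unanimous vs
  foreground-unanimous with different residues; non-planted columns start
  from a single shared residue and receive background noise only, so under
  strict scan settings the planted set is recoverable exactly.
* **Planted enrichment**: a single-rooted layered `is_a` DAG; leaf-term
  annotation at a baseline rate (default 0.05), with foreground odds
  multiplied by `effect_odds` at planted terms.

The validation conditions are the generator defaults: a 5-species panel of
300 groups (gene lengths uniform 300–1500 bp, interspecies divergence
0.05), 20 % planted loss, query divergence 0.05, 150 bp paired-end reads at
depth 10 with 1 % substitution error. At these settings the end-to-end LOST
call achieves sensitivity and specificity ≥ 0.95 (in practice 1.0): deleted
groups share no sequence with anything, retained groups are blanketed.

What the generator deliberately does **not** emulate — and therefore what
passing tests do not certify about real data: paralogy and repeat-driven
cross-mapping (groups descend from independent random ancestors, so the
indeterminate band is nearly empty here but is populated in real genomes),
indels and structural variation, GC and coverage bias, instrument error
profiles and quality-score structure, contamination, and incomplete or
mis-annotated reference CDS sets. The synthetic recovery result shows the
machinery is correct, not that 2 %/50 % are optimal thresholds for any
particular read set.

## Numerical and reporting conventions

* Coordinates are 1-based inclusive everywhere visible; strand-normalized
  subject intervals carry a strand flag and normalization is idempotent.
* Reported percentages round half *up* at one decimal (`round_half_up()`),
  not banker's rounding; only self-consistent published figures are used as
  checks, since mixed rounding conventions exist in the literature.
* All generators and the pipeline are deterministic given a seed;
  `run_pav()`/`run_all()` write input and output MD5 checksums into the run
  summary so reruns are verifiable byte-for-byte.
* Problem sizes in the test suite (300-group end-to-end, 100-node planted
  partitions, 1000-fixture interval oracles, 2500-draw null calibration,
  100 planted alignments) were chosen as the smallest scales at which the
  statistical assertions have comfortable margins; they complete in about a
  minute total.

## Known limitations

* The naive mapper is ungapped and exact-seeded; it is a validation device
  and a convenience, not a replacement for a production aligner on real
  reads.
* Breadth classification inherits the reference panel's quality: missing or
  truncated reference CDSs push groups toward NO_DATA/INDETERMINATE under
  the default NA policy, or toward LOST under `na_species = "zero"`.
* MCL here is the plain algorithm; pipelines that depend on species-pair
  normalized weights will partition borderline families differently.
* Enrichment p-values are as good as the annotation: sparse or biased
  annotations shift ranks, and the elim pass depends on `elim_alpha`.
* The convergence scan is column-wise and model-free: it does not
  distinguish convergence from shared ancestral polymorphism or alignment
  error, and foreground unanimity is fragile to a single poorly assembled
  foreground sequence (relax with `fg_unanimity = FALSE`).
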