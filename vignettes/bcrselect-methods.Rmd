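---
title: "Modeling antigen-specific B-cell bulk selection and antibody library construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling antigen-specific B-cell bulk selection and antibody library construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After immunization, only a minute fraction of B cells — on the order of
0.01–0.1% — recognizes the target antigen. Antibody discovery platforms
differ in how they cope with this scarcity and in what they do to the
natural pairing of heavy and kappa chains:

* **Cognate single-B-cell cloning** keeps each cell's natural heavy/kappa
  pair but scales poorly.
* **Combinatorial display libraries** amplify heavy and kappa chains in
  bulk and re-pair them at random during cloning. Built from **total IgG+ B
  cells (TBC)**, the rare specific chains are diluted into a vast excess of
  bystander chains; built from **bulk-selected antigen-specific cells
  (AgSC)**, shuffling is confined to the antigen-experienced repertoire.

`bcrselect` provides (i) a seeded generative model of this entire workflow
with full ground truth, and (ii) the repertoire informatics used to compare
the resulting clone panels: germline V assignment and CDR delineation,
clonotype uniqueness/sharing, VH/VK family pairing, six-CDR
Jukes–Cantor/neighbor-joining trees, NGS read collapsing, and
plate-screening statistics. Because no public sequence data accompany this
setting, the synthetic generator is a first-class, tested component: every
analysis stage is exercised against known truth at desk scale.

## The generative model

The simulation proceeds in the order of the laboratory workflow.

**Germline reference.** `generate_germline_reference()` synthesizes `n_vh`
heavy and `n_vk` kappa V genes (defaults 9 and 8, matching the number of
leader-sequence primer targets of the emulated platform). Genes descend
from one ancestral codon scaffold per chain, with family-level (25% of
codons) and gene-level (12% of codons) divergence drawn only from the 61
sense codons. This matters for two reasons: genes translate cleanly by
construction, and inter-gene protein distances stay far from the
Jukes–Cantor saturation bound — fully independent random genes would sit
near 95% pairwise difference, where the protein-alphabet correction
diverges. Region boundaries (FR1 25, CDR1 8, FR2 17, CDR2 8, FR3 38
codons) are fixed, in 0-based half-open nucleotide coordinates, and define
this package's CDR scheme; no external numbering system is implied. Each
chain carries a J-segment surrogate: a fixed anchor motif (`WGQG` heavy,
`FGQG` kappa) whose first occurrence after FR3 terminates CDR3 during
annotation.

**Immune response.** `simulate_immune_response()` labels each of `n_cells`
cells antigen-specific with probability `antigen_specific_fraction`
(default 5e-4, inside the 1e-4–1e-3 range above). Specific cells fall into
`n_founder_lineages` clonal lineages (default 8). A lineage fixes a founder
heavy gene, a founder kappa gene, a junctional heavy CDR3 (8–16 random
codons — CDR-H3 is where junctional diversity lives), and a
lineage-private kappa junction: the founder gene's canonical CDR3 with two
junctional substitutions. Kappa junctions are modeled as germline-proximal
(one canonical CDR3 per kappa V gene) because light chains have little
N-nucleotide addition; the two lineage-private substitutions keep clonal
identities distinct without inflating light-chain diversity. Non-specific
cells carry unmutated germline V genes with a cell-private heavy CDR3.

**Somatic hypermutation.** Lineage members accumulate per-site
substitutions at `shm_rate_cdr` (default 0.01/nt) in CDR1/2/3 and
`shm_rate_fr` (default 0.002/nt) in FR1–FR3 of both chains, encoding the
CDR bias of antigen-driven selection (`shm_rate_cdr >= shm_rate_fr` is
enforced). Substitutions that would create a stop codon are redrawn (up to
10 attempts) so every simulated clone stays expressible, as screened clones
are. Only antigen-experienced (specific) cells mutate: bystander cells are
modeled in germline configuration. The anchor motif is never mutated — it
stands in for the primer-annealed J/FR4 segment that the analyses exclude.

**Depletion and bulk selection.** `deplete_igm_igd()` removes IgM/IgD
cells (isotype is IgG with probability `igg_fraction`, default 0.1);
`simulate_selection()` then captures each specific cell with probability
`capture_efficiency` (default 0.98, i.e. ~2% loss) and each non-specific
cell with probability `nonspecific_capture_rate`. The carryover rate is the
one genuinely free parameter of the selection stage: no direct measurement
of nonspecific capture exists, so its default (2e-4) was fixed once so that
the selected pool's binder rate falls inside the 51–88% band reported for
bulk-selected wells, and is not revisited.

**Library construction and binding.** `build_library()` either keeps
cognate pairs or permutes the kappa chains uniformly across records
(heavy fixed) — equivalent in distribution to shuffling both chains, but
simpler to reason about and to test (both chain multisets are preserved).
`assign_binding()` draws antigen binding per clone: cognate specific pairs
bind with `p_bind_cognate` (0.9), shuffled both-specific pairs with
`p_bind_both_specific` (0.6), and shuffled mixed pairs bind only through a
specific *heavy* chain, with `p_bind_mixed` (0.3). Treating recognition as
heavy-chain driven is deliberate: a specific kappa re-paired onto a
bystander heavy essentially never reconstitutes the epitope surface, and
allowing such pairs to bind would let unique bystander heavy junctions leak
into the "antigen-binding" subset and invert the diversity comparison
between libraries. Binders are functional with an origin-matched
conditional (0.8 cognate, 0.5 shuffled). The monotone constraint
`p_bind_cognate >= p_bind_both_specific >= p_bind_mixed` is validated at
construction; the qualitative orderings the test-suite checks hold under
any model satisfying it.

## Annotation conventions

`assign_germline()` aligns every reference gene of a chain against the
query with match +1, mismatch −1, gap open −4, gap extend −1, germline
end-to-end and query end gaps free (the V gene is 5'-anchored; everything
3' of FR3 is handled by the anchor-motif rule). Score ties break to the
lexicographically smallest gene name so annotation is deterministic.
Identity is identical positions over the aligned germline span; queries
where no gene exceeds 0.5 are rejected as unassignable. Region boundaries
are projected through the alignment (a boundary landing in a gap or a
projected region whose length is not a codon multiple raises a frameshift
error), and CDR3 runs from the end of FR3 to the first anchor-motif
occurrence — absent motif or empty CDR3 is a per-record failure. Failing
records are retained with a reason and excluded from diversity analyses,
never silently dropped.

Clonotype keys use amino-acid region strings; FR1 and FR4 never enter any
key because degenerate amplification primers anneal there. The default VH
uniqueness key is heavy CDR1–3 plus FR2–3; the paratope key is all six
CDRs, chain-tagged. Nucleotide-level keys are not offered as a separate
switch — the nucleotide sequences are retained in all outputs, so
nucleotide-level collapsing is a one-liner on the AIRR table.

## Trees and numerical choices

Six-CDR trees concatenate heavy and kappa CDR1–3 per record; each region is
right-padded with `-` to its repertoire-wide maximum (a deterministic
region-wise alignment; no MSA is attempted since regions are already
homologous by construction). p-distances use pairwise deletion of padded
positions; the Jukes–Cantor correction uses alphabet size 20 for protein
(4 for nucleotide), `d = -((a-1)/a) log(1 - a p/(a-1))`. Saturated pairs
(`p >= (a-1)/a`) raise an error rather than being capped — a silent cap
distorts topology. Neighbor joining follows the classic Saitou–Nei
iteration with ties broken to the smallest index pair and negative branch
lengths clamped to zero without redistribution. Newick output is canonical
for the unrooted tree: anchored at the internal node adjacent to the
smallest leaf label, children ordered by smallest contained leaf, so
permuting the input yields byte-identical serializations; branch lengths
are printed at 10 significant digits to absorb permutation-order float
noise.

Percentages reported by the screening module round half-up (never
half-to-even) — integer percent for clone fractions, two decimals for cell
accounting — and the 10-fold hit-calling boundary is inclusive
(`signal >= 10 x` negative-control mean counts as a hit). Both conventions
are fixed here for determinism. The robust Z-prime uses median/MAD
(1.4826 scaling) estimators with the classical mean/SD variant behind a
flag; its masking threshold is 0.5. The Mann–Whitney p-value is exact by
enumeration when the pooled sample size is at most 12 without ties, and a
tie- and continuity-corrected normal approximation otherwise.

## What the tests show, and on what problem sizes

The acceptance suite checks, with all randomness derived from fixed seeds:

* printed worked-example arithmetic (functional-clone percentages 49/196,
  80/203, 54/75; cell-accounting percentages from the packaged example
  table) to the digit;
* neighbor joining against brute-force topology enumeration with
  least-squares fits for 5–8 taxa, and path-length additivity to 1e-9;
* Mann–Whitney exact p against full combinatorial enumeration;
  Jukes–Cantor against its closed-form inverse to 1e-12; clonotype counts
  against set-construction oracles;
* exact annotation round trips at zero mutation load and ≥99% germline
  recovery at 5% per-site mutation over 10 seeded repertoires;
* the selection-model recoveries over 50 seeded replicates at the default
  study conditions (100,000 cells per replicate): ordering of mean binder
  percentages selected > input > flow-through with the selected pool inside
  the 51–88% band, pooled flow-through loss of specific cells consistent
  with 2% by exact binomial test, and mean functional-clone fraction
  ordering cognate > combinatorial-within-AgSC > combinatorial-within-TBC;
* exact recovery of planted NGS repertoires by min-count-2 collapsing.

Replicate counts and cell numbers are the package's chosen desk-scale
study sizes; binder-percentage orderings are asserted on means across
replicates because a single replicate contains only a handful of specific
IgG cells, which is exactly the scarcity the method addresses.

Passing these tests shows the pipeline is internally consistent and that
the qualitative claims follow from the modeled mechanism. It does not
certify behavior on real repertoires: the generator has no
insertions/deletions, no affinity maturation dynamics, no class-switch or
plasma-cell compartments, no clonal expansion during panning, no primer
bias, and no sequencing-quality structure beyond singleton noise reads.
Real IgBLAST-style annotation against curated germline databases, paired
Illumina read processing, and affinity/stability measurements are all out
of scope.

## Interface

The package is driven from R: `run_pipeline()` orchestrates an end-to-end
seeded run (simulate → select → build libraries → annotate → diversity,
trees, NGS, screening summaries) and writes every table atomically with a
machine-readable manifest, and `validate_inputs()` pre-flights a
configuration without touching outputs. `scripts/acceptance.R` is the
reproducibility entry point; a subcommand shell CLI would add nothing over
these and is intentionally not shipped.

```{r example}
library(bcrselect)
res <- run_pipeline(run_config(output_dir = tempfile("run"), seed = 1))
res$tables$enrichment
```
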