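---
title: "Variant cohort browsing and Fisher association: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant cohort browsing and Fisher association: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgccraft)
```

`vgccraft` is a headless engine for browsing case–control variant cohorts:
it indexes coordinate-sorted VCF files, retrieves variants by gene, range or
batch under ALL/PASS/Pathogenic filters, joins them against a local
ClinVar-style table, tests per-variant genotype–phenotype association with
Fisher's exact test, and produces the data models behind histogram, node-graph
and heat-map views. This vignette explains the statistical model, the tunable
parameters, the numerical choices, what the synthetic-data generator does and
does not emulate, and the design decisions taken where the behaviour was
genuinely open.

## 1. The association model

For one variant, every group-assigned sample with a called genotype
contributes to one cell of a *g* × 3 contingency table: rows are the phenotype
groups, columns the genotype classes HOM_REF, HET, HOM_ALT. Conditional on the
row margins $R_i$ and column margins $C_j$, the null distribution of the table
is multivariate hypergeometric,

$$P(T) \;=\; \frac{\prod_i R_i!\; \prod_j C_j!}{N!\;\prod_{ij} n_{ij}!},$$

and the two-sided exact p-value is the probability-ordering sum
$p = \sum_{T:\,P(T)\le P(T_{\mathrm{obs}})} P(T)$.

**Assumptions.** Samples are independent; genotype classes are the diploid
trio (multi-allelic calls are collapsed by alternate-allele count — 0, 1, ≥2
alternate alleles map to HOM_REF, HET, HOM_ALT — and haploid calls count as
homozygous for their allele); missing genotypes are excluded rather than
treated as a fourth class, because the three-column table design presumes
called diploid genotypes. Both margins are held fixed (the conditional test),
which matches the hypergeometric null above. Calls with more than two alleles
are rejected with an explicit error rather than guessed at.

**Two computation routes.**

* `vgc_fisher_exact()` enumerates every table with the observed margins by
  row-wise recursion over bounded compositions, in log-factorial space. The
  enumeration budget defaults to $N \le 500$; beyond it the function refuses
  and points to the Monte Carlo route (2 × 3 tables at $N = 500$ enumerate
  roughly $10^5$ tables, well under a second).
* `vgc_fisher_mc()` draws $B$ tables from the fixed-margin null by sequential
  multivariate hypergeometric fill — row by row, each row filled cell by cell
  with vectorised hypergeometric draws against the remaining margins — and
  estimates $p = (1 + k)/(B + 1)$, where $k$ counts sampled tables with
  $P(T) \le P(T_{\mathrm{obs}})$. The default is $B = 2000$ iterations. The
  $(1+k)/(B+1)$ estimator is slightly conservative and never returns 0; its
  floor is $1/(B+1)$.

**Why both.** The Monte Carlo route is the workhorse (it scales to any margin
sizes); the enumeration route is the internal gold standard the test suite
holds it against: over 200 random 2 × 3 tables with $N \le 60$, the Monte
Carlo estimate at 20 000 iterations must fall within three binomial standard
errors of the enumerated value for at least 99 % of tables.

## 2. Numerical choices

* **Log space.** All table probabilities are computed via `lfactorial`;
  probabilities are only exponentiated for the final comparison and sum.
* **Tie tolerance.** A table counts as "at least as extreme" when
  $P(T) \le P(T_{\mathrm{obs}}) + \varepsilon$ with $\varepsilon = 10^{-12}$,
  absorbing floating-point noise in what are exactly rational quantities.
  When $P(T_{\mathrm{obs}})$ itself underflows double precision the threshold
  degenerates to $10^{-12}$; the resulting p-value is then an upper bound
  inflated by at most (number of tables) × $10^{-12}$ — conservative, and
  negligible at the enumeration budget.
* **Degenerate tables.** Zero rows/columns are removed first (they carry no
  probability mass). If one row or column remains, the margins admit exactly
  one table and the exact p is 1; the Monte Carlo route instead refuses
  (`vgc_degenerate`), and the per-variant driver `vgc_association()` reports
  such variants with `p = NA` and `reason = "degenerate"` — typical for
  monomorphic sites — rather than erroring.
* **Seeds.** `vgc_fisher_mc()` requires a seed and records it in its result.
  `vgc_association()` derives per-variant seeds as `seed + ordinal`, so a
  whole result table is reproducible from one integer, and restores the
  caller's RNG state afterwards.
* **Ranking and ties at the floor.** Any variant whose true p is far below
  $1/(B+1)$ lands exactly at the floor, so two strong variants can tie.
  Downstream "top hit" logic in the tests uses min-rank (a tied minimum
  counts as rank 1); users who need finer resolution should raise
  `iterations` or request `exact = TRUE`.
* **No multiplicity correction** is applied anywhere; the output is raw
  per-variant p-values, stated as such in the column docs.

## 3. Indexing and query semantics

The sidecar index (`info_<stem>.txt`, `index_<stem>.txt` under
`VGC_<stem>/` inside a `VGCGeneratedFiles` directory) stores, per
chromosome: the physical line span, the position span, the PASS count and the
pathogenic count. Choices the file format forced:

* **Line numbers** are 1-based over *all* physical lines, including meta and
  header lines — the most literal reading of "starting and ending lines" of a
  text file. The serialization is deliberately human-readable and diffable:
  `key=value` lines for the info file, a TSV for the index.
* **Staleness.** The info file records the source's size and mtime; a
  mismatch makes `vgc_load_index()` return "absent" (rebuild) rather than
  serve stale spans. Corrupt sidecars raise a distinct error.
* **Line-based, not byte-based.** The index stores line numbers, not byte
  offsets, so a reader of a (possibly gzipped) text stream cannot physically
  skip the preceding lines. The observable efficiency contract is therefore
  "only lines within the target chromosome's span are *parsed* into variant
  candidates"; query results expose that as a `lines_scanned` counter, which
  the tests assert never exceeds the chromosome's span.
* **Range endpoints** are inclusive on both sides; positions stay 1-based
  (as in VCF) everywhere a user sees them, with half-open arithmetic confined
  to interval internals.
* **Chromosome dialects.** `chr1` and `1` are treated as the same name (an
  optional `chr` prefix is stripped on both sides of every comparison), since
  VCFs and gene catalogs routinely disagree here.
* **PATHOGENIC filtering** requires a pathogenicity source — querying with
  the filter and no table is an explicit error, never a silently empty
  result. An index built without a table records pathogenic counts of 0 and a
  `no_pathogenicity_source` flag, and refuses pathogenic histograms.
* **Pathogenic label set.** A matched ClinVar record counts as pathogenic
  iff its significance is (case-insensitively) `Pathogenic`,
  `Likely pathogenic` or `Pathogenic/Likely pathogenic`; conflicting
  interpretations do not count. The label set is fixed here because upstream
  sources do not enumerate it.

## 4. View models

* **Histogram.** Level 0 is one bin per chromosome, read straight from the
  index. Each zoom splits the selected bin into 20 equal-width child bins,
  the last absorbing the integer remainder; ranges of width ≤ 20 collapse to
  single-position bins (the terminal level, where hover payloads carry the
  per-variant ref/alt and ClinVar significance). The bin count of 20 and the
  remainder policy are fixed for determinism — nothing in the underlying
  design prescribes a zoom arithmetic. Count conservation (children sum to
  the parent, at every level and under every filter) is a tested invariant,
  and the zoom stack makes back-navigation an exact inverse.
* **Node graph.** Bipartite: variant nodes (flagged pathogenic) and
  group-labelled sample nodes, with an edge for every HET or HOM_ALT
  genotype. HOM_REF and MISSING produce no edge — connecting reference
  genotypes would make the graph complete and uninformative. Layout and
  rendering are out of scope; the model carries exactly the labels a renderer
  needs, serializable to JSON.
* **Genotype matrix.** Variants × samples integer codes (0/1/2/−1), row
  order following the query, column order following the VCF.

## 5. The synthetic cohort generator

`vgc_simulate_cohort()` emits a VCF, phenotype TSV, gene catalog, ClinVar-style
table, GMT file and a truth manifest, all deterministic in the config seed
(byte-identical reruns). The default preset mirrors the shape of a
preeclampsia case–control exome study: 143 samples (61 cases, 82 controls),
variants clustered inside three muscle-gene-sized models including a TTN-sized
span on chromosome 2, one planted signal (case alt-allele frequency 0.8 vs
control 0.05) and three planted pathogenic loci.

**The generative model** is the simplest null-compatible choice: each locus
gets an alternate-allele frequency drawn uniformly from [0.05, 0.5] (shared
across groups unless planted), genotypes are sampled per sample under
Hardy–Weinberg at that frequency, missingness is injected independently at
rate 0.02, and FILTER is `PASS` with probability 0.85 (preset) else `q10`.
Positions are uniform within chromosomes (plus the in-gene clusters); QUAL is
uniform noise.

**What it does not emulate** — and therefore what a green test does not
establish: linkage disequilibrium between sites, realistic site-frequency
spectra or mutation-rate variation, batch effects, genotyping error
correlated with group, relatedness, population structure, indels/multi-allelic
sites (the generator emits biallelic SNVs; multi-allelic handling is tested
with hand-built fixtures instead). Tests passing on these cohorts certify the
*mechanics* (counting, indexing, the conditional test, calibration under the
stated null), not robustness to confounding in real exomes.

The truth manifest records every planted fact (loci, frequencies, per-chrom
counts), so tests assert against the configuration, never re-deriving ground
truth from the generated VCF itself.

## 6. Interfaces and scope boundaries

The CLI (`vgccraft index|info|query|export|assoc|hist|graph|simulate|plan`)
wires the modules together with flags replacing the original interactive
choices (assembly, filter, seed, iteration count — default 2000). Exports are
CSV/TSV only: of the spreadsheet dialects sometimes expected (.xlsx, .xls,
.csv, .pdf), the binary and layout formats were dropped — .xls and .pdf by
design, .xlsx additionally because no spreadsheet writer is available in the
supported dependency set; requesting them is an explicit `not supported`
error rather than a silent fallback. Filtered-VCF re-export is a non-goal.
gnomAD integration is URL construction only (never a network call), with
dataset tags configurable per assembly (`gnomad_r2_1` for GRCh37, `gnomad_r4`
for GRCh38) because gnomAD versions drift.

## 7. Known limitations

* The exact-test budget is a total-count cutoff, not a table-count estimate;
  pathological margins under the budget could still enumerate slowly for
  large *g* (the package targets *g* × 3 with small *g*).
* The Monte Carlo p-value's resolution is $1/(B+1)$; genuinely tiny p-values
  saturate at the floor (see §2 on ties).
* Under probability underflow the exact p is a slightly inflated upper bound
  (§2); callers comparing p-values below ~$10^{-300}$ should compare observed
  table probabilities instead.
* Index line numbers address the decompressed line stream; editing a VCF in
  place invalidates the index (by design, via the staleness check), and there
  is no partial re-indexing.
* Phenotype groups are unordered labels; ordinal or quantitative phenotypes
  are out of scope, as are covariate adjustment, allele-based 2 × 2 tests and
  FDR control.
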