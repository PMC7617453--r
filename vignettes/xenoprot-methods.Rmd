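---
title: "Methods: species deconvolution and niche-transfer statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species deconvolution and niche-transfer statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoprot)
```

## The scientific problem

When human tumor cells are engrafted into a mouse (a patient-derived
xenograft, PDX) and later recovered by cell sorting, mass spectrometry of the
sorted graft cells sometimes identifies proteins that can only have come from
the mouse. Because human and mouse orthologs differ in sequence, many tryptic
peptides are species-diagnostic: a peptide present in the mouse proteome but
absent from every human protein proves that the protein carrying it was made
by the host. Finding host proteins *inside* sorted graft cells — at
abundances too high to dismiss as sorting contamination — is evidence that
the microenvironment donates protein cargo (for example translation
machinery via extracellular vesicles) to the tumor.

`xenoprot` implements the computational core of that argument: in-silico
digestion of two proteomes into species-unique peptide libraries, assignment
of observed peptide evidence to species, parsimony-based protein grouping,
iBAQ quantification, and an enrichment call for candidate transferred
proteins. Around that core it provides the companion analyses such a study
needs: a moderated-t differential test for labeled nascent-proteome spectral
counts, robust standardized log2-ratios ("Zq-style"), transcript-feature
comparisons and over-representation analysis, and spatial niche-proximity
statistics for imaging data. A seeded synthetic-data module generates every
input with recorded ground truth, so all pipelines are testable end to end.

## In-silico digestion and the peptide library

Digestion uses classical trypsin specificity: cleavage C-terminal to K or R
except before proline. The proline restriction matches the defaults of the
common search engines; `rule = "trypsin/P"` removes it. Up to `max_missed`
missed cleavages are enumerated (default 2, the usual database-search
setting), and every missed-cleavage peptide is by construction the exact
concatenation of adjacent fully cleaved fragments.

Isoleucine and leucine are isobaric and indistinguishable by standard MS, so
every peptide is keyed by its I→L-collapsed sequence for uniqueness and
matching; original sequences are kept for reporting. Uniqueness is computed
over the union of *all* missed-cleavage variants of both proteomes: a
peptide unique at zero missed cleavages is not allowed to collide with a
missed-cleavage variant from the other species.

A peptide is *observable* when its length lies in 7–30 residues and its
monoisotopic mass in 700–4,600 Da. These are common working windows for what
a tryptic LC–MS/MS run can see; both are configurable. The number of
observable fully cleaved peptides of a protein is the iBAQ denominator and
the "expected" count of the observed/expected ratio; missed-cleavage
variants can be included by flag but are excluded by default, following the
standard iBAQ definition.

Non-standard residues (B, Z, X, U, O) are rejected with their position by
default; a `skip_peptide` policy instead drops the peptides containing them.

## Species assignment, parsimony grouping, and the enrichment call

Observed peptides are matched by I/L key and labeled unique-to-host,
unique-to-graft, shared, or unmatched. Protein inference is a greedy minimal
set cover: proteins that are the sole parent of an observed peptide are
forced into the cover, then proteins explaining the most unexplained
peptides are added (ties broken by total evidence, then accession). Proteins
whose observed peptides are nested inside a group's set are recorded as
subsumed members. Groups with fewer than `min_peptides = 2` distinct
peptides are dropped, mirroring the common two-peptide acceptance rule.

A group is **host-exclusive** only if *every* distinct observed peptide is
host-unique — the strictest reading of "exclusively mapping" to one species
— and conserved otherwise; a relaxed mode (at least one host-unique and no
graft-unique peptide) is available. Intensities of shared peptides are
credited in full to each containing group rather than razor-split; razor
splitting changes little at the desk scales used here and is deliberately
not the default.

Quantification is iBAQ: summed assigned intensity divided by the observable
peptide count, normalized to parts-per-million of the run total, with
`iBAQ score = log10(ppm)`. The transfer call is made within each species
class separately: a protein is *enriched* when both its iBAQ score and its
observed/expected ratio are strictly above the arithmetic class means.
Above-average-on-both is the default because it is the conjunction a
practitioner means when requiring two metrics to exceed their averages; the
alternative reading — the *sum* of the two metrics above the mean sum — is
available as `rule = "sum"`. Classes with fewer than two quantifiable members have
undefined enrichment rather than a silently degenerate threshold.

## Differential labeling and Zq standardization

Spectral-count matrices are normalized by total count to the mean column
total (a transparent stand-in for proprietary "normalized spectrum counts";
the operation is idempotent and preserves zeros). `NA` counts are replaced
by zero at load time; zeros are treated as missing on the log2 scale and
imputed per sample from `Normal(mean − 1.8·sd, (0.3·sd)²)` — the common
left-censored imputation defaults — with a mandatory seed.

The two-group test is an empirical-Bayes moderated t: per-protein residual
variances are shrunk toward a scaled inverse-chi-square prior fitted by
method of moments on the log variances, and the t statistic gains the prior
degrees of freedom. The implementation is validated against the reference
empirical-Bayes implementation in `limma` and falls back to the ordinary t
(flagged) when the prior fit is degenerate. Multiple testing uses
Benjamini–Hochberg q-values. Contrast sign convention: first-named group
minus second.

Secretome-style ratio reporting uses a deliberately simple robust
standardization: `Zq = (log2 ratio − median) / (1.4826 · MAD)`. The full
weighted hierarchical ratio model that the label "Zq" originates from is
*not* implemented; outputs carry the "Zq-style" label to make the
simplification explicit.

## Transcript features and over-representation

GC content is `100·(G+C)/(unambiguous bases)` with N excluded; U and T are
interchangeable. UTR lengths may be supplied precomputed or derived from
transcript FASTA plus a 1-based inclusive coordinate table (a zero-length
UTR is encoded by `end < start`). Two-set comparisons use the Welch
unequal-variance two-tailed t-test — the robust default when a legend says
only "unpaired two-tailed t test". Over-representation is the hypergeometric
upper tail `P[X ≥ k]` per term with BH correction across terms; annotation
databases are deliberately not bundled — the user supplies a term-to-gene
table, which keeps results database-version independent.

## Spatial niche proximity

The imaging analysis is 2-D (tissue sections; z is ignored), coordinates in
micrometres, origin arbitrary. For each query cell the Euclidean distance to
its nearest reference (niche) cell is computed; background cells are
subsampled without replacement to the query count (seeded) and given the
same treatment, and the two distance ECDFs are compared with the two-sample
Kolmogorov–Smirnov statistic `D = sup|F₁ − F₂|` (asymptotic p from the KS
limiting distribution plus a seeded permutation p) and a two-sample
Anderson–Darling statistic in its tie-safe ECDF-integral form (permutation p
only; it reduces to the classical rank formula for untied data).
Anderson–Darling appears here in its *two-sample* form: figure legends in
this field sometimes label it a normality test, but comparing observed cells
against randomly placed ones is a two-distribution question, and that is
what is implemented. No edge correction is applied, and
none is needed for the comparison design, because query and background
distances are affected identically by the field boundary.

## The synthetic-data generators

The generators are first-class, seeded, pure functions of their
configuration; every emitted record is traceable to ground truth.

* **Proteomes.** Conserved ortholog pairs are built by drawing a sequence
  from Swiss-Prot amino-acid background frequencies and applying independent
  per-residue substitutions (uniform over the other 19 residues, no indels,
  which keeps the tryptic maps of a pair alignable). Defaults: 1,900
  conserved pairs, 120 host-specific and 120 graft-specific proteins,
  substitution rate 0.12 (~88% identity, typical of human–mouse orthologs),
  log-normal lengths with median 350 residues.
* **Xenograft run.** Graft proteins draw log-normal abundances (σ = 2 on the
  natural-log scale, spanning roughly 3.5 decades — a realistic cellular
  dynamic range). Eight transferred host proteins are planted at 8× the
  median graft abundance. The remaining host-specific proteins model
  residual stromal carry-over: present at `host_background_fraction = 0.015`
  of the median graft abundance with a narrow spread (σ = 0.7), emulating
  the detectability-truncated tail of a contaminant proteome — the host
  proteins one actually sees in sorted-cell data cluster near the detection
  limit. Setting the fraction to 0 models a pure-graft control with no host
  material, which is the specificity condition: nothing may be called
  host-exclusive there. Each observable fully cleaved peptide of a present
  protein is detected with logistic probability in log10 abundance (slope
  2.5 per decade, midpoint at half the median graft abundance), and detected
  intensities carry multiplicative log-normal noise (CV 0.3). Shared
  peptides are emitted once with summed contributions.
* **Spectral counts.** Negative-binomial counts (size 4) with log-normal
  baseline means (median 30 counts), a configurable fraction of planted
  log2 effects (alternating sign), and logistic low-abundance dropout
  (midpoint 4 counts), giving ~5% missingness at the default scale.
* **Point patterns.** References and background are uniform in a
  500 × 500 µm field (40 references, 200 query, 1,000 background).
  Attraction is modeled by rejection sampling: a proposed query point at
  nearest-reference distance *d* is accepted with probability
  `exp(−d/λ)`; `λ = Inf` recovers complete spatial randomness.

What the generators deliberately do **not** emulate: post-translational
modifications, spectrum-level properties (m/z, retention time), protein
complexes and correlated abundances, paralogy within a species, indels
between orthologs, and 3-D tissue structure. Tests passing on these
fixtures therefore certify the algorithmic properties of the pipeline — not
performance on any particular real dataset, which additionally depends on
proteome release, search-engine settings, and instrument characteristics.

## Numerical choices and problem sizes

Simulation-backed checks in the test suite use the desk-scale study
conditions above: 20 evidence replicates for transfer recovery (plus 20
pure-graft controls), 50 null replicates of 1,000 proteins for test
calibration and 20 spike-in replicates for FDR, 1,000 null point patterns
(199 permutations each) for KS/AD calibration and 100 attraction patterns
for power. Permutation p-values use the add-one estimator
`(1 + #{T* ≥ T})/(n_perm + 1)`, which is valid at any permutation count.
Ties in the KS and AD statistics are handled by evaluating the ECDFs at
distinct combined values only. The greedy cover breaks ties
deterministically (evidence size, then accession), and all tabular outputs
are sorted on stable keys, so every pipeline stage is byte-reproducible from
its seeds.

## Known limitations

* Left-censored single imputation distorts calibration slightly even under
  the null: proteins containing imputed values are mildly anti-conservative
  while the imputation-inflated variances contaminate the shared
  empirical-Bayes prior, leaving the remaining proteins mildly conservative.
  At the default ~5% missingness the pooled type-I error sits near 0.048 at
  a nominal 0.05 — close enough for practice, but users testing matrices
  with heavy missingness should prefer filtering over imputation.
* The Zq-style standardization is a robust location/scale transform, not the
  full weighted hierarchical model; values are comparable within a run, not
  across laboratories.
* Host-exclusive classification is conservative by design: a single shared
  peptide demotes a protein to "conserved", so recall on proteins with few
  species-diagnostic peptides is limited by ortholog divergence.
* The spatial module assumes the reference pattern is measured without
  error and applies no edge correction; absolute distance distributions
  near field borders are biased for query and background alike (the
  *comparison* is unaffected).
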