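---
title: "Domain-centric hotspot detection: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-centric hotspot detection: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncodomains)
```

## The problem

Most somatic variants observed in sequenced tumor cohorts are rare:
they occur in one or a few patients, which leaves gene-centric
frequency tests underpowered. A domain-centric analysis borrows
strength across genes. Protein domain families are sets of homologous
sequence regions alignable to a common profile model, so a residue of
gene A and a residue of gene B that align to the same model match state
are structurally and functionally comparable. Aggregating somatic
variants from *all* genes carrying a domain onto the model's
coordinates turns many per-gene singletons into per-position counts
with real signal.

`oncodomains` implements that aggregation and the statistical test on
top of it: per domain family and cancer type, each model position
`1..L` accumulates a mutation count, and positions mutated more often
than an empirical null allows are called **oncodomain hotspots**. A
family with at least one hotspot is an **oncodomain**.

## From variant tables to position counts

1. **Variant input.** TCGA-dialect MAF tables are read with
   case-insensitive column aliasing. Default filters keep validated
   missense variants; nonsense variants can be included via
   `classes = c("missense", "nonsense")`. Silent variants are never
   counted — they do not change the protein, and their genomic rate is a
   poor surrogate for the nonsynonymous background. Duplicate reports
   of the same event (gene, patient, position, alternate residue) are
   collapsed to one.
2. **One protein per gene.** Redundant isoforms and cross-database
   duplicates are resolved by taking the longest Swiss-Prot protein per
   gene, or the longest RefSeq protein when no Swiss-Prot entry exists.
   Swiss-Prot wins regardless of length; ties break by accession so the
   choice is deterministic.
3. **Projection.** Alignments arrive as a Domain Alignment Table (one
   `M`/`I`/`D` state string per hit) or as Stockholm converted
   internally. A residue aligned to a match column inherits that model
   position; a residue in an insert column is assigned to the last
   match position before the gap; an insert *before* the first match
   state has no defined "position before the gap" and is dropped (and
   tallied). Hits with E-value above 0.001 are excluded.
4. **Pileup.** A variant contributes once to every *family* whose hits
   cover it — families are analysed independently, so an event in a
   region where two different domains overlap legitimately informs
   both. Within one family, overlapping hits (tandem repeats) would
   double-count, so the event goes to the single covering hit with the
   smallest E-value, tie-broken by leftmost start.

All coordinates are 1-based closed intervals, matching MAF and profile
HMM conventions.

## The count mixture and the local FDR

Within one family and cancer type, let `n_j` be the number of model
positions carrying exactly `j` variants (`sum(n_j) = L`). Counts are
modelled as a two-component mixture

    f(j) = p0 f0(j) + p1 f1(j)

where `f0` is the null density of non-significantly mutated positions
and `f1` the density of hotspot positions. The null is **zero-inflated
Poisson**, `ZIP(pi0, lambda0)`: most positions carry nothing (zero
inflation on top of the Poisson zero mass), the rest accumulate
passengers at a low rate. Because every position of a family aligns to
the same set of gene regions, region-level covariates (replication
timing, expression, chromatin state) are shared across positions and
cancel out of the comparison — the reason the model needs no covariate
adjustment, and the reason each family is fitted separately.

The decision statistic is the **local false discovery rate**

    fdr(t) = p0 f0(t) / f(t),

the posterior probability that a position with count `t` is null. A
position is a hotspot when `t >= 1` and `fdr(t)` is below the cutoff
(0.05 by default; 0.01 is reported alongside). A tail-area analogue
`q(t) = p0 P0(J >= t) / P(J >= t)` is also emitted for users who prefer
a q-value-style quantity, but the local fdr is the primary statistic
throughout.

### Estimation

The mixture is fitted by EM with `f1` taken as `Poisson(lambda1)`
constrained to `lambda1 >= lambda0` for identifiability. Concretely:

* **Initialisation** (deterministic): `pi0` from the excess of zeros
  over a Poisson moment estimate; `lambda0` from the mean of counts at
  or below the median non-zero count; `p0 = 0.95`;
  `lambda1 = max(2 lambda0, mean of the top decile)`.
* **E step / M step** on the count histogram, with the zero class split
  between the inflation mass and the Poisson zero inside the null
  component. The observed-data log-likelihood is recorded every
  iteration (`fit$ll_trace`) and is non-decreasing.
* **Convergence**: relative log-likelihood change below `1e-8`, at most
  500 iterations.
* **Model-selection guard.** On null-only data the constraint
  `lambda1 >= lambda0` leaves the two components interchangeable and
  the split of weight between them arbitrary, which would corrupt
  `p0`. A pure ZIP null is therefore always fitted as well, and the
  two-component fit is kept only when it beats the pure null by a BIC
  margin (log-likelihood gain above `log(N)` for its two extra
  parameters) and its signal weight amounts to at least one position
  (`p1 >= 1/N`). Otherwise the fit degrades to `p0 = 1`, where
  `fdr(t) = 1` everywhere and nothing is called.
* **Degenerate inputs**: all-zero count vectors return a flagged
  pure-zero fit; families shorter than `min_positions` (default 10) are
  skipped and recorded in the run report.
* **Numerics**: densities are computed in log space; the support is
  capped at `max(j_max, lambda1 + 10 sqrt(lambda1), 20)`, large enough
  that the neglected tail mass is below `1e-12`; raw fdr values are
  regularised by a cumulative minimum over `t >= 1`, so calls are
  nested in the count (if `t` is called, so is every `t' >= t`).

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `evalue_max` | 0.001 | alignment inclusion threshold (dimensionless E-value) |
| `cutoffs` | 0.05, 0.01 | local-fdr significance levels |
| `classes` | missense | variant classes counted |
| `min_positions` | 10 | smallest family length fitted |
| `tol`, `max_iter` | 1e-8, 500 | EM convergence control |

The 0.05 cutoff reads directly as "about 5% of called hotspots are
expected to be false"; the package's simulation checks (below) verify
that the realised false discovery proportion stays under that level.

## Conservation and enrichment

Column conservation is scored by the Shannon entropy of the amino-acid
frequencies in each match column, `H = -sum p ln p`, gaps and
non-standard residues excluded and frequencies renormalised; columns
with fewer than two residues are excluded from summaries. The
published rule flags positions "at or above the mean score plus one
standard deviation", which is meaningful only for a score that
*increases* with conservation, while entropy decreases; the package
therefore applies the rule to `C = -H` (equivalently
`H <= mean(H) - sd(H)`). No sequence weighting or window averaging is
applied — the score is the plain unweighted column entropy. When
`sd(C) = 0` the rule would flag every position, which is vacuous; the
package flags none and warns.

Overlap between hotspot positions and annotated or conserved positions
is tested with a two-sided Fisher exact test computed by hypergeometric
enumeration (zero-margin tables give `p = 1`; odds ratios use the
Haldane–Anscombe 0.5 correction when a cell is empty, for reporting
only). Feature overlap pools all analysed positions of all families
into one universe per feature, producing a single p-value per feature.
Term enrichment (e.g. GO-style gene sets) runs one 2×2 per term with
Bonferroni correction over the number of terms tested, with the family
size `m` passed explicitly. Point-biserial (Pearson) correlations are
reported alongside, since a highly significant overlap can still be a
weak correlate.

## What the synthetic cohorts emulate

The fixture generator builds a domain family (consensus sequence;
per-gene substitutions at `sub_rate`, deletions at `del_rate`,
geometric-length insertions at `ins_rate`; the first gene is always
gapless so every model position is reachable), then plants per-position
counts: null positions draw from `ZIP(pi0, lambda0)`, designated signal
positions from `Poisson(lambda1)`, and each event is materialised as a
MAF row by inverting the alignment map through a uniformly chosen
member gene. Events at one position go to *distinct* patients —
sampling patients independently could emit the identical
(gene, patient, position, alternate) row twice, which the MAF
de-duplication rule would then collapse, silently eroding the planted
count.

Defaults mirror the study conditions the statistical checks assume: a
sparse null (`pi0 = 0.3`, `lambda0 = 0.4`) against strong planted
signal (`lambda1 = 8`) on families of length 200, and the
mixture-recovery simulations use 95% `ZIP(0.3, 0.5)` with 5%
`Poisson(6)` signal. These generators emulate the *count process* and
the coordinate bookkeeping exactly, but not several properties of real
cohorts: no trinucleotide mutation context, no per-patient mutation
burden heterogeneity, no phylogenetically realistic sequence evolution,
and signal positions with rates far closer to the null than `lambda1 =
8` would be genuinely ambiguous (a position with 3–4 events over this
null has posterior null probability well above 0.05, and the method —
correctly — will not call it). Passing tests therefore demonstrate the
statistical contract and the plumbing, not performance on any real
tumor cohort.

## Verification at desk scale

The test suite checks, among others:

* false discovery proportion at cutoff 0.05, pooled over 200 families
  of 300 positions and averaged over 50 replicates, stays below 5%
  (plus two Monte-Carlo standard errors) — the same computation
  `scripts/acceptance.R` reports;
* parameter recovery over 100 replicates of 2,000 positions (mean
  absolute error of `p0` under 0.03, of `lambda0` under 10%);
* exact-test equivalence with full same-margin enumeration for every
  2×2 table of total at most 40; projection equivalence with a
  brute-force column scan over 1,000 random hits; entropy closed forms
  to `1e-9`;
* end-to-end recovery of all and only the planted hotspots on a
  five-family cohort, with byte-identical reruns.

These problem sizes were chosen so the whole suite runs in a few
minutes on one core while keeping Monte-Carlo error well below the
margins being tested.

## Cohort subsampling ("bootstrap")

`bootstrap_cohort()` repeatedly subsamples a fraction of patients (with
all their variants) or of variant events **without replacement**, then
recounts, refits and recalls. Classical with-replacement bootstrap
cannot produce a strict subset of patients, which is what "use only 75%
/ 50% of the available data" means; the subsampling design is the one
implemented, and the label "bootstrap" is kept only because it is the
established name for this experiment. On planted fixtures the mean
number of recovered hotspots is non-decreasing in the fraction — less
data, fewer discoveries.

## Known limitations

* The EM estimator is a concrete, documented choice honouring the
  `fdr(t) = p0 f0(t) / f(t)` contract; other estimators of the same
  functional exist and may differ on sparse families.
* `f1` is a single Poisson; heterogeneous signal strengths within one
  family are absorbed into an averaged `lambda1`, which can dilute very
  weak secondary hotspots.
* No covariate modelling of mutational context *within* a column
  (e.g. CpG-rich codons); the shared-covariate argument holds across
  positions, not across nucleotide contexts at one position.
* Genome-to-protein coordinate annotation, isoform-aware analysis, and
  running the profile-HMM search itself are out of scope: alignments
  and protein positions are inputs.
* CDD-style and Pfam-style model sets should be analysed as separate
  runs; the package never mixes accession namespaces inside one count
  set.
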