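---
title: "Models and methods behind capriscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind capriscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
```

capriscan analyses diploid SNP-array genotypes from structured livestock
populations: quality control, genetic structure, runs of homozygosity
(ROH) and inbreeding, linkage-disequilibrium (LD) decay and effective
population size, and haplotype-based selection scans. This vignette
explains the models the package implements, the tunable parameters and
their defaults, the synthetic-data generator used to validate every
stage, and the numerical and design choices a maintainer would want
spelled out.

```{r setup}
library(capriscan)
library(dplyr)
```

## Containers and coordinate conventions

Genotypes live in a `genotype_matrix`: a dense samples x variants matrix
of alt-allele dosages (0, 1, 2, `NA` for missing) bound to a variant map
(chromosome, 1-based physical position, two allele labels) and a sample
sheet (id, population, optional subpopulation). Phased data live in a
`haplotype_set` with two 0/1 rows per sample. Collapsing a haplotype set
by pair sums must reproduce the corresponding genotype matrix; the test
suite checks this for jointly emitted files.

All internal coordinates are 1-based inclusive (the PLINK MAP
convention); every emitted interval file (BED) is converted to 0-based
half-open on the way out. Variants on non-autosomal or unmapped
chromosomes are dropped at read time with a message. PED allele
orientation is first-observed, which is arbitrary; every squared or
absolute statistic downstream (r², IBS, MAF, HWE, ROH) is invariant to
it, and the phased VCF fixes the reference/alternative orientation that
the sign-carrying statistic (iHS) uses.

## Quality control

`apply_qc()` runs a fixed cascade — sample call rate (< 0.95 excluded,
strictly), sample identity-by-state (IBS > 0.95: the lower-call-rate
member of a pair is dropped; ties go against the lexicographically
larger id), variant call rate (< 1 excluded: any missingness), exact
Hardy-Weinberg test (p < 1e-6), minor allele frequency (<= 0.05
excluded), and greedy LD pruning (r² > 0.5 within 1 Mb) — attributing
each exclusion to the first criterion that removed it, which is what a
per-criterion exclusion table requires. The cascade order itself is a
package choice; the criteria and thresholds are the field's standard
chip defaults and all are arguments.

Three profiles wire the cascade to the downstream analyses: `structure`
(MAF + LD pruning), and `selection` / `diversity` (MAF, no pruning).
Selection scans therefore run on the MAF-filtered unpruned set.

The HWE test is the full conditional enumeration: given the observed
allele counts, all compatible heterozygote counts are enumerated, and
the p-value is the sum of the probabilities of tables no more probable
than the observed one (no mid-p adjustment). The test is exact and, by
discreteness, conservative: its null rejection rate at alpha = 0.05 sits
at or below 0.05, which the suite verifies by simulation. HWE is tested
on the dataset as given; when several populations are present the
function warns, because stratification inflates rejections
(Wahlund effect).

## Genetic structure

`pca_genotypes()` mean-centers each variant (unit-variance scaling is
available but off by default), imputes missing calls to the variant
mean, and decomposes by SVD. Variance fractions are eigenvalue shares of
the total variance. Sign is fixed by orienting each component so its
largest-magnitude loading is positive — PCA signs are otherwise
arbitrary and would break reproducibility of plots.

`admixture_em()` fits the standard admixture model: sample i's dosage at
variant j is Binomial(2, p_ij) with p_ij = sum_k q_ik f_kj, ancestry
fractions Q on the simplex and cluster frequencies F in (0,1). The
optimizer is plain EM from a random start (Q ~ normalized exponentials,
F ~ sample frequencies plus noise). EM guarantees a non-decreasing
log-likelihood, which the tests assert at every iteration; it is slower
than quasi-Newton block relaxation but transparent and entirely adequate
at desk scale. Missing cells are excluded from the likelihood rather
than imputed. Frequencies are clamped to [1e-9, 1 - 1e-9] for numerical
safety.

Cluster-count selection uses masked-entry cross-validation
(`admixture_cv_error()`): non-missing cells are partitioned into folds;
each fold is masked in turn, the model refit, and masked dosages scored
against 2 * QF by RMSE. A partition that would silence a variant
entirely is redrawn. On clean K-population data the error is minimized
at the true K; the acceptance suite checks this for the three-village
design. Masked-prediction RMSE is a deliberate, simple substitute for
tool-specific deviance-based CV; it has the same argmin behavior on
clean data, which is all that K selection uses.

Observed homozygosity (`observed_homozygosity()`) is the per-sample
fraction of non-missing calls that are homozygous; group comparisons use
the two-sided Mann-Whitney U test (exact when the smaller group has at
most 8 values and there are no ties, normal approximation with tie
correction otherwise).

## Runs of homozygosity and F_ROH

`detect_roh()` implements the consecutive-SNP method: per sample and
chromosome, maximal runs of consecutive markers containing at most
`max_opp` heterozygous calls (default 2), at most `max_miss` missing
calls (default 0), and no inter-marker gap above `max_gap_bp` (default
1 Mb); runs must reach `min_snp` markers (default 15) and
`min_length_bp` (default 1 kb). Runs are extended greedily left to
right with per-run budgets, trimmed to homozygous endpoints, and are
non-overlapping per sample; after a run closes the scan resumes
immediately after it. Segment coordinates are first-to-last marker,
inclusive, so `length_bp = end - start + 1`. The suite proves the scan
equal to a brute-force maximal-window enumeration on a thousand random
small instances.

Two parameter notes. The default `max_miss = 0` reflects the stricter
of the two conventions in circulation for this parameter; it is a
plain argument for users who want one missing call allowed. And the
1-kb minimum length is far below one typical chip gap, so in practice
the 15-SNP minimum is the binding constraint; the length rule is still
honored literally.

F_ROH follows the McQuillan estimator: the sum of an individual's ROH
lengths divided by the total autosome length, genome-wide and per
chromosome. Size classes use right-closed boundaries at 2, 4, 8 and
16 Mb.

**A caution that matters for interpretation.** The consecutive caller
with a 15-SNP minimum and a 2-heterozygote allowance has an intrinsic
false-coverage floor on data without long-range haplotype structure,
and that floor depends steeply on the per-marker heterozygosity: on
independent-site genotypes it moves by roughly a factor of two for
every 0.03 change in heterozygosity around 0.4. Estimated F_ROH is
therefore planted autozygosity *plus* this floor. The acceptance suite
keeps an absolute planted-target recovery check at face value, and it
is expected to fail on the synthetic data for exactly this reason,
while the same data show near-perfect recovery of the planted segments
themselves and a decisive group contrast. On real chip data the floor
is smaller wherever heterozygosity is higher, but a population's small
F_ROH values should never be read as precise absolute inbreeding.

ROH islands (`roh_islands()`) are maximal runs of consecutive markers
whose ROH prevalence (fraction of samples covered) reaches the
threshold (default 0.5). Runs are never merged across a prevalence dip:
"merging" here means bookended per-marker peaks only.

## LD decay and effective population size

`pairwise_r2()` computes genotypic r² — the squared Pearson correlation
of dosage vectors over jointly non-missing samples — for all
same-chromosome pairs within a window (default 1 Mb). This matches the
standard unphased-data convention; no haplotype EM is attempted.
`ld_decay_profile()` bins pairs by distance and reports the smallest bin
lower edge whose mean drops below 0.25, the conventional LD-decay
distance.

`estimate_ne_sved()` inverts Sved's relation E[r²] = 1/(alpha + 4 N_e c)
per distance bin: the bin midpoint converts to Morgans at a constant
1 cM/Mb unless another scale is given, the bin mean r² is adjusted for
sample size by subtracting 1/(2n), and N_e = (1/(4c)) (1/r²_adj − alpha)
is dated t = 1/(2c) generations ago. `alpha` is 2 (no mutation) or 2.2.
Bins whose adjusted r² implies a non-positive N_e are skipped with a
warning. No claim of parity with any particular tool's internal
corrections is made; correctness is established algebraically and by
parameter recovery on the generator (below).

## Selection scans: EHH, iHS, Rsb

For a core marker and allele, EHH at marker m is the probability that
two randomly drawn carrier haplotypes are identical at every marker
from the core to m: carriers are partitioned by their allele strings
and EHH(m) = sum_g C(n_g, 2) / C(n, 2). EHH is 1 at the core and
non-increasing outward. The walk stops at a chromosome end, at an
inter-marker gap above 1 Mb (the ROH gap constant reused), or at the
first marker where EHH falls below 0.05; that sub-threshold marker is
not emitted or integrated. The site-specific variant (EHHS) pools all
haplotypes regardless of core allele and is likewise normalized to 1 at
the core. The inner loop is compiled (Rcpp) since a genome scan
evaluates it at every marker; the suite proves it equal to brute-force
pairwise identity counting.

iHH integrates EHH over physical distance by the trapezoid rule on each
side of the core (the chip map is physical; no genetic-map scaling).
Then iHS_raw = ln(iHH_ref / iHH_alt), computed only where both alleles
have at least two carriers and the minor allele frequency reaches 0.05;
Rsb = ln(iES_pop1 / iES_pop2) from the integrated EHHS of two
populations. Raw log-ratios — not frequency-standardized scores — are
what the window stage averages; a conventional within-frequency-bin
z-standardization is available (`standardize = TRUE`) but off by
default. Antisymmetry under allele relabeling (iHS) and population swap
(Rsb) is tested to machine precision.

The scans run on the phased dataset restricted to the QC'd selection
set, with iHS further dropping markers below 0.05 minor allele
frequency within the scanned population — so EHH extension traverses
only retained markers. Windows cover 15 consecutive retained markers
and advance by 7, so neighbors share 8 markers; the window value is the
mean of its non-missing site values. Windows with fewer than 8 usable sites, and a single trailing
partial window per chromosome, are flagged and excluded from ranking.
Ranking pools all chromosomes: right-tailed p = (# >= )/N for Rsb,
two-tailed p = 2 min(# <=, # >=)/N capped at 1 for iHS, ties taking
the conservative count. With 100 distinct window values the top window
gets p = 0.01, i.e. −log10 p = 2 — the "extreme 1% tail" reading of the
significance threshold. Candidate regions require at least two
significant windows in genomic order separated by at most 100 kb
(end-to-start; overlapping windows always chain); the chain's peak
window supplies the region coordinates, and isolated significant
windows are discarded.

Two properties of this recipe deserve emphasis because they shape what
the scans can and cannot find.

* **Raw iHS needs a sign convention to window coherently.** The sign of
  ln(iHH_ref/iHH_alt) at each marker follows which allele rides the
  swept haplotype. If reference alleles are arbitrary, signs alternate
  marker to marker inside a swept region and window means cancel. The
  generator therefore emits the dataset-major allele as the reference
  (the PLINK A2-style coding); a sweep then elevates the reference-side
  iHH coherently and windowed raw iHS works as intended. Note the null
  distribution of raw iHS under this coding is not centered: the minor
  allele tends to have the longer haplotypes (carriers of a rarer
  allele are more related), a frequency dependence that the empirical
  rank p-values absorb.
* **Region-calling specificity depends on the number of ranked
  windows.** With ~400 windows the two-tailed rank threshold admits
  exactly one window per tail and chained false regions are essentially
  impossible; with thousands of windows, six or more windows clear the
  threshold and — because neighboring windows share markers — they
  cluster, so occasional false two-window chains appear even under the
  null. The suite's null-calibration study uses a two-chromosome genome
  (~370 ranked windows) where the discreteness argument is exact; on
  larger genomes users should expect, and we document, a nonzero
  false-region rate from this mechanism. Note also that below ~200
  ranked windows no window can reach p <= 0.01 at all.

## The synthetic-data generator

`sim_dataset()` generates phased, structured genotypes with known truth
so every stage above is testable without any external download. The
model is deliberately simple:

* Ancestral allele frequencies uniform on [0.05, 0.95] per marker (so
  MAF filtering does not gut the simulated chip by construction).
* Population frequencies from the Balding-Nichols model:
  Beta(p(1−F)/F, (1−p)(1−F)/F) with F the population's differentiation
  parameter; village subgroups repeat the construction around the
  population frequencies with a small F (default 0.02).
* Founder panels (default 30 haplotypes) drawn site-wise Bernoulli from
  the panel frequencies; sample haplotypes are founder mosaics that
  re-draw the founder between adjacent markers with probability
  1 − exp(−s·gap), s the switch rate (default 5e-7 per bp). Mosaic
  copying gives LD that decays with distance — E[r²](d) is approximately
  e^(−2 s d)/(K−1) for K founders — and an EHH that decays outward from
  any core, which is all the LD and EHH statistics need. A full
  coalescent simulation would be more realistic but is not required for
  these tests.
* Autozygosity is planted by overwriting haplotype B with haplotype A
  in non-overlapping segments (uniform lengths 1-8 Mb, the last
  truncated so the per-sample total matches the target exactly);
  planted segments are perfectly homozygous and recorded as truth.
* Sweeps are planted by designating the core's major allele as swept,
  choosing a fraction of its carrier haplotypes (default 0.8), and
  copying one donor carrier's alleles over exponential tracts (mean
  1 Mb per side, drawn per carrier and side). Tract-length variation
  makes EHH decay smoothly, as the iHH integrator assumes; the core
  allele frequency is unchanged, emulating an incomplete sweep.
* Finally, sites are re-oriented so the reference allele is the
  dataset-major allele (see above), and PED/MAP, phased VCF and a truth
  JSON are emitted consistently.

The default design mirrors a three-breed mountain/desert comparison:
one breed of 72 with three village subgroups and a planted F_ROH of
0.16, and two comparator breeds (40 and 30 samples) at 0.05 and 0.08,
on 4 autosomes of 50 Mb with 1000 markers each (50-kb spacing, chip
density). Differentiation defaults to F = 0.08, a realistic
between-breed value for goats.

What the generator does *not* emulate: genotyping error and missingness
mechanisms (QC's call-rate stages are exercised with planted
missingness in the tests instead), mutation, X chromosomes,
recombination-rate variation, ascertainment bias of real chips, and the
deep coalescent structure that sets real LD at long range. Passing
recovery tests on this generator therefore demonstrates the
correctness and sensitivity of the estimators under a known model, not
their field performance on any particular real breed.

Study-design sizes used by the validation suites (chosen for desk-scale
determinism): sweep recovery uses 4 chromosomes x 1500 markers x
100 Mb — post-QC spacing ~70 kb, so a 15-marker window spans ~1 Mb —
with 60 samples; the null calibration uses two such chromosomes; N_e
recovery uses 100 samples on 2 x 50 Mb with the analytic calibration
N* from the mosaic LD curve above; the admixture design uses three
villages of 15 at F = 0.3.

## Numerical choices and edge cases

* HWE: log-factorial arithmetic, renormalized in probability space; the
  observed table's probability is compared with a 1 + 1e-12 slack so
  ties of equal-probability tables are included.
* EM: likelihood clamps at 1e-9; convergence when the gain drops below
  1e-4 or at 300 iterations.
* PCA on constant variants: centering leaves zero columns, which
  contribute nothing; unit-variance scaling maps zero SDs to 1.
* r² for pairs involving a monomorphic vector is undefined and the pair
  is skipped; LD pruning treats such pairs as uncorrelated.
* ROH islands on an empty segment table return an empty tibble, not an
  error; size-class fractions of an empty table are zero with an
  `empty` attribute.
* Rank p-values require at least two usable windows; flagged windows
  get `NA` p-values and never enter N.
* All generator functions take explicit seeds and restore the caller's
  RNG state; identical configs give byte-identical emitted files.

## Known limitations

* The admixture EM can converge to local optima on difficult data; K
  selection re-fits per fold from fold-specific seeds, which provides
  some robustness, but a production analysis should compare several
  starts.
* Raw (unstandardized) windowed iHS inherits the frequency dependence
  described above; the rank p-values are calibrated genome-wide, not
  per frequency class.
* F_ROH carries the detector's false-coverage floor discussed above.
* The Sved inversion assumes the constant-recombination map it is
  given; no phase correction or bin weighting beyond the 1/(2n) sample
  adjustment is applied.
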