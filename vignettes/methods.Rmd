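---
title: "Methods: simulation, marker validation and hierarchical diversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, marker validation and hierarchical diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecotypeSNP)
```

`ecotypeSNP` implements the computational workflow behind a fixed-content
Infinium-style SNP genotyping array for a structured plant collection:
probe selection from transcriptome variant calls, marker validation of
the array data, and population-structure analysis (PCA of allele
frequencies, geographic correlation, hierarchical AMOVA).  Because array
intensity data cannot ship with a source package, a calibrated synthetic
generator with exact ground-truth records stands in for every input, so
each stage of the workflow can be tested against planted truth.

## 1. The genotype simulator

### Hierarchical allele frequencies

Genotypes are biallelic calls `AA`, `AB`, `BB` or `NC` (no call) for
individuals sampled from accessions (populations) nested in regions.
Allele frequencies follow a two-level Balding–Nichols beta hierarchy.
For marker $m$ an ancestral frequency is drawn as
$p_{0m} \sim U(0.1, 0.9)$; the region frequency is

$$p_{rm} \sim \mathrm{Beta}\!\left(p_{0m}\tfrac{1-F_{RT}}{F_{RT}},\;
 (1-p_{0m})\tfrac{1-F_{RT}}{F_{RT}}\right),$$

so that $E[p_{rm}] = p_{0m}$ and
$\mathrm{Var}[p_{rm}] = F_{RT}\,p_{0m}(1-p_{0m})$, and the accession
frequency $p_{am}$ is drawn the same way around $p_{rm}$ with
concentration parameter $F_{PR}$.  $F = 0$ is an exact pass-through.
Individuals are sampled under Hardy–Weinberg:
$\text{A-count} \sim \mathrm{Binomial}(2, p_{am})$.  Missing calls are
injected independently at the configured rate.

### Calibrating the targets to the Phi scale

The package's AMOVA (Section 4) operates on squared Euclidean distances
between *genotype* encodings, i.e. a codominant individual-level
distance.  For Hardy–Weinberg binomial sampling the within-accession
variance on this scale is half the allele-count variance, which
*inflates* the realized Phi relative to the beta parameter: with a
literal parameterisation one obtains $E[\Phi_{PT}] \approx 2F/(1+F)$,
not $F$.  Because users state targets on the Phi scale (the scale on
which results are reported), `sim_params(f_rt =, f_pr =)` are treated as
*target Phi values* and the internal beta concentrations are calibrated:

$$F_{PR} = \frac{f_{pr}}{2 - f_{pr}}, \qquad
  c = \frac{1 + F_{PR}}{2}, \qquad
  F_{RT} = \frac{f_{rt}\,c}{1 - f_{rt} + f_{rt}\,c}.$$

The first identity inverts $\Phi = 2F/(1+F)$ at the accession level; the
region-level correction accounts for the accession-level variance
already present below each region.  With this calibration the realized
statistics recover the targets: over ten seeds of the default study
design the mean realized $\Phi_{RT}$ and $\Phi_{PR}$ sit within a few
thousandths of the requested 0.08 and 0.25 (see
`tests/testthat/test-acceptance.R`).

### Geographic clines

A configurable fraction of markers is *clinal*: the accession frequency
is tilted on the logit scale by
$\mathrm{logit}(p) \mapsto \mathrm{logit}(p) + \beta z$, where $z$ is
the accession's standardised longitude or latitude and $\beta$ the
`cline_strength`.  Two thirds of clinal markers follow longitude and one
third latitude.  The asymmetric split is deliberate: with an equal split
the two cline eigenvalues of the frequency covariance are nearly equal
and the leading principal components mix the two axes; the 2:1 split
makes the east–west gradient dominate PC1 and the north–south gradient
PC2, which is the regime the analysis functions are designed to detect.

### Ancillary generators

* `gen_mapping_family()` draws two parents and $n$ progeny by allele
  transmission, optionally injecting genotyping errors.  The truth
  record marks each injected error as *detectable* (Mendelian-impossible
  given the parents) or not; trio screening must recover exactly the
  detectable ones.
* `gen_variant_report()` builds contigs with SNPs planted on a position
  grid that satisfies spacing and flanking constraints, then sabotages
  chosen SNPs so that each one fails exactly one probe-design filter;
  the expected survivor set is exact.
* `gen_cluster_stats()` and `gen_qc_cascade_fixture()` plant
  cluster-quality failures and marker-validation failures with known
  counts.

## 2. Probe selection

`design_panel()` applies, in order, attributing each lost marker to the
first stage that drops it:

1. **Variant filters** (per observation, inclusive thresholds): read
   coverage ≥ 50, SNP quality ≥ 30, neighbourhood quality ≥ 20, variant
   frequency ≥ 25 %, and no non-specific mapping flag.  A marker is lost
   only when all of its per-source observations are lost.
2. **Shared polymorphism**: the marker (contig, position, allele pair)
   must be observed in ≥ 2 distinct source genotypes.
3. **Annotation**: contigs with a duplicated BLAST subject (frameshift
   evidence) or an organellar/retroelement keyword hit are removed;
   unannotated contigs pass.
4. **Spacing**: both members of any within-contig pair closer than
   50 bp are removed (a distance of exactly 50 passes).
5. **Flanking sequence**: each side takes
   $\min(\text{preferred} = 60, \text{available})$ bases; a side with
   fewer than 50 available rejects the candidate.  The probe target is
   rendered `LEFT[A1/A2]RIGHT` with alleles in alphabetical order.
6. **Designability**: score ≥ 0.6.

## 3. Marker validation

`run_qc()` applies a telescoping cascade, attributing every marker to
its first failing stage: cluster-quality triage (fail when any occupied
cluster's mean intensity < 0.2 or the cluster separation < 0.3; review
band [0.3, 0.45)), missingness (> 10 % removed), Mendelian trio errors
against the mapping family (> 4 errors removed), minor allele frequency
(< 5 % removed) and heterozygote excess.

The heterozygote-excess test is exact.  Conditional on $n$ individuals
and allele count $n_A$, the heterozygote count $h$ follows the Levene
distribution

$$P(h \mid n, n_A) = \frac{n!}{n_{AA}!\,h!\,n_{BB}!}\,2^h\,
 \frac{n_A!\,n_B!}{(2n)!}$$

over the admissible $h$ (parity of $n_A$, at most $\min(n_A, n_B)$).
The one-sided excess probability $P(h \ge h_{obs})$ is computed per
accession (skipping accessions where the marker is monomorphic or
uncalled) and combined across the $k$ informative accessions with
Fisher's method, $X^2 = -2\sum_i \ln P_i$ on $2k$ df.  Markers with a
combined probability below 0.5 are removed — a deliberately aggressive
threshold, appropriate for screening paralogous loci whose collapsed
signals masquerade as heterozygotes.

## 4. Diversity and AMOVA

### Encoding and PCA

Calls are encoded per allele: for the A column `AA` → 1, `AB` → 0.5,
`BB` → 0 (and mirrored for B); `NC` contributes 0 to both columns and is
not imputed.  Accession allele frequencies average these columns over
all individuals of the accession (missing calls stay in the
denominator; `adjust_missing = TRUE` switches to called-only
denominators).  PCA centres the frequency columns and takes the SVD;
scores are $U D$, and each component's sign is fixed so its
largest-magnitude loading is positive.  `correlate_pc_with_geography()`
reports the Pearson $r$, $R^2$ and a two-sided $t$-based P value;
`top_loading_markers()` collapses each marker's two allele columns to
the larger absolute loading.

### Distance-based AMOVA

Under the encoding, squared Euclidean distances between individuals take
the values 0, 0.5 or 2 per marker (`AA` vs `AB` = 0.5, `AA` vs `BB` =
2).  Sums of squares come from the standard distance identity
$SS(g) = \sum_{i<j \in g} d^2_{ij} / n_g$; for three strata (regions $R$,
accessions $P$, individuals $N$) the mean squares are equated to their
expectations with the unbalanced-design coefficients

$$n_1 = \frac{N - A}{P - R}, \quad
  n_2 = \frac{A - \sum_p n_p^2 / N}{R - 1}, \quad
  n_3 = \frac{N - \sum_r N_r^2 / N}{R - 1},
  \qquad A = \sum_r \frac{\sum_{p \in r} n_p^2}{N_r},$$

giving components $\sigma^2_{WP} = MS_{WP}$,
$\sigma^2_{AP} = (MS_{AP} - MS_{WP})/n_1$ and
$\sigma^2_{AR} = (MS_{AR} - MS_{WP} - n_2\,\sigma^2_{AP})/n_3$, and

$$\Phi_{RT} = \frac{\sigma^2_{AR}}{\sigma^2_{tot}}, \qquad
  \Phi_{PR} = \frac{\sigma^2_{AP}}{\sigma^2_{AP} + \sigma^2_{WP}}, \qquad
  \Phi_{PT} = \frac{\sigma^2_{AR} + \sigma^2_{AP}}{\sigma^2_{tot}}.$$

Negative components are reported raw but truncated at zero for
percentages and Phi; an all-zero decomposition is flagged as degenerate
rather than returning `NaN`.  The implementation is cross-checked in the
test suite against an independent group-mean decomposition at $10^{-9}$
tolerance.

Permutation P values use the conventional schemes: $\Phi_{PT}$ permutes
individuals among accessions, $\Phi_{PR}$ permutes individuals among
accessions within their region, and $\Phi_{RT}$ permutes whole
accessions among regions; $P = (\#\{ \Phi^* \ge \Phi \} + 1)/(B + 1)$,
with $B = 999$ by default (smallest attainable P: 0.001).

## 5. Worked example

```{r example, eval = FALSE}
p <- study_design_params(n_markers = 500, seed = 1)
sim <- gen_hierarchical_genotypes(p)
enc <- encode_genotypes(sim$genotypes)
reg <- sim$accession_info$Region[match(accession_of(sim$genotypes),
                                       sim$accession_info$ID)]
amova_nested(enc, regions = reg, n_perm = 99)

freqs <- accession_allele_frequencies(enc)
pca <- pca_frequencies(freqs, 4)
correlate_pc_with_geography(pca, sim$accession_info, 1, "longitude")
```

The end-to-end pipeline, including artifact files and a manifest with
MD5 hashes, is available as `run_pipeline()` (and as the thin wrapper
script in `inst/cli/ecotype.R`); `validate_config()` checks a
configuration without running anything.

## 6. Problem sizes and numerical choices

The default study design — 4 regions, 90 accessions (12/45/16/17 per
region), 8 individuals per accession with one accession of 4 (716
individuals), 2185 validated markers — and the default thresholds above
are the package's reference configuration; every one of them is a plain
configuration value that can be overridden.  Numerical choices worth
noting: the Levene pmf is computed with log-factorials and exponentiated
once (exact to ~$10^{-14}$ up to the sample sizes used); exact-test
probabilities are memoised over unique genotype-count triples, so the
cascade cost scales with the number of distinct counts rather than
markers × accessions; distance matrices are formed via `tcrossprod`
with negative round-off clamped at zero; PCA discards singular values
below $10^{-12}$ of the largest.

## 7. Limitations

The generator emulates the statistical *shape* of an array study — beta
hierarchy, Hardy–Weinberg sampling, uniform missingness, single-filter
probe violations — not array chemistry: there are no intensity-space
cluster models (cluster statistics are generated directly), no linkage
disequilibrium between markers, no null alleles, and genotyping errors
in the mapping family are injected uniformly rather than
intensity-dependent.  The exact heterozygote test is one-sided toward
excess by design; it will not flag heterozygote deficits.
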