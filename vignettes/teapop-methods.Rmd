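---
title: "Methods: filtering, diversity, sweep scanning and dating in teapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filtering, diversity, sweep scanning and dating in teapop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teapop)
```

teapop implements the population-genomic core of a tea-plant
(*Camellia sinensis*) resequencing analysis as a reusable, tested R
package: strict SNP filtering, windowed diversity statistics, LD decay,
a composite-likelihood selective-sweep scan with region merging, and
Ks-based molecular dating. This vignette is the package's account of the
underlying models, the choices made where the design was genuinely open,
and what the synthetic-data tests do and do not demonstrate.

## The data model

Everything flows through a *site table*: a tibble with one row per VCF
record, site-level columns (`chrom`, `pos`, `ref`, `alt`, `qual`, the
five INFO annotations `qd`, `fs`, `mq`, `mq_rank_sum`,
`read_pos_rank_sum`, `is_indel`) and two matrix columns holding
per-sample genotype strings (`gt`) and read depths (`dp`). Coordinates
are 1-based inclusive, matching VCF and GFF3; conversion to BED's
0-based half-open convention happens only at the `write_bed()` boundary
(`start - 1`, end unchanged), which makes the round trip an exact
bijection. Genotypes are unphased: `0/1` and `1/0` are identical, and
phase separators are normalised away on input. Every downstream
statistic here is phase-free; r² deliberately uses genotype dosages (see
below).

A deliberate asymmetry in missing-data handling: an *absent INFO
annotation does not fail* its hard-filter condition (rank-sum
annotations are undefined at sites without both ref and alt reads, so
absence is not evidence against a site), whereas a *missing QUAL fails*
the consensus-quality criterion, because quality is the subject of that
criterion rather than a side condition.

## The strict filter cascade

`filter_cascade()` applies the GATK-style hard filter
(QD ≥ 2.0, FS ≤ 60.0, MQ ≥ 40.0, MQRankSum ≥ −12.5,
ReadPosRankSum ≥ −8.0) and then five criteria in a fixed order:

1. *indel proximity*: a SNP survives only if no indel record lies within
   5 bp (|snp − indel| < 5 removes it; exactly 5 bp survives). The indel
   anchor is its POS field, the simplest defensible reading; a span-aware
   mode would be a straightforward extension.
2. *consensus quality* ≥ 40;
3. *biallelic SNP*: exactly one alternate allele, all alleles length 1;
4. *depth percentile*: the 2.5th–97.5th percentiles of per-site total
   depth, computed by linear interpolation (`stats::quantile` type 7)
   over exactly the candidate set that reaches this step, bounds
   inclusive. Reading the band as per-site total depth across all
   candidates is the only interpretation consistent with a genome-wide
   "2.5 to 97.5%" band; the bounds are reported in the filter report so
   the choice is auditable. Genome-wide rather than per-chromosome
   bounds are the default; on the synthetic single-chromosome data the
   two coincide.
5. *minor allele frequency* ≥ 0.01, computed over called genotypes only.

All thresholds are inclusive exactly as the comparison operators are
printed. The cascade is *reported*: each step records its input and
output counts, so survivors of step *i* are provably the input of step
*i+1* and counts are monotone non-increasing. The per-site criteria
(quality, biallelic, MAF) commute; the set-dependent ones (indel
proximity, depth percentile) are order-sensitive, which is why the order
is fixed.

`select_for_structure()` implements the downstream site selection:
missingness ≤ 20%, then thinning so no two sites fall within 2000 bp.
Thinning is a greedy left-to-right minimum-spacing walk — deterministic
and order-independent of ties — with a fixed-bin alternative behind
`mode = "bins"`, since the phrase "no two sites within the same 2000-bp
region" admits both readings.

## Diversity statistics

*Heterozygosity.* Population heterozygosity at a site is the fraction of
heterozygous individuals among called individuals; window values
(40-kb windows, 20-kb step) are means of defined site values, and
windows with mean per-sample depth < 1 are removed. Individual
heterozygosity is the fraction of called loci at which a sample is
heterozygous.

*Nucleotide diversity.* Windowed π (50 kb / 10 kb) sums the unbiased
per-site pairwise difference `2·n_alt·(n_tot − n_alt)/(n_tot·(n_tot −
1))` and divides by window length in bp. No accessible-length correction
is attempted — the denominator is the full window span, the convention
of the windowed VCFtools-style estimator this mirrors.
`subsampled_pi()` implements the equal-sample-size protocol: 8 samples
drawn without replacement, 20 repeats, seeded.

*Tajima's D* uses the textbook normalization constants. Missingness
makes the called allele count vary by site, so the constants use a
window-level sample size — the mean called-allele count by default
(`n_method = "min"` is the conservative alternative). Windows with no
segregating site return `NA` rather than 0.

*Fst* is the Weir & Cockerham (1984) variance-components estimator;
windowed values are ratios of summed components, the standard way to
combine sites. Sites where either population has no called genotype are
skipped.

*LD decay.* r² is the squared Pearson correlation of genotype dosages
(0/1/2) over samples called at both sites — the Rogers–Huff approach
appropriate for unphased resequencing data, since no phasing step exists
in this pipeline. Pairs are binned by distance (1-kb bins by default)
and the half-decay distance is the smallest bin midpoint whose mean r²
falls to half the maximum of the binned means. Both the binning and the
MAF floor (default 0.05) are exposed because "decayed to ~50% of its
maximum" does not pin them down. Note the estimator's noise floor: for
independent sites E[r²] ≈ 1/n, so curves from small panels never decay
to zero.

## The sweep scan

`polarize()` assigns ancestral states from an outgroup allele table: if
the outgroup carries one of the site's two alleles that allele is
ancestral; otherwise the site is folded and its minor count is used.
This replaces tree-based ML ancestral reconstruction with the standard
outgroup heuristic — the folded-likelihood fallback keeps the scan
correct where polarization fails. Sites that are neither polymorphic nor
substitutions are excluded; fixed-derived sites (substitutions) are kept
as frequency class *n* by default.

`background_sfs()` estimates the chromosome-wide spectrum used as the
null. With complete data this is a plain tally. With missing data the
called-allele count varies by site and a short EM estimates the
full-size spectrum, each observation entering through its hypergeometric
downsampling likelihood; the EM reduces exactly to the tally when all
sites are complete. Per-site null probabilities are then hypergeometric
projections of that spectrum to each site's called count, conditioned on
the observable classes.

`clr_scan()` evaluates, at every test position (100-bp spacing, read as
grid point spacing — a whole-genome grid of literally 100 points would
be incompatible with 300-bp regions), the composite likelihood of a hard
sweep against the background. The sweep model is the standard
escape/dragging formulation: at distance *d* from the sweep, a lineage
escapes with probability `p_e = 1 − exp(−α·d)`; the escaped lineages are
a draw from the background spectrum, and all non-escaping lineages copy
the sweeping haplotype (itself an additional background draw). This
construction nests the null — at `p_e = 1` the sweep model *is* the
background — so the CLR `2·(max_α log CL − log CL₀)` is nonnegative with
equality attainable, and sites far from the test position contribute
exactly zero, which bounds the work per grid point (`max_span`, default
50 kb, is a computational bound, not a model assumption). α is maximized
over a log-spaced grid (10⁻⁷–10⁻² per bp, 21 points — sweep footprints
from ~100 bp to ~10 Mb, the range resolvable on a 2-Mb scan) refined by
golden-section search; the inner loop is compiled (Rcpp), as in the
field's C scanners. Escape-probability tables are precomputed on a pe
grid and interpolated linearly.

The region machinery follows the scan: the threshold is the top 1% of
CLR scores pooled across chromosomes per population (backgrounds are per
chromosome, but the threshold is a single per-population quantile); maximal above-threshold runs become regions scored by summed
CLR; adjacent regions merge when the gap is ≤ 50% of the adjacent
regions' size. "The size of the adjacent sweep regions" is ambiguous
(left, right, mean, sum); the default is the symmetric, intermediate
*mean*, with `min`, `max` and `sum` selectable. Merging iterates to a
fixpoint; the rule is monotone (sizes only grow, gaps never), so the
fixpoint is unique and order-independent — the tests verify this against
exhaustive merge-order search. Regions under 300 bp are then dropped
(inclusive at 300), and genes overlapping a final region by ≥ 1 bp are
the candidate set.

## The synthetic-data generator

The generator exists so that every stage is testable without any
download, and its defaults *are* the conditions assumed throughout
the tests: 30 diploids on a 2-Mb chromosome, 10,000 SNPs (5/kb, a
realistic post-filter density for a diverse outcrossing perennial), mean
depth 14 with negative-binomial overdispersion (a typical modern
resequencing panel averages ~14×), 2% missing genotypes, and sweep strength
α = 6.9×10⁻⁵/bp — escape probability ½ at 10 kb, a strong recent sweep.

*Neutral model.* Derived-allele counts follow the 1/k law of the
standard neutral spectrum, alleles are assigned to uniform random
lineage subsets, and genotypes are Hardy–Weinberg pairings. The
reference allele is ancestral, so the bundled outgroup table polarizes
the sample exactly. Sites are independent by default; an optional
founder-mosaic mode (two founder haplotypes, copying scale `ld_scale`)
adds LD decaying as `exp(−d/ld_scale)`, giving a half-decay distance of
about `0.69·ld_scale` — used for LD parameter-recovery tests.

*Sweep model.* `implant_sweep()` is the deterministic-escape (star-like
dragging) approximation: one sweeping haplotype, independent per-lineage
escape at `1 − exp(−α·d)`, non-escapers coalesced onto the sweep
haplotype. This is exactly the signal class the CLR likelihood models,
which is the point: it permits parameter-recovery tests (does the scan
find the center? is α̂ the right magnitude?) without a coalescent
dependency. It is *not* a full coalescent: no recombination genealogy,
no background LD, no soft sweeps. Consequently the scan's measured
recovery rate and null calibration speak to the implemented likelihood
machinery, not to power on real data, where LD, demography and
selection interact.

*Artifacts.* `inject_artifacts()` plants indels (some within 4 bp of
SNPs, some safely distant), QUAL values straddling 40, triallelic sites,
failing hard-filter annotations, and depth outliers — and emits
ground-truth labels computed by independent site-by-site code following
the same sequential set logic as the cascade, so cascade output can be
compared to the labels *exactly*, not approximately.

*Sequence pairs.* `simulate_ltr_pair()` evolves two copies of a random
ancestral sequence under the Kimura two-parameter process, each branch
accumulating `mu·time` expected substitutions. The `tstv` parameter is
the expected transition:transversion *count* ratio (0.5 = all rates
equal; default 2, typical for nuclear DNA).

## Molecular dating

`count_substitutions()` classifies alignment columns (gap or N in either
sequence skips the column pairwise, the EMBOSS distmat convention);
`k2p_distance()` applies `d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q)`,
erroring at saturation rather than returning a complex or infinite
value; `ks_to_time()` applies `Time = Ks/(2μ)` with μ = 6.5×10⁻⁹ for
LTR insertion dating and 6.1×10⁻⁹ for gene-pair divergence. For terminal
repeats the "Ks" is the K2P nucleotide distance of the repeat alignment
— a neutral, non-coding divergence, deliberately not a codon-model Ks.
Codon-aware Ks for paralog pairs is *not* recomputed from sequence;
`date_ks_table()` accepts externally computed values, because a
synonymous-site pipeline (codon alignment, site counting) is a separate
tool's job and was not part of this design.

## Numerical choices and degenerate inputs

* Percentiles and quantile thresholds everywhere use type-7 linear
  interpolation, the R default, so bounds are reproducible to the digit.
* Heterozygosity/π/D at sites or windows with no usable data return
  `NaN`/`NA` sentinels and are excluded from window means, never coerced
  to zero.
* Sweep-table probabilities are floored at 1e-300 before logs; CLR is
  clamped at 0 (the models are nested, so negative values can only arise
  from floating-point noise).
* The EM for the background spectrum runs at most 40 iterations or to a
  1e-10 sup-norm change; with ≤ 5% missingness it converges far earlier.
* Merging and thinning are deterministic left-to-right walks; no
  tie-breaking randomness exists anywhere outside the seeded simulators.

## Problem sizes used in the checks

The bundled verification (test suite and `scripts/acceptance.R`) runs
the full pipeline at the generator's default scale — 20 seeded sweep
replicates and 20 matched null replicates of a 2-Mb, 30-diploid,
10,000-SNP chromosome for the scan; a 10,000-SNP artifact VCF for the
cascade; 40 simulated 5-kb repeat pairs for dating — sizes chosen so a
replicate's scan finishes in seconds while leaving the frequency spectra
well populated. Population-scale quantities (hundreds of millions of SNPs,
absolute heterozygosity levels, 41/59-kb LD half-decay, sweep-gene
counts) depend on the deposited resequencing data and are intentionally
out of the desk-scale verification's reach.

## Known limitations

* The scan assumes a single panmictic population per run; no
  cross-population composite statistics.
* The escape model ignores recombination-rate variation; α̂ is a
  composite scale parameter, not a selection coefficient.
* gVCF merging and the caller's "consistent positions" rule are outside
  the package: input is a called VCF.
* r² from small panels is bias-floored at ~1/n; half-decay distances
  from fewer than ~25 samples should be read with that floor in mind.
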