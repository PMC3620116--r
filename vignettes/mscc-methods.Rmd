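---
title: "Methods: methyl-sensitive cut counting analysis in mscc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methyl-sensitive cut counting analysis in mscc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscc)
```

## The measurement model

Methyl-sensitive cut counting (MSCC) estimates DNA methylation at CG
dinucleotides from restriction digestion. Four methylation-sensitive
enzymes — HpaII (CCGG), AciI (CCGC), HpyCH4IV (ACGT) and HinP1I (GCGC) —
cut only when their recognition site is unmethylated, each leaving a
5′-CG overhang. Adapter ligation and a type-III enzyme then release a
27-nt fragment flanking the cut, the *CG tag*, which is sequenced together
with a 3-nt replicate barcode (30-nt reads). After mapping the tags back
to the cataloged sites, the count at a site in a library (its *digestion
frequency*) is modeled as

$$\mathbb{E}[c_{ij}] \;=\; D_j \, \frac{b_i\,(1 - m_{i,\mathrm{cond}(j)})}
{\sum_k b_k (1 - m_{k,\mathrm{cond}(j)})},$$

where $D_j$ is the library depth, $m_{i}\in[0,1]$ the methylation level of
site $i$ in the cell population, and $b_i > 0$ a site-specific digestion
bias. Two assumptions drive the whole analysis:

* counts are *inversely* proportional to methylation — a zero count means
  either a fully methylated site or shallow coverage, so zeros are kept as
  data, not missingness;
* the biases $b_i$ are multiplicative and *shared across replicates and
  conditions*, so they cancel in any site-by-site contrast between
  conditions. MSCC therefore supports *differential* methylation analysis
  well and absolute methylation estimation poorly; the package only does
  the former.

Methylation level is treated as continuous in $[0,1]$: per cell,
CG methylation is essentially binary, but a seedling pool averages over
many cells, and what the assay sees is the population mean.

## Pipeline and parameter choices

**Catalog.** `scan_restriction_sites()` records every motif occurrence
(both orientations for the non-palindromic AciI, whose reverse-complement
image GCGG is scanned explicitly) and keys each site by the 0-based
forward-strand coordinate of the C of the CG, so the cuts of both strands
at one CG collapse to a single entry. Motif windows containing N are
skipped rather than wildcarded — conservative site calling. Tag geometry
is a package convention (forward tag starts at the CG; reverse tag is the
reverse complement of the 27 nt ending just 3′ of it): downstream
statistics depend only on per-site counts, so any invertible convention
works, and the tests require exactly that invertibility. Sites whose tag
pair lies within Hamming distance 1 of another site's tags are flagged
non-unique and excluded from counting, because one-mismatch mapping
cannot attribute their reads unambiguously.

**Counting.** Barcode matching is exact: a 3-nt barcode has no safe room
for error tolerance. Tag mapping allows one mismatch, implemented with
masked-position keys (27 deletion-neighbourhood keys per tag); the
contract, enforced by tests, is equality with brute-force all-pairs
Hamming search. Tags tied between several sites at the minimal distance
are dropped and reported as ambiguous. Normalization rescales each
library by `mean(totals)/total` — any constant proportional to the
inverse library total yields identical Welch statistics (tested), so the
choice of the mean is cosmetic and keeps values on the raw-count scale.

**DMS calling.** Sites are tested when they hold at least `min_reads = 20`
raw reads in *any* single library (the "detected" tally — at least one
read in every library — is reported alongside). The phrase "in any
library" is genuinely ambiguous; both readings are implemented
(`scope = "any"`/`"every"`), with "any" the default. The per-site test is
Welch's t on normalized counts (no log transform by default, matching how
digestion frequencies are usually compared; `log_transform = TRUE`
exists). Variances are floored at `1e-8` so that tied integer counts at
low depth cannot produce a division by zero; the floor makes
exactly-equal groups score $t = 0$, $p = 1$ rather than NaN. The test is
two-sided because both directions of change are of interest, and BH
step-up FDR is the multiplicity control. Direction reads off the means:
*lower* digestion under treatment is a methylation *gain*.

**TSS enrichment.** Distances to the nearest TSS are signed and
strand-aware (negative upstream); ties between equidistant TSS go to the
lexicographically smaller gene identifier — an arbitrary but
deterministic rule. Null DMS sets are drawn by the literal random-rank
construction (assign each site a uniform number in `[1, 650000]`, sort,
take the first *n*), which is exactly uniform sampling without
replacement; the constant is kept for fidelity to the original
spreadsheet procedure and has no statistical effect. The empirical
p-value is $p = (e+1)/(s+1)$. The exceedance rule has two published
descriptions that do not coincide: the default (`rule = "upper"`) counts
null sets whose near-TSS fraction is at least the *observed* set's — the
standard upper-tail permutation test — while `rule = "all-sites"` counts
null sets at or below the *all-site* fraction, the literal alternative
wording. We expose both rather than guess intent; all reported results
use the default.

**Gene association.** The TSS window for the window rule is the closed
interval $[-3000, +2000]$ nt; the source wording does not state
inclusivity, so inclusive boundaries were chosen and are pinned by tests.
Differential expression is Welch on $\log_2(\mathrm{RPKM}+1)$ with a
1.5-fold and 0.05 cutoff — a transparent two-group stand-in for a
commercial ANOVA pipeline testing the identical hypothesis. The
significance cutoff applies to raw p-values by default (`mode = "p"`),
with an FDR mode available, because both conventions appear in practice;
the inconsistency is surfaced, not resolved. Gene-set enrichment uses the
standard hypergeometric upper tail over an explicit background (default:
all genes carrying at least one term) rather than a ranked-list
statistic.

## The synthetic-data generator

`sim_config()` fixes the study conditions the generator emulates:

* **Design:** two conditions ("control", "drought"), four barcoded
  replicates each; barcodes are 3-mers at pairwise Hamming distance ≥ 2.
* **Depth:** `reads_per_site = 12` expected reads per site per replicate.
  A genome-scale MSCC run of ~32 million reads per condition over
  ~634,000 surveyed sites works out to ~12 reads per site per replicate,
  so this is the realistic default.
* **Biases:** log-normal with `bias_sd = 0.4`, shared across all eight
  libraries — the "systematic and reproducible" component of MSCC noise.
* **Count noise:** negative binomial with `dispersion = 0.005`
  (variance $\mu + 0.005\mu^2$). The dispersion default was calibrated
  once so that two same-condition replicates show a digestion-frequency
  $r^2 \approx 0.8$ at the default depth, the magnitude typical of real
  MSCC replicate scatter; at that depth most of the replicate noise is
  Poisson sampling, which is why the residual overdispersion is small.
* **Methylome:** baseline levels are low (Beta(2, 8)) within 1 kb of a
  TSS and high (Beta(8, 2)) elsewhere — hypomethylated promoters,
  methylated intergenic space. A `dms_fraction = 0.02` subset of sites is
  perturbed in the treated condition with absolute level changes drawn
  from $[0.5, 0.95]$, methylation gain versus loss at 9:1 odds, and
  placement probability boosted 5-fold within 500 nt of a TSS.
* **Reads:** 27-nt tag (forward or reverse, equal odds) + barcode, with a
  1% uniform single-substitution error rate; each condition's four
  replicate libraries form one pooled read set, as when each condition is
  sequenced as a single barcoded lane.
* **Expression:** gene-level negative-binomial counts with exon-length
  scaling, log-normal library sizes, and planted fold changes.

One global seed drives named sub-streams (genome, methylome, counts,
reads, expression), so each stage is independently reproducible.

What the generator does *not* emulate: partial digestion chemistry and
star activity, adapter artefacts, quality-score structure, non-CG
(CHG/CHH) methylation contexts, linked methylation of neighbouring sites,
and cell-type mixture shifts between treatments. Passing tests therefore
demonstrate that the *statistical machinery* behaves as specified under
the assay's idealized measurement model — not that any particular
biological conclusion transfers to real tissue.

## Verification scale and power

The test suite runs everything at desk scale; the sizes are package
choices made for tight feedback:

* brute-force oracle comparisons use 10-kb genomes, catalogs of ~120–150
  sites and a few hundred query tags;
* the planted-DMS recovery check uses two 60-kb contigs (~900–1,000
  surveyed sites), 4+4 replicates, 2% DMS, and 200 reads per site per
  replicate, averaged over 10 seeds. At that depth the calling achieves
  ≥ 80% sensitivity with an observed false-discovery proportion ≤ 0.10
  and ≥ 95% direction concordance. The depth matters: with only four
  replicates per group, the Welch–Satterthwaite degrees of freedom can
  fall to ~3, which bounds how small a p-value even a huge effect can
  reach; at depths near 50 reads per site the BH threshold for a 2%
  signal fraction is then out of reach, so the recovery property is
  verified at the well-powered end of realistic depths;
* null calibration uses 3,000 sites at the same depth: the fraction of
  sites with $p < \alpha$ stays within 3 binomial standard deviations of
  $\alpha$ for $\alpha \in \{0.01, 0.05\}$, and within-condition $r^2$
  matches between-condition $r^2$; planting DMS makes within-condition
  $r^2$ strictly exceed between-condition $r^2$, the qualitative
  reproducibility pattern of a real two-treatment experiment;
* the permutation test's floor, $p = 1/(s+1)$ at $s = 100$, is exercised
  with a 12,000-site catalog in which under 10% of sites lie within
  500 nt of a TSS and an observed set constructed entirely inside that
  zone.

## Known limitations

* Site-level tests only: no merging of neighbouring DMS into regions, no
  covariate adjustment, no beta-binomial modelling of proportions.
* The surveyed-site universe depends on the genome build; the package
  ships no reference genome and makes no claim about any specific
  genome's surveyed fraction.
* Welch on normalized counts is anti-conservative at very low depth where
  counts are far from Gaussian; the filter (≥ 20 reads) is the guard, and
  `log_transform` offers a variance-stabilizing alternative.
* The odds-ratio association treats methylation and expression calls as
  fixed binary labels; threshold choices propagate into the OR and are
  not integrated over.
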