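---
title: "Methods and design of the mitodui pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mitodui pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodui)
```

# The scientific setting

In bivalves with doubly uniparental inheritance (DUI), two deeply
divergent mitochondrial genomes coexist in one species: an F-type genome
transmitted through eggs and an M-type genome transmitted through sperm.
Demonstrating DUI and characterising the two lineages requires several
largely independent computations: compositional scans of the two
circular genomes, divergence estimates per gene, within-population
diversity and selection statistics for each mitotype, absolute
quantification of the two genomes across tissues, and a mixture model
that converts tissue-level qPCR measurements into a per-sperm copy
number. `mitodui` implements each of these as a separately testable
module with a shared set of containers and a synthetic-data generator
that produces inputs with known truth for every stage.

# Coordinates, genomes and site classes

Mitogenomes are circular, so all internal coordinates are 0-based
half-open, and features that span the replication origin are stored
*unwrapped* with `end > length`; every consumer reads positions modulo
the genome length. GenBank's 1-based inclusive coordinates (including
`join(a..L,1..b)` origin-spanning locations and `complement()` strands)
are converted only at the I/O boundary, which keeps window arithmetic and
feature extraction free of special cases. A written record parses back to
the identical genome, and the test suite asserts this round trip on
simulated F and M genomes.

Translation uses NCBI table 5 (invertebrate mitochondrial) by default —
ATA = Met, TGA = Trp, AGA/AGG = Ser, stops TAA/TAG — the standard choice
for mytilid mitogenomes; the table id is configurable everywhere a code
is consumed. Degeneracy classes are derived from the code table itself
rather than hard-coded, so a different table id yields consistent
degeneracy.

`classify_sites()` gives every position exactly one label: first/second
codon position, 2-fold or 4-fold third position (degeneracy computed from
the *actual* codon at that site), RNA gene, or noncoding. Overlaps
resolve by priority protein > RNA > noncoding, and two protein genes
overlapping in different frames are an error rather than an arbitrary
choice. "Neutral" sites — the filter used for skew tracks meant to
reflect mutational rather than selective asymmetry — are the 4-fold
third positions plus noncoding positions; a second preset combines
second codon positions with noncoding sites. Degeneracy is the standard
operationalisation of neutrality here; it ignores selection on codon
usage, which is a documented simplification.

# Sliding-window skew

Windows are anchored at starts `s = k·step` for
`k = 0 … ceil(L/step) − 1`, wrap the circle, and report their centre
`(s + window/2) mod L`. This tiles the full circle exactly once per
step; when `L` is not a multiple of the step the final window re-counts
the overhang, which the tests account for explicitly. Defaults are a
200 bp window with a 25 bp step — the conventional scale for mitogenome
skew profiles — and 1,000 bp for filtered tracks, where a 200 bp window
would often contain no eligible site. Windows with zero eligible
positions carry `NA`, never zero: a zero would read as "no skew" in long
repeat regions where nothing was measured. GC content is divided by the
count of non-N eligible bases, so an all-N window is also `NA`.
Relative GC content divides window values by the genome-wide value over
the same site filter (counts aggregated once, not window values
averaged). Both genomes modelled here encode all genes on a single
strand, so skews are computed on the stored strand with a flag for the
complement; the reverse-complement antisymmetry of both skews is a
tested invariant.

# Divergence

`p_distance()` is the proportion of differing sites among used columns.
The default deletion mode is *complete* (columns containing any gap or
ambiguity in any row are dropped alignment-wide), matching the default
of the distance tool this reproduces; pairwise deletion is an option.
Ambiguity codes count as gaps — conservative mismatch counting.
Between-group distances average over all cross-group pairs, and the
standard error resamples alignment columns with replacement (default
10,000 replicates, seeded). Because the statistic is a mean over equally
weighted pairs, the bootstrap reduces to resampling the per-column mean
mismatch vector, which makes 10,000 replicates cheap at genome scale.
Alignment construction is deliberately an input, not a stage: any
pre-aligned FASTA with `>name|group` headers is accepted.

Per-gene tables report amino-acid distances for protein genes and
nucleotide distances for RNA genes; the overall row is the nucleotide
distance on the concatenation of all per-gene nucleotide alignments.
Which genes enter the overall row is visible in the returned table
(`n_sites_used`), since published overall values rarely state their
exact gene composition.

# Population genetics

Diversity statistics use gap-free columns only. `hd` uses the unbiased
`N/(N−1)` factor; Watterson's θ is reported both per site and per
sequence because published tables are often ambiguous about which is
shown. Tajima's *D* uses the 1989 constants, with `NA` (not zero) when
`S = 0`; significance at p < 0.05 uses the beta-distribution
approximation of the null distribution rescaled to D's theoretical
bounds — deterministic, and the convention behind starred table entries.
An independent transcription of the published constants lives in the
test suite and must agree with the implementation on fixed alignments.

The Nei–Gojobori (1986) implementation counts synonymous site fractions
per codon position with mutations to stop codons excluded from the
denominator, and averages synonymous/nonsynonymous differences over all
minimal mutational pathways between codons, disallowing pathways through
stops (when every pathway is blocked — possible only for some
stop-adjacent pairs — it falls back to counting through stops rather
than dropping the codon). All 64×64 codon-pair difference counts and all
64 per-codon site counts are precomputed once per genetic code and
cached, making pairwise Ka/Ks a table lookup. Proportions are
Jukes–Cantor corrected; `p ≥ 3/4` is reported as saturated rather than
silently clipped. Standard errors resample codons (not sites) with
replacement, 1,000 replicates by default. Under the package's own
neutral codon simulator the estimator shows a small (~3–5%) upward
tendency in the Ka/Ks *ratio*, dominated by the nonlinearity of the
ratio at finite sequence length; the acceptance suite bounds the mean at
ω = 1 within [0.9, 1.1] at gene-scale lengths.

# qPCR quantification

The standard curve is OLS of Cq on log10(copies) with replicates pooled
across experiments; efficiency is `10^(−1/slope) − 1` with QC at
90–110%. Copy numbers invert the fitted curve at the replicate mean Cq.
No confidence-interval construction is standard in this setting, so the
package adopts t-intervals on the replicate mean Cq propagated through
the curve (equivalently, a delta method on the log10 scale), with
Welch–Satterthwaite degrees of freedom for ratios of two targets. The
calibration curve is treated as known when propagating: with the
default 3×3×7 dilution design its uncertainty is an order of magnitude
below replicate noise, and the coverage acceptance test runs in exactly
this regime. The detection cutoff defaults to Cq 35; a sample with no
detected replicate is reported as a bound (`below_detection`), and a
ratio whose numerator is undetected is an upper bound — "between
infinity and the marked value" in the F/M direction. Note the cutoff is
a *policy* layered on the calibration: the noiseless inversion tests lift
it (`cq_cutoff = Inf`) because single-copy inputs legitimately sit past
Cq 35 on a 37-intercept curve.

The NGS ratio is `(reads_M/len_M)/(reads_F/len_F)` with a binomial
bootstrap CI on the read split. It deliberately ignores mappability
differences between the genomes; with genome lengths differing by ~6 kb
and a repeat-rich M genome this can bias the ratio, which is why the
qPCR and NGS estimates are kept as mutually checking, separately
reported quantities.

# The sperm copy-number model

Male mantle tissue mixes somatic cells (F-mtDNA) with sperm (assumed
homoplasmic for M-mtDNA). If sperm content is roughly constant per
nuclear genome while somatic content varies, M-mtDNA/nDNA is linear in
F-mtDNA/nDNA and the intercept at zero somatic signal is the M-mtDNA
content of pure sperm per nuclear genome — i.e. copies per sperm cell.
The fit is unweighted OLS, matching the plain trend line this model
reproduces; a weighted fit would need the per-point qPCR variances and
is left to the caller via the returned point table. The default
intercept interval is ±1 SE (the convention of the annotated trend
line); `interval = "confidence"` gives the proper t-interval. Dividing
by the assumed five mitochondria per sperm cell — the textbook count for
bivalve sperm, exposed as `n_mito` — gives copies per mitochondrion.
Female-mantle points are rejected at input rather than silently
included, and below-detection M points are excluded with a warning; an
exclusion flag for high-F outlier males is deliberately *not* applied by
default, since which points enter the published regression is generally
unstated.

# What the generators emulate — and what they do not

`simulate_mitogenome_pair()` plants per-gene divergence by independent
per-site substitution (realized p is binomial around the target;
substitutions that would create internal stops are redrawn, a bias below
10⁻³ at the supported targets), optional per-region composition/skew
profiles, and the M-specific structural differences: relocated rrnS,
atp8 extended to 885 bp, and a ~5 kb repeat region between the rRNAs. It
does **not** emulate indels, rate heterogeneity along genes, or
between-gene substitution correlation — so a green divergence test
establishes correct counting and bootstrap behaviour, not robustness to
alignment error.

`simulate_haplotypes()` implements the standard neutral coalescent
(exponential coalescence at rate k(k−1)/2, Poisson mutations at θL/2 per
unit branch) with infinite-sites placement, giving exact Watterson and
Tajima oracles: E[S] = θLa₁ and E[D] ≈ 0. Codon mode evolves a stop-free
codon sequence with nonsynonymous proposals thinned by ω. Defaults in
the test world (n = 18, θ per site = 0.02, ND5/ND6/CYTB lengths 1,317,
417 and 663 bp) mirror a realistic mussel panel. No recombination,
population structure or finite-sites homoplasy is modelled.

`simulate_qpcr_dataset()` reproduces the measurement-table structure of
a three-target experiment (F marker, M marker, single-copy nuclear
reference): a 3 experiments × 3 replicates × 7 ten-fold dilution curve
per target, and per-sample Cq triplicates in two tissues, with the male
mantle following the mixture line (default intercept 15, slope 0.8) and
female mantle carrying trace M contamination at a planted F/M ratio of
10³–10⁴. Somatic F levels default to log-uniform between 2 and 60 per
nuclear genome, the spread seen across male mantles. Replicate noise is
Gaussian on the Cq scale (σ = 0.1 cycles, typical instrument precision);
plate effects and inhibition are not modelled.

# Numerical choices and degenerate inputs

* Undefined statistics are `NA`, never 0: empty windows, `S = 0`
  Tajima's D, saturated JC corrections, single-usable-column bootstrap
  SEs, ratios with undetected denominators.
* All Monte Carlo paths (bootstraps, generators, pipeline) accept a seed
  and are byte-reproducible under it; the pipeline stamps every output
  table with the seed and a hash of the configuration.
* Ties and priorities are fixed, not data-dependent: feature overlap
  priority, complete-deletion semantics, and pathway fallbacks are as
  described above.
* Replicate counts in the pipeline default to the conventional 10,000
  (site bootstrap) and 1,000 (codon bootstrap); tests scale these down
  where only determinism, not SE precision, is under test.

# Known limitations

* No model-corrected distances (K2P etc.), no tree inference, and no
  alignment construction — these are inputs or out of scope.
* Tajima significance uses the beta approximation, not coalescent
  simulation; for very small S the approximation is crude.
* The qPCR CI machinery ignores calibration-curve uncertainty and
  between-plate effects.
* The sperm model inherits every assumption of the mixture argument:
  sperm homoplasmy, constant sperm content per nuclear genome across
  individuals, and unbiased quantification at low copy numbers.
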