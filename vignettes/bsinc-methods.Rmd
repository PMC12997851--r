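---
title: "Barcoded spike-in calibration: model, assumptions, and design choices"
author: "bsinc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcoded spike-in calibration: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsinc)
```

## The quantitation model

Multiplexed long-read sequencing pools several barcode libraries on one
flow cell: replicate libraries of a DNA spike-in standard of known
composition, and replicate libraries of the sample. Because all libraries
compete for the same pool of pores, a barcode's share of the output
depends on its ligation efficiency and input mass, not only on its
biology. The model proceeds in four steps.

**Barcode effect factor.** For barcode $i$ with observed output $O_i$ (bp)
and input mass $m_i$ (ng),
$$\mathrm{BEF}_i = \frac{O_i}{\kappa\, m_i},$$
where $\kappa$ (bp/ng) is a run-level *theoretical yield* constant. BEF
rescales each barcode's mapped bases to a common per-input-mass footing,
so one calibration model can serve all barcodes. $\kappa$ is deliberately
cosmetic: multiplying it by any $c>0$ multiplies every BEF by $1/c$ and
every observed copy number by $c$, and the calibration intercept absorbs
the shift exactly — the package asserts this invariance numerically to
better than $10^{-9}$ relative. The default is $\kappa = 10^7$ bp/ng.
When whole libraries are in hand we take $O_i$ as the post-filter
sequenced bases; the deterministic expected-coverage generator, which has
no reads, uses total aligned bases instead.

**Observed genome copy number.** With mapped bases $M_{g,i}$ (sum of
primary-alignment target spans) and covered bases $C_{g,i}$ (size of the
interval union) for genome $g$,
$$N^{\mathrm{obs}}_{g,i} = \frac{M_{g,i}/\mathrm{BEF}_i}{C_{g,i}}.$$
Dividing by *covered* rather than assembly length makes the statistic
usable for draft genomes and MAGs, whose true genome size is unknown.
When $C_{g,i}=0$ the copy number is *absent* (flagged "no coverage"),
never zero: absence of evidence is reported distinctly.

**Dynamic limits.** A genome is *detected* when its coverage fraction
$C_{g,i}/L_g$ strictly exceeds 10% — a guard against false positives from
reads hitting conserved regions only. Detection defaults to the
conservative all-replicates rule (configurable to any-replicate). A
genome is *quantifiable* when the coefficient of variation of
$N^{\mathrm{obs}}_{g,\cdot}$ across replicate barcodes (sample standard
deviation, $n-1$ denominator, over the mean) is at most 10%. Both limits
are dynamic: they move with sequencing effort and community composition
rather than being fixed input concentrations, which is what makes them
transferable across runs of different depth.

**Calibration.** Over spike-in genomes passing both filters, ordinary
least squares of
$$\log_{10} N^{\mathrm{theo}}_g = a + b\,\log_{10} \bar N^{\mathrm{obs}}_g$$
with $\bar N^{\mathrm{obs}}_g$ the replicate mean. Sample estimates are
$10^{a + b \log_{10} N^{\mathrm{obs}}}$. Two orientations of this
regression are conceivable; we regress theoretical on observed so the
fitted line *is* the estimator, applied directly to sample observations.
Replicates are averaged before fitting by default; `aggregate = "pooled"`
fits per-barcode points instead. Fewer than two retained genomes is a
hard "calibration underdetermined" error; $R^2$ is reported from three
points up.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `minQuality` | 7 | Phred | read filter; mean quality is the Phred of the mean error probability, not the mean of Q values |
| `minLength` | 200 | bp | read filter; both filters drop *strictly below* the threshold, so boundary reads are kept |
| `lod` | 0.10 | coverage fraction | detection threshold, strictly greater-than |
| `loqCv` | 0.10 | fraction | replicate-CV quantitation threshold |
| `kappa` | 1e7 | bp/ng | theoretical yield; estimates invariant to it |
| `targetBases` | — | bp | subsampling target; the read crossing the target is included |
| `seed` | 42 | — | every stochastic operation takes a seed and restores the session RNG |

## What the synthetic generator emulates

The generator exists so that every stage is testable without sequencing
data. It has two faces.

The **read-level generator** draws reads with probability proportional to
`copies × genome length × extraction bias` — the genome-length factor is
exactly the bias that dividing by covered bases corrects, which makes the
correction testable — with lognormal lengths (default
$\mu=\log 3800$, $\sigma=0.6$, echoing a long-read run with N50 near
3.8 kb; purely cosmetic), uniform start positions, and a per-barcode
throughput multiplier emulating ligation-efficiency differences. Reads
start uniformly at positions where the whole read fits on the genome, so
a read's true interval always spans its full length; each read's source
interval is emitted as a primary truth alignment (PAF-writable), so the
pipeline can be exercised without an aligner. Default input masses derive
from the community's actual DNA mass (`copies × length × 1.08e-12` ng),
keeping spike-in and sample barcodes on one copy scale. Outputs are
byte-deterministic per seed.

The **expected-coverage generator** replaces sampling with expectations:
depth $\lambda_g$ from the community shares, mapped bases
$\lambda_g L_g$, and covered bases $L_g(1-e^{-\lambda_g})$ (the classical
Poisson-coverage expectation). It is the noise-free face used for exact
identity checks — with all genomes deep ($\lambda \gtrsim 20$) the
pipeline must return theoretical copies to better than $10^{-6}$
relative — and for the detection-flip demonstration, where one genome's
coverage fraction is pinned at 5% and then 12% while everything else
stays put.

Neither face models real nanopore error profiles, homopolymer artifacts,
chimeras, barcode cross-talk, or reference-database incompleteness.
Passing tests therefore demonstrate the *computational* correctness and
statistical behavior of the workflow under its own assumptions, not
robustness to those wet-lab effects; DNA-extraction bias in particular is
representable (per-taxon multiplicative factors) but not corrected by the
method, matching its real-world limitation.

## Numerical and design choices

- **Threshold semantics.** "Quality < 7" and "length < 200" are removals,
  so boundary values are kept; the LOD is strictly greater-than 10%.
- **Saturation bias at low coverage.** At low depth the observed copy
  number $\lambda/(1-e^{-\lambda})$ is floored near 1, so sparse genomes
  are systematically over-estimated before calibration. This is why a
  single near-LOD spike-in taxon makes a poor calibrant (its correction
  factor inherits the bias) and why the multi-taxon regression, fitted
  mostly in the linear regime, outperforms it. The strategy comparison is
  scored on *absolute* copy deviations: an intercept-only single-taxon
  correction cannot change relative abundances at all, so only the
  absolute scale distinguishes the strategies.
- **BEF-necessity comparison.** Without BEF normalization, replicate
  observed copies disagree by the throughput ratios and the LOQ filter
  simply empties the calibration; the with/without error comparison is
  therefore made with the LOQ relaxed in both arms, isolating the
  normalization effect itself.
- **Mapped bases** are target-interval spans of primary alignments
  (deletions within the span count, soft-clips do not; one contribution
  per read). SAM supplementary records are excluded by default,
  includable via `countSupplementary`.
- **Coordinates** are 0-based half-open internally (PAF-native); SAM is
  converted on parse. Covered bases use `IRanges::reduce`; tests verify
  it against a per-base boolean oracle on hundreds of random instances.
- **Degenerate inputs.** Empty manifests warn and return empty databases;
  zero-slope calibrations warn that estimates are constant; zero covered
  bases, below-LOD genomes and sub-2-replicate CVs propagate as flagged
  `NA`s, never as zeros.
- **Pipeline thresholds.** The reporting LOD/LOQ may be set stricter than
  the calibration filters (`calibration_lod`, `calibration_loq_cv`), so a
  survey run with `lod = 1.0` still calibrates and reports an empty
  quantified set rather than aborting.
- **CV with an unavailable mean.** A zero mean or a single replicate
  yields an absent CV, hence "not quantifiable".

## Study conditions used by the checks

The test suite and `scripts/acceptance.R` use deliberately small but
fully specified conditions: a 6-taxon spike-in over 2.5 decades with an
even 5-taxon sample at 8–20 Mbp per barcode for the property checks; an
8-genome calibration community spanning 4 decades (rare members on larger
genomes, as the rare fungi of commercial standards are) at 0.7 Gbp per
barcode with throughput multipliers in $[0.5, 2]$ and per-taxon lognormal
bias of 0.1 log10 units for parameter recovery; 20 seeds for the BEF
comparison and 40 for the spike-in strategy comparison; and the bundled
log-distributed (10-member) and gut (21-member) standard compositions for
the Simpson summaries, whose genome-copy dominance values come out at
about 0.9 and 0.11. These sizes keep a full run of suite plus acceptance
script in a few minutes on one core while leaving every statistical
ordering decisive.

## Known limitations

Extraction bias is modeled but uncorrected (the regression corrects
systematic, taxon-independent distortions only). Quantifying very rare
taxa requires raising sequencing effort until they clear the dynamic LOD.
Multi-mapping reads contribute once via their primary alignment;
conserved-region cross-mapping is mitigated, not eliminated, by the
coverage-fraction LOD. Taxonomic resolution is bounded by the reference
database: genus-level aggregation sums only quantifiable member species.
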