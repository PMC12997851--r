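# bsinc

Absolute microbial quantitation from multiplexed long-read metagenomes with
**b**arcoded **s**pike-**in** **c**alibration.

## The problem

Shotgun long-read (nanopore-style) metagenomics profiles whole communities
without primers or prior knowledge, but it natively reports only *relative*
abundances. Many decisions in environmental microbiology — bioprocess
control, water-quality surveillance, wastewater epidemiology — need
*absolute* concentrations (genome copies per library or per µL of DNA
extract). `bsinc` implements the computational core of a barcoded spike-in
calibration workflow: a DNA standard of known composition (e.g. a
log-distributed mock community) is ligated with its own barcodes, pooled
with barcoded sample DNA, and sequenced together. The standard's known
copy numbers then calibrate the sample's observed signal on the same run,
with dynamic limits of detection and quantitation instead of fixed input
thresholds.

## The model

For genome *g* in barcode library *i*, with mapped bases
*M<sub>g,i</sub>* and covered bases *C<sub>g,i</sub>* from primary
alignments:

- **Barcode effect factor** (ligation-efficiency batch correction):
  `BEF_i = observed_bases_i / (kappa × input_DNA_ng_i)`, with `kappa` a
  run-level theoretical yield constant (bp/ng). Final estimates are
  provably invariant to `kappa`.
- **Observed genome copy number**:
  `N_obs(g,i) = (M_g,i / BEF_i) / C_g,i` — dividing by *covered* rather
  than total genome length makes the statistic valid for draft genomes
  and MAGs.
- **Dynamic LOD**: genome detected iff coverage fraction
  `C/L > 10%` (in every replicate barcode, by default).
- **Dynamic LOQ**: quantifiable iff the coefficient of variation of
  `N_obs` across replicate barcodes is ≤ 10%.
- **Calibration**: ordinary least squares
  `log10(N_theoretical) = a + b·log10(N_obs)` over the spike-in genomes
  passing both filters; sample estimates are `10^(a + b·log10(N_obs))`.

The package also ships the surrounding tooling: reference-manifest and
spike-in truth handling, read filtering (mean Q ≥ 7, length ≥ 200 bp) and
seeded subsampling to target bases, PAF/SAM coverage summarization
(interval-union covered bases), composition metrics (relative abundance,
percent deviation, Simpson dominance Σp²), single- vs multi-taxon
spike-in comparison, a synthetic mock-experiment generator (lognormal read
lengths, per-barcode throughput multipliers, per-taxon extraction bias,
truth alignments), and a one-config pipeline runner with a thin
`exec/bsinc` CLI (`run` / `simulate` / `calibrate` / `quantify`).

## Worked example

Simulate a 3+3-barcode run (spike-in standard over 2.5 decades, even
sample community, unequal barcode throughputs), then calibrate and
quantify:

```r
library(bsinc)

spike  <- communitySpec(sprintf("sp%02d", 1:6), rep(5e4, 6),
                        1e5 * 10^-seq(0, 2.5, length.out = 6))
sample <- evenCommunity(nTaxa = 5, topCopies = 2e4, genomeLength = 5e4)
run    <- standardRunDesign(spikeThroughput  = c(0.5, 1, 2),
                            sampleThroughput = c(2, 1, 0.5))
sim <- simulateExperiment(spike, sample, run, targetBases = 5e7, seed = 7)

res <- calibrateAndQuantify(sim, kappa = 1e7)
res$model
#> CalibrationModel (ols_mean): log10(theoretical) = 4.9597 + 0.9826 * log10(observed)
#>   n = 5, R^2 = 0.9998; LOD 0.1, LOQ CV 0.1
res$quant[, c("genome_id", "detected", "cv", "quantifiable", "estimated_copies")]
#>   genome_id detected         cv quantifiable estimated_copies
#> 1  evensp01     TRUE 0.01584709         TRUE         20202.96
#> 2  evensp02     TRUE 0.03256281         TRUE         20210.85
#> 3  evensp03     TRUE 0.02689315         TRUE         19780.33
#> 4  evensp04     TRUE 0.01075010         TRUE         20190.63
#> 5  evensp05     TRUE 0.03237847         TRUE         20534.85
#> 6  evensp06     TRUE 0.03218718         TRUE         20507.12
```

Every sample genome was simulated at 20,000 copies: the calibrated
estimates land within ~1–3% despite 4-fold throughput differences between
barcodes. The slope near 1 and R² near 1 say the spike-in standard's
signal is linear in log-log space over its abundance range; `cv` is the
replicate coefficient of variation that the dynamic LOQ thresholds.

File-based runs use the same machinery from one YAML config
(`runPipeline("run.yaml")` or `exec/bsinc run --config run.yaml`), writing
`model.json`, `quant.tsv`, rank-aggregated totals, coverage and
accounting tables, and a run log.

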