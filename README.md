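# nextpeak

Strand-aware ChIP-seq peak calling with a normal-exponential two-peak
generative model.

## The problem and the model

ChIP-seq locates transcription-factor binding sites by sequencing the ends
("tags") of immunoprecipitated chromatin fragments. Around a site centered
at μ, the cross-link position is normal, ξ ~ N(μ, σ²), and the distance
from the cross-link to a fragment end is exponential with mean β, so a
reverse-strand tag location follows the exponentially modified Gaussian
density

    f^R(x | μ, σ², β) = Φ((x−μ)/σ − σ/β) · (1/β) · exp(−(x−μ)/β + σ²/(2β²))

and forward-strand tags follow its mirror image around μ. Per-position tag
counts on each strand are Poisson with intensity

    λ_j = ν · f(j | μ, σ, β) + ρ

where ν is the expected number of binding tags per strand (2ν is the
reported binding intensity and the ranking statistic) and ρ is the local
background rate. Genomic positions whose tag sequence is not unique are
*censored* — excluded from the likelihood — so ν estimates total binding
strength even when part of the signal cannot map, and every fitted location
μ̂ carries an asymptotic standard error.

The package provides, for users who analyze mapped ChIP-seq tags:

* per-region maximum-likelihood fits of (μ, ν, ρ) with standard errors
  from the observed information;
* a likelihood-ratio binding test (χ²₁) and a saturated-model
  goodness-of-fit screen (Poisson deviance) that flags PCR spikes and
  multiple-binding regions;
* windowed candidate-region selection from BED / SAM / Bowtie tag files,
  with optional mappability (unmappable-interval) tracks;
* exact PSSM motif p-values by score-distribution convolution on an
  integer lattice, for training (σ, β) on motif-anchored regions and for
  evaluating calls;
* a simulator that reproduces the assumed generative process, for
  calibration and recovery studies;
* screening-cutoff recommendation by precision-curve area, and the
  fragment-length identity 2β + d − 1.

## Worked example

Simulate three binding events on a 30 kb chromosome (10% of positions
unmappable), call peaks, and evaluate against the planted sites:

```r
library(nextpeak)

sh <- global_shape(40, 60)      # sigma = 40 bp, beta = 60 bp
truth <- data.frame(chrom = "chr1", mu = c(6000, 14000, 26000),
                    nu = c(300, 180, 240))
sim <- simulate_dataset(truth, c(chr1 = 30000), sh, rho = 0.02,
                        unmappable_frac = 0.1, dir = tempdir(),
                        prefix = "demo", seed = 17)

peaks <- call_peaks(sim$tags_path, mappability = sim$mappability_path,
                    shape = sh)
peaks[1:3, c("chrom", "site", "se_mu", "binding_intensity", "total_count",
             "lr_pvalue", "gof_pvalue", "rank")]
#>   chrom  site se_mu binding_intensity total_count  lr_pvalue gof_pvalue rank
#> 1  chr1  6002 2.735             585.1         586 3.502e-199          1    1
#> 2  chr1 26004 2.825             536.6         538 1.427e-194          1    2
#> 3  chr1 13995 4.098             388.6         261  4.618e-86          1    3

evaluate_against_motifs(peaks, data.frame(chrom = truth$chrom,
                                          position = truth$mu))
#> EvalSummary: 3 TPs; mean distance 3.8 bp; mean bias +0.7 bp
```

Each planted event is recovered within a few bp (`site` vs. 6000, 26000,
14000), with a standard error (`se_mu`) describing that precision. The
third peak shows the censoring compensation at work: only 261 tags were
observable in its heavily masked region, but the fitted binding intensity
(2ν̂ ≈ 389) recovers the full planted strength (2·180 = 360) by accounting
for the unmappable positions. `gof_pvalue` near 1 says the two-peak shape
fits; small values would flag spikes (short regions) or multiple events
(long regions), and `screen_peaks()` / `recommend_cutoffs()` act on them.

The implied mean fragment length for a fit with β = 60 and 36 bp tags:

```r
estimate_fragment_length(60, 36)
#> [1] 155
```

A thin command-line wrapper with `simulate`, `regions`, `train`, `call`
and `evaluate` subcommands is installed at `inst/cli/nextpeak.R`:

```sh
Rscript inst/cli/nextpeak.R call --tags tags.bed --sigma 40 --beta 60 \
    --out-prefix peaks
```

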