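# scfamsi

Short-chain fatty acids (SCFAs) — acetate, propionate, butyrate — are the
main fermentation products of gut bacteria, and mapping where they sit in a
tissue section is a direct readout of where the producing microbes live.
They are, however, volatile and ionize poorly, so MALDI mass spectrometry
imaging (MSI) only sees them after on-tissue chemical derivatization: the
quaternary amine **TMPA** (N,N,N-trimethyl-2-(piperazin-1-yl)ethan-1-amine)
is coupled to each carboxyl group with a uronium activator, adding a
permanent positive charge.

`scfamsi` implements the computational side of that workflow for R:

* **Mass model** — elemental-formula arithmetic over pinned isotope masses
  and atomic weights. For an acid M with one tag the target ion is

  *m/z* = M(acid) + M(C9H22N3⁺) − M(H2O),

  where the tag contributes its formula mass minus one electron (it is a
  pre-formed cation). Multiply tagged polycarboxylic species are enumerated
  with charge = tag count. A catalogue of matrix interference ions (CHCA
  [M+H]⁺, [2M−CO₂+H]⁺, the CHCA–TMPA condensation amide, cholesterol
  [M−OH]⁺, and the empirical 1,5-DAN-protocol contaminant at m/z 242.231)
  is built from the same constants.
* **MSI** — imzML (continuous and processed) and a plain-text pixel-grid
  format; ion-image extraction as the closed-window sum
  [*m/z* − tol, *m/z* + tol] per pixel (default ±0.05 u); TIC
  normalization; region-mask statistics and contrast ratios.
* **Proteotyping** — bacterial identification from linear-TOF protein
  fingerprints: predicted average [M+H]⁺ of ribosomal proteins from
  sequence (ExPASy residue masses, rule-based N-terminal Met excision),
  MAD-noise peak picking, tolerance-window matching, and a transparent
  species score `n_matched × (1 − mean|Δm|/tol)`. Miles–Misra CFU
  estimation from 10-fold dilution series is included.
* **Synthetic data** — a seeded, stylized cecum phantom (smooth-muscle
  ring, epithelium band, bacterial-lumen and food-residue patches over
  background) and Gaussian-peak linear-TOF spectra, with known ground
  truth, so the whole pipeline is testable offline.
* **CLI** — `targets`, `image`, `proteotype`, `cfu`, `simulate`
  subcommands via `scfamsi::run_cli()`, with JSON configs, manifests and
  0/1/2 exit codes.

## Worked example

Build the theoretical target table for the bundled 19-acid panel:

```r
library(scfamsi)
panel <- read_panel(system.file("extdata", "scfa_panel.tsv", package = "scfamsi"))
tab <- build_target_table(panel)
head(tab[, c("name", "n_tags", "charge", "theoretical_mz")], 4)
#>             name n_tags charge theoretical_mz
#> 1 Propionic acid      1      1       228.2070
#> 2   Butyric acid      1      1       242.2227
#> 3    Lactic acid      1      1       244.2020
#> 4 Pentanoic acid      1      1       256.2383
```

These are the singly tagged, singly charged TMPA amides; the butyrate
target at m/z 242.2227 is the ion whose image localizes bacterial
fermentation.

Identify a cultured isolate from its 12-peak linear-TOF fingerprint:

```r
db <- cecum_isolates_db()   # 50 ribosomal proteins, 3 organisms
peaks <- read_peaks(system.file("extdata", "bacteroides_acidifaciens_peaks.tsv",
                                package = "scfamsi"))
score_species(match_peaks(peaks, db, tolerance = 2.5), db)
#>                    organism n_matched n_candidates mean_abs_error score
#> 1  Bacteroides acidifaciens        12           12          1.323 5.648
#> 2   Lactococcus sp002492185         0           22             NA 0.000
#> 3 Ligilactobacillus murinus         0           16             NA 0.000
```

All 12 peaks are explained by *B. acidifaciens* ribosomal proteins within
2.5 u (mean error 1.3 u, typical of external calibration), and no peak
matches the other two organisms.

Simulate a cecum phantom and measure butyrate contrast between the
bacteria-dense lumen and background:

```r
layout <- make_cecum_phantom(30, 30, 50, seed = 1)   # 30x30 px, 50 um pitch
grid   <- simulate_msi(layout, noise_model(seed = 1))
img    <- extract_ion_image(grid, 242.2227, tolerance = 0.05)
region_stats(img, layout$masks)
#>            region n_pixels   mean  median    max
#> 1   smooth_muscle      180  10.19   9.911  18.69
#> 2      epithelium      136  10.97  10.240  21.86
#> 3 bacterial_lumen       53 108.78 104.739 184.06
#> 4    food_residue       16  11.05  10.978  15.36
#> 5      background      515  11.27  10.704  28.76
contrast_ratio(img, layout$masks$bacterial_lumen, layout$masks$background)
#> [1] 9.650131
```

The configured 10x butyrate enrichment in the bacterial lumen is
recovered as a ~9.7x mean contrast under default noise (the additive
baseline pulls the ratio slightly below 10).

## Documentation

The methods vignette (`vignettes/scfamsi-methods.Rmd`) describes the mass
model and its conventions, the proteotyping score, the synthetic-data
generator and what its green tests do and do not establish, and all
numerical choices.
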