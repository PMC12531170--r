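---
title: "scfamsi: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scfamsi: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfamsi)
```

This vignette is the package's own account of the science it implements:
the derivatization mass model, the imaging window semantics, the
proteotyping statistics, the synthetic-data generator, and the numerical
and design choices made where the problem left them open.

## 1. The derivatization mass model

Short-chain fatty acids are volatile and lack a proton-affine site that
common MALDI matrices ionize well, so they are imaged after on-tissue
coupling to TMPA, a piperazine bearing a quaternary trimethylammonium
group. Amide formation at each carboxyl consumes one water and leaves the
permanent positive charge of the tag on the product. The model is purely
additive over elemental formulas:

$$ m/z \;=\; \frac{M_\mathrm{mono}(\mathrm{acid}) \;+\;
  n_\mathrm{tags}\,\bigl(M_\mathrm{mono}(\mathrm{C_9H_{22}N_3}) - m_e\bigr)
  \;-\; n_\mathrm{tags}\,M_\mathrm{mono}(\mathrm{H_2O})
  \;-\; \textstyle\sum M_\mathrm{mono}(\mathrm{losses})}{z} $$

Three conventions matter at the fourth decimal:

* **Pinned constants.** Monoisotopic masses (AME/IUPAC), IUPAC 2021
  standard atomic weights, and the CODATA proton and electron masses are
  shipped as data (`mass_constants()`), not scattered literals. Every
  theoretical value in the package derives from this one table.
* **Electron correction.** The tag is a pre-formed cation, so each tag
  contributes its formula mass minus one electron (≈ 0.00055 u). Without
  this correction every target is high by ~5×10⁻⁴ u, which is visible at
  the printed precision of reference tables.
* **Comparisons are numeric**, at absolute tolerance 5×10⁻⁴ u, never
  string equality on rounded output. One reference acid (propionic)
  computes 228.20704, which prints as 228.2070 against a published
  228.2071 — a one-digit-in-the-last-place rounding difference well
  inside the tolerance; we report the computed value.

**Polycarboxylic acids.** A compound with $k$ carboxyls is enumerated as
species with $n_\mathrm{tags} = z = 1 \dots k$ (each quaternary tag
carries +1), no neutral loss. Published multivalent "theoretical" values
for citric acid are *not* reproduced by this additive model; a
trimethylamine (C3H9N) loss per tag brings the monovalent species within
≈ 6×10⁻⁴ u but not the di-/trivalent ones cleanly. The package therefore
exposes the loss as an explicit option (`tma_loss`,
`neutral_losses = list("C3H9N")`) and records residuals rather than
asserting a formula it cannot verify. In practice MALDI detects only the
singly derivatized, singly charged species of polyacids anyway.

**Interference ions.** `interference_ions()` catalogues, per matrix, the
species that crowd the SCFA mass range: CHCA [M+H]⁺ (190.0499),
CHCA [2M−CO₂+H]⁺ (335.1026), the CHCA–TMPA condensation amide (343.213)
formed when residual tag reacts with the matrix, cholesterol [M−OH]⁺
(369.352), and — for the 1,5-DAN protocol — a contaminant observed at
m/z 242.231, only 0.008 u above butyrate-TMPA (242.2227). The contaminant
is flagged `empirical = TRUE`: its composition is unknown and its m/z is
an observation, not a computation. Note [M−OH]⁺ and [M+H−H₂O]⁺ are the
same arithmetic (−17.00329 u including the electron), so the convention
choice is immaterial.

## 2. Ion images and region comparison

`extract_ion_image()` sums, per pixel, all intensities inside the
*closed* window [center − tol, center + tol]. The default ±0.05 u is the
conventional display window for high-resolution small-molecule MSI. The
closed-interval choice means two calls with exactly adjacent windows
double-count a peak sitting on the shared endpoint; tests document this
and the package makes no attempt to hide it. The window sum is identical
logic for centroid and profile data.

Consequences worth knowing:

* The default window **cannot** separate butyrate-TMPA from the DAN
  contaminant 0.008 u away; a ±0.003 u window can. This is the
  quantitative form of the practical advice to avoid amine matrices (or
  switch to sublimed CHCA) for SCFA imaging.
* Tolerance is monotone: enlarging the window never decreases a pixel.
* `tic_normalize()` rescales each non-empty pixel's spectrum to unit
  total ion current. The default is *no* normalization, because vendor
  display defaults are generally unknown; TIC is offered explicitly and
  flagged in grid metadata.

Region masks are plain pixel sets in grid coordinates (0-based, x
rightward, y downward; row-major TSV export). Optical registration is out
of scope — masks arrive already in grid space. `region_stats()` reports
mean/median/max per mask and `contrast_ratio()` the ratio of means, with
`Inf` (not an error) for a zero-signal denominator.

**imzML.** Both binary modes are supported: continuous (one shared m/z
axis, stored once) and processed (per-pixel axes). The writer emits
64-bit little-endian floats and the reader accepts 32- or 64-bit.
Checksums/UUID bytes are written but not verified — the round-trip
contract is on values, not container forensics.

## 3. Proteotyping

Bacterial colonies are identified by matching linear-TOF peak lists
(m/z 4,000–20,000) against predicted average [M+H]⁺ of ribosomal
proteins.

**Mass prediction.** Sum of ExPASy average residue masses + average water
(18.01528 u) + proton. The proton convention (1.00728 u vs the hydrogen
atom's 1.00794 u) changes nothing at a 0.15 u comparison tolerance.

**N-terminal methionine.** `protein_average_mh()` applies the standard
bacterial excision rule *by default*: the initiator Met is removed when
the second residue is small (A, C, G, P, S, T, V). This default is a
deliberate, data-driven choice: across the bundled 50-protein catalogue,
35 reported masses are exactly one Met (~131.19 u) below the
retained-Met sum and all 50 reproduce within 0.053 u under the rule —
mature ribosomal proteins are Met-processed, and fingerprint databases
reflect the mature chain. `met_excision = FALSE` restores the naive sum.

**Peak picking.** Baseline = median intensity; noise = median absolute
deviation (robust because a linear-TOF protein spectrum is mostly
baseline with a few tall peaks). Contiguous runs above
`baseline + min_snr × noise` become candidate peaks; a run containing
several local maxima is split at any valley below half the smaller
flanking maximum, so near-neighbour proteins ~30 u apart resolve at
resolution 1000. Centroid = intensity-weighted mean m/z of the segment.

**Matching and score.** Each protein matches at most its nearest peak
within the tolerance (default ±2.5 u — externally calibrated linear TOF;
isolated real-world deviations up to ~4.5 u exist, so the value is a
user parameter and a documented failure mode of the default). The
species score is

$$ \mathrm{score} = n_\mathrm{matched}\,
   \Bigl(1 - \frac{\overline{|\Delta m|}}{\mathrm{tol}}\Bigr) $$

— monotone in explained peaks, discounted by average error, with
deterministic tie-breaks (lower mean error, then name). It is this
package's own statistic; commercial confidence scores are proprietary
and no numerical equivalence is claimed or attempted.

**CFU estimation.** Miles–Misra: over spots whose colony count lies in
the countable range (default 1–100, a conventional choice the source
protocols leave implicit), CFU/mL = count × dilution / volume, averaged,
reported as log10. The operation is validated arithmetically; no
published colony counts exist to regress against.

## 4. The synthetic-data generator

No raw imaging data accompany the deposited bacterial spectra, so the
phantom is declared **stylized**: it emulates the geometry and effect
directions of a cecal cross-section, not any measured image.

`make_cecum_phantom()` lays out five disjoint regions — a smooth-muscle
ring, an epithelium band inside it, seeded random bacterial-lumen and
food-residue patches in the interior, background elsewhere — and an
abundance map stating the conditions the imaging experiments describe:
butyrate- and propionate-TMPA 10× enriched in the bacterial lumen,
lactate-TMPA 5× in smooth muscle (glycolytic tissue), palmitate-TMPA in
food residue, the cholesterol fragment in epithelium. Baseline abundances
(10–20 units) and the 10×/5× folds are fixed once; they are the stated
world, not tuning knobs.

`simulate_msi()` writes one centroid peak per species per pixel:
m/z jittered by Gaussian ppm error (default SD 3 ppm, QTOF-class),
intensity = abundance × lognormal(mean 1, CV 0.3) + additive baseline
(default 1). Multiplicative lognormal noise is the documented choice for
MALDI intensity variation; it is a modelling convention, not a fit.
The optional DAN contaminant is a spatially uniform peak at 242.231
(mean intensity 200 — "large" relative to background butyrate), uniform
because nothing is known about its spatial pattern.

`simulate_protein_spectrum()` sums Gaussians at predicted [M+H]⁺ with
FWHM = m/z / resolution (default 1000, linear TOF), 300 ppm mass-error
SD (≈ 1.4–6 u over the acquisition range, matching observed
calibration-level deviations), lognormal amplitude jitter, flat baseline
with additive Gaussian noise.

All randomness flows through one explicit integer seed; the global RNG
state is saved and restored, and identical seeds give bit-identical
output.

**What a green test establishes.** Zero-noise recovery is exact by
construction, so those tests check plumbing, not realism. The
default-noise contrast and ranking tests establish that the pipeline's
statistics recover *configured* effects through *modelled* noise; they
say nothing about matrix crystallization heterogeneity, isotopic
envelopes, detector saturation, or real biological spatial structure,
none of which the generator emulates.

## 5. Numerical choices and degenerate inputs

* Formula subtraction refuses negative element counts (classed error).
* Empty formulas have mass 0; empty peak lists and match sets propagate
  as empty results, not errors; an all-zero pixel stays all-zero under
  TIC normalization, and a grid with no positive pixel refuses it.
* An extraction window outside every pixel's acquired range yields an
  all-zero image with a warning, not an error (the CLI logs and muffles
  it).
* Ion-image TSV export is full precision and round-trips exactly; PNG is
  a min–max rendering for eyes only.
* Ties in species ranking break deterministically (error, then name);
  peaks at exactly the window edge are *in* (closed interval).
* CLI exit codes: 0 success, 1 usage/config (missing flags or files,
  invalid config keys — listed exhaustively), 2 data (malformed
  content). Every run writes a JSON manifest with version, resolved
  config, seed and input checksums, so deterministic stages reproduce
  bit-identically from the log.

## 6. Known limitations

* The mass model is additive only: no reaction yields, isotope patterns,
  or fragment prediction.
* Multivalent derivatized species of polyacids carry an unresolved
  composition question (above); their defaults are an enumeration
  convention, not validated chemistry.
* The ±2.5 u matching default is documented as missing rare ~4.5 u
  outliers; widen it knowingly.
* mzML profile input is not parsed; profile spectra travel as two-column
  text (the imzML pathway covers imaging data).
* The phantom is stylized; quantitative claims about real tissue require
  real data.
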