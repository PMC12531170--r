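# Seeded synthetic data: a stylized cecum tissue phantom for the imaging
# pipeline and linear-TOF protein spectra for the proteotyping pipeline.
# All randomness flows through an explicit seed; the global RNG state is
# saved and restored around every draw.

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Describe a noise model
#'
#' @param mass_error_ppm_sd Gaussian m/z error SD in ppm. Defaults to 3
#'   (QTOF-class accuracy, the level seen in high-resolution
#'   measured-vs-theoretical comparisons); use ~300 for linear-TOF
#'   protein spectra, where deviations of 0.1-4.5 u at m/z 4000-16000
#'   are typical with external calibration.
#' @param intensity_cv Coefficient of variation of the multiplicative
#'   lognormal intensity noise (mean 1). Default 0.3.
#' @param baseline_level Additive baseline in intensity units. Default 1.
#' @param seed Optional integer seed carried with the model.
#' @return A `noise_model` list.
#' @export
noise_model <- function(mass_error_ppm_sd = 3, intensity_cv = 0.3,
                        baseline_level = 1, seed = NULL) {
  if (mass_error_ppm_sd < 0 || intensity_cv < 0 || baseline_level < 0)
    data_error("noise parameters must be non-negative")
  structure(list(mass_error_ppm_sd = mass_error_ppm_sd,
                 intensity_cv = intensity_cv,
                 baseline_level = baseline_level, seed = seed),
            class = "noise_model")
}

# lognormal with mean 1 and coefficient of variation cv
.rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# The phantom's default species and their theoretical m/z, computed from
# the mass model so phantom truth and extraction targets always agree.
.phantom_species <- function() {
  acid <- function(name, f) tmpa_derivatized_mz(compound_spec(name, f, 1))$theoretical_mz
  chol <- interference_ions("cholesterol-endogenous")$theoretical_mz[1]
  data.frame(
    species = c("lactate-TMPA", "propionate-TMPA", "butyrate-TMPA",
                "palmitate-TMPA", "cholesterol-fragment"),
    mz = c(acid("Lactic acid", "C3H6O3"),
           acid("Propionic acid", "C3H6O2"),
           acid("Butyric acid", "C4H8O2"),
           acid("Palmitic acid", "C16H32O2"),
           chol),
    stringsAsFactors = FALSE)
}

#' Build a stylized cecum phantom layout
#'
#' Deterministically (per seed) partitions a pixel grid into five
#' disjoint anatomical regions echoing a cecal cross-section: an outer
#' `smooth_muscle` ring, an `epithelium` band inside it, randomly placed
#' `bacterial_lumen` and `food_residue` patches in the interior, and
#' `background` elsewhere. The default abundance map places
#' butyrate-TMPA and propionate-TMPA 10x higher in the bacterial lumen,
#' lactate-TMPA 5x higher in smooth muscle, palmitate-TMPA 10x higher in
#' food residue, and the cholesterol fragment 10x higher in epithelium,
#' each over a uniform background level.
#'
#' @param width,height Grid size in pixels (at least 20x20).
#' @param pitch Pixel pitch in micrometres (10, 25 or 50 are the usual
#'   laser pitches; any positive value accepted).
#' @param seed Integer seed controlling patch placement.
#' @return A `phantom_layout`: `width`, `height`, `pitch`, `masks`
#'   (named list of `region_mask`), `abundance` (data.frame `region`,
#'   `species`, `mz`, `abundance`), `seed`.
#' @export
make_cecum_phantom <- function(width = 50, height = 50, pitch = 50, seed = 1) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 20L || height < 20L)
    data_error("phantom needs at least 20x20 pixels to host all regions")
  if (pitch <= 0) data_error("pitch must be positive")
  cx <- (width - 1) / 2; cy <- (height - 1) / 2
  R <- 0.48 * min(width, height)
  px <- expand.grid(x = seq_len(width) - 1L, y = seq_len(height) - 1L)
  d <- sqrt((px$x - cx)^2 + (px$y - cy)^2)
  assign_vec <- rep("background", nrow(px))
  assign_vec[d <= R & d > 0.85 * R] <- "smooth_muscle"
  assign_vec[d <= 0.85 * R & d > 0.72 * R] <- "epithelium"
  interior <- which(d <= 0.72 * R)
  with_seed(seed, {
    place_patches <- function(n_patches, radius, label, taken) {
      free <- setdiff(interior, taken)
      for (i in seq_len(n_patches)) {
        if (!length(free)) break
        c_idx <- free[sample.int(length(free), 1L)]
        dd <- sqrt((px$x - px$x[c_idx])^2 + (px$y - px$y[c_idx])^2)
        blob <- intersect(which(dd <= radius), free)
        assign_vec[blob] <<- label
        free <- setdiff(free, blob)
      }
      which(assign_vec == label)
    }
    lum <- place_patches(3L, 0.20 * R, "bacterial_lumen", integer(0))
    place_patches(2L, 0.15 * R, "food_residue", lum)
  })
  masks <- lapply(c("smooth_muscle", "epithelium", "bacterial_lumen",
                    "food_residue", "background"), function(nm) {
    sel <- assign_vec == nm
    region_mask(nm, px[sel, c("x", "y")])
  })
  names(masks) <- vapply(masks, `[[`, character(1), "name")
  sp <- .phantom_species()
  base <- c("lactate-TMPA" = 20, "propionate-TMPA" = 10, "butyrate-TMPA" = 10,
            "palmitate-TMPA" = 10, "cholesterol-fragment" = 10)
  home <- c("lactate-TMPA" = "smooth_muscle",
            "propionate-TMPA" = "bacterial_lumen",
            "butyrate-TMPA" = "bacterial_lumen",
            "palmitate-TMPA" = "food_residue",
            "cholesterol-fragment" = "epithelium")
  fold <- c("lactate-TMPA" = 5, "propionate-TMPA" = 10, "butyrate-TMPA" = 10,
            "palmitate-TMPA" = 10, "cholesterol-fragment" = 10)
  ab <- do.call(rbind, lapply(names(masks), function(region) {
    data.frame(region = region, species = sp$species, mz = sp$mz,
               abundance = ifelse(home[sp$species] == region,
                                  base[sp$species] * fold[sp$species],
                                  base[sp$species]),
               stringsAsFactors = FALSE)
  }))
  rownames(ab) <- NULL
  structure(list(width = width, height = height, pitch = pitch,
                 masks = masks, abundance = ab, seed = seed),
            class = "phantom_layout")
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf("<phantom_layout> %dx%d px, pitch %g um, %d regions, seed %s\n",
              x$width, x$height, x$pitch, length(x$masks), format(x$seed)))
  invisible(x)
}

#' Simulate an MSI grid from a phantom layout
#'
#' Per pixel, one centroid peak per species with a positive regional
#' abundance: m/z is the species' theoretical value perturbed by Gaussian
#' ppm error, intensity is `abundance * lognormal(mean 1, cv) +
#' baseline`. With the 1,5-DAN contaminant flag on, a spatially uniform
#' peak is added at m/z 242.231 (0.008 u above butyrate-TMPA) so that the
#' conventional +/- 0.05 u window cannot exclude it but a +/- 0.003 u
#' window can.
#'
#' @param layout A `phantom_layout` from [make_cecum_phantom()].
#' @param noise A [noise_model()]; zero-noise models reproduce the
#'   abundance map exactly.
#' @param include_dan_contaminant Add the uniform contaminant peak.
#' @param contaminant_intensity Mean intensity of that peak (default 200,
#'   i.e. large relative to the background butyrate level).
#' @param seed Seed for this simulation; defaults to `noise$seed` then
#'   `layout$seed`.
#' @return An `msi_grid` with the layout and seed recorded in metadata.
#' @export
simulate_msi <- function(layout, noise = noise_model(),
                         include_dan_contaminant = FALSE,
                         contaminant_intensity = 200,
                         seed = noise$seed %||% layout$seed) {
  stopifnot(inherits(layout, "phantom_layout"))
  grid <- msi_grid(layout$width, layout$height, layout$pitch,
                   metadata = list(phantom_seed = layout$seed,
                                   simulation_seed = seed,
                                   contaminant = include_dan_contaminant))
  region_of <- rep(NA_character_, layout$width * layout$height)
  for (m in layout$masks)
    region_of[m$pixels$y * layout$width + m$pixels$x + 1L] <- m$name
  ab_split <- split(layout$abundance, layout$abundance$region)
  with_seed(seed, {
    for (y in seq_len(layout$height) - 1L) {
      for (x in seq_len(layout$width) - 1L) {
        idx <- y * layout$width + x + 1L
        ab <- ab_split[[region_of[idx]]]
        ab <- ab[ab$abundance > 0, , drop = FALSE]
        mzs <- ab$mz * (1 + stats::rnorm(nrow(ab), 0, noise$mass_error_ppm_sd) * 1e-6)
        ints <- ab$abundance * .rlnorm_cv(nrow(ab), noise$intensity_cv) +
          noise$baseline_level
        if (include_dan_contaminant) {
          mzs <- c(mzs, 242.231)
          ints <- c(ints, contaminant_intensity *
                      .rlnorm_cv(1L, noise$intensity_cv) + noise$baseline_level)
        }
        o <- order(mzs)
        mzs <- mzs[o]; ints <- ints[o]
        keep <- c(TRUE, diff(mzs) > 0)  # drop exact m/z collisions
        grid <- set_pixel(grid, x, y, mass_spectrum(mzs[keep], ints[keep]))
      }
    }
  })
  grid
}

#' Simulate a linear-TOF protein profile spectrum
#'
#' Sums Gaussian peaks centered at each protein's predicted average
#' \[M+H\]+ (perturbed by Gaussian ppm error) with FWHM = center /
#' `resolution`, multiplied by lognormal-jittered abundances, over an
#' additive flat baseline with Gaussian noise.
#'
#' @param proteins Data.frame with columns `predicted_mh_avg` and
#'   `abundance` (relative peak heights; e.g. a [cecum_isolates_db()]
#'   subset joined with observed intensities).
#' @param resolution Mass resolving power m/dm (FWHM), default 1000
#'   (linear TOF).
#' @param mz_range Acquisition range, default `c(4000, 20000)`.
#' @param step Profile sampling step in u, default 0.5.
#' @param noise A [noise_model()]; use `mass_error_ppm_sd` around 300 for
#'   realistic linear-TOF calibration error. The additive Gaussian noise
#'   SD is `0.25 * baseline_level`.
#' @param amplitude_scale Multiplies all abundances (default 100) so
#'   peaks stand clear of a unit baseline.
#' @param seed Integer seed; defaults to `noise$seed` then 1.
#' @return A profile `mass_spectrum`.
#' @export
simulate_protein_spectrum <- function(proteins, resolution = 1000,
                                      mz_range = c(4000, 20000), step = 0.5,
                                      noise = noise_model(mass_error_ppm_sd = 300),
                                      amplitude_scale = 100,
                                      seed = noise$seed %||% 1) {
  if (!is.data.frame(proteins) || !nrow(proteins) ||
      !all(c("predicted_mh_avg", "abundance") %in% names(proteins)))
    data_error("proteins must be a non-empty data.frame with predicted_mh_avg, abundance")
  if (any(proteins$abundance <= 0)) data_error("abundances must be positive")
  if (resolution <= 0) data_error("resolution must be positive")
  mz <- seq(mz_range[1], mz_range[2], by = step)
  with_seed(seed, {
    y <- rep(noise$baseline_level, length(mz))
    centers <- proteins$predicted_mh_avg *
      (1 + stats::rnorm(nrow(proteins), 0, noise$mass_error_ppm_sd) * 1e-6)
    amps <- proteins$abundance * amplitude_scale *
      .rlnorm_cv(nrow(proteins), noise$intensity_cv)
    for (i in seq_len(nrow(proteins))) {
      sigma <- centers[i] / resolution / (2 * sqrt(2 * log(2)))
      lo <- max(1L, findInterval(centers[i] - 6 * sigma, mz))
      hi <- min(length(mz), findInterval(centers[i] + 6 * sigma, mz) + 1L)
      sel <- lo:hi
      y[sel] <- y[sel] + amps[i] * exp(-((mz[sel] - centers[i])^2) / (2 * sigma^2))
    }
    if (noise$baseline_level > 0)
      y <- y + stats::rnorm(length(mz), 0, 0.25 * noise$baseline_level)
    y[y < 0] <- 0
  })
  mass_spectrum(mz, y, mode = "profile")
}

#' Write a profile spectrum to two-column text
#'
#' @param spectrum A `mass_spectrum`.
#' @param path Output TSV path (columns `mz`, `intensity`).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(
    data.frame(mz = format(spectrum$mz, digits = 15),
               intensity = format(spectrum$intensity, digits = 15)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile spectrum from two-column text
#'
#' @param path TSV with columns `mz`, `intensity`.
#' @return A profile `mass_spectrum`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("spectrum file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df))) {
    if (ncol(df) >= 2L) names(df)[1:2] <- c("mz", "intensity")
    else data_error(sprintf("spectrum %s needs columns mz, intensity", path))
  }
  mass_spectrum(as.numeric(df$mz), as.numeric(df$intensity), mode = "profile")
}
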