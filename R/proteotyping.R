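# MALDI-TOF bacterial proteotyping: predicted average \[M+H\]+ for
# ribosomal proteins from sequence, peak picking on linear-TOF profile
# spectra, peak-to-protein matching, species ranking, and Miles-Misra
# CFU estimation from serial dilution counts.

.aa_alphabet <- names(.residue_avg_masses)

#' Clean and validate a protein sequence
#'
#' Strips a trailing stop character (`*`), uppercases, and validates
#' against the 20 standard one-letter amino-acid codes.
#'
#' @param raw Sequence string, possibly ending in `*`.
#' @return Cleaned sequence string.
#' @examples
#' clean_sequence("acde*")
#' @export
clean_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw))
    data_error("empty sequence")
  s <- toupper(sub("\\*$", "", raw))
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% .aa_alphabet)
  if (length(bad))
    data_error(sprintf("invalid residue '%s' at position %d", chars[bad[1]], bad[1]))
  s
}

#' Predicted average \[M+H\]+ of a protein
#'
#' Sums standard average residue masses (ExPASy table), adds the average
#' mass of water and one proton. With `met_excision = TRUE` (default) the
#' initiator methionine is removed when the second residue is small
#' (A, C, G, P, S, T, V) -- the standard bacterial N-terminal methionine
#' excision rule, which mature ribosomal proteins follow and which
#' linear-TOF fingerprints of cultured isolates reflect.
#'
#' @param sequence Cleaned amino-acid string (see [clean_sequence()]).
#' @param met_excision Apply the rule-based initiator-Met removal.
#' @return Average \[M+H\]+ in u.
#' @examples
#' protein_average_mh("G", met_excision = FALSE)  # ~76.07
#' @export
protein_average_mh <- function(sequence, met_excision = TRUE) {
  s <- clean_sequence(sequence)
  chars <- strsplit(s, "")[[1]]
  if (met_excision && length(chars) >= 2L && chars[1] == "M" &&
      chars[2] %in% c("A", "C", "G", "P", "S", "T", "V")) {
    chars <- chars[-1]
  }
  sum(.residue_avg_masses[chars]) + .water_avg_mass + .proton_mass
}

#' Read a protein database
#'
#' Accepts a TSV with columns `organism`, `protein_name`, `sequence`
#' (additional columns are kept), or a FASTA file whose headers encode
#' the organism before `fasta_delim` and the protein name after it.
#' Predicted average \[M+H\]+ is computed for every record.
#'
#' @param path Path to TSV or FASTA.
#' @param met_excision Passed to [protein_average_mh()].
#' @param fasta_delim Delimiter splitting organism from protein name in
#'   FASTA headers (default `"|"`).
#' @return Data.frame with columns `organism`, `protein_name`, `sequence`,
#'   `predicted_mh_avg` (plus any extra input columns).
#' @export
read_protein_db <- function(path, met_excision = TRUE, fasta_delim = "|") {
  if (!file.exists(path)) usage_error(sprintf("protein db not found: %s", path))
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (!length(hdr)) data_error(sprintf("no FASTA records in %s", path))
    ends <- c(hdr[-1] - 1L, length(lines))
    recs <- lapply(seq_along(hdr), function(i) {
      h <- sub("^>", "", lines[hdr[i]])
      parts <- strsplit(h, fasta_delim, fixed = TRUE)[[1]]
      seqs <- paste(lines[seq(hdr[i] + 1L, ends[i])], collapse = "")
      data.frame(organism = trimws(parts[1]),
                 protein_name = trimws(paste(parts[-1], collapse = fasta_delim)),
                 sequence = seqs, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, recs)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("organism", "protein_name", "sequence")
    if (!all(req %in% names(df)))
      data_error(sprintf("protein db %s must have columns: %s",
                         path, paste(req, collapse = ", ")))
  }
  df$sequence <- vapply(df$sequence, clean_sequence, character(1), USE.NAMES = FALSE)
  df$predicted_mh_avg <- vapply(df$sequence, protein_average_mh, numeric(1),
                                met_excision = met_excision, USE.NAMES = FALSE)
  df
}

#' The bundled ribosomal-protein catalogue of three murine cecal isolates
#'
#' Loads the package's reference catalogue of ribosomal subunit proteins
#' observed by linear-TOF MALDI for three anaerobes cultured from murine
#' cecal contents (Bacteroides acidifaciens, Lactococcus sp002492185,
#' Ligilactobacillus murinus), with predicted average \[M+H\]+ recomputed
#' from sequence.
#'
#' @inheritParams read_protein_db
#' @return See [read_protein_db()]; also carries the catalogue's reported
#'   masses in column `reported_mh_avg`.
#' @export
cecum_isolates_db <- function(met_excision = TRUE) {
  path <- system.file("extdata", "cecum_isolates_rproteins.tsv",
                      package = "scfamsi", mustWork = TRUE)
  read_protein_db(path, met_excision = met_excision)
}

#' Read a two-column peak list (m/z, intensity)
#'
#' @param path TSV/whitespace-delimited text with a header row naming
#'   columns `mz` and `intensity` (or two unnamed columns).
#' @return A sorted data.frame `mz`, `intensity`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("peak list not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df))) {
    if (ncol(df) >= 2L) names(df)[1:2] <- c("mz", "intensity")
    else data_error(sprintf("peak list %s needs columns mz, intensity", path))
  }
  peak_list(as.numeric(df$mz), as.numeric(df$intensity))
}

peak_list <- function(mz, intensity) {
  if (length(mz) != length(intensity))
    data_error("mz and intensity lengths differ")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) data_error("duplicate m/z in peak list")
  if (any(intensity < 0)) data_error("negative intensity in peak list")
  data.frame(mz = mz, intensity = intensity)
}

#' Pick peaks from a profile spectrum
#'
#' The baseline is estimated as the median intensity and the noise as the
#' median absolute deviation (robust to the few large protein peaks).
#' Contiguous runs of samples above `baseline + min_snr * noise` become
#' candidate peaks; a run holding several local maxima is split at any
#' valley falling below half the smaller flanking maximum. Each peak is
#' centroided by the intensity-weighted mean m/z of its samples; the
#' centroid intensity is the segment maximum.
#'
#' @param spectrum A `mass_spectrum` (see [mass_spectrum()]) in profile
#'   mode, or any list with ascending `mz` and `intensity`.
#' @param min_snr Threshold in noise units above baseline (default 3).
#' @param min_mz,max_mz Restrict output to this closed m/z range.
#' @return Sorted data.frame `mz`, `intensity` (possibly 0 rows).
#' @export
pick_peaks <- function(spectrum, min_snr = 3, min_mz = -Inf, max_mz = Inf) {
  mz <- spectrum$mz; y <- spectrum$intensity
  if (!length(mz)) data_error("empty spectrum")
  if (min_mz >= max_mz) data_error("min_mz must be below max_mz")
  if (is.unsorted(mz, strictly = TRUE)) data_error("spectrum m/z must ascend")
  baseline <- stats::median(y)
  noise <- stats::mad(y)
  if (noise == 0) noise <- max(baseline, 1e-12) * 0.01  # flat baseline
  thr <- baseline + min_snr * noise
  above <- y > thr
  if (!any(above)) return(data.frame(mz = numeric(0), intensity = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  split_run <- function(i) {
    yy <- y[i]
    n <- length(yy)
    if (n < 3L) return(list(i))
    maxima <- which(diff(sign(diff(yy))) < 0) + 1L
    if (length(maxima) < 2L) return(list(i))
    segs <- list(); start <- 1L
    for (k in seq_len(length(maxima) - 1L)) {
      a <- maxima[k]; b <- maxima[k + 1L]
      v <- which.min(yy[a:b]) + a - 1L
      if (yy[v] < 0.5 * min(yy[a], yy[b])) {
        segs[[length(segs) + 1L]] <- i[start:v]
        start <- v + 1L
      }
    }
    segs[[length(segs) + 1L]] <- i[start:n]
    segs
  }
  segments <- unlist(lapply(which(r$values), function(k)
    split_run(starts[k]:ends[k])), recursive = FALSE)
  cen <- vapply(segments, function(i) sum(mz[i] * y[i]) / sum(y[i]), numeric(1))
  amp <- vapply(segments, function(i) max(y[i]), numeric(1))
  ok <- cen >= min_mz & cen <= max_mz
  peak_list(cen[ok], amp[ok])
}

#' Match a peak list against a protein database
#'
#' Each protein matches at most the nearest peak within `tolerance`;
#' one peak may satisfy proteins of several organisms. The result is
#' invariant under permutation of the database rows.
#'
#' @param peaks Data.frame `mz`, `intensity` ([read_peaks()],
#'   [pick_peaks()]).
#' @param db Protein database from [read_protein_db()].
#' @param tolerance Matching half-window in u (default 2.5, typical of
#'   externally calibrated linear TOF; note isolated deviations up to
#'   ~4.5 u occur in real fingerprints, so the value is configurable).
#' @return Data.frame `organism`, `protein_name`, `predicted_mh_avg`,
#'   `observed_mz`, `mass_error` (observed - predicted), `intensity`,
#'   sorted by observed m/z; the tolerance is attached as attribute
#'   `"tolerance"`.
#' @export
match_peaks <- function(peaks, db, tolerance = 2.5) {
  if (tolerance <= 0) data_error("tolerance must be positive")
  empty <- data.frame(organism = character(0), protein_name = character(0),
                      predicted_mh_avg = numeric(0), observed_mz = numeric(0),
                      mass_error = numeric(0), intensity = numeric(0))
  attr(empty, "tolerance") <- tolerance
  if (!nrow(peaks) || !nrow(db)) return(empty)
  rows <- lapply(seq_len(nrow(db)), function(i) {
    d <- abs(peaks$mz - db$predicted_mh_avg[i])
    j <- which.min(d)
    if (d[j] > tolerance) return(NULL)
    data.frame(organism = db$organism[i], protein_name = db$protein_name[i],
               predicted_mh_avg = db$predicted_mh_avg[i],
               observed_mz = peaks$mz[j],
               mass_error = peaks$mz[j] - db$predicted_mh_avg[i],
               intensity = peaks$intensity[j], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$observed_mz, out$organism, out$protein_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tolerance") <- tolerance
  out
}

#' Rank candidate organisms from peak matches
#'
#' Per organism the score is `n_matched * (1 - mean_abs_error / tolerance)`:
#' it grows with the number of explained peaks and shrinks toward zero as
#' the average mass error approaches the matching window. This score is
#' this package's own definition; it is not numerically comparable to any
#' vendor confidence score.
#'
#' @param matches Output of [match_peaks()].
#' @param db Either the protein database (a data.frame with `organism`)
#'   or a named integer vector of candidate counts per organism.
#' @param tolerance Matching tolerance in u; defaults to the value
#'   attached to `matches`.
#' @return Data.frame `organism`, `n_matched`, `n_candidates`,
#'   `mean_abs_error`, `score`, sorted by descending score, ties broken
#'   by lower mean error then organism name.
#' @export
score_species <- function(matches, db, tolerance = attr(matches, "tolerance")) {
  if (is.null(tolerance) || tolerance <= 0)
    data_error("a positive matching tolerance is required")
  if (is.data.frame(db)) {
    sizes <- table(db$organism)
    db_sizes <- stats::setNames(as.integer(sizes), names(sizes))
  } else db_sizes <- db
  unknown <- setdiff(unique(matches$organism), names(db_sizes))
  if (length(unknown))
    data_error(sprintf("organism(s) in matches absent from db sizes: %s",
                       paste(unknown, collapse = ", ")))
  orgs <- names(db_sizes)
  rows <- lapply(orgs, function(o) {
    m <- matches[matches$organism == o, , drop = FALSE]
    n <- nrow(m)
    mae <- if (n) mean(abs(m$mass_error)) else NA_real_
    score <- if (n) n * (1 - mae / tolerance) else 0
    data.frame(organism = o, n_matched = n,
               n_candidates = as.integer(db_sizes[[o]]),
               mean_abs_error = mae, score = score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$mean_abs_error, out$organism), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Describe a Miles-Misra dilution series
#'
#' @param colony_counts Non-negative integer colony counts per spot.
#' @param dilution_factors Strictly increasing positive dilution factors
#'   (e.g. `10^(1:8)` for a 10-fold series), aligned with the counts.
#' @param spot_volume_ml Spotted volume in mL (default 0.01, i.e. 10 uL).
#' @return A `dilution_series` list.
#' @export
dilution_series <- function(colony_counts, dilution_factors,
                            spot_volume_ml = 0.01) {
  if (length(colony_counts) != length(dilution_factors))
    data_error("colony_counts and dilution_factors lengths differ")
  if (any(colony_counts < 0)) data_error("negative colony count")
  if (any(dilution_factors <= 0) ||
      is.unsorted(dilution_factors, strictly = TRUE))
    data_error("dilution_factors must be strictly increasing and positive")
  if (spot_volume_ml <= 0) data_error("spot_volume_ml must be positive")
  structure(list(colony_counts = colony_counts,
                 dilution_factors = dilution_factors,
                 spot_volume_ml = spot_volume_ml),
            class = "dilution_series")
}

#' Estimate log10 CFU/mL from a dilution series
#'
#' Miles-Misra style estimate: over spots whose count falls in the
#' countable range, CFU/mL = count * dilution_factor / spot_volume; the
#' estimates are averaged and returned as log10.
#'
#' @param series A [dilution_series()].
#' @param countable_range Closed count interval considered reliable
#'   (default 1-100).
#' @return log10 CFU per mL.
#' @examples
#' s <- dilution_series(c(200, 10, 1), c(1e5, 1e7, 1e8))
#' estimate_log_cfu(s)
#' @export
estimate_log_cfu <- function(series, countable_range = c(1, 100)) {
  stopifnot(inherits(series, "dilution_series"))
  ok <- series$colony_counts >= countable_range[1] &
    series$colony_counts <= countable_range[2]
  if (!any(ok))
    data_error("uncountable series: no spot count inside the countable range")
  cfu <- series$colony_counts[ok] * series$dilution_factors[ok] /
    series$spot_volume_ml
  log10(mean(cfu))
}
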