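# MSI containers and I/O. A grid holds one spectrum per pixel on a
# physical pitch; ion images are window sums per pixel. Coordinates are
# 0-based, x rightward, y downward; imzML's 1-based positions are
# converted on read/write.

#' Construct a mass spectrum
#'
#' @param mz Strictly ascending m/z values (u).
#' @param intensity Non-negative intensities, same length.
#' @param mode `"centroid"` or `"profile"`.
#' @return A `mass_spectrum` list.
#' @export
mass_spectrum <- function(mz, intensity, mode = c("centroid", "profile")) {
  mode <- match.arg(mode)
  if (length(mz) != length(intensity))
    data_error("mz and intensity lengths differ")
  if (length(mz) && is.unsorted(mz, strictly = TRUE))
    data_error("spectrum m/z must be strictly ascending")
  if (any(intensity < 0)) data_error("negative intensity")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 mode = mode), class = "mass_spectrum")
}

#' Construct an MSI grid
#'
#' @param width,height Grid dimensions in pixels.
#' @param pitch Physical pixel pitch in micrometres (any positive value;
#'   10/25/50 are the usual laser pitches).
#' @param metadata Free-form named list.
#' @return An `msi_grid` with an empty pixel list; fill with
#'   [set_pixel()].
#' @export
msi_grid <- function(width, height, pitch, metadata = list()) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L || pitch <= 0)
    data_error("grid dimensions and pitch must be positive")
  structure(list(width = width, height = height, pitch = pitch,
                 spectra = vector("list", width * height),
                 metadata = metadata),
            class = "msi_grid")
}

.pix_idx <- function(grid, x, y) {
  if (any(x < 0L) || any(x >= grid$width) || any(y < 0L) || any(y >= grid$height))
    data_error(sprintf("pixel (%d,%d) outside %dx%d grid",
                       x[1], y[1], grid$width, grid$height))
  y * grid$width + x + 1L
}

#' Set or get one pixel's spectrum
#'
#' @param grid An `msi_grid`.
#' @param x,y 0-based pixel coordinates.
#' @param spectrum A `mass_spectrum` (for `set_pixel`).
#' @return `set_pixel` returns the modified grid; `get_pixel` the
#'   spectrum or `NULL` for an empty pixel.
#' @export
set_pixel <- function(grid, x, y, spectrum) {
  stopifnot(inherits(grid, "msi_grid"), inherits(spectrum, "mass_spectrum"))
  grid$spectra[[.pix_idx(grid, as.integer(x), as.integer(y))]] <- spectrum
  grid
}

#' @rdname set_pixel
#' @export
get_pixel <- function(grid, x, y) {
  grid$spectra[[.pix_idx(grid, as.integer(x), as.integer(y))]]
}

#' @export
print.msi_grid <- function(x, ...) {
  n <- sum(!vapply(x$spectra, is.null, logical(1)))
  cat(sprintf("<msi_grid> %dx%d px, pitch %g um, %d non-empty pixels\n",
              x$width, x$height, x$pitch, n))
  invisible(x)
}

## ---- plain text-grid format -------------------------------------------

#' Write an MSI grid
#'
#' `format = "text"` writes the plain-text grid format: a header with
#' `width`, `height`, `pitch`, then one line per non-empty pixel with
#' `x`, `y` and semicolon-separated `mz:intensity` pairs.
#' `format = "imzml"` writes an imzML XML file plus its binary `.ibd`
#' companion; `imzml_mode = "continuous"` requires all non-empty pixels
#' to share one m/z axis, `"processed"` stores each pixel's own axis.
#'
#' @param grid An `msi_grid`.
#' @param path Output path (for imzML, the `.imzML` path; the `.ibd`
#'   companion is written alongside).
#' @param format `"text"` or `"imzml"`.
#' @param imzml_mode `"continuous"` or `"processed"`.
#' @return `path`, invisibly.
#' @export
write_msi <- function(grid, path, format = c("text", "imzml"),
                      imzml_mode = c("processed", "continuous")) {
  stopifnot(inherits(grid, "msi_grid"))
  format <- match.arg(format)
  if (format == "text") .write_msi_text(grid, path)
  else .write_imzml(grid, path, match.arg(imzml_mode))
  invisible(path)
}

.write_msi_text <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# scfamsi text-grid v1",
               sprintf("width\t%d", grid$width),
               sprintf("height\t%d", grid$height),
               sprintf("pitch\t%s", format(grid$pitch, digits = 15))), con)
  for (y in seq_len(grid$height) - 1L) {
    for (x in seq_len(grid$width) - 1L) {
      sp <- grid$spectra[[y * grid$width + x + 1L]]
      if (is.null(sp) || !length(sp$mz)) next
      pairs <- paste(format(sp$mz, digits = 15),
                     format(sp$intensity, digits = 15), sep = ":")
      writeLines(sprintf("%d\t%d\t%s", x, y, paste(pairs, collapse = ";")), con)
    }
  }
}

.read_msi_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^(width|height|pitch)\t", lines[i])) {
    kv <- strsplit(lines[i], "\t")[[1]]
    hdr[[kv[1]]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  for (k in c("width", "height", "pitch"))
    if (is.null(hdr[[k]])) data_error(sprintf("text-grid %s: missing header '%s'", path, k))
  grid <- msi_grid(hdr$width, hdr$height, hdr$pitch)
  seen <- new.env(hash = TRUE)
  for (ln in if (i <= length(lines)) lines[i:length(lines)] else character(0)) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) != 3L)
      data_error(sprintf("text-grid %s: malformed pixel line '%s'", path, ln))
    x <- as.integer(parts[1]); y <- as.integer(parts[2])
    key <- paste(x, y)
    if (!is.null(seen[[key]]))
      data_error(sprintf("text-grid %s: duplicate pixel coordinate (%d,%d)", path, x, y))
    assign(key, TRUE, envir = seen)
    pairs <- strsplit(strsplit(parts[3], ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    mz <- vapply(pairs, function(p) as.numeric(p[1]), numeric(1))
    it <- vapply(pairs, function(p) as.numeric(p[2]), numeric(1))
    if (anyNA(mz) || anyNA(it))
      data_error(sprintf("text-grid %s: malformed peaks at pixel (%d,%d)", path, x, y))
    if (is.unsorted(mz, strictly = TRUE))
      data_error(sprintf("text-grid %s: non-ascending m/z at pixel (%d,%d)", path, x, y))
    grid <- set_pixel(grid, x, y, mass_spectrum(mz, it))
  }
  grid
}

#' Read an MSI dataset
#'
#' Reads imzML (continuous or processed binary mode, 32/64-bit float
#' arrays) or the plain text-grid format; both load to identical
#' in-memory semantics. Format is sniffed from the file when `"auto"`.
#'
#' @param path Path to `.imzML` or text-grid file.
#' @param format `"auto"`, `"imzml"` or `"text"`.
#' @return An `msi_grid`.
#' @export
read_msi <- function(path, format = c("auto", "imzml", "text")) {
  format <- match.arg(format)
  if (!file.exists(path)) usage_error(sprintf("MSI file not found: %s", path))
  if (format == "auto") {
    head <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("xml|mzML", head, ignore.case = TRUE)) "imzml" else "text"
  }
  if (format == "text") .read_msi_text(path) else .read_imzml(path)
}

## ---- imzML ------------------------------------------------------------

# Minimal imzML writer/reader: external binary arrays in the .ibd
# companion, 64-bit float encoding on write, 32/64-bit float accepted on
# read. Obo accessions used: IMS:1000030/31 (continuous/processed),
# IMS:1000050/51 (position x/y), IMS:1000102/103 (external offset /
# array length), MS:1000523/521 (64/32-bit float).

.write_imzml <- function(grid, path, mode) {
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  filled <- which(!vapply(grid$spectra, is.null, logical(1)))
  if (!length(filled)) data_error("cannot write imzML for an empty grid")
  if (mode == "continuous") {
    ref_mz <- grid$spectra[[filled[1]]]$mz
    same <- vapply(filled, function(i) identical(grid$spectra[[i]]$mz, ref_mz),
                   logical(1))
    if (!all(same))
      data_error("continuous imzML requires one shared m/z axis; use mode='processed'")
  }
  ibd <- file(ibd_path, "wb")
  on.exit(close(ibd))
  uuid <- as.raw(c(0x73, 0x63, 0x66, 0x61, 0x6d, 0x73, 0x69, 0x00,
                   0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x01))
  writeBin(uuid, ibd)
  offset <- 16
  mz_off <- numeric(length(filled)); mz_len <- integer(length(filled))
  it_off <- numeric(length(filled)); it_len <- integer(length(filled))
  if (mode == "continuous") {
    mz_vec <- grid$spectra[[filled[1]]]$mz
    writeBin(as.numeric(mz_vec), ibd, size = 8, endian = "little")
    mz_off[] <- offset; mz_len[] <- length(mz_vec)
    offset <- offset + 8 * length(mz_vec)
    for (k in seq_along(filled)) {
      it <- grid$spectra[[filled[k]]]$intensity
      writeBin(as.numeric(it), ibd, size = 8, endian = "little")
      it_off[k] <- offset; it_len[k] <- length(it)
      offset <- offset + 8 * length(it)
    }
  } else {
    for (k in seq_along(filled)) {
      sp <- grid$spectra[[filled[k]]]
      writeBin(as.numeric(sp$mz), ibd, size = 8, endian = "little")
      mz_off[k] <- offset; mz_len[k] <- length(sp$mz)
      offset <- offset + 8 * length(sp$mz)
      writeBin(as.numeric(sp$intensity), ibd, size = 8, endian = "little")
      it_off[k] <- offset; it_len[k] <- length(sp$intensity)
      offset <- offset + 8 * length(sp$intensity)
    }
  }
  mode_acc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
  mode_name <- paste0(mode, " imzML")
  xy <- arrayInd(filled, c(grid$width, grid$height))  # column-major index -> x,y
  spectra_xml <- vapply(seq_along(filled), function(k) {
    x1 <- xy[k, 1]; y1 <- xy[k, 2]  # already 1-based
    paste0(
      '<spectrum index="', k - 1L, '" id="spectrum=', k, '" defaultArrayLength="0">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="', x1, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="', y1, '"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', mz_len[k], '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', format(mz_off[k], scientific = FALSE), '"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', it_len[k], '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', format(it_off[k], scientific = FALSE), '"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="', mode_acc, '" name="', mode_name, '"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<scanSettingsList count="1"><scanSettings id="scan1">',
    '<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="', grid$width, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="', grid$height, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="', grid$pitch, '"/>',
    '</scanSettings></scanSettingsList>',
    '<run id="run1">',
    '<spectrumList count="', length(filled), '">',
    paste(spectra_xml, collapse = ""),
    '</spectrumList></run></mzML>\n')
  writeLines(xml, path, sep = "")
}

.cv_value <- function(node, accession) {
  p <- xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) return(NA_character_)
  xml2::xml_attr(p, "value")
}

.read_imzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path) || !file.exists(ibd_path))
    ibd_path <- paste0(path, ".ibd")
  if (!file.exists(ibd_path))
    data_error(sprintf("imzML binary companion not found for %s", path))
  fc <- xml2::xml_find_first(doc, ".//fileContent")
  continuous <- !inherits(
    xml2::xml_find_first(fc, ".//cvParam[@accession='IMS:1000030']"),
    "xml_missing")
  # param groups: which array + precision
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  ginfo <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    kind <- if (!inherits(xml2::xml_find_first(
      g, ".//cvParam[@accession='MS:1000514']"), "xml_missing")) "mz"
    else if (!inherits(xml2::xml_find_first(
      g, ".//cvParam[@accession='MS:1000515']"), "xml_missing")) "intensity"
    else NA_character_
    size <- if (!inherits(xml2::xml_find_first(
      g, ".//cvParam[@accession='MS:1000521']"), "xml_missing")) 4L else 8L
    ginfo[[id]] <- list(kind = kind, size = size)
  }
  ss <- xml2::xml_find_first(doc, ".//scanSettings")
  width <- as.integer(.cv_value(ss, "IMS:1000042"))
  height <- as.integer(.cv_value(ss, "IMS:1000043"))
  pitch <- as.numeric(.cv_value(ss, "IMS:1000046"))
  if (is.na(pitch)) pitch <- 1
  spectra <- xml2::xml_find_all(doc, ".//run//spectrum")
  if (is.na(width) || is.na(height)) {
    xs <- as.integer(vapply(spectra, .cv_value, character(1), "IMS:1000050"))
    ys <- as.integer(vapply(spectra, .cv_value, character(1), "IMS:1000051"))
    width <- max(xs); height <- max(ys)
  }
  grid <- msi_grid(width, height, pitch,
                   metadata = list(source = path,
                                   imzml_mode = if (continuous) "continuous" else "processed"))
  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd))
  read_array <- function(offset, n, size) {
    seek(ibd, where = offset, origin = "start")
    readBin(ibd, what = "double", n = n, size = size, endian = "little")
  }
  seen <- new.env(hash = TRUE)
  for (sp in spectra) {
    x1 <- as.integer(.cv_value(sp, "IMS:1000050"))
    y1 <- as.integer(.cv_value(sp, "IMS:1000051"))
    key <- paste(x1, y1)
    if (!is.null(seen[[key]]))
      data_error(sprintf("imzML %s: duplicate pixel coordinate (%d,%d)", path, x1, y1))
    assign(key, TRUE, envir = seen)
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- NULL; it <- NULL
    for (a in arrays) {
      ref <- xml2::xml_find_first(a, ".//referenceableParamGroupRef")
      gid <- if (inherits(ref, "xml_missing")) NA else xml2::xml_attr(ref, "ref")
      info <- if (!is.na(gid) && gid %in% names(ginfo)) ginfo[[gid]]
      else {
        kind <- if (!inherits(xml2::xml_find_first(
          a, ".//cvParam[@accession='MS:1000514']"), "xml_missing")) "mz" else "intensity"
        size <- if (!inherits(xml2::xml_find_first(
          a, ".//cvParam[@accession='MS:1000521']"), "xml_missing")) 4L else 8L
        list(kind = kind, size = size)
      }
      off <- as.numeric(.cv_value(a, "IMS:1000102"))
      n <- as.integer(.cv_value(a, "IMS:1000103"))
      vals <- read_array(off, n, info$size)
      if (identical(info$kind, "mz")) mz <- vals else it <- vals
    }
    if (is.null(mz) || is.null(it))
      data_error(sprintf("imzML %s: spectrum at (%d,%d) lacks m/z or intensity array",
                         path, x1, y1))
    if (is.unsorted(mz, strictly = TRUE))
      data_error(sprintf("imzML %s: non-ascending m/z at pixel (%d,%d)", path, x1, y1))
    grid <- set_pixel(grid, x1 - 1L, y1 - 1L, mass_spectrum(mz, it))
  }
  grid
}

## ---- ion images -------------------------------------------------------

#' Extract an ion image at a target m/z
#'
#' Per pixel, sums all intensities whose m/z falls in the closed window
#' `[center - tolerance, center + tolerance]`. Pixels with no samples in
#' the window (or no spectrum) get 0. The default +/- 0.05 u window is
#' the conventional display width for high-resolution small-molecule
#' imaging; note it cannot separate species 0.008 u apart, so a
#' contaminated target needs a much tighter window.
#'
#' @param grid An `msi_grid`.
#' @param center Target m/z (u).
#' @param tolerance Half-window in u (> 0), default 0.05.
#' @return An `ion_image`: matrix of values (`height` rows, `width`
#'   columns, y increasing downward) plus window metadata.
#' @export
extract_ion_image <- function(grid, center, tolerance = 0.05) {
  stopifnot(inherits(grid, "msi_grid"))
  if (tolerance <= 0) data_error("tolerance must be positive")
  lo <- center - tolerance; hi <- center + tolerance
  vals <- matrix(0, nrow = grid$height, ncol = grid$width)
  any_cover <- FALSE
  for (y in seq_len(grid$height) - 1L) {
    for (x in seq_len(grid$width) - 1L) {
      sp <- grid$spectra[[y * grid$width + x + 1L]]
      if (is.null(sp) || !length(sp$mz)) next
      if (sp$mz[1] <= hi && sp$mz[length(sp$mz)] >= lo) any_cover <- TRUE
      i <- findInterval(c(lo - 1e-12, hi + 1e-12), sp$mz)
      if (i[2] > i[1]) {
        sel <- (i[1] + 1L):i[2]
        sel <- sel[sp$mz[sel] >= lo & sp$mz[sel] <= hi]
        vals[y + 1L, x + 1L] <- sum(sp$intensity[sel])
      }
    }
  }
  if (!any_cover)
    warning(sprintf("m/z %.4f +/- %g outside every pixel's range; image is all zero",
                    center, tolerance))
  structure(list(values = vals, center = center, tolerance = tolerance,
                 normalization = grid$metadata$normalization %||% "none",
                 pitch = grid$pitch),
            class = "ion_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> m/z %.4f +/- %g, %dx%d px, max %.3g\n",
              x$center, x$tolerance, ncol(x$values), nrow(x$values),
              max(x$values)))
  invisible(x)
}

#' Total-ion-current normalize a grid
#'
#' Scales each non-empty pixel's intensities so they sum to 1; empty and
#' all-zero pixels are left untouched. Idempotent; flagged in metadata.
#'
#' @param grid An `msi_grid` with at least one pixel of positive total
#'   intensity.
#' @return The normalized grid.
#' @export
tic_normalize <- function(grid) {
  stopifnot(inherits(grid, "msi_grid"))
  any_pos <- FALSE
  for (i in seq_along(grid$spectra)) {
    sp <- grid$spectra[[i]]
    if (is.null(sp)) next
    tot <- sum(sp$intensity)
    if (tot > 0) {
      any_pos <- TRUE
      grid$spectra[[i]]$intensity <- sp$intensity / tot
    }
  }
  if (!any_pos) data_error("TIC normalization: no pixel with positive total intensity")
  grid$metadata$normalization <- "TIC"
  grid
}

## ---- region masks and statistics --------------------------------------

#' Construct a named region mask
#'
#' @param name Region name (e.g. `"smooth_muscle"`, `"bacterial_lumen"`).
#' @param pixels Data.frame with 0-based integer columns `x`, `y`.
#' @return A `region_mask`.
#' @export
region_mask <- function(name, pixels) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.data.frame(pixels) || !all(c("x", "y") %in% names(pixels)))
    data_error("pixels must be a data.frame with columns x, y")
  structure(list(name = name,
                 pixels = data.frame(x = as.integer(pixels$x),
                                     y = as.integer(pixels$y))),
            class = "region_mask")
}

#' Read/write region masks as TSV of name, x, y
#'
#' @param path TSV path.
#' @param masks List of `region_mask` (for writing).
#' @return `read_masks` returns a named list of `region_mask`.
#' @export
read_masks <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("mask file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y") %in% names(df)))
    data_error(sprintf("mask file %s must have columns name, x, y", path))
  out <- lapply(split(df, df$name), function(d)
    region_mask(d$name[1], d[, c("x", "y")]))
  out[unique(df$name)]
}

#' @rdname read_masks
#' @export
write_masks <- function(masks, path) {
  df <- do.call(rbind, lapply(masks, function(m)
    data.frame(name = m$name, x = m$pixels$x, y = m$pixels$y)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.mask_values <- function(image, mask) {
  v <- image$values
  if (!nrow(mask$pixels))
    data_error(sprintf("region '%s' is empty", mask$name))
  if (any(mask$pixels$x < 0) || any(mask$pixels$x >= ncol(v)) ||
      any(mask$pixels$y < 0) || any(mask$pixels$y >= nrow(v)))
    data_error(sprintf("region '%s' has pixels outside the image", mask$name))
  v[cbind(mask$pixels$y + 1L, mask$pixels$x + 1L)]
}

#' Descriptive statistics of an ion image per region
#'
#' @param image An `ion_image`.
#' @param masks List of `region_mask` (pairwise disjoint for a fair
#'   comparison; not enforced).
#' @return Data.frame `region`, `n_pixels`, `mean`, `median`, `max`.
#' @export
region_stats <- function(image, masks) {
  stopifnot(inherits(image, "ion_image"))
  if (inherits(masks, "region_mask")) masks <- list(masks)
  if (!length(masks)) data_error("no region masks supplied")
  rows <- lapply(masks, function(m) {
    vals <- .mask_values(image, m)
    data.frame(region = m$name, n_pixels = length(vals),
               mean = mean(vals), median = stats::median(vals),
               max = max(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean-signal contrast ratio between two regions
#'
#' @param image An `ion_image`.
#' @param region_a,region_b `region_mask` objects.
#' @return `mean(a) / mean(b)`; `Inf` when region b has zero mean signal
#'   and region a does not; `NaN` when both are zero.
#' @export
contrast_ratio <- function(image, region_a, region_b) {
  a <- mean(.mask_values(image, region_a))
  b <- mean(.mask_values(image, region_b))
  if (b == 0) {
    if (a == 0) return(NaN)
    return(Inf)
  }
  a / b
}

## ---- image export -----------------------------------------------------

#' Export an ion image
#'
#' TSV is exact: full-precision values, row-major with y increasing
#' downward, tab-separated, no header. PNG is a linear min-max grayscale
#' rendering for visual inspection only (requires PNG support in the R
#' build).
#'
#' @param image An `ion_image`.
#' @param path Output path.
#' @param format `"tsv"` or `"png"`.
#' @return `path`, invisibly.
#' @export
export_image <- function(image, path, format = c("tsv", "png")) {
  stopifnot(inherits(image, "ion_image"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(format(image$values, digits = 17), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    if (!capabilities("png"))
      data_error("this R build lacks PNG support; use format='tsv'")
    v <- image$values
    rng <- range(v)
    g <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
    grDevices::png(path, width = ncol(v), height = nrow(v))
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(t(g)[, nrow(g):1, drop = FALSE], axes = FALSE,
                    col = grDevices::gray.colors(256, 0, 1), useRaster = TRUE)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(path)
}

#' Re-import an image exported as TSV
#'
#' @param path TSV written by [export_image()].
#' @return Numeric matrix (y rows downward, x columns).
#' @export
import_image_tsv <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("image file not found: %s", path))
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}
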