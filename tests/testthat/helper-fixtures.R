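# Shared fixtures built in code.

# The 19-compound monocarboxylic panel with its published theoretical
# m/z reference column (frozen from the high-resolution reference table;
# values are singly tagged, singly charged TMPA amides).
reference_panel <- function() {
  data.frame(
    name = c("Propionic acid", "Lactic acid", "Butyric acid",
             "Pentanoic acid", "Hexanoic acid", "Octanoic acid",
             "Decanoic acid", "Lauric acid", "Myristic acid",
             "Palmitoleic acid", "Palmitic acid", "Linolenic acid",
             "Linoleic acid", "Oleic acid", "Stearic acid",
             "Arachidic acid", "Arachidonic acid",
             "Eicosapentaenoic acid", "Docosahexaenoic acid"),
    formula = c("C3H6O2", "C3H6O3", "C4H8O2", "C5H10O2", "C6H12O2",
                "C8H16O2", "C10H20O2", "C12H24O2", "C14H28O2",
                "C16H30O2", "C16H32O2", "C18H30O2", "C18H32O2",
                "C18H34O2", "C18H36O2", "C20H40O2", "C20H32O2",
                "C20H30O2", "C22H32O2"),
    n_carboxyl = 1L,
    printed_mz = c(228.2071, 244.2020, 242.2227, 256.2384, 270.2540,
                   298.2853, 326.3166, 354.3479, 382.3792, 408.3949,
                   410.4105, 432.3949, 434.4105, 436.4262, 438.4418,
                   466.4731, 458.4105, 456.3949, 482.4105),
    stringsAsFactors = FALSE)
}

extdata <- function(file) {
  system.file("extdata", file, package = "scfamsi", mustWork = TRUE)
}

# a small deterministic grid: 2x2, distinct peaks per pixel
tiny_grid <- function() {
  g <- msi_grid(2, 2, pitch = 25)
  g <- set_pixel(g, 0, 0, mass_spectrum(c(100.0, 242.223, 242.231), c(1, 10, 5)))
  g <- set_pixel(g, 1, 0, mass_spectrum(c(150.5, 300.25), c(2, 3)))
  g <- set_pixel(g, 0, 1, mass_spectrum(c(242.223), c(7)))
  # pixel (1,1) intentionally left empty
  g
}

# random centroid grids for property tests
random_grid <- function(width, height, n_peaks = 8) {
  g <- msi_grid(width, height, pitch = 10)
  for (y in seq_len(height) - 1L) {
    for (x in seq_len(width) - 1L) {
      mz <- sort(stats::runif(n_peaks, 200, 500))
      mz <- mz[c(TRUE, diff(mz) > 0)]
      g <- set_pixel(g, x, y, mass_spectrum(mz, stats::rexp(length(mz))))
    }
  }
  g
}

# brute-force window-sum oracle, independent of extract_ion_image
oracle_window_image <- function(grid, center, tolerance) {
  vals <- matrix(0, nrow = grid$height, ncol = grid$width)
  for (y in seq_len(grid$height) - 1L) {
    for (x in seq_len(grid$width) - 1L) {
      sp <- get_pixel(grid, x, y)
      if (is.null(sp)) next
      s <- 0
      for (i in seq_along(sp$mz)) {
        if (sp$mz[i] >= center - tolerance && sp$mz[i] <= center + tolerance)
          s <- s + sp$intensity[i]
      }
      vals[y + 1, x + 1] <- s
    }
  }
  vals
}

# brute-force per-atom mass oracle, independent of the vectorized sum
oracle_atom_mass <- function(formula_string, table) {
  f <- parse_formula(formula_string)
  total <- 0
  for (el in names(f)) {
    for (i in seq_len(f[[el]])) total <- total + table[[el]]
  }
  total
}

random_formula_string <- function() {
  els <- sample(c("C", "H", "N", "O", "S", "P", "I"),
                size = sample(2:5, 1))
  paste0(els, sample(1:30, length(els), replace = TRUE), collapse = "")
}
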