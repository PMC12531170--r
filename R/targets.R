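# TMPA derivatization mass model: theoretical target species for
# carboxylic acids tagged with the quaternary amine, plus the catalogue of
# matrix interference ions.
#
# The amide-coupling stoichiometry is: acid + TMPA cation - H2O per tag.
# The tag is a pre-formed cation, so its contribution is the formula mass
# of C9H22N3 minus one electron per tag (each tag carries +1).

#' Describe a carboxylic-acid compound
#'
#' @param name Compound name, unique within a panel.
#' @param formula Neutral molecule as `chem_formula` or Hill string.
#' @param n_carboxyl Number of carboxyl groups (>= 1 for derivatization).
#' @return A `compound_spec` list with fields `name`, `formula`, `n_carboxyl`.
#' @examples
#' compound_spec("Butyric acid", "C4H8O2", 1)
#' @export
compound_spec <- function(name, formula, n_carboxyl = 1L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_carboxyl <- as.integer(n_carboxyl)
  if (is.na(n_carboxyl) || n_carboxyl < 0L)
    data_error("n_carboxyl must be a non-negative integer")
  structure(list(name = name, formula = as_formula(formula),
                 n_carboxyl = n_carboxyl),
            class = "compound_spec")
}

.tmpa_tag_mass <- function() {
  monoisotopic_mass(.tmpa_cation_formula) - .electron_mass
}

#' Theoretical m/z of a TMPA-derivatized species
#'
#' Computes the mass-to-charge ratio of a carboxylic acid carrying
#' `n_tags` TMPA amide tags. Each tag adds the mass of the pre-formed
#' TMPA cation (formula mass minus one electron) and removes one water
#' (amide condensation). Optional neutral losses are subtracted before
#' dividing by the charge.
#'
#' @param compound A `compound_spec` (see [compound_spec()]).
#' @param n_tags Number of TMPA tags; `1 <= n_tags <= n_carboxyl`.
#' @param charge Positive charge; `1 <= charge <= n_tags`.
#' @param neutral_losses List of formulas (objects or strings) subtracted
#'   as neutral losses; default none.
#' @return A `target_species` list: `name`, `n_tags`, `charge`,
#'   `neutral_losses` (character vector, Hill notation),
#'   `theoretical_mz`, `label`.
#' @examples
#' tmpa_derivatized_mz(compound_spec("Butyric acid", "C4H8O2", 1))
#' @export
tmpa_derivatized_mz <- function(compound, n_tags = 1L, charge = 1L,
                                neutral_losses = list()) {
  if (!inherits(compound, "compound_spec"))
    data_error("compound must be a compound_spec")
  n_tags <- as.integer(n_tags); charge <- as.integer(charge)
  if (compound$n_carboxyl < 1L)
    data_error(sprintf("'%s' has no carboxyl group to derivatize", compound$name))
  if (n_tags < 1L || n_tags > compound$n_carboxyl)
    data_error(sprintf("n_tags (%d) must be in 1..n_carboxyl (%d) for '%s'",
                       n_tags, compound$n_carboxyl, compound$name))
  if (charge < 1L || charge > n_tags)
    data_error(sprintf("charge (%d) must be in 1..n_tags (%d)", charge, n_tags))
  losses <- lapply(neutral_losses, as_formula)
  # composition check: losses must be subtractable from the tagged species
  tagged <- compound$formula
  for (i in seq_len(n_tags)) {
    tagged <- formula_add(tagged, .tmpa_cation_formula)
    tagged <- formula_subtract(tagged, .water_formula)
  }
  for (l in losses) tagged <- formula_subtract(tagged, l)  # errors if negative
  loss_mass <- sum(vapply(losses, monoisotopic_mass, numeric(1)), 0)
  mz <- (monoisotopic_mass(compound$formula) +
           n_tags * .tmpa_tag_mass() -
           n_tags * monoisotopic_mass(.water_formula) -
           loss_mass) / charge
  label <- sprintf("%s [+%dTMPA]%s%s", compound$name, n_tags,
                   if (length(losses))
                     paste0(" -", vapply(losses, format_formula, character(1)),
                            collapse = "")
                   else "",
                   sprintf(" %d+", charge))
  structure(list(name = compound$name, n_tags = n_tags, charge = charge,
                 neutral_losses = vapply(losses, format_formula, character(1)),
                 theoretical_mz = mz, label = label),
            class = "target_species")
}

#' @export
print.target_species <- function(x, ...) {
  cat(sprintf("<target_species> %s  m/z %.4f\n", x$label, x$theoretical_mz))
  invisible(x)
}

.species_row <- function(sp) {
  data.frame(name = sp$name, n_tags = sp$n_tags, charge = sp$charge,
             losses = paste(sp$neutral_losses, collapse = ";"),
             theoretical_mz = sp$theoretical_mz, label = sp$label,
             stringsAsFactors = FALSE)
}

#' Build a theoretical target table for a compound panel
#'
#' Monocarboxylic compounds yield one singly tagged, singly charged
#' species. Polycarboxylic compounds are enumerated with
#' `charge = n_tags` for each tag count up to `n_carboxyl` (each
#' quaternary tag carries one permanent positive charge). Output is
#' sorted by theoretical m/z with a stable order.
#'
#' @param panel A list of `compound_spec` objects, or a data.frame with
#'   columns `name`, `formula`, `n_carboxyl`.
#' @param tma_loss If `TRUE`, additionally subtract one trimethylamine
#'   (C3H9N) per tag as a neutral loss. Off by default; offered because
#'   in-source fragmentation of the quaternary tag is commonly observed
#'   for multiply tagged species.
#' @return A data.frame with columns `name`, `n_tags`, `charge`,
#'   `losses`, `theoretical_mz`, `label`.
#' @examples
#' panel <- list(compound_spec("Propionic acid", "C3H6O2", 1),
#'               compound_spec("Citric acid", "C6H8O7", 3))
#' build_target_table(panel)
#' @export
build_target_table <- function(panel, tma_loss = FALSE) {
  if (is.data.frame(panel)) {
    req <- c("name", "formula", "n_carboxyl")
    if (!all(req %in% names(panel)))
      data_error(sprintf("panel data.frame must have columns: %s",
                         paste(req, collapse = ", ")))
    panel <- lapply(seq_len(nrow(panel)), function(i)
      compound_spec(panel$name[i], panel$formula[i], panel$n_carboxyl[i]))
  }
  if (!length(panel)) data_error("panel is empty")
  nms <- vapply(panel, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    data_error(sprintf("duplicate compound name(s): %s",
                       paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  rows <- list()
  for (cp in panel) {
    for (k in seq_len(cp$n_carboxyl)) {
      losses <- if (tma_loss) rep(list(.trimethylamine_formula), k) else list()
      rows[[length(rows) + 1L]] <-
        .species_row(tmpa_derivatized_mz(cp, n_tags = k, charge = k,
                                         neutral_losses = losses))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$theoretical_mz, out$name, out$n_tags), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Catalogue of matrix interference ions
#'
#' Returns the catalogued adduct/fragment species associated with a MALDI
#' matrix or endogenous interference source, with theoretical m/z
#' computed from the pinned mass tables except where flagged empirical.
#'
#' Supported catalogues:
#' \describe{
#'   \item{`"CHCA"`}{alpha-cyano-4-hydroxycinnamic acid (C10H7NO3):
#'     protonated monomer, the dimer fragment \eqn{[2M-CO_2+H]^+}, and the
#'     TMPA condensation amide (matrix + tag cation - water).}
#'   \item{`"1,5-DAN"`}{1,5-diaminonaphthalene (C10H10N2): protonated
#'     monomer, plus the empirical derivatization-protocol contaminant at
#'     m/z 242.231 that sits 0.008 u above butyrate-TMPA (242.2227) and is
#'     not formula-derived.}
#'   \item{`"cholesterol-endogenous"`}{cholesterol (C27H46O) hydroxide-loss
#'     cation \eqn{[M-OH]^+}.}
#' }
#'
#' @param matrix_name One of `"CHCA"`, `"1,5-DAN"`,
#'   `"cholesterol-endogenous"`.
#' @return Data.frame with columns `name`, `species`, `theoretical_mz`,
#'   `empirical` (logical: m/z observed, not computed).
#' @examples
#' interference_ions("CHCA")
#' @export
interference_ions <- function(matrix_name) {
  proton <- .proton_mass; electron <- .electron_mass
  row <- function(name, species, mz, empirical = FALSE)
    data.frame(name = name, species = species, theoretical_mz = mz,
               empirical = empirical, stringsAsFactors = FALSE)
  if (identical(matrix_name, "CHCA")) {
    chca <- monoisotopic_mass("C10H7NO3")
    rbind(
      row("CHCA", "[M+H]+", chca + proton),
      row("CHCA", "[2M-CO2+H]+",
          2 * chca - monoisotopic_mass(.carbon_dioxide_formula) + proton),
      row("CHCA-TMPA amide", "[M+TMPA-H2O]+",
          chca + .tmpa_tag_mass() - monoisotopic_mass(.water_formula))
    )
  } else if (identical(matrix_name, "1,5-DAN")) {
    dan <- monoisotopic_mass("C10H10N2")
    rbind(
      row("1,5-DAN", "[M+H]+", dan + proton),
      row("DAN-protocol contaminant", "unknown (empirical)", 242.231,
          empirical = TRUE)
    )
  } else if (identical(matrix_name, "cholesterol-endogenous")) {
    row("Cholesterol", "[M-OH]+",
        monoisotopic_mass("C27H46O") - monoisotopic_mass("HO") - electron)
  } else {
    data_error(sprintf(
      "unknown matrix '%s' (supported: CHCA, 1,5-DAN, cholesterol-endogenous)",
      matrix_name))
  }
}

#' Read a compound panel from delimited text
#'
#' Expects a TSV with a header row and columns `name`, `formula`,
#' `n_carboxyl`.
#'
#' @param path Path to the panel file.
#' @return A list of `compound_spec` objects.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("panel file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("name", "formula", "n_carboxyl")
  if (!all(req %in% names(df)))
    data_error(sprintf("panel file %s must have columns: %s",
                       path, paste(req, collapse = ", ")))
  if (!nrow(df)) data_error(sprintf("panel file %s has no rows", path))
  lapply(seq_len(nrow(df)), function(i) {
    tryCatch(compound_spec(df$name[i], df$formula[i], df$n_carboxyl[i]),
             scfamsi_data_error = function(e)
               data_error(sprintf("%s (panel line %d)", conditionMessage(e), i + 1L)))
  })
}

#' Write a target table to TSV
#'
#' Theoretical m/z is formatted at 4 decimals (the working precision of
#' high-resolution small-molecule reporting).
#'
#' @param table Data.frame from [build_target_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(table, path) {
  out <- table
  out$theoretical_mz <- sprintf("%.4f", out$theoretical_mz)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a target table written by [write_target_table()]
#'
#' @param path Path to the TSV.
#' @return Data.frame with numeric `theoretical_mz`.
#' @export
read_target_table <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("target table not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "theoretical_mz") %in% names(df)))
    data_error(sprintf("target table %s must have columns name, theoretical_mz", path))
  df$theoretical_mz <- as.numeric(df$theoretical_mz)
  df
}
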