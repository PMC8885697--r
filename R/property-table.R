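#' Read a variant property table
#'
#' Reads a CSV of per-variant functional measurements made in heterologous
#' expression systems and converts agonist EC50 values to potencies (1/EC50).
#' The table must contain a `WT` reference row with no missing values; mutant
#' rows may have missing cells (left empty in the CSV), which can later be
#' filled by [impute_missing()].
#'
#' Expected columns: `mutation`, `glu_ec50_uM`, `gly_ec50_uM`, `deact_tau_ms`,
#' `current_density_pA_pF`, `open_prob`, `surface_rel`. All observed values
#' must be strictly positive (they are later log-transformed).
#'
#' @param path Path to the CSV file.
#' @return A `property_table`: a tibble with columns `mutation`, `glu_potency`,
#'   `gly_potency`, `deact_tau`, `current_density`, `open_prob`,
#'   `surface_level`, carrying attribute `wt` (named numeric reference row).
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("mutation", "glu_ec50_uM", "gly_ec50_uM", "deact_tau_ms",
              "current_density_pA_pF", "open_prob", "surface_rel")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  tbl <- tibble::tibble(
    mutation        = as.character(raw$mutation),
    glu_potency     = 1 / as.numeric(raw$glu_ec50_uM),
    gly_potency     = 1 / as.numeric(raw$gly_ec50_uM),
    deact_tau       = as.numeric(raw$deact_tau_ms),
    current_density = as.numeric(raw$current_density_pA_pF),
    open_prob       = as.numeric(raw$open_prob),
    surface_level   = as.numeric(raw$surface_rel)
  )
  as_property_table(tbl)
}

property_cols <- function() {
  c("glu_potency", "gly_potency", "deact_tau", "current_density",
    "open_prob", "surface_level")
}

#' Construct a property table from a data frame
#'
#' Validates positivity and the WT reference row and attaches the WT row as an
#' attribute so downstream normalisation always has its reference.
#'
#' @param x Data frame with a `mutation` column and the six property columns
#'   (`glu_potency`, `gly_potency`, `deact_tau`, `current_density`,
#'   `open_prob`, `surface_level`). Potencies are reciprocal EC50s (1/uM).
#' @return A `property_table` tibble.
#' @export
as_property_table <- function(x) {
  cols <- property_cols()
  stopifnot(all(c("mutation", cols) %in% names(x)))
  tbl <- tibble::as_tibble(x)[, c("mutation", cols)]
  for (cl in cols) {
    bad <- which(!is.na(tbl[[cl]]) & tbl[[cl]] <= 0)
    if (length(bad) > 0) {
      abort(paste0("non-positive value in column '", cl, "', row '",
                   tbl$mutation[bad[1]], "' (all properties must be > 0)"))
    }
  }
  iwt <- which(tbl$mutation == "WT")
  if (length(iwt) != 1) abort("exactly one 'WT' reference row is required")
  wt <- unlist(tbl[iwt, cols])
  if (anyNA(wt)) abort("the WT reference row must have no missing values")
  structure(tbl, wt = wt, class = c("property_table", class(tbl)))
}

#' Missingness mask of a property table
#'
#' @param tbl A `property_table`.
#' @return Logical matrix (rows = variants, columns = properties), `TRUE`
#'   where the measurement is missing.
#' @export
missing_mask <- function(tbl) {
  m <- is.na(as.matrix(tbl[, property_cols()]))
  rownames(m) <- tbl$mutation
  m
}

#' Approximate an agonist potency from single-channel proxies
#'
#' Scales a reference variant's potency by the target/reference ratio of
#' single-channel opening frequency, corrected for the difference in surface
#' expression. Used when a variant has no direct concentration-response data
#' but its channel activity relative to a measured variant is known.
#'
#' @param potency_ref Reference potency (1/uM).
#' @param open_freq_ref,open_freq_target Single-channel opening frequencies
#'   (events/s) for the reference and target variants.
#' @param surface_ref,surface_target Relative surface expression of each.
#' @return Approximated potency (1/uM):
#'   `potency_ref * (open_freq_target / surface_target) /
#'    (open_freq_ref / surface_ref)`.
#' @export
approximate_potency_from_proxy <- function(potency_ref, open_freq_ref,
                                           surface_ref, open_freq_target,
                                           surface_target) {
  vals <- c(potency_ref, open_freq_ref, surface_ref,
            open_freq_target, surface_target)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all proxy inputs must be positive and finite")
  }
  potency_ref * (open_freq_target / surface_target) /
    (open_freq_ref / surface_ref)
}

#' Normalise a complete property table to WT log10 ratios
#'
#' Each cell becomes `log10(value / WT value)` for that property. Because
#' potencies are stored as reciprocal EC50s and the deactivation time constant
#' enters un-inverted, positive values read as gain-of-function throughout
#' (slower deactivation = more charge = gain).
#'
#' @param tbl A complete (no missing cells) `property_table`.
#' @return A tibble with `mutation` plus the six properties on the log10-ratio
#'   scale; the WT row is all zeros. Class `log_ratio_table`.
#' @export
normalize_log <- function(tbl) {
  stopifnot(inherits(tbl, "property_table"))
  if (any(missing_mask(tbl))) {
    abort("table has missing cells; run impute_missing() first")
  }
  wt <- attr(tbl, "wt")
  out <- tbl
  for (cl in property_cols()) out[[cl]] <- log10(tbl[[cl]] / wt[[cl]])
  class(out) <- c("log_ratio_table", "tbl_df", "tbl", "data.frame")
  attr(out, "wt") <- wt
  out
}
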