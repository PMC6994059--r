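#' Build a diet composition table
#'
#' Constructs a validated table of proximate composition on a dry-matter
#' basis (DMB). Every nutrient column is a percentage of dry matter on the
#' 0--100 scale; `dm_pct` (dry matter as a percentage of as-is mass) is
#' carried as metadata only and never enters a calculation. Gross energy
#' `ge` is measured bomb-calorimetry energy in kcal/g DM and may be `NA`
#' when only predictions are needed.
#'
#' @param df data.frame with columns `diet_id`, `dm_pct`, `ash`, `cp`,
#'   `ahf`, `tdf`, `tif`, `tsf`, `ge` (crude protein, acid-hydrolyzed fat,
#'   total/insoluble/soluble dietary fiber, gross energy).
#' @param subfraction_tol tolerance (percentage points) for the consistency
#'   check `|tif + tsf - tdf|`; default 0.5.
#' @return the data.frame with class `composition_table`, after validation.
#'   Invariant violations raise an error; use [validate_composition()] to
#'   obtain them as a report instead.
#' @seealso [compute_nfe()], [predict_ge_nrc()], [validate_composition()]
#' @export
composition_table <- function(df, subfraction_tol = 0.5) {
  req <- c("diet_id", "dm_pct", "ash", "cp", "ahf", "tdf", "tif", "tsf", "ge")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("composition table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  df$diet_id <- as.character(df$diet_id)
  if (anyDuplicated(df$diet_id)) stop("duplicate diet_id in composition table")
  viol <- validate_composition(df, subfraction_tol = subfraction_tol)
  if (length(viol) > 0L) {
    stop("invalid composition:\n  ", paste(viol, collapse = "\n  "))
  }
  structure(df, class = c("composition_table", "data.frame"),
            subfraction_tol = subfraction_tol)
}

#' Single-diet convenience constructor
#'
#' @param diet_id diet label.
#' @param cp,ahf,tdf,ash percentages of DM (crude protein, acid-hydrolyzed
#'   fat, total dietary fiber, ash).
#' @param tif,tsf insoluble/soluble fiber fractions (% DM); default to a
#'   split consistent with `tdf`.
#' @param dm_pct dry matter percent of as-is mass (metadata).
#' @param ge measured gross energy, kcal/g DM, or `NA`.
#' @inheritParams composition_table
#' @return a one-row [composition_table()].
#' @export
proximate_composition <- function(diet_id, cp, ahf, tdf, ash,
                                  tif = tdf, tsf = tdf - tif,
                                  dm_pct = NA_real_, ge = NA_real_,
                                  subfraction_tol = 0.5) {
  composition_table(
    data.frame(diet_id = diet_id, dm_pct = dm_pct, ash = ash, cp = cp,
               ahf = ahf, tdf = tdf, tif = tif, tsf = tsf, ge = ge,
               stringsAsFactors = FALSE),
    subfraction_tol = subfraction_tol)
}

#' Report composition invariant violations
#'
#' Checks each row of a composition table against the DMB invariants and
#' returns human-readable violations; it never raises, so it can be used to
#' triage incoming files.
#'
#' Checks: all percentages in \[0, 100\]; `ge > 0` when present;
#' `cp + ahf + tdf + ash <= 100` (otherwise nitrogen-free extract by
#' difference would be negative); `|tif + tsf - tdf|` within
#' `subfraction_tol` percentage points.
#'
#' @param df data.frame with the composition columns (see
#'   [composition_table()]); class is not required.
#' @inheritParams composition_table
#' @return character vector of violations; `character(0)` when all
#'   invariants hold.
#' @export
validate_composition <- function(df, subfraction_tol = 0.5) {
  viol <- character(0)
  pct_cols <- c("dm_pct", "ash", "cp", "ahf", "tdf", "tif", "tsf")
  for (i in seq_len(nrow(df))) {
    id <- as.character(df$diet_id[i])
    for (col in pct_cols) {
      x <- df[[col]][i]
      if (!is.na(x) && (x < 0 || x > 100)) {
        viol <- c(viol, sprintf("%s: %s = %.4g outside [0, 100]", id, col, x))
      }
    }
    ge <- df$ge[i]
    if (!is.na(ge) && ge <= 0) {
      viol <- c(viol, sprintf("%s: ge = %.4g must be > 0", id, ge))
    }
    macro_sum <- df$cp[i] + df$ahf[i] + df$tdf[i] + df$ash[i]
    if (!is.na(macro_sum) && macro_sum > 100) {
      viol <- c(viol, sprintf(
        "%s: CP + AHF + TDF + ash = %.2f exceeds 100 (NFE would be negative)",
        id, macro_sum))
    }
    gap <- abs(df$tif[i] + df$tsf[i] - df$tdf[i])
    if (!is.na(gap) && gap > subfraction_tol) {
      viol <- c(viol, sprintf(
        "%s: |TIF + TSF - TDF| = %.2f exceeds tolerance %.2f",
        id, gap, subfraction_tol))
    }
  }
  viol
}

#' Nitrogen-free extract by difference
#'
#' NFE (% DM) = 100 - (CP + AHF + TDF + ash), the fiber-based carbohydrate
#' estimate (total dietary fiber, not crude fiber, as the fiber term). NFE
#' is always recomputed from components so the downstream energy equations
#' stay self-consistent with their inputs; a printed NFE column in a source
#' table is only ever used as a cross-check.
#'
#' @param comp a [composition_table()] (or data.frame with `cp`, `ahf`,
#'   `tdf`, `ash` columns).
#' @return named numeric vector (names = `diet_id`), percent of DM.
#'   A negative result raises an error naming the diet and the component
#'   sum, since it signals inconsistent input chemistry.
#' @export
compute_nfe <- function(comp) {
  nfe <- 100 - (comp$cp + comp$ahf + comp$tdf + comp$ash)
  names(nfe) <- if (!is.null(comp$diet_id)) as.character(comp$diet_id)
  bad <- which(nfe < 0)
  if (length(bad) > 0L) {
    i <- bad[1L]
    stop(sprintf(
      "NFE negative for diet %s: CP + AHF + TDF + ash = %.2f > 100",
      names(nfe)[i], 100 - nfe[i]))
  }
  nfe
}

#' NRC-predicted gross energy
#'
#' GE (kcal/100 g DM) = 5.7 CP + 9.4 AHF + 4.1 (NFE + TDF), the first step
#' of the NRC fiber-based metabolizable-energy chain. Note the units: the
#' chain works per 100 g DM until the final ME step divides by 100.
#'
#' @inheritParams compute_nfe
#' @param nfe nitrogen-free extract (% DM); recomputed from `comp` by
#'   default.
#' @return named numeric, kcal per 100 g DM.
#' @export
predict_ge_nrc <- function(comp, nfe = compute_nfe(comp)) {
  out <- 5.7 * comp$cp + 9.4 * comp$ahf + 4.1 * (unname(nfe) + comp$tdf)
  names(out) <- if (!is.null(comp$diet_id)) as.character(comp$diet_id)
  out
}

#' Canonical amino-acid panel
#'
#' The fixed panel of 10 indispensable and 9 dispensable amino acids
#' (taurine included with the dispensables, as is conventional for pet-food
#' assays even though it is a sulfonic acid rather than a true amino acid).
#'
#' @param class `"all"`, `"indispensable"` or `"dispensable"`.
#' @return character vector of lower-case amino-acid names.
#' @export
aa_panel <- function(class = c("all", "indispensable", "dispensable")) {
  class <- match.arg(class)
  ind <- c("arginine", "histidine", "isoleucine", "leucine", "lysine",
           "methionine", "phenylalanine", "threonine", "tryptophan", "valine")
  disp <- c("alanine", "aspartic acid", "cysteine", "glutamic acid",
            "glycine", "proline", "serine", "tyrosine", "taurine")
  switch(class, all = c(ind, disp), indispensable = ind, dispensable = disp)
}

#' Build an amino-acid concentration table
#'
#' Long-format table of amino-acid concentrations (% DM) per diet,
#' validated against the canonical panel of [aa_panel()].
#'
#' @param df data.frame with columns `diet_id`, `amino_acid`, `pct_dm`.
#' @return the data.frame with class `aa_table`.
#' @export
aa_table <- function(df) {
  req <- c("diet_id", "amino_acid", "pct_dm")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("AA table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  df$diet_id <- as.character(df$diet_id)
  df$amino_acid <- tolower(as.character(df$amino_acid))
  unknown <- setdiff(unique(df$amino_acid), aa_panel())
  if (length(unknown) > 0L) {
    stop("amino acids outside the canonical panel: ",
         paste(unknown, collapse = ", "))
  }
  if (any(df$pct_dm < 0, na.rm = TRUE)) {
    stop("negative amino-acid concentration")
  }
  if (anyDuplicated(df[c("diet_id", "amino_acid")])) {
    stop("duplicate (diet_id, amino_acid) entries")
  }
  structure(df, class = c("aa_table", "data.frame"))
}

#' Read a composition CSV
#'
#' Expects the header `diet_id,dm_pct,ash,cp,ahf,tdf,tif,tsf,ge` (UTF-8,
#' comma-delimited, `.` decimal); all nutrient columns % DM, `ge` kcal/g DM.
#' If the file carries an extra `nfe` column it is cross-checked against the
#' recomputed value and a warning is issued at |difference| > 0.05.
#'
#' @param path file path.
#' @inheritParams composition_table
#' @return a [composition_table()].
#' @export
read_composition_csv <- function(path, subfraction_tol = 0.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("nfe" %in% names(df)) {
    supplied <- df$nfe
    df$nfe <- NULL
    comp <- composition_table(df, subfraction_tol = subfraction_tol)
    delta <- abs(supplied - unname(compute_nfe(comp)))
    if (any(delta > 0.05, na.rm = TRUE)) {
      warning(sprintf(
        "supplied NFE differs from recomputed NFE by up to %.3f; recomputed values are used",
        max(delta, na.rm = TRUE)))
    }
    comp
  } else {
    composition_table(df, subfraction_tol = subfraction_tol)
  }
}

#' Read an amino-acid CSV (long format)
#'
#' Expects the header `diet_id,amino_acid,pct_dm`.
#'
#' @param path file path.
#' @return an [aa_table()].
#' @export
read_aa_csv <- function(path) {
  aa_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("Diet composition (%% DM basis), %d diet(s)\n", nrow(x)))
  df <- as.data.frame(x)
  df$nfe <- round(unname(compute_nfe(x)), 2)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}
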