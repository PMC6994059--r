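#' True (endogenous-corrected) digestibility
#'
#' digestibility (%) = 100 \[intake - (excreted - endogenous)\] / intake.
#' With `endogenous = 0` this is apparent digestibility; with the
#' fasted-bird endogenous losses supplied it is the true/standardized
#' value (the Sibbald-type correction). One routine serves both modes and
#' every analyte — gram flows for nutrients and amino acids, kcal flows
#' for gross energy — since the arithmetic is unit-agnostic as long as the
#' three arguments share a unit.
#'
#' Values above 100% occur in noisy data whenever corrected excretion goes
#' negative; they are returned with a warning, never truncated, so that
#' group means stay unbiased.
#'
#' @param intake nutrient (or energy) intake, g (or kcal); must be > 0.
#' @param excreted amount excreted over the collection, same unit.
#' @param endogenous endogenous loss (mean of fasted birds), same unit;
#'   default 0 (apparent mode).
#' @return percent; vectorized.
#' @export
true_digestibility <- function(intake, excreted, endogenous = 0) {
  if (any(intake <= 0)) stop("intake must be > 0")
  if (any(excreted < 0) || any(endogenous < 0)) {
    stop("excreted and endogenous must be non-negative")
  }
  d <- 100 * (intake - (excreted - endogenous)) / intake
  if (any(d > 100)) {
    warning(sprintf(
      "%d digestibility value(s) exceed 100%% (endogenous correction larger than excretion); reported unclipped",
      sum(d > 100)))
  }
  d
}

#' Per-amino-acid standardized digestibility for one diet
#'
#' Intake of each amino acid is `fi_g x pct_dm / 100`; excreta and
#' endogenous amounts are matched by amino-acid name. Amino acids missing
#' from any of the three inputs are skipped with a warning.
#'
#' @param aa an [aa_table()] restricted to (or containing) one diet.
#' @param diet_id which diet to compute.
#' @param fi_g feed intake, g DM per bird (scalar, the precision-fed dose).
#' @param excreta_aa data.frame with columns `bird_id`, `amino_acid`,
#'   `excreted_g` (per-bird 48-h excreta amounts).
#' @param endogenous_aa named numeric, g per bird, mean of the fasted
#'   birds, names = amino acids.
#' @return data.frame of class `digestibility_result`: one row per amino
#'   acid with `diet_id`, `analyte`, `n`, `mean` (%), and the per-bird
#'   values in the list-column `per_bird`.
#' @export
batch_aa_digestibility <- function(aa, diet_id, fi_g, excreta_aa,
                                   endogenous_aa) {
  stopifnot(length(fi_g) == 1L, fi_g > 0)
  aa <- aa[aa$diet_id == diet_id, , drop = FALSE]
  if (nrow(aa) == 0L) stop("no amino-acid concentrations for diet ", diet_id)
  panel <- sort(unique(aa$amino_acid))
  have_exc <- sort(unique(excreta_aa$amino_acid))
  have_end <- names(endogenous_aa)
  usable <- Reduce(intersect, list(panel, have_exc, have_end))
  dropped <- setdiff(panel, usable)
  if (length(dropped) > 0L) {
    warning("amino acid(s) missing from excreta or endogenous input, skipped: ",
            paste(dropped, collapse = ", "))
  }
  rows <- lapply(usable, function(a) {
    conc <- aa$pct_dm[aa$amino_acid == a]
    exc <- excreta_aa[excreta_aa$amino_acid == a, , drop = FALSE]
    d <- true_digestibility(fi_g * conc / 100, exc$excreted_g,
                            endogenous_aa[[a]])
    data.frame(diet_id = diet_id, analyte = a, n = length(d), mean = mean(d),
               per_bird = I(list(stats::setNames(d, exc$bird_id))),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("digestibility_result", "data.frame"))
}

#' Organic matter from dry matter and ash
#'
#' OM = DM x (1 - ash fraction); organic matter is what remains of dry
#' matter after the mineral (ash) fraction.
#'
#' @param intake_dm g DM.
#' @param ash_fraction ash as a fraction of DM, in \[0, 1\].
#' @return g organic matter.
#' @export
organic_matter <- function(intake_dm, ash_fraction) {
  if (any(ash_fraction < 0) || any(ash_fraction > 1)) {
    stop("ash_fraction must be within [0, 1]")
  }
  intake_dm * (1 - ash_fraction)
}

#' Per-bird digestibility from long nutrient-flow records
#'
#' Workhorse used by the pipeline: applies [true_digestibility()] to each
#' (bird, diet, analyte) record.
#'
#' @param flows data.frame with columns `bird_id`, `diet_id`, `analyte`,
#'   `intake`, `excreted` (g, or kcal for GE).
#' @param endogenous data.frame with columns `analyte`, `amount` — the
#'   across-bird mean of the fasted reference birds, same units as the
#'   flows; analytes absent from it get `0` (apparent mode) with a
#'   warning.
#' @return `flows` with a `digestibility` column (%) appended.
#' @export
digestibility_by_bird <- function(flows, endogenous) {
  req <- c("bird_id", "diet_id", "analyte", "intake", "excreted")
  missing_cols <- setdiff(req, names(flows))
  if (length(missing_cols) > 0L) {
    stop("flow records missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  endo <- stats::setNames(endogenous$amount, endogenous$analyte)
  unmatched <- setdiff(unique(flows$analyte), names(endo))
  if (length(unmatched) > 0L) {
    warning("no endogenous reference for analyte(s), apparent mode used: ",
            paste(unmatched, collapse = ", "))
  }
  e <- ifelse(flows$analyte %in% names(endo), endo[flows$analyte], 0)
  flows$digestibility <- true_digestibility(flows$intake, flows$excreted, e)
  flows
}

#' Summarize per-bird digestibility to diet x analyte means
#'
#' @param flows output of [digestibility_by_bird()].
#' @return data.frame with `diet_id`, `analyte`, `n`, `mean`.
#' @export
summarize_digestibility <- function(flows) {
  agg <- stats::aggregate(digestibility ~ diet_id + analyte, data = flows,
                          FUN = function(x) c(n = length(x), mean = mean(x)))
  out <- data.frame(diet_id = agg$diet_id, analyte = agg$analyte,
                    n = as.integer(agg$digestibility[, "n"]),
                    mean = agg$digestibility[, "mean"],
                    stringsAsFactors = FALSE)
  out[order(out$analyte, out$diet_id), , drop = FALSE]
}
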