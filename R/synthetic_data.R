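#' Packaged reference tables
#'
#' Parses and validates the composition, amino-acid and reported-results
#' tables shipped with the package (six complete, cooked adult-dog foods:
#' BRP, CWR, FSP, LBR, TWM, VSR). These are the default study conditions
#' for the synthetic generator and the ground truth used in consistency
#' tests.
#'
#' @return list with elements
#'   `composition` (a [composition_table()], 6 diets),
#'   `aa` (an [aa_table()], long format, 19 amino acids x 6 diets),
#'   `reported` (wide data.frame of reported result rows: NFE, nutrient
#'   digestibilities, TMEn, ME systems, TMEn/GE, with SEM and P columns),
#'   `aa_digestibility` (wide data.frame of reported amino-acid
#'   digestibilities, 18 amino acids).
#'   Structural inconsistencies in the shipped files raise an error.
#' @export
fixture_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "pfda",
                                  mustWork = TRUE)
  comp <- composition_table(utils::read.csv(path("table1_composition.csv"),
                                            stringsAsFactors = FALSE))
  aa_wide <- utils::read.csv(path("table2_aa.csv"), check.names = FALSE,
                             stringsAsFactors = FALSE)
  diets <- as.character(comp$diet_id)
  aa_long <- do.call(rbind, lapply(diets, function(d) {
    data.frame(diet_id = d, amino_acid = aa_wide$amino_acid,
               pct_dm = aa_wide[[d]], stringsAsFactors = FALSE)
  }))
  aa <- aa_table(aa_long)
  reported <- utils::read.csv(path("table1_reported.csv"),
                              check.names = FALSE, stringsAsFactors = FALSE)
  aa_dig <- utils::read.csv(path("table3_aa_digestibility.csv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  # integrity checks on the shipped data
  if (nrow(comp) != 6L) stop("fixture mismatch: expected 6 diets")
  if (!setequal(unique(aa$amino_acid), aa_panel())) {
    stop("fixture mismatch: amino-acid panel incomplete")
  }
  if (!all(diets %in% names(reported)) || !all(diets %in% names(aa_dig))) {
    stop("fixture mismatch: diet columns missing from reported tables")
  }
  list(composition = comp, aa = aa, reported = reported,
       aa_digestibility = aa_dig)
}

reported_row <- function(reported, item) {
  row <- reported[reported$item == item, , drop = FALSE]
  if (nrow(row) != 1L) stop("no reported row ", item)
  diets <- setdiff(names(row), c("item", "sem", "p_value"))
  stats::setNames(as.numeric(row[1L, diets]), diets)
}

default_noise_sd <- function() {
  c(DM = 0.8, OM = 0.7, AHF = 0.06, GE = 2.0, N = 0.08, AA = 0.009)
}

default_endogenous_means <- function(constants = endogenous_constants()) {
  c(DM = 4.0, OM = 3.2, AHF = 0.25, GE = constants$ee_fasted,
    N = constants$n_fasted)
}

#' Define a precision-fed assay scenario
#'
#' Bundles the study conditions for the generator: the diets, the true
#' (generating) digestibility and TMEn parameters, assay geometry (birds
#' per substrate, fasted reference birds, dose), and the per-analyte
#' additive noise on excreta amounts. Defaults reproduce the packaged
#' study: 6 diets, 4 birds per substrate, 5 fasted birds, a 20 g DM
#' crop-intubated dose, 48-h collection, with true digestibilities and
#' TMEn taken from the packaged reference tables.
#'
#' @param composition a [composition_table()]; default the packaged diets.
#' @param aa an [aa_table()]; default the packaged concentrations.
#' @param true_digestibility data.frame `diet_id`, `analyte`, `true_pct`
#'   (analytes: DM, OM, AHF, GE and amino acids); default the packaged
#'   reported means.
#' @param true_tmen named numeric, kcal/g DM per diet; default the
#'   packaged TMEn row.
#' @param true_n_digestibility true nitrogen digestibility (%) used to
#'   place fed-bird excreta nitrogen; default 85 (typical of the measured
#'   amino-acid digestibilities).
#' @param n_birds_per_diet birds per substrate; default 4.
#' @param n_fasted fasted endogenous-reference birds; default 5.
#' @param dose_dm crop-intubated dose, g DM; default 20.
#' @param noise_sd named numeric of additive Gaussian SDs on excreta
#'   amounts, in the analyte's own unit (g; kcal for GE): entries `DM`,
#'   `OM`, `AHF`, `GE`, `N` and a common `AA` entry applied to every
#'   amino acid (individual amino-acid names override it). Defaults are
#'   calibrated so simulated pooled SEMs fall in the magnitude range of
#'   the reported SEM columns.
#' @param fasted_noise_sd named numeric of additive SDs on fasted-bird
#'   excreta amounts, same layout as `noise_sd`; defaults to
#'   `noise_sd / 2`, reflecting that fasted birds excrete roughly half
#'   the mass of fed birds so the absolute measurement scatter is
#'   correspondingly smaller.
#' @param endogenous_means named numeric of true endogenous amounts per
#'   fasted bird per 48 h (same units); a common `AA` entry (default
#'   0.015 g) applies to every amino acid.
#' @param constants an [endogenous_constants()] object (also the source
#'   of the default `GE`/`N` endogenous means).
#' @param seed integer seed; per-bird random streams are derived from
#'   (seed, diet index, bird index) so any subset of birds is reproducible
#'   on its own.
#' @return list of class `assay_scenario`.
#' @export
assay_scenario <- function(composition = NULL, aa = NULL,
                           true_digestibility = NULL, true_tmen = NULL,
                           true_n_digestibility = 85,
                           n_birds_per_diet = 4, n_fasted = 5, dose_dm = 20,
                           noise_sd = default_noise_sd(),
                           fasted_noise_sd = NULL,
                           endogenous_means = NULL,
                           constants = endogenous_constants(),
                           seed = 1L) {
  if (is.null(composition) || is.null(aa) || is.null(true_digestibility) ||
      is.null(true_tmen)) {
    fx <- fixture_tables()
    if (is.null(composition)) composition <- fx$composition
    if (is.null(aa)) aa <- fx$aa
    if (is.null(true_tmen)) true_tmen <- reported_row(fx$reported, "tmen")
    if (is.null(true_digestibility)) {
      diets <- as.character(composition$diet_id)
      macro <- do.call(rbind, lapply(
        c(DM = "dm_digestibility", OM = "om_digestibility",
          AHF = "ahf_digestibility", GE = "ge_digestibility"),
        function(item) {
          v <- reported_row(fx$reported, item)
          data.frame(diet_id = names(v), analyte = NA_character_,
                     true_pct = unname(v), stringsAsFactors = FALSE)
        }))
      macro$analyte <- rep(c("DM", "OM", "AHF", "GE"),
                           each = length(diets))
      aa_truth <- do.call(rbind, lapply(diets, function(d) {
        data.frame(diet_id = d, analyte = fx$aa_digestibility$amino_acid,
                   true_pct = fx$aa_digestibility[[d]],
                   stringsAsFactors = FALSE)
      }))
      true_digestibility <- rbind(macro, aa_truth)
      rownames(true_digestibility) <- NULL
    }
  }
  stopifnot(n_birds_per_diet >= 1, n_fasted >= 1, dose_dm > 0,
            all(noise_sd >= 0), true_n_digestibility >= 0,
            true_n_digestibility <= 100)
  if (is.null(fasted_noise_sd)) fasted_noise_sd <- noise_sd / 2
  stopifnot(all(fasted_noise_sd >= 0))
  if (is.null(endogenous_means)) {
    endogenous_means <- c(default_endogenous_means(constants), AA = 0.015)
  }
  structure(list(composition = composition, aa = aa,
                 true_digestibility = true_digestibility,
                 true_tmen = true_tmen,
                 true_n_digestibility = true_n_digestibility,
                 n_birds_per_diet = as.integer(n_birds_per_diet),
                 n_fasted = as.integer(n_fasted), dose_dm = dose_dm,
                 noise_sd = noise_sd, fasted_noise_sd = fasted_noise_sd,
                 endogenous_means = endogenous_means,
                 constants = constants, seed = as.integer(seed)),
            class = "assay_scenario")
}

# deterministic per-bird stream seed; kept well below 2^31
stream_seed <- function(seed, diet_index, bird_index, role) {
  as.integer((abs(seed) %% 1000003) * 1009 + diet_index * 5003 +
               bird_index * 211 + role)
}

lookup_sd <- function(noise_sd, analyte, is_aa) {
  if (analyte %in% names(noise_sd)) return(unname(noise_sd[[analyte]]))
  if (is_aa && "AA" %in% names(noise_sd)) return(unname(noise_sd[["AA"]]))
  0
}

#' Simulate a complete precision-fed assay
#'
#' Inverts the digestibility and TMEn equations: per bird, nutrient intake
#' is dose x diet concentration and expected excretion is
#' `intake (1 - d/100) + endogenous` for each analyte with a generating
#' truth `d`; fed-bird excreta energy is solved from the TMEn balance
#' given the diet's true TMEn; fasted reference birds are drawn around the
#' endogenous means. Additive Gaussian noise (per-analyte SD) is applied
#' to every excreta amount; negative draws are truncated at zero and
#' counted, with a warning when more than 10% of draws truncate (a sign
#' the noise model is misconfigured).
#'
#' @param scenario an [assay_scenario()].
#' @return list of class `simulated_assay`:
#'   `fed_records` (TMEn assay, one row per conventional bird:
#'   `bird_id`, `diet_id`, `feed_intake_dm_g`, `energy_intake_kcal`,
#'   `excreta_energy_kcal`, `excreta_n_g`),
#'   `flows` (digestibility assay, one row per cecectomized bird x
#'   analyte: `bird_id`, `diet_id`, `analyte`, `intake`, `excreted`),
#'   `fasted` (one row per fasted bird x analyte: `bird_id`, `analyte`,
#'   `amount`), plus `scenario` and `truncated` (count of truncated
#'   draws).
#' @export
simulate_assay <- function(scenario) {
  stopifnot(inherits(scenario, "assay_scenario"))
  comp <- scenario$composition
  diets <- as.character(comp$diet_id)
  dose <- scenario$dose_dm
  cns <- scenario$constants
  truth <- scenario$true_digestibility
  analytes <- sort(unique(truth$analyte))
  is_aa_analyte <- !(analytes %in% c("DM", "OM", "AHF", "GE"))
  n_trunc <- 0L
  n_draws <- 0L

  draw <- function(expected, sd) {
    x <- expected + if (sd > 0) stats::rnorm(length(expected), 0, sd) else 0
    n_draws <<- n_draws + length(x)
    n_trunc <<- n_trunc + sum(x < 0)
    pmax(x, 0)
  }

  endo_of <- function(analyte, is_aa) {
    em <- scenario$endogenous_means
    if (analyte %in% names(em)) return(unname(em[[analyte]]))
    if (is_aa && "AA" %in% names(em)) return(unname(em[["AA"]]))
    0
  }

  flows <- vector("list", length(diets) * scenario$n_birds_per_diet)
  fed <- vector("list", length(diets) * scenario$n_birds_per_diet)
  idx <- 0L
  for (di in seq_along(diets)) {
    d <- diets[di]
    crow <- comp[di, , drop = FALSE]
    dtruth <- truth[truth$diet_id == d, , drop = FALSE]
    conc <- stats::setNames(dtruth$true_pct, dtruth$analyte)
    aa_d <- scenario$aa[scenario$aa$diet_id == d, , drop = FALSE]
    aa_conc <- stats::setNames(aa_d$pct_dm, aa_d$amino_acid)
    for (b in seq_len(scenario$n_birds_per_diet)) {
      idx <- idx + 1L
      # --- digestibility assay bird (cecectomized) ---
      set.seed(stream_seed(scenario$seed, di, b, role = 1L))
      rows <- lapply(seq_along(analytes), function(ai) {
        a <- analytes[ai]
        if (!(a %in% names(conc))) return(NULL)
        intake <- switch(a,
          DM = dose,
          OM = organic_matter(dose, crow$ash / 100),
          AHF = dose * crow$ahf / 100,
          GE = dose * crow$ge,
          if (a %in% names(aa_conc)) dose * unname(aa_conc[[a]]) / 100
          else NA_real_)
        if (is.na(intake) || intake <= 0) return(NULL)
        expected <- intake * (1 - conc[[a]] / 100) + endo_of(a, is_aa_analyte[ai])
        data.frame(bird_id = sprintf("%s_dig_%d", d, b), diet_id = d,
                   analyte = a,
                   intake = intake,
                   excreted = draw(expected,
                                   lookup_sd(scenario$noise_sd, a,
                                             is_aa_analyte[ai])),
                   stringsAsFactors = FALSE)
      })
      flows[[idx]] <- do.call(rbind, rows)
      # --- TMEn assay bird (conventional) ---
      set.seed(stream_seed(scenario$seed, di, b, role = 2L))
      ei <- dose * crow$ge
      n_intake <- dose * (crow$cp / 100) / 6.25
      n_expected <- n_intake * (1 - scenario$true_n_digestibility / 100) +
        cns$n_fasted
      ee_expected <- ei + cns$uric_acid_factor * n_expected +
        (cns$ee_fasted - cns$uric_acid_factor * cns$n_fasted) -
        scenario$true_tmen[[d]] * dose
      fed[[idx]] <- data.frame(
        bird_id = sprintf("%s_tme_%d", d, b), diet_id = d,
        feed_intake_dm_g = dose, energy_intake_kcal = ei,
        excreta_energy_kcal = draw(ee_expected,
                                   lookup_sd(scenario$noise_sd, "GE", FALSE)),
        excreta_n_g = draw(n_expected,
                           lookup_sd(scenario$noise_sd, "N", FALSE)),
        stringsAsFactors = FALSE)
    }
  }

  fasted_analytes <- c(analytes, "N")
  fasted <- vector("list", scenario$n_fasted)
  for (b in seq_len(scenario$n_fasted)) {
    set.seed(stream_seed(scenario$seed, 0L, b, role = 3L))
    amounts <- vapply(seq_along(fasted_analytes), function(ai) {
      a <- fasted_analytes[ai]
      is_aa <- !(a %in% c("DM", "OM", "AHF", "GE", "N"))
      draw(endo_of(a, is_aa), lookup_sd(scenario$fasted_noise_sd, a, is_aa))
    }, numeric(1))
    fasted[[b]] <- data.frame(bird_id = sprintf("fasted_%d", b),
                              analyte = fasted_analytes, amount = amounts,
                              stringsAsFactors = FALSE)
  }

  if (n_trunc > 0.1 * n_draws) {
    warning(sprintf(
      "%d of %d excreta draws truncated at zero; noise model likely misconfigured",
      n_trunc, n_draws))
  }
  structure(list(fed_records = do.call(rbind, fed),
                 flows = do.call(rbind, flows),
                 fasted = do.call(rbind, fasted),
                 scenario = scenario, truncated = n_trunc),
            class = "simulated_assay")
}

#' Endogenous reference means from fasted-bird records
#'
#' @param fasted data.frame `bird_id`, `analyte`, `amount` (the fasted
#'   birds of an assay).
#' @return data.frame `analyte`, `amount` — the across-bird mean applied
#'   uniformly in the endogenous correction.
#' @export
endogenous_reference <- function(fasted) {
  agg <- stats::aggregate(amount ~ analyte, data = fasted, FUN = mean)
  agg[order(agg$analyte), , drop = FALSE]
}

#' Analyze a (simulated or real) precision-fed assay
#'
#' Runs the estimation side of the pipeline on assay records: endogenous
#' means from the fasted birds, per-bird true digestibility for every
#' analyte, per-bird TMEn, and per-diet summaries.
#'
#' @param assay a `simulated_assay`, or a list with elements
#'   `fed_records`, `flows`, `fasted` in the schemas of
#'   [simulate_assay()].
#' @param constants an [endogenous_constants()] object for the TMEn
#'   correction.
#' @return list of class `assay_analysis`: `digestibility` (per-bird
#'   long), `digestibility_summary` (diet x analyte means),
#'   `tmen_by_bird`, `tmen_summary` (per-diet mean, n), `endogenous`
#'   (reference means used).
#' @export
analyze_assay <- function(assay, constants = endogenous_constants()) {
  if (is.null(assay$flows) || nrow(assay$flows) == 0L) {
    stop("assay contains no nutrient-flow records")
  }
  if (is.null(assay$fed_records) || nrow(assay$fed_records) == 0L) {
    stop("assay contains no fed-bird TMEn records")
  }
  endo <- endogenous_reference(assay$fasted)
  dig <- digestibility_by_bird(assay$flows, endo)
  tm <- tmen_records(assay$fed_records, constants)
  tm_agg <- stats::aggregate(tmen_kcal_g ~ diet_id, data = tm,
                             FUN = function(x) c(n = length(x),
                                                 mean = mean(x)))
  tmen_summary <- data.frame(diet_id = tm_agg$diet_id,
                             n = as.integer(tm_agg$tmen_kcal_g[, "n"]),
                             mean = tm_agg$tmen_kcal_g[, "mean"],
                             stringsAsFactors = FALSE)
  structure(list(digestibility = dig,
                 digestibility_summary = summarize_digestibility(dig),
                 tmen_by_bird = tm, tmen_summary = tmen_summary,
                 endogenous = endo),
            class = "assay_analysis")
}
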