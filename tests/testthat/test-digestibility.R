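test_that("true digestibility arithmetic, modes and error handling", {
  expect_equal(true_digestibility(6, 1.2, 0.3), 85)
  expect_equal(true_digestibility(6, 1.2), 80)           # apparent mode
  expect_equal(true_digestibility(5, 0.7, 0.7), 100)     # full correction
  expect_error(true_digestibility(0, 1), "intake")
  expect_error(true_digestibility(5, -1), "non-negative")
  expect_warning(over <- true_digestibility(5, 0, 0.5), "exceed 100")
  expect_equal(over, 110)  # reported unclipped
})

test_that("true digestibility is affine and monotone in its flows", {
  set.seed(23)
  intake <- runif(30, 1, 10)
  excreted <- runif(30, 0, 1)
  endo <- runif(30, 0, 0.5)
  base <- suppressWarnings(true_digestibility(intake, excreted, endo))
  eps <- 0.01
  more_exc <- suppressWarnings(true_digestibility(intake, excreted + eps, endo))
  more_endo <- suppressWarnings(true_digestibility(intake, excreted,
                                                   endo + eps))
  expect_true(all(more_exc < base))
  expect_true(all(more_endo > base))
  # affine: the step size is exactly 100 * eps / intake either way
  expect_equal(base - more_exc, 100 * eps / intake)
  expect_equal(more_endo - base, 100 * eps / intake)
  # true >= apparent whenever endogenous > 0
  apparent <- suppressWarnings(true_digestibility(intake, excreted, 0))
  expect_true(all(base >= apparent))
})

test_that("organic matter follows the ash fraction", {
  expect_equal(organic_matter(20, 0.0661), 18.678)
  expect_equal(organic_matter(20, 0), 20)
  expect_equal(organic_matter(20, 1), 0)
  expect_error(organic_matter(20, 1.2), "ash_fraction")
})

test_that("per-amino-acid digestibility recovers generating truths", {
  fx <- fixture_tables()
  aa <- fx$aa
  fi <- 20
  panel <- sort(unique(aa$amino_acid[aa$diet_id == "LBR"]))
  conc <- setNames(aa$pct_dm[aa$diet_id == "LBR"],
                   aa$amino_acid[aa$diet_id == "LBR"])[panel]
  endo <- setNames(rep(0.015, length(panel)), panel)
  truth_tbl <- fx$aa_digestibility
  truths <- setNames(truth_tbl$LBR, truth_tbl$amino_acid)
  truths <- truths[names(truths) %in% panel]
  make_excreta <- function(truth_pct) {
    do.call(rbind, lapply(1:4, function(b) {
      data.frame(bird_id = paste0("b", b), amino_acid = names(truth_pct),
                 excreted_g = fi * conc[names(truth_pct)] / 100 *
                   (1 - truth_pct / 100) + endo[names(truth_pct)],
                 stringsAsFactors = FALSE)
    }))
  }
  # uniform truth of 88% comes back as 88 for every amino acid
  flat <- setNames(rep(88, length(panel)), panel)
  res <- batch_aa_digestibility(aa, "LBR", fi, make_excreta(flat), endo)
  expect_equal(res$mean, rep(88, nrow(res)))
  expect_true(all(res$n == 4L))
  # the published per-amino-acid truths round-trip exactly at zero noise
  # (taurine has no published digestibility, so it is excluded here)
  aa_sub <- aa[aa$amino_acid %in% names(truths), ]
  res2 <- batch_aa_digestibility(aa_sub, "LBR", fi, make_excreta(truths),
                                 endo)
  expect_equal(setNames(res2$mean, res2$analyte), truths[res2$analyte])
  # zero excreta pushes every value above 100, with a warning, not an error
  zero_exc <- make_excreta(flat)
  zero_exc$excreted_g <- 0
  warns <- capture_warnings(
    res3 <- batch_aa_digestibility(aa, "LBR", fi, zero_exc, endo))
  expect_true(all(grepl("exceed 100", warns)))
  expect_gt(length(warns), 0L)
  expect_true(all(res3$mean >= 100))
  # amino acids absent from the endogenous input are skipped with a warning
  expect_warning(res4 <- batch_aa_digestibility(aa, "LBR", fi,
                                                make_excreta(flat),
                                                endo[-1]),
                 "skipped")
  expect_false(panel[1] %in% res4$analyte)
})

test_that("long-flow digestibility matches scalar computation and summary", {
  flows <- data.frame(bird_id = rep(c("b1", "b2"), each = 2),
                      diet_id = "D", analyte = rep(c("DM", "GE"), 2),
                      intake = c(20, 110, 20, 110),
                      excreted = c(6, 20, 7, 24))
  endo <- data.frame(analyte = c("DM", "GE"), amount = c(4, 16.74))
  out <- digestibility_by_bird(flows, endo)
  expect_equal(out$digestibility,
               true_digestibility(flows$intake, flows$excreted,
                                  c(4, 16.74, 4, 16.74)))
  sm <- summarize_digestibility(out)
  expect_equal(sm$n, c(2L, 2L))
  expect_equal(sm$mean[sm$analyte == "DM"],
               mean(out$digestibility[out$analyte == "DM"]))
  # analytes without an endogenous reference fall back to apparent mode
  expect_warning(digestibility_by_bird(transform(flows, analyte = "OM"),
                                       endo),
                 "apparent mode")
})
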