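test_that("one-way CRD ANOVA matches hand-computed sums of squares", {
  fit <- crd_anova(list(a = c(1, 2, 3), b = c(2, 3, 4)))
  expect_equal(fit$f_stat, 1.5)
  expect_equal(fit$df1, 1L)
  expect_equal(fit$df2, 4L)
  expect_equal(fit$mse, 1)
  expect_equal(fit$pooled_sem, sqrt(1 / 3))
  same <- crd_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$f_stat, 0)
  expect_equal(same$p_value, 1)
  expect_error(crd_anova(list(a = 1, b = c(1, 2))), "at least 2 observations")
  expect_error(crd_anova(list(a = c(1, 2))), "at least 2 groups")
})

test_that("k = 2 ANOVA F equals the squared pooled t statistic", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6, 0.5)
    # unbalanced on purpose; the identity holds regardless
    fit <- suppressWarnings(crd_anova(list(x = x, y = y)))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(fit$f_stat, unname(tt$statistic)^2)
    expect_equal(fit$p_value, tt$p.value)
  }
})

test_that("zero within-group variance with unequal means is flagged", {
  fit <- suppressWarnings(crd_anova(list(a = c(1, 1), b = c(2, 2))))
  expect_true(fit$degenerate)
  expect_equal(fit$f_stat, Inf)
  expect_lte(fit$p_value, .Machine$double.xmin)
})

test_that("unbalanced designs fall back to the harmonic-mean pooled SEM", {
  expect_warning(fit <- crd_anova(list(a = c(1, 2, 3), b = c(2, 4))),
                 "harmonic")
  n_h <- 2 / (1 / 3 + 1 / 2)
  expect_equal(fit$pooled_sem, sqrt(fit$mse / n_h))
})

test_that("Tukey HSD: k = 2 equals the two-sided t test, q = t sqrt(2)", {
  set.seed(47)
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(4, 1)
    th <- tukey_hsd(list(x = x, y = y))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(th$pairwise$p_adj, tt$p.value, tolerance = 1e-4)
    expect_equal(th$pairwise$q, abs(unname(tt$statistic)) * sqrt(2))
  }
})

test_that("Tukey HSD agrees with stats::TukeyHSD and separates a shifted group", {
  set.seed(53)
  vbg <- setNames(lapply(1:5, function(i) rnorm(4, mean = i %% 2)),
                  paste0("g", 1:5))
  th <- tukey_hsd(vbg)
  dat <- data.frame(value = unlist(vbg),
                    group = factor(rep(names(vbg), each = 4)))
  ref <- TukeyHSD(aov(value ~ group, data = dat))$group
  ref_pairs <- do.call(rbind, strsplit(rownames(ref), "-"))
  key <- paste(pmin(ref_pairs[, 1], ref_pairs[, 2]),
               pmax(ref_pairs[, 1], ref_pairs[, 2]))
  ours <- setNames(th$pairwise$p_adj,
                   paste(pmin(th$pairwise$group1, th$pairwise$group2),
                         pmax(th$pairwise$group1, th$pairwise$group2)))
  expect_equal(unname(ours[key]), unname(ref[, "p adj"]), tolerance = 1e-8)

  # identical groups: nothing significant
  same <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_false(any(same$pairwise$significant))

  # one mean shifted by 10 residual SDs: exactly its pairs are significant
  set.seed(59)
  shifted <- setNames(lapply(1:6, function(i) {
    rnorm(4, mean = if (i == 3) 10 else 0, sd = 1)
  }), paste0("g", 1:6))
  th2 <- tukey_hsd(shifted)
  has_g3 <- th2$pairwise$group1 == "g3" | th2$pairwise$group2 == "g3"
  expect_true(all(th2$pairwise$significant[has_g3]))
  expect_false(any(th2$pairwise$significant[!has_g3]))
})

test_that("compact letter display covers canonical patterns", {
  means <- c(A = 3, B = 2, C = 1, D = 0)
  none <- matrix(FALSE, 4, 4, dimnames = list(names(means), names(means)))
  expect_equal(compact_letter_display(none, means),
               c(A = "a", B = "a", C = "a", D = "a"))
  all_sig <- !none; diag(all_sig) <- FALSE
  expect_equal(compact_letter_display(all_sig, means),
               c(A = "a", B = "b", C = "c", D = "d"))
  # chain: A differs from C only
  m3 <- matrix(FALSE, 3, 3, dimnames = list(c("A", "B", "C"),
                                            c("A", "B", "C")))
  m3["A", "C"] <- m3["C", "A"] <- TRUE
  expect_equal(compact_letter_display(m3, c(A = 3, B = 2, C = 1)),
               c(A = "a", B = "ab", C = "b"))
})

test_that("letter displays regenerate their significance matrix exactly (k <= 5)", {
  for (k in 2:5) {
    means <- setNames(rev(seq_len(k)), LETTERS[seq_len(k)])
    for (m in all_sig_patterns(k)) {
      cld <- compact_letter_display(m, means)
      expect_identical(matrix_from_letters(cld), m)
    }
  }
})

test_that("letter sharing agrees with an independent multcomp implementation", {
  set.seed(61)
  for (i in 1:5) {
    dat <- data.frame(value = rnorm(24, mean = rep(c(0, 0, 1, 1, 3, 3),
                                                   each = 4)),
                      group = factor(rep(paste0("g", 1:6), each = 4)))
    fit <- aov(value ~ group, data = dat)
    ref <- multcomp::cld(multcomp::glht(fit,
                                        linfct = multcomp::mcp(group = "Tukey")))
    ref_letters <- ref$mcletters$Letters
    ours <- compact_letter_display(
      tukey_hsd(split(dat$value, dat$group)))
    expect_identical(matrix_from_letters(ours)[names(ref_letters),
                                               names(ref_letters)],
                     matrix_from_letters(ref_letters))
  }
})

test_that("group_comparison assembles means, letters, SEM and F test", {
  set.seed(67)
  vbg <- setNames(lapply(c(0, 0, 5), function(m) rnorm(4, m)),
                  c("g1", "g2", "g3"))
  gc <- group_comparison(vbg, analyte = "demo")
  expect_equal(gc$groups$mean, unname(vapply(vbg, mean, numeric(1))))
  expect_equal(gc$pooled_sem, sqrt(crd_anova(vbg)$mse / 4))
  expect_true(all(nchar(gc$groups$letters) >= 1))
  expect_identical(gc$analyte, "demo")
  shared <- matrix_from_letters(setNames(gc$groups$letters, gc$groups$group))
  expect_identical(shared["g1", "g2"], FALSE)
  expect_identical(shared["g1", "g3"], TRUE)
})
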