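# Study-level statistics: one observation per bird in a completely
# randomized design, so the "bird random / substrate fixed" mixed model
# reduces to one-way fixed-effects ANOVA (the bird variance component is
# not separable from residual).

as_groups <- function(values_by_group) {
  if (is.data.frame(values_by_group)) {
    stopifnot(all(c("group", "value") %in% names(values_by_group)))
    values_by_group <- split(values_by_group$value,
                             as.character(values_by_group$group))
  }
  if (is.null(names(values_by_group)) || any(names(values_by_group) == "")) {
    stop("groups must be named")
  }
  lapply(values_by_group, as.numeric)
}

#' One-way ANOVA for a completely randomized design
#'
#' Fits the one-way fixed-effects decomposition with [stats::aov()] and
#' reports the F test together with the pooled standard error of a group
#' mean, `sqrt(MSE / n)`. Under unequal group sizes the harmonic mean of
#' the `n` is used for the pooled SEM, with a warning, since a single SEM
#' is only exact under balance.
#'
#' @param values_by_group named list of numeric vectors (one per group),
#'   or a data.frame with `group` and `value` columns. At least 2 groups
#'   with at least 2 observations each.
#' @return list of class `crd_anova`: `f_stat`, `df1`, `df2`, `p_value`,
#'   `mse`, `pooled_sem`, `means`, `n`, `degenerate` (TRUE when within-group
#'   variance is zero while group means differ, in which case `p_value` is
#'   reported as the smallest positive double).
#' @export
crd_anova <- function(values_by_group) {
  vbg <- as_groups(values_by_group)
  k <- length(vbg)
  if (k < 2L) stop("at least 2 groups are required")
  ns <- lengths(vbg)
  if (any(ns < 2L)) {
    stop("every group needs at least 2 observations; offending group(s): ",
         paste(names(vbg)[ns < 2L], collapse = ", "))
  }
  dat <- data.frame(
    value = unlist(vbg, use.names = FALSE),
    group = factor(rep(names(vbg), ns), levels = names(vbg)))
  # zero-residual fits are detected and flagged below; muffle the stock
  # "essentially perfect fit" notice so the flag is the single signal
  tab <- withCallingHandlers(
    stats::anova(stats::aov(value ~ group, data = dat)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  f <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  mse <- tab[["Mean Sq"]][2L]
  means <- vapply(vbg, mean, numeric(1))
  degenerate <- FALSE
  within_const <- all(vapply(vbg, function(x) diff(range(x)) == 0,
                             logical(1)))
  if (within_const || mse <= 0 || !is.finite(f)) {
    if (stats::var(means) > 0) {
      degenerate <- TRUE
      f <- Inf
      p <- .Machine$double.xmin
    } else {
      f <- 0
      p <- 1
    }
  }
  balanced <- length(unique(ns)) == 1L
  n_eff <- if (balanced) {
    ns[[1L]]
  } else {
    warning("unbalanced groups; pooled SEM uses the harmonic mean n")
    k / sum(1 / ns)
  }
  structure(list(f_stat = f, df1 = tab$Df[1L], df2 = tab$Df[2L],
                 p_value = p, mse = mse, pooled_sem = sqrt(mse / n_eff),
                 means = means, n = ns, degenerate = degenerate),
            class = "crd_anova")
}

#' Tukey HSD multiple comparisons
#'
#' All-pairs comparisons of group means with studentized-range (Tukey)
#' adjustment for experiment-wise error: for groups i, j the statistic is
#' `q = |mean_i - mean_j| / sqrt((MSE/2) (1/n_i + 1/n_j))` (the
#' Tukey--Kramer standard error; `sqrt(MSE/n)` under balance) and the
#' adjusted p comes from the studentized-range distribution with k groups
#' and the ANOVA residual df.
#'
#' @inheritParams crd_anova
#' @param alpha experiment-wise significance level; default 0.05.
#' @return list of class `tukey_hsd`: `pairwise` (data.frame `group1`,
#'   `group2`, `diff`, `q`, `p_adj`, `significant`), `means`, `alpha`,
#'   `anova` (the underlying [crd_anova()] fit).
#' @export
tukey_hsd <- function(values_by_group, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  vbg <- as_groups(values_by_group)
  fit <- crd_anova(vbg)
  k <- length(vbg)
  pairs <- utils::combn(names(vbg), 2L)
  diffs <- fit$means[pairs[1L, ]] - fit$means[pairs[2L, ]]
  se <- sqrt((fit$mse / 2) * (1 / fit$n[pairs[1L, ]] + 1 / fit$n[pairs[2L, ]]))
  q <- abs(diffs) / se
  # mse == 0: identical values within groups; any mean difference is "sure"
  q[se == 0 & abs(diffs) > 0] <- Inf
  q[se == 0 & abs(diffs) == 0] <- 0
  p_adj <- stats::ptukey(q, nmeans = k, df = fit$df2, lower.tail = FALSE)
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   diff = unname(diffs), q = unname(q),
                   p_adj = unname(p_adj),
                   significant = unname(p_adj < alpha),
                   stringsAsFactors = FALSE)
  structure(list(pairwise = pw, means = fit$means, alpha = alpha,
                 anova = fit),
            class = "tukey_hsd")
}

# significance matrix (logical, groups x groups) from a pairwise data.frame
sig_matrix <- function(pairwise, group_names) {
  m <- matrix(FALSE, length(group_names), length(group_names),
              dimnames = list(group_names, group_names))
  for (i in seq_len(nrow(pairwise))) {
    g1 <- pairwise$group1[i]
    g2 <- pairwise$group2[i]
    m[g1, g2] <- m[g2, g1] <- isTRUE(pairwise$significant[i])
  }
  m
}

#' Compact letter display
#'
#' Summarizes an all-pairs comparison as superscript letters: two groups
#' share at least one letter if and only if they are not significantly
#' different. Uses the insert-and-absorb algorithm: start with one letter
#' covering all groups; for each significant pair, split every letter
#' column containing both; absorb columns that became subsets of another.
#' This represents any significance pattern exactly, including
#' non-transitive ones, and never raises.
#'
#' Letters are ordered `a, b, c, ...` by descending group mean, ties in
#' the means broken by group label (lexicographic), so output is
#' deterministic.
#'
#' @param x a [tukey_hsd()] result, or a data.frame with columns `group1`,
#'   `group2`, `significant` (complete pairwise set), or a logical
#'   significance matrix with dimnames.
#' @param means named numeric group means used for letter ordering;
#'   required unless `x` is a `tukey_hsd` object.
#' @return named character vector of letter sets, one per group.
#' @export
compact_letter_display <- function(x, means = NULL) {
  if (inherits(x, "tukey_hsd")) {
    means <- x$means
    m <- sig_matrix(x$pairwise, names(means))
  } else if (is.matrix(x)) {
    if (is.null(means)) stop("means are required for letter ordering")
    m <- x[names(means), names(means)]
  } else {
    if (is.null(means)) stop("means are required for letter ordering")
    m <- sig_matrix(x, names(means))
  }
  # rank groups: descending mean, ties by label
  ord <- names(means)[order(-means, names(means))]
  cols <- list(ord)
  sig_pairs <- which(m & upper.tri(m), arr.ind = TRUE)
  for (r in seq_len(nrow(sig_pairs))) {
    g1 <- rownames(m)[sig_pairs[r, 1L]]
    g2 <- colnames(m)[sig_pairs[r, 2L]]
    nxt <- list()
    for (col in cols) {
      if (g1 %in% col && g2 %in% col) {
        nxt <- c(nxt, list(setdiff(col, g1)), list(setdiff(col, g2)))
      } else {
        nxt <- c(nxt, list(col))
      }
    }
    # absorb: drop any column that is a (or an equal, later-indexed)
    # subset of another; subsets add no information about shared letters
    keep <- rep(TRUE, length(nxt))
    for (i in seq_along(nxt)) {
      for (j in seq_along(nxt)) {
        if (i == j || !keep[j]) next
        if (all(nxt[[i]] %in% nxt[[j]]) &&
            (length(nxt[[i]]) < length(nxt[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- nxt[keep]
  }
  # order columns by the rank of their best (highest-mean) member
  rank_of <- stats::setNames(seq_along(ord), ord)
  best <- vapply(cols, function(col) min(rank_of[col]), numeric(1))
  cols <- cols[order(best)]
  out <- stats::setNames(rep("", length(ord)), ord)
  for (i in seq_along(cols)) {
    lab <- letters[i]
    for (g in cols[[i]]) out[g] <- paste0(out[g], lab)
  }
  out[names(means)]
}

#' Full group comparison for one analyte
#'
#' Runs [crd_anova()], [tukey_hsd()] and [compact_letter_display()] and
#' assembles the row shape of a means-separation table: per-group mean,
#' n and letters, one pooled SEM, the F test, and the pairwise detail.
#'
#' @inheritParams tukey_hsd
#' @param analyte label carried into the output.
#' @return list of class `group_comparison`: `analyte`, `groups`
#'   (data.frame `group`, `n`, `mean`, `letters`), `pooled_sem`, `f_stat`,
#'   `p_value`, `pairwise`, `alpha`.
#' @export
group_comparison <- function(values_by_group, analyte = "value",
                             alpha = 0.05) {
  th <- tukey_hsd(values_by_group, alpha = alpha)
  cld <- compact_letter_display(th)
  fit <- th$anova
  groups <- data.frame(group = names(fit$means), n = unname(fit$n),
                       mean = unname(fit$means),
                       letters = unname(cld[names(fit$means)]),
                       stringsAsFactors = FALSE)
  structure(list(analyte = analyte, groups = groups,
                 pooled_sem = fit$pooled_sem, f_stat = fit$f_stat,
                 df1 = fit$df1, df2 = fit$df2, p_value = fit$p_value,
                 pairwise = th$pairwise, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Group comparison: %s\n", x$analyte))
  g <- x$groups
  g$mean <- signif(g$mean, digits + 2)
  print.data.frame(g, row.names = FALSE)
  cat(sprintf("pooled SEM %.4g; F(%d, %d) = %.4g; P = %.4g\n",
              x$pooled_sem, x$df1, x$df2, x$f_stat, x$p_value))
  cat(sprintf("groups lacking a common letter differ (P < %.3g)\n", x$alpha))
  invisible(x)
}
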