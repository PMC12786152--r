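#' Cohen's d (pooled standard deviation)
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' pooled standard deviation
#' `s_pooled = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#' With `a` = artery and `b` = vein the sign is negative whenever veins are
#' more tortuous.
#'
#' @param a,b Numeric samples.
#' @return Cohen's d; `NA` when the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (!is.finite(sp2) || sp2 <= 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) return(0)
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Compare two tortuosity samples
#'
#' Runs the comparison battery on two labelled samples (typically per-image
#' mean tortuosities: artery vs vein, or healthy vs diseased). Shapiro-Wilk
#' normality is tested on each sample; when both p-values exceed `alpha` the
#' parametric branch is primary (Pearson correlation, single-predictor
#' linear-regression R-squared, Cohen's d), otherwise the nonparametric
#' branch (Spearman correlation, Mann-Whitney U, Wilcoxon signed-rank on
#' paired values). All statistics that the sample sizes permit are computed
#' regardless of the branch; the branch only marks which set is primary.
#'
#' Correlation, regression and the Wilcoxon signed-rank test operate on
#' pairs; when `a` and `b` have names (image ids) pairs are formed on the
#' intersection, with a warning if any observation is dropped.
#'
#' @param a,b Numeric samples (optionally named by image id).
#' @param paired Treat samples as paired for the signed-rank test (default
#'   TRUE, the artery-vein-within-eye design).
#' @param alpha Significance level for the Shapiro-Wilk gate (default 0.05).
#' @param label_a,label_b Group labels for reporting.
#' @return A `tortuosity_comparison` object; see [tidy()] / [glance()].
#' @export
compare_groups <- function(a, b, paired = TRUE, alpha = 0.05,
                           label_a = "artery", label_b = "vein") {
  if (length(a) < 3L || length(b) < 3L) {
    stop("each sample needs n >= 3 (Shapiro-Wilk minimum)")
  }
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) < max(length(a), length(b))) {
      warning("unmatched observations dropped; pairs formed on ",
              length(common), " common ids")
    }
    pa <- a[common]; pb <- b[common]
  } else if (length(a) == length(b)) {
    pa <- a; pb <- b
  } else {
    pa <- pb <- NULL
  }
  sw_a <- shapiro.test(a)$p.value
  sw_b <- shapiro.test(b)$p.value
  branch <- if (sw_a > alpha && sw_b > alpha) "parametric" else "nonparametric"

  pearson_r <- pearson_p <- r_squared <- NA_real_
  spearman_r <- spearman_p <- wilcoxon_p <- NA_real_
  if (!is.null(pa) && length(pa) >= 3L) {
    if (sd(pa) > 0 && sd(pb) > 0) {
      ct <- cor.test(pa, pb, method = "pearson")
      pearson_r <- unname(ct$estimate); pearson_p <- ct$p.value
      r_squared <- summary(lm(pb ~ pa))$r.squared
      st <- suppressWarnings(cor.test(pa, pb, method = "spearman",
                                      exact = FALSE))
      spearman_r <- unname(st$estimate); spearman_p <- st$p.value
    }
    if (paired) {
      wilcoxon_p <- suppressWarnings(
        wilcox.test(pa, pb, paired = TRUE, exact = FALSE)$p.value
      )
    }
  }
  mannwhitney_p <- suppressWarnings(
    wilcox.test(a, b, paired = FALSE, exact = FALSE)$p.value
  )
  structure(
    list(
      label_a = label_a, label_b = label_b,
      n_a = length(a), n_b = length(b),
      mean_a = mean(a), mean_b = mean(b),
      shapiro_p_a = sw_a, shapiro_p_b = sw_b,
      alpha = alpha, branch = branch, paired = paired,
      pearson_r = pearson_r, pearson_p = pearson_p, r_squared = r_squared,
      spearman_r = spearman_r, spearman_p = spearman_p,
      mannwhitney_p = mannwhitney_p, wilcoxon_p = wilcoxon_p,
      cohens_d = cohens_d(a, b)
    ),
    class = "tortuosity_comparison"
  )
}

#' @export
print.tortuosity_comparison <- function(x, ...) {
  cat(sprintf("<tortuosity_comparison> %s (n=%d, mean %.4f) vs %s (n=%d, mean %.4f)\n",
              x$label_a, x$n_a, x$mean_a, x$label_b, x$n_b, x$mean_b))
  cat(sprintf("  Shapiro-Wilk p: %.4g / %.4g -> %s branch\n",
              x$shapiro_p_a, x$shapiro_p_b, x$branch))
  if (x$branch == "parametric") {
    cat(sprintf("  Pearson r = %.4f (p = %.4g), R^2 = %.4f, Cohen's d = %.4f\n",
                x$pearson_r, x$pearson_p, x$r_squared, x$cohens_d))
  } else {
    cat(sprintf("  Spearman r = %.4f (p = %.4g), Mann-Whitney p = %.4g, Wilcoxon p = %.4g\n",
                x$spearman_r, x$spearman_p, x$mannwhitney_p, x$wilcoxon_p))
  }
  invisible(x)
}

#' Tidy a tortuosity comparison
#'
#' One row per computed statistic, in broom's `term`/`estimate` layout.
#'
#' @param x A `tortuosity_comparison`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `p.value`, `primary`
#'   (whether the statistic belongs to the selected branch).
#' @export
tidy.tortuosity_comparison <- function(x, ...) {
  par <- x$branch == "parametric"
  tibble(
    term = c("pearson_r", "r_squared", "cohens_d",
             "spearman_r", "mannwhitney_u", "wilcoxon_signed_rank"),
    estimate = c(x$pearson_r, x$r_squared, x$cohens_d,
                 x$spearman_r, NA_real_, NA_real_),
    p.value = c(x$pearson_p, NA_real_, NA_real_,
                x$spearman_p, x$mannwhitney_p, x$wilcoxon_p),
    primary = c(par, par, par, !par, !par, !par)
  )
}

#' Glance at a tortuosity comparison
#'
#' @param x A `tortuosity_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with group means, Shapiro-Wilk p-values, the
#'   selected branch and the effect size.
#' @export
glance.tortuosity_comparison <- function(x, ...) {
  tibble(
    label_a = x$label_a, label_b = x$label_b,
    n_a = x$n_a, n_b = x$n_b,
    mean_a = x$mean_a, mean_b = x$mean_b,
    shapiro_p_a = x$shapiro_p_a, shapiro_p_b = x$shapiro_p_b,
    branch = x$branch, cohens_d = x$cohens_d
  )
}

#' Build a report table from comparisons
#'
#' Emits two rows (one per group) for each comparison, mirroring the
#' dataset/FOV/total/mean/Shapiro/Pearson/Spearman/R-squared/Cohen's-d/
#' Mann-Whitney/Wilcoxon column layout of the summary tables. Statistics not
#' computed on a branch are left blank (NA).
#'
#' @param comparisons List of `tortuosity_comparison` objects.
#' @param dataset Character vector of dataset labels (recycled).
#' @param fov_deg Numeric vector of fields of view (recycled).
#' @param totals Optional list of length-2 numeric vectors with per-group
#'   segment counts.
#' @return A tibble, two rows per comparison.
#' @export
build_report <- function(comparisons, dataset = NA_character_,
                         fov_deg = NA_real_, totals = NULL) {
  if (inherits(comparisons, "tortuosity_comparison")) {
    comparisons <- list(comparisons)
  }
  dataset <- rep_len(dataset, length(comparisons))
  fov_deg <- rep_len(fov_deg, length(comparisons))
  rows <- lapply(seq_along(comparisons), function(i) {
    x <- comparisons[[i]]
    par <- x$branch == "parametric"
    tot <- if (is.null(totals)) c(x$n_a, x$n_b) else totals[[i]]
    tibble(
      dataset = dataset[i],
      group = c(x$label_a, x$label_b),
      fov_deg = fov_deg[i],
      total = as.integer(tot),
      mean_tortuosity = c(x$mean_a, x$mean_b),
      shapiro_p = c(x$shapiro_p_a, x$shapiro_p_b),
      pearson_r = c(if (par) x$pearson_r else NA_real_, NA_real_),
      spearman_r = c(if (par) NA_real_ else x$spearman_r, NA_real_),
      pearson_p = c(if (par) x$pearson_p else NA_real_, NA_real_),
      spearman_p = c(if (par) NA_real_ else x$spearman_p, NA_real_),
      r_squared = c(if (par) x$r_squared else NA_real_, NA_real_),
      cohens_d = c(if (par) x$cohens_d else NA_real_, NA_real_),
      mannwhitney_p = c(if (par) NA_real_ else x$mannwhitney_p, NA_real_),
      wilcoxon_p = c(if (par) NA_real_ else x$wilcoxon_p, NA_real_)
    )
  })
  do.call(rbind, rows)
}
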