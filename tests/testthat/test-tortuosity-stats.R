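test_that("tortuosity is arc over chord with a zero-chord guard", {
  expect_equal(tortuosity(100, 100), 1.0)
  expect_warning(out <- tortuosity(50, 0))
  expect_true(is.na(out))

  # axial 100-px chain in pixel-count mode: 100 / 99
  chain <- cbind(x = 1:100, y = rep(50L, 100))
  rec <- trace_chain_records(chain, c(100L, 120L), "pixel")
  expect_equal(rec$t, 100 / 99)

  # pure diagonal 100-px chain: chord rounds to 140, t ~ 0.714
  diag_chain <- cbind(x = 1:100, y = 1:100)
  rec <- trace_chain_records(diag_chain, c(120L, 120L), "pixel")
  expect_equal(rec$l_straight, 140L)
  expect_equal(rec$t, 100 / 140)
})

test_that("arc modes differ in chord rounding and digitization handling", {
  chain <- cbind(x = 1:100, y = rep(50L, 100))
  geo <- trace_chain_records(chain, c(100L, 120L), "geometric")
  expect_equal(geo$t, 1.0, tolerance = 1e-9)
  ch <- trace_chain_records(chain, c(100L, 120L), "chain")
  expect_equal(ch$arc, 99)
})

test_that("aggregation returns per-image and per-class means with counts", {
  rec <- tibble::tibble(
    image_id = c("a", "a", "b", "b", "b"),
    vessel_class = c("artery", "vein", "artery", "artery", "vein"),
    t = c(1.2, 1.4, 1.0, 1.2, 1.3),
    valid = TRUE
  )
  agg <- aggregate_tortuosity(rec)
  expect_equal(nrow(agg$per_image), 4)
  a_b <- agg$per_image[agg$per_image$image_id == "b" &
                         agg$per_image$vessel_class == "artery", ]
  expect_equal(a_b$mean_t, 1.1)
  expect_equal(a_b$n_segments, 2L)
  ov <- agg$overall
  expect_equal(sum(ov$n_segments), nrow(rec))   # totals conserve
  expect_equal(ov$grand_mean_t[ov$vessel_class == "artery"], mean(c(1.2, 1.1)))

  one <- aggregate_tortuosity(tibble::tibble(
    image_id = "a", vessel_class = "artery", t = 1.2, valid = TRUE))
  expect_equal(one$overall$mean_t, 1.2)
  expect_equal(one$overall$n_segments, 1L)

  rec$valid[rec$vessel_class == "vein"] <- FALSE
  expect_warning(aggregate_tortuosity(rec), "vein")
})

test_that("effect size and correlation agree with brute-force formulas", {
  set.seed(31)
  a <- rnorm(20, 1.1, 0.05)
  b <- rnorm(20, 1.2, 0.06)
  cmp <- compare_groups(a, b)
  sp <- sqrt(((19) * var(a) + (19) * var(b)) / 38)
  expect_equal(cmp$cohens_d, (mean(a) - mean(b)) / sp, tolerance = 1e-10)
  r_manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cmp$pearson_r, r_manual, tolerance = 1e-10)
  expect_equal(cmp$r_squared, r_manual^2, tolerance = 1e-10)
  rho_manual <- cor(rank(a), rank(b))
  expect_equal(cmp$spearman_r, rho_manual, tolerance = 1e-10)
})

test_that("Cohen's d recovers a unit standardized difference", {
  set.seed(99)
  a <- rnorm(400, 0, 1)
  b <- rnorm(400, 1, 1)
  expect_equal(cohens_d(a, b), -1, tolerance = 0.15)
  expect_equal(cohens_d(a, a), 0)
})

test_that("the Shapiro gate selects the branch exactly at alpha = 0.05", {
  set.seed(5)
  for (i in 1:20) {
    a <- if (i %% 2 == 0) rnorm(20) else exp(rnorm(20, 0, 1.5))
    b <- if (i %% 3 == 0) rnorm(20) else exp(rnorm(20, 0, 1.5))
    cmp <- compare_groups(a, b)
    gate <- shapiro.test(a)$p.value > 0.05 && shapiro.test(b)$p.value > 0.05
    expect_identical(cmp$branch,
                     if (gate) "parametric" else "nonparametric")
  }
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("a correlation of 0.5608 over 20 paired means gives p near 0.0101", {
  r <- 0.5608; n <- 20
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p_analytic <- 2 * pt(-abs(t_stat), df = n - 2)
  expect_equal(p_analytic, 0.0101, tolerance = 5e-4)

  # build a sample pair with exactly that correlation and check the test
  set.seed(17)
  x <- as.numeric(scale(rnorm(n)))
  e <- as.numeric(scale(resid(lm(rnorm(n) ~ x))))
  y <- r * x + sqrt(1 - r^2) * e
  y <- 1.2 + 0.1 * y; x <- 1.1 + 0.1 * x   # plausible tortuosity scale
  cmp <- compare_groups(x, y)
  expect_equal(cmp$pearson_r, r, tolerance = 1e-10)
  expect_equal(cmp$pearson_p, p_analytic, tolerance = 1e-10)
})

test_that("identical samples yield zero effect and missing correlation", {
  a <- c(1.0, 1.1, 1.2, 1.3, 1.15, 1.05)
  cmp <- suppressWarnings(compare_groups(a, a))
  expect_equal(cmp$cohens_d, 0)
  expect_true(is.na(cmp$pearson_r) ||
                abs(cmp$pearson_r) == 1)  # constant difference handled
})

test_that("paired comparisons align samples by image id", {
  a <- stats::setNames(c(1.1, 1.22, 1.3, 1.16, 1.21), paste0("img", 1:5))
  b <- stats::setNames(c(1.21, 1.3, 1.38, 1.27, 1.35, 1.5), paste0("img", 1:6))
  expect_warning(cmp <- compare_groups(a, b), "dropped")
  expect_equal(cmp$n_b, 6)       # full samples still summarized
  expect_false(is.na(cmp$wilcoxon_p))
})

test_that("report rows mirror the summary-table layout and survive CSV", {
  set.seed(8)
  a <- rnorm(12, 1.1, 0.04); b <- rnorm(12, 1.2, 0.05)
  cmp <- compare_groups(a, b)
  rep <- build_report(list(cmp), dataset = "phantom", fov_deg = 45,
                      totals = list(c(120, 130)))
  expect_equal(nrow(rep), 2)
  expect_equal(rep$group, c("artery", "vein"))
  expect_equal(rep$total, c(120L, 130L))
  if (cmp$branch == "parametric") {
    expect_true(is.na(rep$mannwhitney_p[1]))  # blank nonparametric cells
    expect_false(is.na(rep$pearson_r[1]))
  }
  f <- tempfile(fileext = ".csv")
  write.csv(rep, f, row.names = FALSE)
  back <- read.csv(f)
  expect_equal(back$mean_tortuosity, rep$mean_tortuosity, tolerance = 1e-12)
  expect_equal(back$cohens_d, rep$cohens_d, tolerance = 1e-12)
  unlink(f)
})

test_that("tidy and glance methods summarize a comparison", {
  set.seed(21)
  cmp <- compare_groups(rnorm(10, 1.1, 0.05), rnorm(10, 1.2, 0.05))
  td <- tidy(cmp)
  expect_true(all(c("term", "estimate", "p.value", "primary") %in% names(td)))
  expect_equal(sum(td$primary), 3)
  gl <- glance(cmp)
  expect_equal(nrow(gl), 1)
  expect_identical(gl$branch, cmp$branch)
})
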