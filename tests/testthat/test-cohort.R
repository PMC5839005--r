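# Cohort statistics: density records, landscape, paired tests, report.

test_that("density records follow count/area arithmetic and aggregate additively", {
  sq <- square_poly(100, 100, 201)
  rs <- build_regions(list(sq), margin_config(50, 50), frame = c(400, 400),
                      um_per_px = 1)
  cells <- data.frame(
    x_px = c(rep(200, 7), rep(105, 3)),
    y_px = c(rep(200, 7), rep(105, 3)),
    cd8_positive = TRUE)
  cells <- assign_cells_to_regions(cells, rs)
  rec <- compute_densities(cells, rs, "s1", "NSCLC")
  expect_equal(nrow(plausibility_check(rec)), 0L)
  tc <- rec[rec$region == "TC", ]; im <- rec[rec$region == "IM", ]
  ta <- rec[rec$region == "tumor_area", ]
  expect_equal(tc$count, 7); expect_equal(im$count, 3)
  expect_equal(ta$count, 10)
  expect_equal(ta$area_mm2, tc$area_mm2 + im$area_mm2)
  expect_equal(ta$density_per_mm2, ta$count / ta$area_mm2)
  # aggregate density lies between the region densities
  expect_gte(ta$density_per_mm2, min(tc$density_per_mm2, im$density_per_mm2))
  expect_lte(ta$density_per_mm2, max(tc$density_per_mm2, im$density_per_mm2))
})

test_that("no-IM mode emits no IM record", {
  sq <- square_poly(50, 50, 101)
  rs <- build_regions(list(sq), margin_config(50, 50, "no_im"),
                      frame = c(200, 200), um_per_px = 1)
  cells <- assign_cells_to_regions(
    data.frame(x_px = 100, y_px = 100, cd8_positive = TRUE), rs)
  rec <- compute_densities(cells, rs)
  expect_false("IM" %in% rec$region)
  expect_true(all(c("TC", "tumor_area") %in% rec$region))
})

test_that("landscape summary reports per-indication medians", {
  rec <- data.frame(sample = sprintf("s%d", 1:7),
                    indication = c(rep("A", 3), rep("B", 3), "C"),
                    region = "tumor_area", count = 1:7, area_mm2 = 1,
                    density_per_mm2 = c(1, 2, 3, 10, 20, 30, 5))
  ls_ <- landscape_summary(rec)
  expect_equal(ls_$summary$median[ls_$summary$indication == "A"], 2)
  expect_equal(ls_$summary$median[ls_$summary$indication == "B"], 20)
  expect_equal(ls_$summary$median[ls_$summary$indication == "C"], 5)
  expect_warning(landscape_summary(rec[0, ]), "no usable")
})

test_that("Wilcoxon signed-rank: exact enumeration oracle for n <= 10", {
  # 5 concordant pairs: two-sided exact p = 2/2^5
  w <- wilcoxon_tc_vs_im(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(w$p_value, 0.0625)
  expect_equal(w$method, "exact")
  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:10, 1)
    tc <- round(runif(n, 0, 30)); im <- round(runif(n, 0, 30))
    if (all(im == tc)) im[1] <- tc[1] + 1
    if (sum(im != tc) < 5) next
    w <- wilcoxon_tc_vs_im(tc, im)
    expect_equal(w$p_value, enum_signed_rank_p(im - tc), tolerance = 1e-12)
  }
})

test_that("Wilcoxon handles nulls, rescaling invariance, and large-n approximation", {
  # symmetric differences -> p near 1
  tc <- c(10, 20, 30, 40, 50, 60)
  im <- c(12, 18, 33, 37, 52, 58)
  w <- wilcoxon_tc_vs_im(tc, im)
  expect_gt(w$p_value, 0.8)
  # common positive rescaling of both members leaves p unchanged
  # (power-of-two factor keeps the tied |differences| exactly tied)
  w2 <- wilcoxon_tc_vs_im(4 * tc, 4 * im)
  expect_equal(w$p_value, w2$p_value)
  # n > 25 uses the tie-corrected normal approximation and agrees with
  # stats::wilcox.test
  set.seed(4)
  a <- rnorm(40, 10); b <- a + rnorm(40, 0.5)
  w3 <- wilcoxon_tc_vs_im(a, b)
  expect_equal(w3$method, "normal_approx")
  ref <- suppressWarnings(wilcox.test(b, a, paired = TRUE, exact = FALSE,
                                      correct = FALSE))
  expect_equal(w3$p_value, ref$p.value, tolerance = 1e-9)
  # long-format records input, samples lacking IM excluded
  rec <- rbind(
    data.frame(sample = sprintf("s%d", 1:6), region = "TC",
               density_per_mm2 = tc, count = 1, area_mm2 = 1),
    data.frame(sample = sprintf("s%d", 1:5), region = "IM",
               density_per_mm2 = im[1:5], count = 1, area_mm2 = 1))
  expect_equal(wilcoxon_tc_vs_im(rec)$n_effective, 5)
  expect_error(wilcoxon_tc_vs_im(c(1, 2), c(2, 3)), ">= 5")
})

test_that("paired t test matches the closed form and handles degeneracy", {
  pt <- paired_pre_post_test(c(0, 0, 0), c(1, 2, 3))
  expect_equal(pt$mean_difference, 2)
  expect_equal(pt$t, 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(pt$p_value, 0.0742, tolerance = 1e-3)
  same <- paired_pre_post_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p_value, 1)
  expect_equal(same$conf_int, c(0, 0))
  expect_error(paired_pre_post_test(1:2, 2:3), ">= 3")
})

test_that("planted paired shift is recovered and estimates are unbiased", {
  pb <- generate_paired_biopsies(25, 365, seed = 1)
  pt <- paired_pre_post_test(pb$screening_density, pb$on_treatment_density)
  expect_lt(pt$conf_int[1], 365); expect_gt(pt$conf_int[2], 365)
  expect_lt(pt$p_value, 0.05)
  est <- vapply(1:200, function(s)
    mean(generate_paired_biopsies(25, 365, seed = s)$true_difference), 0)
  expect_lt(abs(mean(est) - 365) / 365, 0.05)
})

test_that("cohort report is deterministic and refuses implausible records", {
  rec <- data.frame(sample = c("a", "a", "b", "b"),
                    region = c("TC", "tumor_area", "TC", "tumor_area"),
                    count = c(4, 4, 8, 8), area_mm2 = c(2, 2, 2, 2),
                    density_per_mm2 = c(2, 2, 4, 4),
                    indication = "X")
  d1 <- tempfile(); d2 <- tempfile()
  cohort_report(rec, d1, figures = FALSE)
  cohort_report(rec, d2, figures = FALSE)
  expect_identical(readLines(file.path(d1, "density_records.csv")),
                   readLines(file.path(d2, "density_records.csv")))
  bad <- rec; bad$count[1] <- -1; bad$density_per_mm2[1] <- -0.5
  expect_error(cohort_report(bad, tempfile(), figures = FALSE),
               "plausibility")
  # empty cohort does not crash
  expect_silent(cohort_report(rec[0, ], tempfile(), figures = FALSE))
})
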