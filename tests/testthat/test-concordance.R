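# Concordance statistics and the validation framework.

test_that("F1 closed forms and pooling contract", {
  expect_equal(f1_score(8, 2, 2), 0.8)
  expect_equal(f1_score(10, 0, 0), 1)
  # pooled over fields, not averaged
  expect_equal(f1_score(c(4, 4), c(1, 1), c(1, 1)), 0.8)
  expect_true(is.na(f1_score(0, 0, 0)))
})

test_that("Lin CCC matches the hand-evaluated formula and limit behavior", {
  x <- c(10, 12, 8, 15)
  expect_equal(lin_ccc(x, x), 1)
  expect_equal(lin_ccc(x, c(11, 13, 9, 14)), 0.9059, tolerance = 1e-4)
  # location shift drives CCC to 0 while PCC stays 1
  shifts <- vapply(c(10, 100, 1000), function(k) lin_ccc(x, x + k), 0)
  expect_true(all(diff(abs(shifts)) < 0))
  expect_lt(shifts[3], 0.001)
  expect_equal(pearson_cc(x, x + 1000), 1)
  expect_true(is.na(lin_ccc(c(1, 1), c(1, 1))))
})

test_that("|CCC| <= |PCC| over 1000 random pairs; CCC symmetric and permutation-invariant", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:20, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3)) +
      runif(1, -1, 1) * x
    ccc <- lin_ccc(x, y); pcc <- pearson_cc(x, y)
    if (!is.na(ccc) && !is.na(pcc))
      expect_lte(abs(ccc), abs(pcc) + 1e-12)
  }
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(lin_ccc(x, y), lin_ccc(y, x))
  p <- sample(10)
  expect_equal(lin_ccc(x[p], y[p]), lin_ccc(x, y))
})

test_that("Spearman equals brute-force mid-rank computation on tie-heavy vectors", {
  set.seed(7)
  for (i in 1:20) {
    x <- sample(1:4, 15, replace = TRUE)
    y <- sample(1:3, 15, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    # oracle: Pearson on explicitly computed mid-ranks
    midrank <- function(v) {
      sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
    }
    expect_equal(spearman_cc(x, y), pearson_cc(midrank(x), midrank(y)),
                 tolerance = 1e-12)
  }
  expect_equal(spearman_cc(1:8, (1:8)^3), 1)   # monotone transform
  expect_true(is.na(spearman_cc(rep(2, 5), 1:5)))
})

test_that("bootstrap lower bound: perfect agreement, determinism, below point estimate", {
  x <- c(3, 9, 14, 2, 8, 11)
  expect_equal(bootstrap_lower_ci(x, x, iterations = 200, seed = 1), 1)
  b1 <- bootstrap_lower_ci(x, x + rnorm(6), iterations = 500, seed = 5)
  b2 <- bootstrap_lower_ci(x, x + rnorm(6), iterations = 500, seed = 5)
  expect_false(identical(b1, b2))  # different y draws
  set.seed(31); y <- x + rnorm(6, sd = 2)
  expect_identical(bootstrap_lower_ci(x, y, iterations = 500, seed = 9),
                   bootstrap_lower_ci(x, y, iterations = 500, seed = 9))
  # percentile property over seeded runs
  set.seed(11)
  below <- vapply(1:50, function(s) {
    xx <- rnorm(12); yy <- xx + rnorm(12, sd = 0.5)
    bootstrap_lower_ci(xx, yy, iterations = 300, seed = s) <=
      lin_ccc(xx, yy) + 1e-12
  }, TRUE)
  expect_gte(mean(below), 0.99)
  expect_error(bootstrap_lower_ci(1:2, 1:2), ">= 3")
})

test_that("McBride categories use the quoted cut points, closed on the left", {
  expect_equal(mcbride_category(0.92), "almost_perfect")
  expect_equal(mcbride_category(0.90), "almost_perfect")
  expect_equal(mcbride_category(0.80), "substantial")
  expect_equal(mcbride_category(0.89), "substantial")
  expect_equal(mcbride_category(0.65), "moderate")
  expect_equal(mcbride_category(0.64), "poor")
  expect_error(mcbride_category(1.5), "\\[-1, 1\\]")
})

test_that("field selection is seeded, stratified across slides, and validated", {
  geom <- data.frame(slide = sprintf("sl%02d", 1:9),
                     width_um = 1200, height_um = 1200)
  f1 <- select_fields(geom, n_fields = 13, diameter_um = 250, seed = 4)
  f2 <- select_fields(geom, n_fields = 13, diameter_um = 250, seed = 4)
  expect_identical(f1, f2)
  # every slide receives at least one field
  expect_setequal(unique(f1$slide), geom$slide)
  # non-overlap within slides
  for (s in unique(f1$slide)) {
    sub <- f1[f1$slide == s, ]
    if (nrow(sub) > 1) {
      d <- as.matrix(dist(sub[, c("cx_um", "cy_um")]))
      expect_gte(min(d[upper.tri(d)]), 250)
    }
  }
  expect_error(select_fields(geom, n_fields = 0), ">= 1")
  expect_error(select_fields(geom, n_fields = 5, diameter_um = 300),
               "250 or 500")
})

test_that("plausibility check flags each violation class and passes clean tables", {
  clean <- data.frame(sample = c("a", "a", "b"), region = c("TC", "IM", "TC"),
                      count = c(10, 5, 0), area_mm2 = c(2, 1, 3),
                      density_per_mm2 = c(5, 5, 0))
  expect_equal(nrow(plausibility_check(clean)), 0L)
  bad <- clean
  bad$count[1] <- -1
  expect_true("negative_count" %in% plausibility_check(bad)$rule)
  bad2 <- rbind(clean, clean[1, ])
  expect_true("duplicate_key" %in% plausibility_check(bad2)$rule)
  bad3 <- clean; bad3$count[2] <- 5.5
  expect_true("noninteger_count" %in% plausibility_check(bad3)$rule)
  bad4 <- clean; bad4$density_per_mm2[1] <- 4.9
  expect_true("density_mismatch" %in% plausibility_check(bad4)$rule)
  bad5 <- clean; bad5$area_mm2[3] <- NA
  expect_true("missing_value" %in% plausibility_check(bad5)$rule)
  expect_error(plausibility_check(data.frame(a = 1)), "malformed")
})

test_that("validate_run: identical counts give perfect scores; consolidation is the per-field median", {
  set.seed(3)
  pts <- lapply(1:3, function(i) cbind(runif(60, 0, 1000), runif(60, 0, 1000)))
  names(pts) <- c("s1", "s2", "s3")
  geom <- data.frame(slide = names(pts), width_um = 1000, height_um = 1000)
  fields <- select_fields(geom, n_fields = 13, diameter_um = 250, seed = 2)
  vr <- validate_run(pts, pts, fields, iterations = 300, seed = 1)
  expect_equal(vr$ccc, 1); expect_equal(vr$f1, 1)
  expect_equal(vr$category, "almost_perfect")
  expect_equal(vr$fp + vr$fn, 0L)
  # three annotators: jittered copies; consolidated = per-field median
  ann <- lapply(c(0, 2, 50), function(k) {
    lapply(pts, function(p) {
      keep <- p
      if (k > 0) keep <- p[seq_len(max(1, nrow(p) - k)), , drop = FALSE]
      keep
    })
  })
  vr3 <- validate_run(pts, ann, fields, iterations = 300, seed = 1)
  counts <- sapply(seq_len(nrow(fields)), function(k) {
    f <- fields[k, ]
    sapply(ann, function(a) nrow(tilquant:::points_in_field(a[[f$slide]], f)))
  })
  expect_equal(vr3$per_field$annotated, apply(t(counts), 1, median))
  expect_length(vr3$per_annotator, 3L)
})
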