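# Three-stage CD8 detection and acceptance filtering, validated in closed
# loop against the synthetic generator's planted truth.

test_that("nucleus detection recovers planted nuclei and splits overlaps", {
  out <- small_mono()
  od <- rgb_to_od(out$slide$rgb)
  sf <- unmix_stains(od, stain_profile("mono_dab"))
  tis <- detect_tissue(od)
  nuc <- detect_nuclei(sf$fields$hematoxylin, tis, detection_config(), 0.5)
  tr <- out$truth$cells
  # recall: a detected nucleus within 3 um of each planted centroid
  hits <- vapply(seq_len(nrow(tr)), function(i) {
    d2 <- (nuc$centroids$x_px - tr$x_px[i])^2 +
          (nuc$centroids$y_px - tr$y_px[i])^2
    any(d2 <= (3 / 0.5)^2)
  }, TRUE)
  expect_gt(mean(hits), 0.95)
  # blank field
  none <- detect_nuclei(matrix(0, 64, 64), matrix(TRUE, 64, 64))
  expect_equal(nrow(none$centroids), 0L)
  # two overlapping nuclei (< 30% overlap) are split by watershed
  h <- matrix(0, 64, 64)
  h[raster_ellipse(64, 64, 26, 32, 6, 6)] <- 0.6
  h[raster_ellipse(64, 64, 36, 32, 6, 6)] <- 0.6
  two <- detect_nuclei(h, matrix(TRUE, 64, 64), detection_config(), 0.5)
  expect_equal(nrow(two$centroids), 2L)
})

test_that("stage 1 takes clean single cells and defers pairs and clusters", {
  # build a clean synthetic positive mask directly
  nr <- 200
  ring_at <- function(m, cx, cy, r = 9) {
    m | (raster_ellipse(nr, nr, cx, cy, r, r) &
           !raster_ellipse(nr, nr, cx, cy, r - 3, r - 3))
  }
  pos <- matrix(FALSE, nr, nr)
  pos <- ring_at(pos, 40, 40)                    # isolated
  pos <- ring_at(pos, 150, 40); pos <- ring_at(pos, 165, 40)  # touching pair
  no_nuc <- list(labels = matrix(0L, nr, nr),
                 centroids = data.frame(id = integer(0), x_px = numeric(0),
                                        y_px = numeric(0),
                                        area_um2 = numeric(0)))
  nuc3 <- list(labels = matrix(0L, nr, nr),
               centroids = data.frame(id = 1:3, x_px = c(40, 150, 165),
                                      y_px = c(40, 40, 40), area_um2 = 30))
  st1 <- detect_isolated_cells(pos, nuc3, detection_config(), 0.5)
  # the merged pair holds two nuclei -> deferred to cluster splitting;
  # the single ring is the only stage-1 candidate
  expect_length(st1$candidates, 1L)
  expect_length(st1$deferred, 1L)
  cen_pix <- st1$candidates[[1]]$pix
  ys <- (cen_pix - 1) %% nr; xs <- (cen_pix - 1) %/% nr
  expect_lt(abs(mean(xs) - 40), 2); expect_lt(abs(mean(ys) - 40), 2)
  # two cells 50 um apart -> both isolated
  pos2 <- ring_at(ring_at(matrix(FALSE, nr, nr), 40, 40), 140, 140)
  st2 <- detect_isolated_cells(pos2, no_nuc, detection_config(), 0.5)
  expect_length(st2$candidates, 2L)
})

test_that("stage 2 recovers partial-ring cells anchored at nuclei, drops nucleus-free blobs", {
  cf <- synthetic_config(image_size_px = c(512, 512),
                         target_density_per_mm2 = 400, cluster_fraction = 0,
                         elongate_fraction = 0, partial_ring_fraction = 1,
                         seed = 3)
  out <- generate_slide(cf)
  cells <- segment_cd8(out$slide)
  mr <- match_cells(cells, out$truth$cells)
  expect_gte(f1_score(mr$tp, mr$fp, mr$fn), 0.9)
  expect_gt(attr(cells, "stage_counts")["difficult"], 0)
  # empty residual -> nothing
  no_nuc <- detect_nuclei(matrix(0, 64, 64), matrix(TRUE, 64, 64))
  st <- detect_difficult_cells(matrix(FALSE, 64, 64), no_nuc)
  expect_length(st$candidates, 0L)
  # artifact blob without a nucleus is not recovered
  blob <- raster_ellipse(64, 64, 32, 32, 8, 8)
  st2 <- detect_difficult_cells(blob, no_nuc, detection_config(), 0.5)
  expect_length(st2$candidates, 0L)
})

test_that("cluster resolution splits merged cells by their nuclei", {
  cf <- synthetic_config(image_size_px = c(512, 512),
                         target_density_per_mm2 = 900, cluster_fraction = 1,
                         elongate_fraction = 0, partial_ring_fraction = 0,
                         seed = 4)
  out <- generate_slide(cf)
  cells <- segment_cd8(out$slide)
  expect_gt(attr(cells, "stage_counts")["cluster_split"], 0)
  mr <- match_cells(cells, out$truth$cells)
  expect_gte(f1_score(mr$tp, mr$fp, mr$fn), 0.9)
  # oversize component with a single nucleus stays one candidate
  comp <- list(pix = which(raster_ellipse(80, 80, 40, 40, 14, 14)),
               nuclei = 1L)
  nuc <- list(labels = matrix(0L, 80, 80),
              centroids = data.frame(id = 1L, x_px = 40, y_px = 40,
                                     area_um2 = 30))
  frag <- resolve_clusters(list(comp), nuc, c(80, 80), detection_config(), 0.5)
  expect_length(frag, 1L)
  # component with no nuclei -> nothing
  expect_length(resolve_clusters(list(list(pix = comp$pix,
                                           nuclei = integer(0))),
                                 nuc, c(80, 80)), 0L)
})

test_that("acceptance filter applies the size and weak_no_nucleus rules", {
  base <- data.frame(
    id = 1:4,
    area_um2 = c(60, 600, 18, 60),
    compactness = c(0.9, 0.9, 0.9, 0.9),
    membrane_completeness = c(0.2, 0.9, 0.9, 0.2),
    mean_cd8_od = c(0.2, 0.9, 0.9, 0.9),
    mean_threshold = c(0.15, 0.15, 0.15, 0.15),
    has_nucleus = c(FALSE, TRUE, TRUE, FALSE))
  out <- filter_candidates(base, detection_config())
  # 1: weak partial, no nucleus -> weak_no_nucleus; 2: oversize -> size;
  # 3: undersize -> size; 4: strong but incomplete membrane, no nucleus
  expect_setequal(out$rejections$id, c(1L, 2L, 3L, 4L))
  expect_equal(out$rejections$rule[out$rejections$id == 1L],
               "weak_no_nucleus")
  expect_true(all(out$rejections$rule[out$rejections$id %in% c(2L, 3L)] ==
                    "size"))
  # canonical cell passes
  good <- data.frame(id = 1L, area_um2 = 60, compactness = 0.9,
                     membrane_completeness = 0.95, mean_cd8_od = 0.8,
                     mean_threshold = 0.15, has_nucleus = TRUE)
  expect_equal(nrow(filter_candidates(good)$accepted), 1L)
})

test_that("full pipeline: blank slide empty, determinism, stage partition", {
  blank <- til_slide(array(255, c(128, 128, 3)), 0.5, "blank")
  expect_equal(nrow(segment_cd8(blank)), 0L)
  cells1 <- small_mono_cells()
  cells2 <- segment_cd8(small_mono()$slide)
  expect_identical(as.data.frame(cells1), as.data.frame(cells2))
  # accepted footprints pairwise disjoint, one stage per cell
  fp <- attr(cells1, "footprints")
  allpix <- unlist(fp)
  expect_equal(anyDuplicated(allpix), 0L)
  expect_true(all(cells1$stage %in% c("isolated", "difficult",
                                      "cluster_split")))
})

test_that("recovered count is within 5% of planted truth at moderate density", {
  out <- small_mono()
  cells <- small_mono_cells()
  n_true <- nrow(out$truth$cells)
  expect_lte(abs(nrow(cells) - n_true) / n_true, 0.05)
})

test_that("raising the OD floor never increases the accepted count", {
  sl <- small_mono()$slide
  counts <- vapply(c(0.15, 0.3, 0.5), function(fl)
    nrow(segment_cd8(sl, config = detection_config(od_floor = fl))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("zero-noise isolated-only slides are recovered exactly", {
  cf <- synthetic_config(image_size_px = c(512, 512),
                         target_density_per_mm2 = 500, cluster_fraction = 0,
                         elongate_fraction = 0, partial_ring_fraction = 0,
                         noise_sd = 0, illumination_amplitude = 0, seed = 13)
  out <- generate_slide(cf)
  cells <- segment_cd8(out$slide)
  expect_equal(nrow(cells), nrow(out$truth$cells))
  mr <- match_cells(cells, out$truth$cells, max_dist_um = 1)  # <= 2 px
  expect_equal(mr$fp, 0L); expect_equal(mr$fn, 0L)
})
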