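# Synthetic IHC slide generator with exact planted ground truth.
#
# The renderer works entirely in optical-density (OD) space: per-stain
# scalar fields are painted (hematoxylin nuclei, DAB or purple membrane
# rings, graded PD-L1 regions), mixed through the stain profile's color
# vectors by Beer-Lambert and only then exposed to illumination bias,
# Gaussian sensor noise and 8-bit quantization.  Because mixing is linear in
# OD, color deconvolution inverts it exactly in the noise-free limit, which
# gives every downstream module an analytic oracle.

#' Configuration for the synthetic slide generator
#'
#' @param image_size_px integer pair (rows, cols); each side >= 64.
#' @param um_per_px physical calibration, microns per pixel (default 0.5,
#'   a typical 20X scan).
#' @param target_density_per_mm2 expected planted CD8+ cell density over the
#'   plantable tissue area; the realized count is Poisson.
#' @param elongate_fraction fraction of cells rendered as elongate
#'   (isolated rotated ellipses built to satisfy the elongate criteria with
#'   >= 10\% margin).
#' @param cluster_fraction fraction of the non-elongate cells placed in
#'   tight Matern-style clusters (rings touching, nuclei distinct).
#' @param mean_cell_diameter_um mean diameter of round cells (default 9).
#' @param stain_mode \code{"mono_dab"} (CD8 brown) or
#'   \code{"dual_purple_dab"} (CD8 purple + PD-L1 brown).
#' @param necrosis_fraction fraction of the tissue area occupied by one
#'   necrotic blob (no cells planted there; recorded as exclusion).
#' @param pdl1_region_fraction dual mode only: fraction of the tumor area
#'   covered by PD-L1+ blobs with graded intensity.
#' @param partial_ring_fraction fraction of round cells rendered with an
#'   incomplete membrane arc (exercises the nucleus-anchored second
#'   detection stage).
#' @param noise_sd Gaussian sensor noise SD in 8-bit intensity levels.
#' @param illumination_amplitude relative amplitude of the low-frequency
#'   multiplicative illumination field.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(image_size_px = c(1024L, 1024L),
                             um_per_px = 0.5,
                             target_density_per_mm2 = 500,
                             elongate_fraction = 0.05,
                             cluster_fraction = 0.2,
                             mean_cell_diameter_um = 9,
                             stain_mode = c("mono_dab", "dual_purple_dab"),
                             necrosis_fraction = 0,
                             pdl1_region_fraction = 0,
                             partial_ring_fraction = 0.05,
                             noise_sd = 2,
                             illumination_amplitude = 0.05,
                             seed = 1L) {
  stain_mode <- match.arg(stain_mode)
  image_size_px <- as.integer(rep(image_size_px, length.out = 2L))
  if (any(image_size_px < 64L))
    stop("degenerate image size: each side must be >= 64 px")
  stopifnot_scalar(um_per_px, "um_per_px", positive = TRUE)
  stopifnot_scalar(mean_cell_diameter_um, "mean_cell_diameter_um",
                   positive = TRUE)
  stopifnot_scalar(target_density_per_mm2, "target_density_per_mm2")
  if (target_density_per_mm2 < 0) stop("density must be >= 0")
  for (f in c("elongate_fraction", "cluster_fraction", "necrosis_fraction",
              "pdl1_region_fraction", "partial_ring_fraction"))
    check_fraction(get(f), f)
  structure(list(
    image_size_px = image_size_px, um_per_px = um_per_px,
    target_density_per_mm2 = target_density_per_mm2,
    elongate_fraction = elongate_fraction,
    cluster_fraction = cluster_fraction,
    mean_cell_diameter_um = mean_cell_diameter_um,
    stain_mode = stain_mode,
    necrosis_fraction = necrosis_fraction,
    pdl1_region_fraction = pdl1_region_fraction,
    partial_ring_fraction = partial_ring_fraction,
    noise_sd = noise_sd,
    illumination_amplitude = illumination_amplitude,
    seed = as.integer(seed)), class = "synthetic_config")
}

# Local ellipse rasterization: returns row/col index ranges and the logical
# mask of pixels (centers) inside the rotated ellipse.  Coordinates are
# 0-based (x = col - 1, y = row - 1).
ellipse_window <- function(nr, nc, cx, cy, a, b, theta) {
  ext <- max(a, b) + 1
  r1 <- max(1L, floor(cy - ext) + 1L); r2 <- min(nr, ceiling(cy + ext) + 1L)
  c1 <- max(1L, floor(cx - ext) + 1L); c2 <- min(nc, ceiling(cx + ext) + 1L)
  if (r1 > r2 || c1 > c2) return(NULL)
  ys <- (r1:r2) - 1; xs <- (c1:c2) - 1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  list(r = r1:r2, c = c1:c2, u = u, v = v,
       inside = (u / a)^2 + (v / b)^2 <= 1)
}

# linear indices (into the full [nr, nc] matrix) of the selected pixels of
# an ellipse window; lets the renderer paint in place without copying the
# full raster
win_idx <- function(win, sel, nr) {
  si <- which(sel)
  if (!length(si)) return(integer(0))
  sub_nr <- length(win$r)
  rr <- win$r[(si - 1L) %% sub_nr + 1L]
  cc <- win$c[(si - 1L) %/% sub_nr + 1L]
  (cc - 1L) * nr + rr
}

# Sequential hard-core placement.  Each accepted point carries a group id
# and an inter-group separation requirement `sep_out`; two points of
# different groups must be at least max(sep_out_i, sep_out_j) apart, while
# points of the same group (a cluster) only need `sep_intra`.
make_placer <- function(nr, nc, margin_px, forbidden_mask = NULL) {
  pts_x <- numeric(0); pts_y <- numeric(0)
  pts_sep <- numeric(0); pts_grp <- integer(0)
  list(
    place = function(sep_out, group, sep_intra = sep_out,
                     max_try = 200L, near = NULL, near_r = NULL) {
      for (i in seq_len(max_try)) {
        if (is.null(near)) {
          x <- runif(1, margin_px, nc - 1 - margin_px)
          y <- runif(1, margin_px, nr - 1 - margin_px)
        } else {
          ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * near_r
          x <- near[1] + rad * cos(ang); y <- near[2] + rad * sin(ang)
          if (x < margin_px || x > nc - 1 - margin_px ||
              y < margin_px || y > nr - 1 - margin_px) next
        }
        if (!is.null(forbidden_mask) &&
            forbidden_mask[round(y) + 1L, round(x) + 1L]) next
        if (length(pts_x)) {
          d2 <- (pts_x - x)^2 + (pts_y - y)^2
          req <- ifelse(pts_grp == group, sep_intra, pmax(pts_sep, sep_out))
          if (any(d2 < req^2)) next
        }
        pts_x <<- c(pts_x, x); pts_y <<- c(pts_y, y)
        pts_sep <<- c(pts_sep, sep_out); pts_grp <<- c(pts_grp, group)
        return(c(x, y))
      }
      NULL
    },
    points = function() cbind(x = pts_x, y = pts_y)
  )
}

#' Generate a synthetic IHC slide with planted ground truth
#'
#' Renders an RGB raster of DAB- (or purple-) membrane-labeled lymphocytes
#' with hematoxylin nuclei over a faintly counterstained tissue background,
#' and returns the exact planted truth: per-cell centroids, footprint label
#' map, shape parameters and class flags, region polygons, and (in dual
#' mode) the planted PD-L1 mask and grade raster.
#'
#' @param config a [synthetic_config()].
#' @return list with elements \code{slide} (class \code{til_slide}) and
#'   \code{truth} (class \code{til_truth}; fields \code{cells},
#'   \code{label_map}, \code{regions}, \code{pdl1_mask},
#'   \code{pdl1_grade}, \code{tissue_mask}, \code{plantable_area_mm2}).
#' @export
generate_slide <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_slide_impl(config))
}

generate_slide_impl <- function(cf) {
  nr <- cf$image_size_px[1]; nc <- cf$image_size_px[2]
  upp <- cf$um_per_px
  margin_px <- 12
  d_px <- cf$mean_cell_diameter_um / upp

  # tissue occupies the full frame minus a glass border
  tis <- matrix(FALSE, nr, nc)
  tis[(margin_px + 1):(nr - margin_px), (margin_px + 1):(nc - margin_px)] <- TRUE
  tissue_poly <- cbind(
    x = c(margin_px, nc - 1 - margin_px, nc - 1 - margin_px, margin_px),
    y = c(margin_px, margin_px, nr - 1 - margin_px, nr - 1 - margin_px))
  inset <- round(0.12 * min(nr, nc))
  tumor_poly <- cbind(
    x = c(inset, nc - 1 - inset, nc - 1 - inset, inset),
    y = c(inset, inset, nr - 1 - inset, nr - 1 - inset))

  # necrotic blob: debris-like smear without nuclei, recorded as exclusion
  necro_mask <- matrix(FALSE, nr, nc)
  exclusions <- list()
  if (cf$necrosis_fraction > 0) {
    A_tis <- sum(tis)
    a_n <- sqrt(cf$necrosis_fraction * A_tis / pi) * 1.2
    b_n <- cf$necrosis_fraction * A_tis / pi / a_n
    cxn <- runif(1, 0.3 * nc, 0.7 * nc); cyn <- runif(1, 0.3 * nr, 0.7 * nr)
    thn <- runif(1, 0, pi)
    w <- ellipse_window(nr, nc, cxn, cyn, a_n, b_n, thn)
    necro_mask[win_idx(w, w$inside, nr)] <- TRUE
    necro_mask <- necro_mask & tis
    # polygonal record of the blob (32-gon on the ellipse)
    ang <- seq(0, 2 * pi, length.out = 33)[-33]
    ex <- cbind(x = cxn + a_n * cos(ang) * cos(thn) - b_n * sin(ang) * sin(thn),
                y = cyn + a_n * cos(ang) * sin(thn) + b_n * sin(ang) * cos(thn))
    exclusions <- list(ex)
  }

  plantable <- tis & !necro_mask
  plantable_area_mm2 <- sum(plantable) * (upp / 1000)^2

  n_total <- if (cf$target_density_per_mm2 > 0)
    rpois(1, cf$target_density_per_mm2 * plantable_area_mm2) else 0L

  n_elong <- rbinom(1, n_total, cf$elongate_fraction)
  n_rest <- n_total - n_elong
  n_clustered <- round(cf$cluster_fraction * n_rest)
  n_iso <- n_rest - n_clustered

  placer <- make_placer(nr, nc, margin_px + d_px, forbidden_mask = necro_mask)
  cells <- list()
  add_cell <- function(xy, type, a_um, b_um, theta, cluster_id = NA_integer_,
                       ring_coverage = 1) {
    cells[[length(cells) + 1L]] <<- list(
      x_px = xy[1], y_px = xy[2], type = type, a_um = a_um, b_um = b_um,
      orientation = theta, cluster = cluster_id, ring_coverage = ring_coverage)
  }

  # group ids: 0 reserved; isolated/elongate cells get unique groups,
  # cluster members share one per cluster
  grp <- 0L
  # elongate cells first (they need the widest clearance); criteria met with
  # >= 10% margin: width <= 8 um < 10, ratio >= 2.6 > 2.3, isolation wide
  iso_elong_px <- (cf$mean_cell_diameter_um + 30) / upp
  for (i in seq_len(n_elong)) {
    grp <- grp + 1L
    xy <- placer$place(sep_out = iso_elong_px, group = grp)
    if (is.null(xy)) break
    W <- runif(1, 4.5, 8); ratio <- runif(1, 2.6, 3.8)
    add_cell(xy, "elongate", a_um = W * ratio / 2, b_um = W / 2,
             theta = runif(1, 0, pi))
  }

  # isolated round cells: hard-core at ~1.3 cell diameters so stage 1 sees
  # clean single components
  for (i in seq_len(n_iso)) {
    grp <- grp + 1L
    xy <- placer$place(sep_out = 1.3 * d_px, group = grp)
    if (is.null(xy)) break
    r <- cf$mean_cell_diameter_um / 2 * runif(1, 0.9, 1.1)
    cov <- if (runif(1) < cf$partial_ring_fraction) runif(1, 0.4, 0.7) else 1
    add_cell(xy, "round", a_um = r, b_um = r, theta = runif(1, 0, pi),
             ring_coverage = cov)
  }

  # Matern-style clusters: members tightly packed (rings merge, nuclei
  # stay distinct), whole cluster kept clear of other cells
  placed_cl <- 0L; cl_id <- 0L; failures <- 0L
  while (placed_cl < n_clustered && failures < 20L) {
    k <- min(sample(3:6, 1), n_clustered - placed_cl)
    if (k < 2) k <- 2
    grp <- grp + 1L
    ctr <- placer$place(sep_out = 2.2 * d_px, group = grp)
    if (is.null(ctr)) { failures <- failures + 1L; next }
    cl_id <- cl_id + 1L
    r0 <- cf$mean_cell_diameter_um / 2 * runif(1, 0.9, 1.05)
    add_cell(ctr, "round", a_um = r0, b_um = r0, theta = 0, cluster_id = cl_id)
    placed_cl <- placed_cl + 1L
    for (j in seq_len(k - 1L)) {
      if (placed_cl >= n_clustered) break
      xy <- placer$place(sep_out = 2.2 * d_px, group = grp,
                         sep_intra = 0.72 * d_px,
                         near = ctr, near_r = 1.4 * d_px)
      if (is.null(xy)) next
      r <- cf$mean_cell_diameter_um / 2 * runif(1, 0.9, 1.05)
      add_cell(xy, "round", a_um = r, b_um = r, theta = 0, cluster_id = cl_id)
      placed_cl <- placed_cl + 1L
    }
  }

  ncell <- length(cells)

  # ---- render OD fields -------------------------------------------------
  profile <- stain_profile(cf$stain_mode)
  hema <- matrix(0.09, nr, nc); hema[!tis] <- 0      # faint counterstain wash
  cd8f <- matrix(0, nr, nc)                           # CD8 chromogen field
  pdl1f <- NULL
  label_map <- matrix(0L, nr, nc)

  ring_t_px <- max(1, 1.3 / upp)
  nuc_scale <- 0.55

  cell_rows <- vector("list", ncell)
  for (i in seq_len(ncell)) {
    ce <- cells[[i]]
    a_px <- ce$a_um / upp; b_px <- ce$b_um / upp
    w <- ellipse_window(nr, nc, ce$x_px, ce$y_px, a_px, b_px, ce$orientation)
    if (is.null(w)) next
    label_map[win_idx(w, w$inside, nr)] <- i
    # membrane ring: between full ellipse and one shrunk by the ring
    # thickness along the minor axis
    s <- max(0.05, 1 - ring_t_px / b_px)
    ring <- w$inside & ((w$u / (a_px * s))^2 + (w$v / (b_px * s))^2 > 1)
    if (ce$ring_coverage < 1) {
      phi <- atan2(w$v / b_px, w$u / a_px) %% (2 * pi)
      phi0 <- runif(1, 0, 2 * pi)
      arc <- ((phi - phi0) %% (2 * pi)) <= 2 * pi * ce$ring_coverage
      ring <- ring & arc
    }
    od_ring <- 0.85 * runif(1, 0.85, 1.15)
    ri <- win_idx(w, ring, nr)
    cd8f[ri] <- pmax(cd8f[ri], od_ring)
    ci <- win_idx(w, w$inside & !ring, nr)
    cd8f[ci] <- pmax(cd8f[ci], 0.06)   # faint cytoplasm
    # nucleus
    wn <- ellipse_window(nr, nc, ce$x_px, ce$y_px,
                         max(1.2, a_px * nuc_scale), max(1.2, b_px * nuc_scale),
                         ce$orientation)
    ni <- win_idx(wn, wn$inside, nr)
    hema[ni] <- pmax(hema[ni], 0.55 * runif(1, 0.9, 1.1))
    cell_rows[[i]] <- data.frame(
      id = i, x_px = ce$x_px, y_px = ce$y_px,
      x_um = ce$x_px * upp, y_um = ce$y_px * upp,
      type = ce$type, elongate = ce$type == "elongate",
      length_um = 2 * ce$a_um, width_um = 2 * ce$b_um,
      orientation = ce$orientation, cluster = ce$cluster,
      ring_coverage = ce$ring_coverage)
  }
  truth_cells <- if (ncell)
    do.call(rbind, cell_rows[!vapply(cell_rows, is.null, TRUE)]) else
    data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
               x_um = numeric(0), y_um = numeric(0), type = character(0),
               elongate = logical(0), length_um = numeric(0),
               width_um = numeric(0), orientation = numeric(0),
               cluster = integer(0), ring_coverage = numeric(0))
  if (nrow(truth_cells)) {
    px_area <- tabulate(label_map[label_map > 0L], nbins = ncell)
    truth_cells$area_um2 <- px_area[truth_cells$id] * upp^2
  } else truth_cells$area_um2 <- numeric(0)

  # necrotic smear: weak structureless chromogen + almost no counterstain
  if (any(necro_mask)) {
    hema[necro_mask] <- 0.03
    cd8f[necro_mask] <- pmax(cd8f[necro_mask], 0.08)
  }

  # PD-L1 graded blobs (dual mode): painted on the DAB field
  pdl1_mask <- NULL; pdl1_grade <- NULL
  if (cf$stain_mode == "dual_purple_dab") {
    pdl1f <- matrix(0, nr, nc)
    pdl1_grade <- matrix(0L, nr, nc)
    if (cf$pdl1_region_fraction > 0) {
      # tumor rectangle bounds (px, 1-based rows/cols)
      rr <- (inset + 1):(nr - inset); cc <- (inset + 1):(nc - inset)
      target <- cf$pdl1_region_fraction * length(rr) * length(cc)
      covered <- 0
      grade_od <- c(0.30, 0.55, 0.85)
      while (covered < target) {
        rad <- runif(1, 0.06, 0.14) * min(nr, nc)
        cx <- runif(1, min(cc) + rad, max(cc) - rad) - 1
        cy <- runif(1, min(rr) + rad, max(rr) - rad) - 1
        g <- sample(1:3, 1)
        w <- ellipse_window(nr, nc, cx, cy, rad, rad * runif(1, 0.6, 1), runif(1, 0, pi))
        bi <- win_idx(w, w$inside, nr)
        pdl1f[bi] <- pmax(pdl1f[bi], grade_od[g])
        pdl1_grade[bi] <- pmax(pdl1_grade[bi], g)
        covered <- sum(pdl1_grade > 0L)
      }
    }
    pdl1_mask <- pdl1_grade > 0L
  }

  fields <- if (cf$stain_mode == "mono_dab") list(hematoxylin = hema, dab = cd8f)
            else list(hematoxylin = hema, purple = cd8f, dab = pdl1f)
  rgb <- od_to_rgb(fields, profile, bit8 = FALSE)

  if (cf$illumination_amplitude > 0) {
    L <- illumination_field(nr, nc, cf$illumination_amplitude)
    rgb <- rgb * as.vector(L)
  }
  if (cf$noise_sd > 0)
    rgb <- rgb + rnorm(length(rgb), 0, cf$noise_sd)
  rgb <- round(pmin(pmax(rgb, 0), 255))

  regions <- region_set(
    tumor = list(tumor_poly), exclusions = exclusions,
    frame = c(nr, nc), um_per_px = upp)

  slide <- til_slide(rgb, um_per_px = upp,
                     id = sprintf("synthetic-%d", cf$seed),
                     stain_mode = cf$stain_mode)
  truth <- structure(list(
    cells = truth_cells, label_map = label_map, regions = regions,
    tissue_mask = tis, tissue_poly = tissue_poly,
    pdl1_mask = pdl1_mask, pdl1_grade = pdl1_grade,
    plantable_area_mm2 = plantable_area_mm2, config = cf),
    class = "til_truth")
  list(slide = slide, truth = truth)
}

#' @export
print.til_truth <- function(x, ...) {
  cat("Synthetic ground truth:", nrow(x$cells), "planted cells over",
      sprintf("%.3f mm^2 (%.0f/mm^2 target)", x$plantable_area_mm2,
              x$config$target_density_per_mm2), "\n")
  invisible(x)
}

#' Generate a synthetic cohort of slides
#'
#' Draws per-sample target densities from per-indication lognormal
#' distributions and renders one slide per sample with a deterministically
#' derived per-sample seed.
#'
#' @param n_samples number of samples (>= 1).
#' @param indications character vector of indication names recycled across
#'   samples, or a data.frame with columns \code{indication},
#'   \code{median_density}, \code{sdlog}.  Defaults to the built-in presets
#'   (see [indication_presets()]).
#' @param seed master seed.
#' @param config_template [synthetic_config()] whose non-density fields are
#'   reused for every sample.
#' @param render if \code{FALSE}, skip image rendering and return truth-only
#'   records (fast path for cohort-statistics work).
#' @return list of per-sample lists: \code{sample_id}, \code{indication},
#'   \code{true_density}, and when rendered \code{slide}, \code{truth}.
#' @export
generate_cohort <- function(n_samples, indications = indication_presets(),
                            seed = 1L, config_template = synthetic_config(),
                            render = TRUE) {
  if (!is.numeric(n_samples) || n_samples < 1)
    stop("n_samples must be >= 1")
  n_samples <- as.integer(n_samples)
  if (is.character(indications)) {
    pre <- indication_presets()
    if (!all(indications %in% pre$indication))
      stop("unknown indication name")
    indications <- pre[match(indications, pre$indication), ]
  }
  idx <- rep(seq_len(nrow(indications)), length.out = n_samples)
  with_seed(seed, {
    dens <- stats::rlnorm(n_samples,
                          meanlog = log(indications$median_density[idx]),
                          sdlog = indications$sdlog[idx])
    lapply(seq_len(n_samples), function(i) {
      cf <- config_template
      cf$target_density_per_mm2 <- dens[i]
      cf$seed <- derive_seed(seed, i)
      out <- list(sample_id = sprintf("S%03d", i),
                  indication = indications$indication[idx[i]],
                  true_density = dens[i])
      if (render) {
        sl <- generate_slide(cf)
        out$slide <- sl$slide; out$truth <- sl$truth
      }
      out
    })
  })
}

#' Built-in synthetic indication presets
#'
#' Nine tumor-type presets for the cohort generator.  The medians are
#' synthetic settings chosen to span a realistic dynamic range (lymphoma
#' richest in CD8+ cells, prostate and kidney poorest); they are not
#' measurements.
#'
#' @return data.frame with columns \code{indication},
#'   \code{median_density} (cells/mm2), \code{sdlog}.
#' @export
indication_presets <- function() {
  data.frame(
    indication = c("DLBCL", "LSCC", "LNSQ", "HNSCC", "GEC", "PANC",
                   "UBC", "RCC", "PROS"),
    median_density = c(1500, 700, 600, 500, 400, 350, 250, 150, 120),
    sdlog = c(0.5, 0.6, 0.7, 0.6, 0.7, 0.6, 0.6, 0.8, 0.4))
}

#' Generate paired screening / on-treatment biopsy truths
#'
#' Emulates matched tumor biopsies taken at screening and about six weeks
#' into therapy: the on-treatment member's true density equals the screening
#' density plus a systematic shift plus Gaussian noise (clamped at zero).
#'
#' @param n_pairs number of patients (>= 2).
#' @param mean_density_shift_per_mm2 systematic on-treatment density change.
#' @param seed master seed.
#' @param screening_median,screening_sdlog lognormal parameters of the
#'   screening densities.
#' @param noise_sd SD of the pairwise biological + sampling noise
#'   (cells/mm2; default 300).
#' @param render if \code{TRUE} additionally renders slides for each biopsy
#'   via [generate_slide()] (slow; truth-only is the default).
#' @param config_template used when rendering.
#' @return data.frame with one row per pair: \code{pair_id},
#'   \code{screening_density}, \code{on_treatment_density},
#'   \code{true_difference}; rendered slides (if any) attached as the
#'   \code{"slides"} attribute.
#' @export
generate_paired_biopsies <- function(n_pairs, mean_density_shift_per_mm2 = 0,
                                     seed = 1L,
                                     screening_median = 400,
                                     screening_sdlog = 0.5,
                                     noise_sd = 300,
                                     render = FALSE,
                                     config_template = synthetic_config()) {
  if (!is.numeric(n_pairs) || n_pairs < 2) stop("n_pairs must be >= 2")
  n_pairs <- as.integer(n_pairs)
  with_seed(seed, {
    scr <- stats::rlnorm(n_pairs, log(screening_median), screening_sdlog)
    on <- pmax(0, scr + mean_density_shift_per_mm2 + rnorm(n_pairs, 0, noise_sd))
    df <- data.frame(pair_id = sprintf("P%03d", seq_len(n_pairs)),
                     screening_density = scr,
                     on_treatment_density = on,
                     true_difference = on - scr)
    if (render) {
      slides <- lapply(seq_len(n_pairs), function(i) {
        lapply(c(scr = scr[i], on = on[i]), function(d) {
          cf <- config_template
          cf$target_density_per_mm2 <- d
          cf$seed <- derive_seed(seed, i * 2L + (d == on[i]))
          generate_slide(cf)
        })
      })
      attr(df, "slides") <- slides
    }
    df
  })
}
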