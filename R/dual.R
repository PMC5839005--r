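# CD8/PD-L1 dual-assay analysis: purple-channel CD8 detection, graded
# brown (DAB) PD-L1 region classification, and CD8 counting inside
# PD-L1-positive vs -negative tumor.

#' PD-L1 grading configuration
#'
#' PD-L1 positivity is pixel-wise: the DAB field is thresholded adaptively
#' and positive pixels are binned into three ordered intensity grades by
#' OD cut points (equal-width bins above the positivity threshold by
#' default).
#'
#' @param grade_od_cuts increasing OD cut points separating grades 1/2/3
#'   (default \code{c(0.2, 0.45, 0.7)}: grade 1 up to 0.45, grade 2 up to
#'   0.7, grade 3 above).
#' @param min_region_area_um2 specks below this area are removed from the
#'   positive mask.
#' @return object of class \code{pdl1_config}.
#' @export
pdl1_config <- function(grade_od_cuts = c(0.2, 0.45, 0.7),
                        min_region_area_um2 = 100) {
  if (any(diff(grade_od_cuts) <= 0)) stop("grade cut points must increase")
  structure(list(grade_od_cuts = grade_od_cuts,
                 min_region_area_um2 = min_region_area_um2),
            class = "pdl1_config")
}

#' Segment a CD8/PD-L1 dual-stained slide
#'
#' Runs the CD8 detection pipeline on the purple chromogen channel and
#' classifies PD-L1+ regions from the DAB channel with graded intensity.
#'
#' @param slide a [til_slide()] with \code{stain_mode = "dual_purple_dab"}.
#' @param regions optional [region_set()] for region labels.
#' @param config a [detection_config()].
#' @param pdl1 a [pdl1_config()].
#' @param criteria an [elongate_criteria()].
#' @return list with \code{cells} (a \code{til_cells} table from the
#'   purple channel) and \code{pdl1} (class \code{pdl1_regions}: list with
#'   \code{positive_mask}, \code{intensity_grade} raster in 0..3,
#'   \code{grade_od_cuts}).
#' @export
segment_dual <- function(slide, regions = NULL, config = detection_config(),
                         pdl1 = pdl1_config(),
                         criteria = elongate_criteria()) {
  stopifnot(inherits(slide, "til_slide"))
  if (slide$stain_mode != "dual_purple_dab")
    stop("segment_dual requires a dual_purple_dab slide")
  cells <- segment_cd8(slide, regions = regions, config = config,
                       criteria = criteria, cd8_stain = "purple")
  od <- rgb_to_od(slide$rgb)
  sf <- unmix_stains(od, stain_profile("dual_purple_dab"))
  tissue <- detect_tissue(od)
  dab <- sf$fields$dab
  pos <- dab > pdl1$grade_od_cuts[1] & tissue
  # clean specks
  if (any(pos)) {
    cc <- label_components(pos)
    min_px <- pdl1$min_region_area_um2 / slide$um_per_px^2
    drop <- which(cc$sizes < min_px)
    if (length(drop)) pos[cc$labels %in% drop] <- FALSE
  }
  grade <- matrix(0L, nrow(dab), ncol(dab))
  grade[pos] <- findInterval(dab[pos], pdl1$grade_od_cuts)
  list(cells = cells,
       pdl1 = structure(list(positive_mask = pos, intensity_grade = grade,
                             grade_od_cuts = pdl1$grade_od_cuts),
                        class = "pdl1_regions"))
}

#' @export
print.pdl1_regions <- function(x, ...) {
  cat(sprintf("PD-L1 regions: %.1f%% of raster positive; grade share %s\n",
              100 * mean(x$positive_mask),
              paste(sprintf("g%d=%.1f%%", 1:3,
                            100 * vapply(1:3, function(g)
                              mean(x$intensity_grade == g), 0)),
                    collapse = " ")))
  invisible(x)
}

#' Count CD8+ TILs in PD-L1-positive vs -negative tumor
#'
#' Partitions the tumor region into (tumor intersect PD-L1+) and (tumor
#' minus PD-L1+) sub-areas and reports counts and densities for both.
#' Count conservation \code{n_pos + n_neg = n_tumor} holds exactly.
#'
#' @param cells cell table with \code{x_px}, \code{y_px} (e.g. from
#'   [segment_dual()]).
#' @param pdl1 a \code{pdl1_regions} object.
#' @param rs a [region_set()]; the \code{"tumor"} region defines the tumor
#'   area (exclusions subtracted).
#' @return data.frame with rows \code{pdl1_pos} / \code{pdl1_neg}:
#'   \code{count}, \code{area_mm2}, \code{density_per_mm2}.
#' @export
count_cd8_by_pdl1 <- function(cells, pdl1, rs) {
  tumor <- region_mask(rs, "tumor") & !region_mask(rs, "exclusions")
  pos_area <- tumor & pdl1$positive_mask
  neg_area <- tumor & !pdl1$positive_mask
  upp2 <- (rs$um_per_px / 1000)^2
  r <- round(cells$y_px) + 1L; c_ <- round(cells$x_px) + 1L
  inframe <- r >= 1L & r <= rs$frame[1] & c_ >= 1L & c_ <= rs$frame[2]
  idx <- cbind(pmin(pmax(r, 1L), rs$frame[1]), pmin(pmax(c_, 1L), rs$frame[2]))
  in_tumor <- tumor[idx] & inframe
  in_pos <- pos_area[idx] & inframe
  n_pos <- sum(in_pos); n_neg <- sum(in_tumor) - n_pos
  a_pos <- sum(pos_area) * upp2; a_neg <- sum(neg_area) * upp2
  if ((a_pos == 0 && n_pos > 0) || (a_neg == 0 && n_neg > 0))
    stop("inconsistent inputs: cells fall in a zero-area sub-region")
  data.frame(
    region = c("pdl1_pos", "pdl1_neg"),
    count = c(n_pos, n_neg),
    area_mm2 = c(a_pos, a_neg),
    density_per_mm2 = c(if (a_pos > 0) n_pos / a_pos else NA_real_,
                        if (a_neg > 0) n_neg / a_neg else NA_real_))
}

#' Mono-vs-dual stain comparability
#'
#' Compares per-sample CD8+ TIL counts obtained from the single (DAB) and
#' dual (purple) stains of the same specimens using the concordance
#' statistics (CCC with bootstrap lower bound, Pearson, Spearman).
#'
#' @param mono_counts,dual_counts paired per-sample counts (n >= 3).
#' @param iterations,seed bootstrap settings.
#' @return object of class \code{concordance_result} (no cell-level F1:
#'   comparison is per-sample).
#' @export
mono_dual_comparability <- function(mono_counts, dual_counts,
                                    iterations = 10000L, seed = 1L) {
  if (length(mono_counts) != length(dual_counts)) stop("length mismatch")
  if (length(mono_counts) < 3L) stop("need >= 3 paired samples")
  lower <- bootstrap_lower_ci(mono_counts, dual_counts,
                              iterations = iterations, seed = seed)
  structure(list(ccc = lin_ccc(mono_counts, dual_counts),
                 ccc_lower = lower,
                 pcc = pearson_cc(mono_counts, dual_counts),
                 scc = spearman_cc(mono_counts, dual_counts),
                 category = mcbride_category(lower),
                 f1 = NA_real_, tp = NA, fp = NA, fn = NA,
                 n_fields = length(mono_counts),
                 per_field = data.frame(mono = mono_counts,
                                        dual = dual_counts),
                 bootstrap = list(iterations = iterations, seed = seed,
                                  level = 0.95)),
            class = "concordance_result")
}
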