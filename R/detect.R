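# Three-stage CD8+ lymphocyte detection:
#   stage 1 "isolated"      clearly labeled non-clustered cells
#   stage 2 "difficult"     weaker / partial cells, anchored at nuclei
#   stage 3 "cluster_split" dense clusters resolved by nucleus-seeded
#                           propagation on the distance transform
# followed by rule-based rejection of false-positive candidates.

#' Detection configuration
#'
#' Numeric thresholds of the rule-based CD8 detector.  The published
#' description of the scoring scheme names the filter families (size,
#' ellipticity, compactness, membrane completeness, nucleus association,
#' adaptive stain thresholds) but no numbers; these defaults are
#' biologically plausible surrogates, and every one is overridable.
#'
#' @param cell_area_um2 accepted cell footprint area range (default 20-250;
#'   lymphocyte diameters of roughly 5-15 um, with headroom for stretched
#'   elongate cells).
#' @param cell_diameter_um nominal cell diameter used for the stage-1
#'   isolation test (default 9).
#' @param nucleus_area_um2 accepted nucleus area range.
#' @param nucleus_od_threshold hematoxylin OD threshold for nuclei.
#' @param nucleus_assoc_dist_um maximum centroid-to-footprint distance for
#'   nucleus association (default 4, about one nucleus radius plus the
#'   membrane offset).
#' @param min_membrane_completeness acceptance floor for nucleus-free
#'   candidates (default 0.33).
#' @param min_compactness hard lower bound excluding ragged stain smears.
#' @param strong_od_factor multiple of the local adaptive threshold a
#'   nucleus-free candidate must reach ("strong" staining; default 1.5).
#' @param stage2_factor threshold relaxation for the stage-2 rescan
#'   (default 0.6 x adaptive threshold).
#' @param od_floor,k_sd,window_px forwarded to [adaptive_threshold()].
#' @return object of class \code{detection_config}.
#' @export
detection_config <- function(cell_area_um2 = c(20, 250),
                             cell_diameter_um = 9,
                             nucleus_area_um2 = c(4, 120),
                             nucleus_od_threshold = 0.3,
                             nucleus_assoc_dist_um = 4,
                             min_membrane_completeness = 0.33,
                             min_compactness = 0.15,
                             strong_od_factor = 1.5,
                             stage2_factor = 0.6,
                             od_floor = 0.15, k_sd = 3, window_px = 256L) {
  if (cell_area_um2[1] >= cell_area_um2[2] ||
      nucleus_area_um2[1] >= nucleus_area_um2[2])
    stop("area ranges must satisfy min < max")
  structure(list(cell_area_um2 = cell_area_um2,
                 cell_diameter_um = cell_diameter_um,
                 nucleus_area_um2 = nucleus_area_um2,
                 nucleus_od_threshold = nucleus_od_threshold,
                 nucleus_assoc_dist_um = nucleus_assoc_dist_um,
                 min_membrane_completeness = min_membrane_completeness,
                 min_compactness = min_compactness,
                 strong_od_factor = strong_od_factor,
                 stage2_factor = stage2_factor,
                 od_floor = od_floor, k_sd = k_sd,
                 window_px = as.integer(window_px)),
            class = "detection_config")
}

#' Detect hematoxylin-stained nuclei
#'
#' Thresholds the hematoxylin field, splits touching nuclei by watershed on
#' the distance transform, and size-filters the resulting labels.
#'
#' @param hema_field unmixed hematoxylin OD matrix.
#' @param tissue_mask logical tissue mask.
#' @param config a [detection_config()].
#' @param um_per_px microns per pixel.
#' @return list with \code{labels} (integer label matrix) and
#'   \code{centroids} (data.frame \code{id}, \code{x_px}, \code{y_px},
#'   \code{area_um2}).
#' @export
detect_nuclei <- function(hema_field, tissue_mask, config = detection_config(),
                          um_per_px = 0.5) {
  m <- (hema_field > config$nucleus_od_threshold) & tissue_mask
  empty <- list(labels = matrix(0L, nrow(hema_field), ncol(hema_field)),
                centroids = data.frame(id = integer(0), x_px = numeric(0),
                                       y_px = numeric(0), area_um2 = numeric(0)))
  if (!any(m)) return(empty)
  dm <- EBImage::distmap(as_ebi(m * 1))
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  L <- from_ebi(lab)
  px_per_um2 <- 1 / um_per_px^2
  sz <- tabulate(L[L > 0L])
  ok <- which(sz >= config$nucleus_area_um2[1] * px_per_um2 &
              sz <= config$nucleus_area_um2[2] * px_per_um2)
  if (!length(ok)) return(empty)
  remap <- integer(max(L)); remap[ok] <- seq_along(ok)
  L2 <- matrix(0L, nrow(L), ncol(L))
  keep <- L > 0L
  L2[keep] <- remap[L[keep]]
  idx <- which(L2 > 0L)
  nr <- nrow(L2)
  ys <- (idx - 1L) %% nr; xs <- (idx - 1L) %/% nr
  cen <- data.frame(
    x_px = as.numeric(tapply(xs, L2[idx], mean)),
    y_px = as.numeric(tapply(ys, L2[idx], mean)),
    area_um2 = as.numeric(tabulate(L2[idx])) * um_per_px^2)
  cen <- cbind(id = seq_len(nrow(cen)), cen)
  list(labels = L2, centroids = cen)
}

# components of a logical mask, returned as list(label matrix, sizes)
label_components <- function(mask) {
  L <- from_ebi(EBImage::bwlabel(as_ebi(mask * 1)))
  storage.mode(L) <- "integer"
  list(labels = L, sizes = if (max(L) > 0L) tabulate(L[L > 0L]) else integer(0))
}

comp_centroids <- function(L, nmax) {
  idx <- which(L > 0L)
  nr <- nrow(L)
  ys <- (idx - 1L) %% nr; xs <- (idx - 1L) %/% nr
  g <- L[idx]
  cbind(x = as.numeric(tapply(xs, g, mean)),
        y = as.numeric(tapply(ys, g, mean)))
}

#' Stage 1: detect clearly labeled non-clustered cells
#'
#' Hole-filled connected components of the CD8-positive mask whose area
#' lies in the configured range, whose centroid is at least one cell
#' diameter from every other component's centroid and which hold at most
#' one detected nucleus become isolated candidates; multi-nucleus
#' components are deferred to cluster splitting, everything else to stage
#' 2.
#'
#' @param pos_mask logical CD8-positive mask (from [adaptive_threshold()]).
#' @param nuclei output of [detect_nuclei()].
#' @param config a [detection_config()].
#' @param um_per_px microns per pixel.
#' @return list with \code{candidates} (each has \code{pix}, linear pixel
#'   indices of the filled footprint, and \code{stage = "isolated"}) and
#'   \code{deferred} (multi-nucleus components for [resolve_clusters()]).
#' @export
detect_isolated_cells <- function(pos_mask, nuclei,
                                  config = detection_config(),
                                  um_per_px = 0.5) {
  out <- list(candidates = list(), deferred = list())
  filled <- from_ebi(EBImage::fillHull(as_ebi(pos_mask * 1))) > 0.5
  cc <- label_components(filled)
  if (!length(cc$sizes)) return(out)
  amin <- config$cell_area_um2[1] / um_per_px^2
  amax <- config$cell_area_um2[2] / um_per_px^2
  inr <- which(cc$sizes >= amin & cc$sizes <= amax)
  if (!length(inr)) return(out)
  cen <- comp_centroids(cc$labels, max(cc$labels))
  # isolation: nearest other-component centroid farther than one diameter
  d_px <- config$cell_diameter_um / um_per_px
  keep <- logical(length(inr))
  if (nrow(cen) == 1L) keep[] <- TRUE else {
    D <- as.matrix(dist(cen))
    diag(D) <- Inf
    nn <- apply(D[inr, , drop = FALSE], 1L, min)
    keep <- nn > d_px
  }
  ids <- inr[keep]
  if (!length(ids)) return(out)
  assoc_px <- config$nucleus_assoc_dist_um / um_per_px
  frame <- dim(pos_mask)
  pixlist <- split(which(cc$labels %in% ids), cc$labels[cc$labels %in% ids])
  for (p in pixlist) {
    nin <- nuclei_in_footprint(p, frame, nuclei$centroids, assoc_px)
    if (length(nin) > 1L)
      out$deferred[[length(out$deferred) + 1L]] <- list(pix = p, nuclei = nin)
    else
      out$candidates[[length(out$candidates) + 1L]] <-
        list(pix = p, stage = "isolated")
  }
  out
}

# nuclei associated with a pixel set: nucleus centroid inside the footprint
# or within assoc_px of any footprint pixel (checked on a cropped window)
nuclei_in_footprint <- function(pix, frame, nuc_cen, assoc_px) {
  nr <- frame[1]
  ys <- (pix - 1L) %% nr; xs <- (pix - 1L) %/% nr
  hit <- logical(nrow(nuc_cen))
  for (i in seq_len(nrow(nuc_cen))) {
    dx <- abs(nuc_cen$x_px[i] - xs); dy <- abs(nuc_cen$y_px[i] - ys)
    near <- dx <= assoc_px & dy <= assoc_px
    if (any(near) && min(dx[near]^2 + dy[near]^2) <= assoc_px^2) hit[i] <- TRUE
  }
  which(hit)
}

#' Stage 2: recover difficult (weak / partial) cells at nuclei
#'
#' Re-scans the slide at a relaxed threshold, removes the footprints
#' already accepted in stage 1, and keeps residual components that are
#' anchored by exactly one detected nucleus and fit the single-cell area
#' range.  Components without a nucleus are dropped (artifact suppression);
#' multi-nucleus or oversized components are left for [resolve_clusters()].
#'
#' @param residual_mask logical mask: relaxed positive mask minus accepted
#'   stage-1 footprints (hole-filled by the caller).
#' @param nuclei output of [detect_nuclei()].
#' @param config a [detection_config()].
#' @param um_per_px microns per pixel.
#' @return list with \code{candidates} (stage \code{"difficult"}) and
#'   \code{cluster_comps} (pixel sets deferred to stage 3).
#' @export
detect_difficult_cells <- function(residual_mask, nuclei,
                                   config = detection_config(),
                                   um_per_px = 0.5) {
  cc <- label_components(residual_mask)
  out <- list(candidates = list(), cluster_comps = list())
  if (!length(cc$sizes)) return(out)
  amin <- config$cell_area_um2[1] / um_per_px^2
  amax <- config$cell_area_um2[2] / um_per_px^2
  assoc_px <- config$nucleus_assoc_dist_um / um_per_px
  frame <- dim(residual_mask)
  ids <- which(cc$sizes >= pmax(4, amin * 0.25))  # ignore specks
  if (!length(ids)) return(out)
  allpix <- which(cc$labels > 0L)
  pixlist <- split(allpix, cc$labels[allpix])
  nucpix <- NULL
  for (id in ids) {
    pix <- pixlist[[as.character(id)]]
    nin <- nuclei_in_footprint(pix, frame, nuclei$centroids, assoc_px)
    if (length(nin) == 0L) next
    if (length(nin) == 1L && cc$sizes[id] <= amax) {
      # footprint = partial membrane signal united with its nucleus and
      # hole-filled: the visible extent of the cell body
      if (is.null(nucpix)) {
        nz <- which(nuclei$labels > 0L)
        nucpix <- split(nz, nuclei$labels[nz])
      }
      pixu <- fill_pix_union(c(pix, nucpix[[as.character(nin)]]), frame)
      out$candidates[[length(out$candidates) + 1L]] <-
        list(pix = pixu, stage = "difficult")
    } else {
      out$cluster_comps[[length(out$cluster_comps) + 1L]] <-
        list(pix = pix, nuclei = nin)
    }
  }
  out
}

# hole-fill the union of a pixel set, working on a cropped window
fill_pix_union <- function(pix, frame) {
  pix <- unique(pix)
  nr <- frame[1]
  ys <- (pix - 1L) %% nr; xs <- (pix - 1L) %/% nr
  r0 <- min(ys); c0 <- min(xs)
  sub <- matrix(FALSE, max(ys) - r0 + 1L, max(xs) - c0 + 1L)
  sub[cbind(ys - r0 + 1L, xs - c0 + 1L)] <- TRUE
  subf <- from_ebi(EBImage::fillHull(as_ebi(sub * 1))) > 0.5
  w <- which(subf)
  fy <- (w - 1L) %% nrow(subf) + r0
  fx <- (w - 1L) %/% nrow(subf) + c0
  fx * nr + fy + 1L
}

#' Stage 3: resolve dense CD8+ clusters
#'
#' Each deferred component is split by seeded propagation (seeds = detected
#' nuclei, propagation cost from the component's Euclidean distance
#' transform, i.e. a nucleus-seeded watershed); every fragment that
#' contains its seed nucleus becomes a candidate.
#'
#' @param cluster_comps deferred components from
#'   [detect_difficult_cells()].
#' @param nuclei output of [detect_nuclei()].
#' @param frame raster dimensions (rows, cols).
#' @param config a [detection_config()].
#' @param um_per_px microns per pixel.
#' @return list of candidates with \code{stage = "cluster_split"}.
#' @export
resolve_clusters <- function(cluster_comps, nuclei, frame,
                             config = detection_config(), um_per_px = 0.5) {
  cands <- list()
  nr <- frame[1]
  amin_frag <- 0.5 * config$cell_area_um2[1] / um_per_px^2
  for (comp in cluster_comps) {
    pix <- comp$pix
    ys <- (pix - 1L) %% nr; xs <- (pix - 1L) %/% nr
    r0 <- min(ys); r1 <- max(ys); c0 <- min(xs); c1 <- max(xs)
    pad <- 2L
    rr <- max(0L, r0 - pad):min(frame[1] - 1L, r1 + pad)
    cc_ <- max(0L, c0 - pad):min(frame[2] - 1L, c1 + pad)
    sub <- matrix(FALSE, length(rr), length(cc_))
    sub[cbind(ys - rr[1] + 1L, xs - cc_[1] + 1L)] <- TRUE
    nin <- comp$nuclei
    if (length(nin) == 0L) next
    seeds <- matrix(0L, length(rr), length(cc_))
    for (k in seq_along(nin)) {
      i <- nin[k]
      sr <- round(nuclei$centroids$y_px[i]) - rr[1] + 1L
      sc <- round(nuclei$centroids$x_px[i]) - cc_[1] + 1L
      sr <- min(max(sr, 1L), nrow(seeds)); sc <- min(max(sc, 1L), ncol(seeds))
      seeds[sr, sc] <- k
    }
    if (length(nin) == 1L) {
      frag <- list(which(sub))
    } else {
      dmap <- EBImage::distmap(as_ebi(sub * 1))
      prop <- EBImage::propagate(x = max(dmap) - dmap, seeds = as_ebi(seeds),
                                 mask = as_ebi(sub * 1))
      P <- from_ebi(prop)
      frag <- split(which(P > 0), P[P > 0])
    }
    for (f in frag) {
      if (length(f) < amin_frag) next
      fy <- (f - 1L) %% length(rr) + rr[1]
      fx <- (f - 1L) %/% length(rr) + cc_[1]
      cands[[length(cands) + 1L]] <-
        list(pix = fx * frame[1] + fy + 1L, stage = "cluster_split")
    }
  }
  cands
}

# compute the per-candidate feature table
candidate_features <- function(cands, frame, cd8_field, thr_mat, nuclei,
                               config, um_per_px) {
  n <- length(cands)
  if (n == 0L)
    return(empty_cell_table())
  nr <- frame[1]
  assoc_px <- config$nucleus_assoc_dist_um / um_per_px
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pix <- cands[[i]]$pix
    ys <- (pix - 1L) %% nr; xs <- (pix - 1L) %/% nr
    r0 <- min(ys); r1 <- max(ys); c0 <- min(xs); c1 <- max(xs)
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(ys - r0 + 1L, xs - c0 + 1L)] <- TRUE
    obb <- if (length(pix) >= 3L)
      oriented_bounding_box(cbind(xs, ys), um_per_px)
    else list(length_um = um_per_px, width_um = um_per_px, orientation_rad = 0)
    ell <- if (length(pix) >= 3L) ellipticity(cbind(xs, ys)) else 1
    subfield <- cd8_field[(r0:r1) + 1L, (c0:c1) + 1L, drop = FALSE]
    subthr <- thr_mat[(r0:r1) + 1L, (c0:c1) + 1L, drop = FALSE]
    mc <- membrane_completeness(sub, subfield, subthr)
    nin <- nuclei_in_footprint(pix, frame, nuclei$centroids, assoc_px)
    rows[[i]] <- data.frame(
      x_px = mean(xs), y_px = mean(ys),
      area_um2 = length(pix) * um_per_px^2,
      obb_length_um = obb$length_um, obb_width_um = obb$width_um,
      orientation_rad = obb$orientation_rad,
      ellipticity = ell, compactness = compactness(sub),
      membrane_completeness = mc,
      mean_cd8_od = mean(cd8_field[pix]),
      mean_threshold = mean(thr_mat[pix]),
      has_nucleus = length(nin) > 0L,
      stage = cands[[i]]$stage)
  }
  df <- do.call(rbind, rows)
  df <- cbind(id = seq_len(n), df)
  df$x_um <- df$x_px * um_per_px
  df$y_um <- df$y_px * um_per_px
  df
}

empty_cell_table <- function() {
  data.frame(id = integer(0), x_px = numeric(0), y_px = numeric(0),
             area_um2 = numeric(0), obb_length_um = numeric(0),
             obb_width_um = numeric(0), orientation_rad = numeric(0),
             ellipticity = numeric(0), compactness = numeric(0),
             membrane_completeness = numeric(0), mean_cd8_od = numeric(0),
             mean_threshold = numeric(0), has_nucleus = logical(0),
             stage = character(0), x_um = numeric(0), y_um = numeric(0))
}

#' Rule-based acceptance filtering of candidate cells
#'
#' A candidate is accepted iff its footprint area is in range, its
#' compactness clears the floor, and it either has an associated nucleus or
#' is strongly stained (mean CD8 OD at least \code{strong_od_factor} times
#' the local adaptive threshold) with sufficiently complete membrane
#' labeling.  Weakly stained or partial candidates without a nucleus are
#' always discarded.  Every rejection is logged with the rule that fired.
#'
#' @param feats candidate feature table from the detection stages.
#' @param config a [detection_config()].
#' @return list with \code{accepted} (feature table, \code{cd8_positive =
#'   TRUE}) and \code{rejections} (data.frame \code{id}, \code{rule}).
#' @export
filter_candidates <- function(feats, config = detection_config()) {
  n <- nrow(feats)
  rule <- rep(NA_character_, n)
  small <- feats$area_um2 < config$cell_area_um2[1]
  big <- feats$area_um2 > config$cell_area_um2[2]
  rule[small | big] <- "size"
  ragged <- is.na(rule) & feats$compactness < config$min_compactness
  rule[ragged] <- "compactness"
  strong <- feats$mean_cd8_od >= config$strong_od_factor * feats$mean_threshold
  ok_membrane <- strong &
    feats$membrane_completeness >= config$min_membrane_completeness
  weak <- is.na(rule) & !feats$has_nucleus & !ok_membrane
  rule[weak] <- "weak_no_nucleus"
  acc <- feats[is.na(rule), , drop = FALSE]
  if (nrow(acc)) acc$cd8_positive <- TRUE else acc$cd8_positive <- logical(0)
  list(accepted = acc,
       rejections = data.frame(id = feats$id[!is.na(rule)],
                               rule = rule[!is.na(rule)]))
}

#' Segment CD8+ cells in a slide (full pipeline)
#'
#' Runs stain unmixing, tissue detection, nucleus detection, the three
#' detection stages, acceptance filtering, feature computation, elongate
#' classification and (optionally) region assignment.  Fully deterministic
#' for fixed inputs.
#'
#' @param slide a [til_slide()].
#' @param regions optional [region_set()] with built TC/IM masks; when
#'   supplied, cells get region labels.
#' @param config a [detection_config()].
#' @param criteria an [elongate_criteria()].
#' @param cd8_stain name of the CD8 chromogen channel; defaults to
#'   \code{"dab"} for mono slides and \code{"purple"} for dual.
#' @return object of class \code{til_cells}: the accepted-cell data.frame
#'   with attributes \code{footprints} (list of pixel-index vectors),
#'   \code{rejections}, \code{stage_counts}, \code{um_per_px},
#'   \code{frame}, \code{threshold} (mean applied threshold).
#' @export
segment_cd8 <- function(slide, regions = NULL, config = detection_config(),
                        criteria = elongate_criteria(), cd8_stain = NULL) {
  stopifnot(inherits(slide, "til_slide"))
  upp <- slide$um_per_px
  profile <- stain_profile(slide$stain_mode)
  od <- rgb_to_od(slide$rgb)
  sf <- unmix_stains(od, profile)
  tissue <- detect_tissue(od)
  if (is.null(cd8_stain))
    cd8_stain <- if (slide$stain_mode == "mono_dab") "dab" else "purple"
  cd8 <- sf$fields[[cd8_stain]]
  frame <- dim(cd8)

  finish_empty <- function() {
    cells <- empty_cell_table()
    cells$cd8_positive <- logical(0); cells$elongate <- logical(0)
    structure(cells, footprints = list(),
              rejections = data.frame(id = integer(0), rule = character(0)),
              stage_counts = c(isolated = 0L, difficult = 0L,
                               cluster_split = 0L),
              um_per_px = upp, frame = frame, class = c("til_cells",
                                                        "data.frame"))
  }
  if (!any(tissue)) return(finish_empty())

  at <- adaptive_threshold(cd8, tissue, floor = config$od_floor,
                           k = config$k_sd, window_px = config$window_px)
  nuclei <- detect_nuclei(sf$fields$hematoxylin, tissue, config, upp)

  st1 <- detect_isolated_cells(at$mask, nuclei, config, upp)
  stage1 <- st1$candidates

  # relaxed rescan for stages 2-3
  pos2 <- (cd8 > pmax(config$stage2_factor * at$threshold,
                      config$od_floor * config$stage2_factor)) & tissue
  filled2 <- from_ebi(EBImage::fillHull(as_ebi(pos2 * 1))) > 0.5
  if (length(stage1)) filled2[unlist(lapply(stage1, `[[`, "pix"))] <- FALSE
  if (length(st1$deferred))
    filled2[unlist(lapply(st1$deferred, `[[`, "pix"))] <- FALSE
  st2 <- detect_difficult_cells(filled2, nuclei, config, upp)
  st3 <- resolve_clusters(c(st1$deferred, st2$cluster_comps), nuclei, frame,
                          config, upp)

  cands <- c(stage1, st2$candidates, st3)
  feats <- candidate_features(cands, frame, cd8, at$threshold, nuclei,
                              config, upp)
  fl <- filter_candidates(feats, config)
  cells <- fl$accepted
  keep_idx <- cells$id
  if (nrow(cells)) {
    cells <- classify_elongate(cells, criteria)
  } else cells$elongate <- logical(0)
  if (!is.null(regions)) cells <- assign_cells_to_regions(cells, regions)
  rownames(cells) <- NULL
  stages <- vapply(cands, `[[`, "", "stage")
  structure(cells,
            footprints = lapply(cands[keep_idx], `[[`, "pix"),
            rejections = fl$rejections,
            stage_counts = c(isolated = sum(stages[keep_idx] == "isolated"),
                             difficult = sum(stages[keep_idx] == "difficult"),
                             cluster_split = sum(stages[keep_idx] ==
                                                   "cluster_split")),
            um_per_px = upp, frame = frame,
            class = c("til_cells", "data.frame"))
}

#' @export
print.til_cells <- function(x, ...) {
  sc <- attr(x, "stage_counts")
  cat(sprintf("CD8+ cells: %d accepted (isolated %d, difficult %d, cluster %d), %d rejected\n",
              nrow(x), sc["isolated"], sc["difficult"], sc["cluster_split"],
              nrow(attr(x, "rejections"))))
  if (nrow(x)) {
    cat(sprintf("  elongate: %d (%.1f%%)\n", sum(x$elongate),
                100 * mean(x$elongate)))
    if ("region" %in% names(x)) print(table(x$region))
  }
  invisible(x)
}
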