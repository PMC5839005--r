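# Concordance statistics and the scoring-validation framework.

#' F1 score from pooled matching counts
#'
#' \code{2 TP / (2 TP + FP + FN)}; inputs may be vectors of per-field
#' counts, which are summed (pooled) before the ratio is taken -- pooling,
#' not averaging, is the contract.
#'
#' @param tp,fp,fn non-negative counts (scalars or vectors).
#' @return numeric; \code{NA} when all pooled counts are zero.
#' @export
f1_score <- function(tp, fp, fn) {
  tp <- sum(tp); fp <- sum(fp); fn <- sum(fn)
  if (tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Lin concordance correlation coefficient
#'
#' \code{2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)} with population
#' (1/n) moments.  Unlike Pearson correlation, the CCC penalizes systematic
#' location or scale shifts, so it is the primary agreement measure for
#' method-vs-pathologist comparison.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return numeric in \code{[-1, 1]}; \code{NA} when the denominator is
#'   zero (both vectors constant with equal means).
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 2L || anyNA(x) || anyNA(y)) return(NA_real_)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- sx2 + sy2 + (mx - my)^2
  if (den == 0) return(NA_real_)
  2 * sxy / den
}

#' Pearson and Spearman correlation
#'
#' Thin wrappers around [stats::cor()] that return \code{NA} (reported
#' missing) instead of warning when a vector is constant.  Spearman uses
#' mid-ranks for ties.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return numeric in \code{[-1, 1]} or \code{NA}.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' @rdname pearson_cc
#' @export
spearman_cc <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' One-sided bootstrap lower confidence bound
#'
#' Nonparametric bootstrap over paired observations (the fields of view of
#' a validation run): pairs are resampled with replacement, the statistic
#' recomputed per iterate, and the \code{(1 - level)} percentile of the
#' bootstrap distribution returned as the one-sided lower bound.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @param statistic function of (x, y); default [lin_ccc()] (vectorized
#'   internally for speed).
#' @param iterations bootstrap iterations (default 10000).
#' @param level one-sided confidence level (default 0.95).
#' @param seed RNG seed; fixed seed gives identical bounds.
#' @return the lower bound (numeric scalar).
#' @export
bootstrap_lower_ci <- function(x, y, statistic = lin_ccc,
                               iterations = 10000L, level = 0.95,
                               seed = 1L) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need >= 3 complete pairs")
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * iterations, replace = TRUE), iterations, n)
    if (identical(statistic, lin_ccc)) {
      X <- matrix(x[idx], iterations, n); Y <- matrix(y[idx], iterations, n)
      mx <- rowMeans(X); my <- rowMeans(Y)
      sx2 <- rowMeans(X^2) - mx^2; sy2 <- rowMeans(Y^2) - my^2
      sxy <- rowMeans(X * Y) - mx * my
      den <- sx2 + sy2 + (mx - my)^2
      stats <- ifelse(den == 0, NA_real_, 2 * sxy / den)
    } else {
      stats <- vapply(seq_len(iterations),
                      function(b) statistic(x[idx[b, ]], y[idx[b, ]]),
                      numeric(1))
    }
    if (mean(is.na(stats)) > 0.5)
      stop("statistic undefined in more than half of the bootstrap iterates")
    unname(quantile(stats, probs = 1 - level, na.rm = TRUE))
  })
}

#' McBride strength-of-agreement category
#'
#' Categorizes a lower one-sided 95\% confidence bound of the CCC:
#' \code{>= 0.90} almost perfect, \code{>= 0.80} substantial,
#' \code{>= 0.65} moderate, below that poor.
#'
#' @param ccc_lower numeric in \code{[-1, 1]}.
#' @return factor level among \code{almost_perfect}, \code{substantial},
#'   \code{moderate}, \code{poor}.
#' @export
mcbride_category <- function(ccc_lower) {
  if (is.na(ccc_lower)) return(NA_character_)
  if (ccc_lower < -1 || ccc_lower > 1) stop("ccc_lower must be in [-1, 1]")
  if (ccc_lower >= 0.9) "almost_perfect"
  else if (ccc_lower >= 0.8) "substantial"
  else if (ccc_lower >= 0.65) "moderate"
  else "poor"
}

#' Select validation fields of view
#'
#' Places non-overlapping circular high-magnification fields across slides
#' (round-robin, so with \code{n_fields >= } number of slides every slide
#' receives at least one field).  When per-slide cell positions are
#' supplied the candidate fields are spread over low/medium/high local
#' density terciles.
#'
#' @param slides list of [til_slide()] objects, or a data.frame with
#'   columns \code{slide}, \code{width_um}, \code{height_um}.
#' @param n_fields number of fields (>= 1; the validation design calls for
#'   at least 13 over at least nine slides).
#' @param diameter_um field diameter, 250 or 500.
#' @param seed RNG seed.
#' @param points optional list (parallel to \code{slides}) of cell
#'   coordinate matrices in microns, used for density stratification.
#' @param margin_um keep-out border inside each slide.
#' @return data.frame \code{slide}, \code{cx_um}, \code{cy_um},
#'   \code{diameter_um}.
#' @export
select_fields <- function(slides, n_fields = 13L, diameter_um = c(250, 500),
                          seed = 1L, points = NULL, margin_um = 20) {
  diameter_um <- diameter_um[1]
  if (!diameter_um %in% c(250, 500)) stop("diameter must be 250 or 500 um")
  if (!is.numeric(n_fields) || n_fields < 1) stop("n_fields must be >= 1")
  n_fields <- as.integer(n_fields)
  if (is.data.frame(slides)) {
    geom <- slides
  } else {
    geom <- data.frame(
      slide = vapply(slides, function(s) s$id, ""),
      width_um = vapply(slides, function(s) dim(s$rgb)[2] * s$um_per_px, 0),
      height_um = vapply(slides, function(s) dim(s$rgb)[1] * s$um_per_px, 0))
  }
  ns <- nrow(geom)
  r <- diameter_um / 2
  with_seed(seed, {
    out <- vector("list", n_fields)
    placed <- data.frame(slide = character(0), cx = numeric(0), cy = numeric(0))
    for (k in seq_len(n_fields)) {
      # round-robin over slides, falling through to the next slide when one
      # cannot hold another non-overlapping field
      cx <- cy <- numeric(0); si <- NA_integer_
      for (try_s in seq_len(ns)) {
        si <- ((k - 1L + try_s - 1L) %% ns) + 1L
        lo_x <- margin_um + r; hi_x <- geom$width_um[si] - margin_um - r
        lo_y <- margin_um + r; hi_y <- geom$height_um[si] - margin_um - r
        if (hi_x <= lo_x || hi_y <= lo_y) next
        ncand <- 80L
        cx0 <- runif(ncand, lo_x, hi_x); cy0 <- runif(ncand, lo_y, hi_y)
        prev <- placed[placed$slide == geom$slide[si], , drop = FALSE]
        ok <- rep(TRUE, ncand)
        if (nrow(prev))
          for (q in seq_len(nrow(prev)))
            ok <- ok & (sqrt((cx0 - prev$cx[q])^2 + (cy0 - prev$cy[q])^2) >=
                          diameter_um)
        if (any(ok)) { cx <- cx0[ok]; cy <- cy0[ok]; break }
      }
      if (!length(cx))
        stop("could not place non-overlapping fields on any slide")
      pick <- 1L
      if (!is.null(points) && nrow(as_points(points[[si]])) > 0L) {
        pts <- as_points(points[[si]])
        cnt <- vapply(seq_along(cx), function(q)
          sum((pts[, 1] - cx[q])^2 + (pts[, 2] - cy[q])^2 <= r^2), 0L)
        ter <- (k %% 3L) + 1L   # rotate low/mid/high tercile
        ordq <- order(cnt)
        third <- ceiling(length(ordq) / 3)
        grp <- ordq[((ter - 1L) * third + 1L):min(ter * third, length(ordq))]
        pick <- grp[1L]
      }
      out[[k]] <- data.frame(slide = geom$slide[si], cx_um = cx[pick],
                             cy_um = cy[pick], diameter_um = diameter_um)
      placed <- rbind(placed, data.frame(slide = geom$slide[si],
                                         cx = cx[pick], cy = cy[pick]))
    }
    do.call(rbind, out)
  })
}

points_in_field <- function(pts, field) {
  pts <- as_points(pts)
  if (!nrow(pts)) return(pts)
  d2 <- (pts[, 1] - field$cx_um)^2 + (pts[, 2] - field$cy_um)^2
  pts[d2 <= (field$diameter_um / 2)^2, , drop = FALSE]
}

#' Plausibility check of a results table
#'
#' Screens an image-analysis results table for violations: negative or
#' non-integer counts, negative areas or densities, density inconsistent
#' with count/area (relative tolerance 1e-6), missing values, and
#' duplicate (sample, region) keys.  An empty report means the table
#' passes.
#'
#' @param tbl data.frame with columns \code{sample}, \code{region},
#'   \code{count}, \code{area_mm2} (or \code{area}), \code{density_per_mm2}
#'   (or \code{density}).
#' @return data.frame \code{rule}, \code{row} (0-row when clean).
#' @export
plausibility_check <- function(tbl) {
  if (!is.data.frame(tbl)) stop("malformed table: not a data.frame")
  nm <- names(tbl)
  area_col <- intersect(c("area_mm2", "area"), nm)[1]
  dens_col <- intersect(c("density_per_mm2", "density"), nm)[1]
  if (!all(c("sample", "region", "count") %in% nm) ||
      is.na(area_col) || is.na(dens_col))
    stop("malformed table: need sample, region, count, area, density columns")
  v <- list()
  flag <- function(rule, rows)
    if (length(rows)) v[[length(v) + 1L]] <<- data.frame(rule = rule, row = rows)
  cnt <- tbl$count; ar <- tbl[[area_col]]; de <- tbl[[dens_col]]
  flag("missing_value",
       which(is.na(tbl$sample) | is.na(tbl$region) | is.na(cnt) |
               is.na(ar) | is.na(de)))
  flag("negative_count", which(!is.na(cnt) & cnt < 0))
  flag("noninteger_count",
       which(!is.na(cnt) & cnt >= 0 & abs(cnt - round(cnt)) > 1e-9))
  flag("negative_area", which(!is.na(ar) & ar < 0))
  flag("negative_density", which(!is.na(de) & de < 0))
  ok <- !is.na(cnt) & !is.na(ar) & !is.na(de) & ar > 0
  mismatch <- which(ok & abs(de - cnt / ar) > 1e-6 * pmax(1, abs(cnt / ar)))
  flag("density_mismatch", mismatch)
  key <- paste(tbl$sample, tbl$region, sep = "\r")
  flag("duplicate_key", which(duplicated(key)))
  if (!length(v)) data.frame(rule = character(0), row = integer(0))
  else do.call(rbind, v)
}

#' Validation run: concordance of detected vs annotated cells
#'
#' For each field of view, counts detected and annotated cells, matches
#' them cell-by-cell (pooled TP/FP/FN and F1), and computes CCC, Pearson
#' and Spearman correlations of the per-field counts, the bootstrap
#' one-sided 95\% lower confidence bound of the CCC, and the McBride
#' agreement category.  With several annotators, each is compared
#' individually and against the consolidated per-field median count.
#'
#' @param detected list (per slide) of detected cell positions in microns
#'   ([til_cells()] tables or 2-column matrices), named by slide id.
#' @param annotated same structure for one annotator, or an unnamed list of
#'   such structures for several annotators.
#' @param fields data.frame from [select_fields()].
#' @param match_radius_um gating radius for cell matching (default 7.5).
#' @param iterations,seed,level bootstrap settings (see
#'   [bootstrap_lower_ci()]).
#' @return object of class \code{concordance_result}; fields \code{ccc},
#'   \code{ccc_lower}, \code{pcc}, \code{scc}, \code{f1}, \code{category},
#'   \code{tp}, \code{fp}, \code{fn}, \code{n_fields}, \code{per_field}
#'   (data.frame), \code{per_annotator} (list, multi-annotator case).
#' @export
validate_run <- function(detected, annotated, fields,
                         match_radius_um = 7.5, iterations = 10000L,
                         seed = 1L, level = 0.95) {
  multi <- is.list(annotated) && !is.data.frame(annotated) &&
    length(annotated) > 0L && is.null(names(annotated)) &&
    (is.list(annotated[[1]]) && !is.data.frame(annotated[[1]]) &&
       !is.matrix(annotated[[1]]))
  annotators <- if (multi) annotated else list(annotated)
  nf <- nrow(fields)
  if (is.null(nf) || nf == 0L) stop("no fields supplied")
  if (nf < 13L)
    warning("fewer than 13 fields: below the recommended validation design")
  det_counts <- integer(nf)
  ann_counts <- matrix(0L, nf, length(annotators))
  tp <- fp <- fn <- integer(nf)
  for (k in seq_len(nf)) {
    fld <- fields[k, ]
    dpts <- points_in_field(detected[[fld$slide]], fld)
    det_counts[k] <- nrow(dpts)
    for (a in seq_along(annotators)) {
      apts <- points_in_field(annotators[[a]][[fld$slide]], fld)
      ann_counts[k, a] <- nrow(apts)
      if (a == 1L) {
        mr <- match_cells(dpts, apts, match_radius_um)
        tp[k] <- mr$tp; fp[k] <- mr$fp; fn[k] <- mr$fn
      }
    }
  }
  consolidated <- apply(ann_counts, 1L, median)
  build <- function(y) {
    ccc <- lin_ccc(det_counts, y)
    lower <- bootstrap_lower_ci(det_counts, y, iterations = iterations,
                                seed = seed, level = level)
    list(ccc = ccc, ccc_lower = lower, pcc = pearson_cc(det_counts, y),
         scc = spearman_cc(det_counts, y),
         category = mcbride_category(lower))
  }
  main <- build(consolidated)
  per_annotator <- if (length(annotators) > 1L)
    lapply(seq_len(ncol(ann_counts)), function(a) build(ann_counts[, a]))
  else NULL
  structure(c(main, list(
    f1 = f1_score(tp, fp, fn), tp = sum(tp), fp = sum(fp), fn = sum(fn),
    n_fields = nf,
    per_field = data.frame(fields, detected = det_counts,
                           annotated = consolidated),
    per_annotator = per_annotator,
    bootstrap = list(iterations = iterations, seed = seed, level = level))),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance over %d fields: CCC=%.3f (lower %.3f, %s)\n",
              x$n_fields, x$ccc, x$ccc_lower, x$category))
  cat(sprintf("  PCC=%.3f SCC=%.3f | pooled TP=%d FP=%d FN=%d F1=%.3f\n",
              x$pcc, x$scc, x$tp, x$fp, x$fn, x$f1))
  invisible(x)
}
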