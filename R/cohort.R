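# Cohort-level density records and statistics.

#' Compute density records from labeled cells and region areas
#'
#' One record per region (TC, IM when present, and the tumor_area
#' aggregate = TC + IM with additive counts and areas).  Densities are
#' count/area in cells/mm2; regions with zero annotated area yield a
#' missing density, not zero.
#'
#' @param cells region-labeled cell table (see
#'   [assign_cells_to_regions()]); only CD8+ rows are counted.
#' @param rs a [region_set()] with built TC/IM masks.
#' @param sample_id,indication identifiers copied into the records.
#' @return data.frame \code{sample}, \code{indication}, \code{region},
#'   \code{count}, \code{area_mm2}, \code{density_per_mm2}, guaranteed to
#'   pass [plausibility_check()].
#' @export
compute_densities <- function(cells, rs, sample_id = "S1",
                              indication = NA_character_) {
  if (!"cd8_positive" %in% names(cells)) cells$cd8_positive <- TRUE
  cells <- cells[cells$cd8_positive, , drop = FALSE]
  a_tc <- region_area_mm2(rs, "tc")
  a_im <- region_area_mm2(rs, "im")
  n_tc <- sum(cells$region == "TC")
  n_im <- sum(cells$region == "IM")
  if (a_tc == 0 && n_tc > 0) stop("TC has zero area but nonzero count")
  if (a_im == 0 && n_im > 0) stop("IM has zero area but nonzero count")
  rows <- list(data.frame(region = "TC", count = n_tc, area_mm2 = a_tc))
  if (a_im > 0)
    rows <- c(rows, list(data.frame(region = "IM", count = n_im,
                                    area_mm2 = a_im)))
  rows <- c(rows, list(data.frame(region = "tumor_area",
                                  count = n_tc + n_im,
                                  area_mm2 = a_tc + a_im)))
  df <- do.call(rbind, rows)
  df$density_per_mm2 <- ifelse(df$area_mm2 > 0, df$count / df$area_mm2,
                               NA_real_)
  cbind(sample = sample_id, indication = indication, df)
}

#' Per-indication landscape summary
#'
#' Median, quartiles and per-sample listing of tumor-area densities by
#' indication.
#'
#' @param records density records (rows as from [compute_densities()]).
#' @param region region to summarize (default \code{"tumor_area"}).
#' @return list with \code{summary} (data.frame \code{indication},
#'   \code{n}, \code{q25}, \code{median}, \code{q75}) and
#'   \code{per_sample} (sorted records).
#' @export
landscape_summary <- function(records, region = "tumor_area") {
  rec <- records[records$region == region & !is.na(records$density_per_mm2), ,
                 drop = FALSE]
  if (nrow(rec) && "indication" %in% names(rec))
    rec$indication[is.na(rec$indication)] <- "unspecified"
  if (!nrow(rec)) {
    warning("no usable records")
    return(list(summary = data.frame(), per_sample = rec))
  }
  groups <- split(rec$density_per_mm2, rec$indication)
  groups <- groups[vapply(groups, length, 0L) > 0L]
  sm <- data.frame(
    indication = names(groups),
    n = vapply(groups, length, 0L),
    q25 = vapply(groups, function(g) unname(quantile(g, 0.25)), 0),
    median = vapply(groups, median, 0),
    q75 = vapply(groups, function(g) unname(quantile(g, 0.75)), 0))
  rownames(sm) <- NULL
  list(summary = sm[order(-sm$median), ],
       per_sample = rec[order(rec$indication, -rec$density_per_mm2), ])
}

# exact signed-rank distribution over doubled mid-ranks via
# generating-function convolution; returns P(T+ <= t) and P(T+ >= t)
signed_rank_exact_p <- function(ranks2, tplus2) {
  total <- sum(ranks2)
  gf <- numeric(total + 1L); gf[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), gf[seq_len(total + 1L - r)])
    gf <- gf + shifted
  }
  gf <- gf / sum(gf)
  t_idx <- round(tplus2)
  p_le <- sum(gf[seq_len(t_idx + 1L)])
  p_ge <- sum(gf[(t_idx + 1L):(total + 1L)])
  c(p_le = p_le, p_ge = p_ge)
}

#' Wilcoxon signed-rank test: TC vs IM densities
#'
#' Paired two-sided signed-rank test of per-sample TC and IM densities.
#' Zero differences are dropped (Wilcoxon's rule); ties receive mid-ranks.
#' For n <= 25 effective pairs the p-value is exact (tie-aware
#' distribution by convolution); above that a normal approximation with
#' tie correction is used.
#'
#' @param tc,im paired density vectors, or a records data.frame from
#'   [compute_densities()] (long format with \code{sample}, \code{region},
#'   \code{density_per_mm2}); samples lacking an IM record are excluded.
#' @param min_pairs minimum effective pairs required (default 5).
#' @return list \code{statistic} (T+ = sum of positive ranks), \code{p_value}
#'   (two-sided), \code{n_effective}, \code{method}.
#' @export
wilcoxon_tc_vs_im <- function(tc, im = NULL, min_pairs = 5L) {
  if (is.data.frame(tc)) {
    rec <- tc
    wtc <- rec[rec$region == "TC", c("sample", "density_per_mm2")]
    wim <- rec[rec$region == "IM", c("sample", "density_per_mm2")]
    mg <- merge(wtc, wim, by = "sample", suffixes = c("_tc", "_im"))
    tc <- mg$density_per_mm2_tc; im <- mg$density_per_mm2_im
  }
  keep <- complete.cases(tc, im)
  d <- (im - tc)[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n < min_pairs)
    stop(sprintf("need >= %d nonzero complete pairs (have %d)", min_pairs, n))
  r <- rank(abs(d))
  tplus <- sum(r[d > 0])
  if (n <= 25L) {
    pp <- signed_rank_exact_p(round(2 * r), 2 * tplus)
    p <- min(1, 2 * min(pp))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (tplus - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(statistic = tplus, p_value = p, n_effective = n, method = method)
}

#' Paired pre/post treatment density comparison
#'
#' Two-sided paired t test of on-treatment minus screening densities, with
#' the 95\% confidence interval of the mean difference.
#'
#' @param screening,on_treatment paired density vectors (n >= 3 complete
#'   pairs).
#' @return list \code{mean_difference}, \code{t}, \code{df},
#'   \code{p_value}, \code{conf_int} (length 2), \code{n}.  With zero
#'   variance of the differences the test degenerates: \code{p_value} is 1
#'   when the mean difference is 0 and \code{NA} otherwise, with a
#'   zero-width interval.
#' @export
paired_pre_post_test <- function(screening, on_treatment) {
  keep <- complete.cases(screening, on_treatment)
  x <- screening[keep]; y <- on_treatment[keep]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs")
  d <- y - x
  if (sd(d) == 0) {
    return(list(mean_difference = mean(d), t = NA_real_, df = n - 1,
                p_value = if (mean(d) == 0) 1 else NA_real_,
                conf_int = c(mean(d), mean(d)), n = n))
  }
  tt <- t.test(y, x, paired = TRUE)
  list(mean_difference = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value,
       conf_int = as.numeric(tt$conf.int), n = n)
}

#' Cohort report: figures and tables
#'
#' Writes the density records as CSV, a JSON file of the computed
#' statistics, and (optionally) base-graphics figures: per-indication
#' distribution summary, TC-vs-IM paired-line plot, and pre/post paired
#' plot.  Refuses records that fail [plausibility_check()].
#'
#' @param records density records.
#' @param out_dir output directory (created if needed).
#' @param paired_pre_post optional data.frame with
#'   \code{screening_density}, \code{on_treatment_density}.
#' @param figures write PDF figures (default TRUE).
#' @return (invisibly) list of written file paths.
#' @export
cohort_report <- function(records, out_dir, paired_pre_post = NULL,
                          figures = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stats <- list()
  if (nrow(records)) {
    viol <- plausibility_check(records)
    if (nrow(viol))
      stop("records fail plausibility check: ",
           paste(unique(viol$rule), collapse = ", "))
    ls_ <- landscape_summary(records)
    stats$landscape <- ls_$summary
    tcim <- try(wilcoxon_tc_vs_im(records), silent = TRUE)
    if (!inherits(tcim, "try-error")) stats$tc_vs_im <- tcim
    f <- file.path(out_dir, "density_records.csv")
    write.csv(records, f, row.names = FALSE)
    files <- c(files, f)
    if (figures) {
      f <- file.path(out_dir, "landscape.pdf")
      pdf(f, width = 7, height = 5)
      rec <- records[records$region == "tumor_area" &
                       !is.na(records$density_per_mm2), ]
      if (nrow(rec)) {
        rec$indication[is.na(rec$indication)] <- "unspecified"
        rec$indication <- factor(rec$indication)
        boxplot(density_per_mm2 ~ indication, data = rec,
                ylab = "CD8+ TILs / mm2 (tumor area)", las = 2,
                main = "CD8 landscape")
        points(jitter(as.integer(rec$indication)), rec$density_per_mm2,
               pch = 16, col = "#00000055")
      }
      dev.off(); files <- c(files, f)
      rec_tc <- records[records$region == "TC", ]
      rec_im <- records[records$region == "IM", ]
      mg <- merge(rec_tc, rec_im, by = "sample", suffixes = c(".tc", ".im"))
      if (nrow(mg)) {
        f <- file.path(out_dir, "tc_vs_im.pdf")
        pdf(f, width = 5, height = 5)
        plot(rep(1, nrow(mg)), mg$density_per_mm2.tc, xlim = c(0.5, 2.5),
             ylim = range(c(mg$density_per_mm2.tc, mg$density_per_mm2.im)),
             xaxt = "n", xlab = "", ylab = "CD8+ TILs / mm2",
             main = "TC vs IM", pch = 16)
        points(rep(2, nrow(mg)), mg$density_per_mm2.im, pch = 16)
        segments(1, mg$density_per_mm2.tc, 2, mg$density_per_mm2.im,
                 col = "#00000044")
        axis(1, at = 1:2, labels = c("TC", "IM"))
        dev.off(); files <- c(files, f)
      }
    }
  }
  if (!is.null(paired_pre_post) && nrow(paired_pre_post) >= 3) {
    pt <- paired_pre_post_test(paired_pre_post$screening_density,
                               paired_pre_post$on_treatment_density)
    stats$pre_post <- pt
    if (figures) {
      f <- file.path(out_dir, "pre_post.pdf")
      pdf(f, width = 5, height = 5)
      n <- nrow(paired_pre_post)
      plot(rep(1, n), paired_pre_post$screening_density, xlim = c(0.5, 2.5),
           ylim = range(c(paired_pre_post$screening_density,
                          paired_pre_post$on_treatment_density)),
           xaxt = "n", xlab = "", ylab = "CD8+ TILs / mm2 (tumor)",
           main = sprintf("screening vs on-treatment (p=%.3g)", pt$p_value),
           pch = 16)
      points(rep(2, n), paired_pre_post$on_treatment_density, pch = 16)
      segments(1, paired_pre_post$screening_density, 2,
               paired_pre_post$on_treatment_density, col = "#00000044")
      axis(1, at = 1:2, labels = c("screening", "on-treatment"))
      dev.off(); files <- c(files, f)
    }
  }
  f <- file.path(out_dir, "statistics.json")
  jsonlite::write_json(stats, f, auto_unbox = TRUE, digits = 10,
                       force = TRUE)
  files <- c(files, f)
  invisible(files)
}
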