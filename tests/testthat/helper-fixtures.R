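# Shared fixtures and independent oracles.  Expensive synthetic slides are
# generated lazily and cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# a small mono slide with all cell types present
small_mono <- function() fixture("small_mono", function() {
  generate_slide(synthetic_config(image_size_px = c(512, 512),
                                  target_density_per_mm2 = 800, seed = 7))
})

# its segmentation (computed once)
small_mono_cells <- function() fixture("small_mono_cells", function() {
  segment_cd8(small_mono()$slide)
})

small_dual <- function() fixture("small_dual", function() {
  generate_slide(synthetic_config(image_size_px = c(768, 768),
                                  target_density_per_mm2 = 400,
                                  stain_mode = "dual_purple_dab",
                                  pdl1_region_fraction = 0.3, seed = 31))
})

# ---- independent oracles -------------------------------------------------

# exhaustive-search minimum-cost maximum-cardinality matching (<= ~6 points)
brute_force_match <- function(det, ann, maxd) {
  nd <- nrow(det); na <- nrow(ann)
  if (nd == 0L || na == 0L) return(list(tp = 0L, cost = 0))
  D <- sqrt(outer(det[, 1], ann[, 1], "-")^2 +
            outer(det[, 2], ann[, 2], "-")^2)
  best_tp <- 0L; best_cost <- Inf
  used <- rep(FALSE, na)
  rec <- function(i, tp, cost) {
    if (i > nd) {
      if (tp > best_tp || (tp == best_tp && cost < best_cost)) {
        best_tp <<- tp; best_cost <<- cost
      }
      return(invisible())
    }
    rec(i + 1L, tp, cost)                      # leave i unmatched
    for (j in seq_len(na)) {
      if (!used[j] && D[i, j] <= maxd) {
        used[j] <<- TRUE
        rec(i + 1L, tp + 1L, cost + D[i, j])
        used[j] <<- FALSE
      }
    }
  }
  rec(1L, 0L, 0)
  list(tp = best_tp, cost = if (is.finite(best_cost)) best_cost else 0)
}

# exact two-sided signed-rank p by enumeration of all sign assignments
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  tobs <- sum(r[d > 0])
  tot <- 0L; le <- 0L; ge <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    tv <- sum(r[signs])
    tot <- tot + 1L
    if (tv <= tobs) le <- le + 1L
    if (tv >= tobs) ge <- ge + 1L
  }
  min(1, 2 * min(le / tot, ge / tot))
}

# rasterize a filled rotated ellipse into a logical matrix (truth-side
# shape construction, independent of the package's renderer)
raster_ellipse <- function(nr, nc, cx, cy, a, b, theta = 0) {
  xs <- rep(0:(nc - 1L), each = nr); ys <- rep(0:(nr - 1L), times = nc)
  dx <- xs - cx; dy <- ys - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  matrix((u / a)^2 + (v / b)^2 <= 1, nr, nc)
}

square_poly <- function(x0, y0, side) {
  cbind(x = c(x0, x0 + side - 1, x0 + side - 1, x0),
        y = c(y0, y0, y0 + side - 1, y0 + side - 1))
}
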