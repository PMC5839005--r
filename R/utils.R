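# Internal helpers shared across modules.
#
# Image convention: rasters are base-R matrices indexed [row, col] with the
# row axis pointing down.  Cell and polygon coordinates are (x, y) pairs in
# pixel units, 0-based, x along columns, y along rows (y-down), with integer
# coordinates at pixel centers.  EBImage stores images transposed (first
# index = x), so every call into EBImage goes through as_ebi()/from_ebi().

as_ebi <- function(m) EBImage::Image(t(m))

from_ebi <- function(img) t(EBImage::imageData(img))

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards.  All stochastic operations in the package go
# through this so that a seed argument fully determines the output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic child seed derivation, kept inside 32-bit signed range.
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + 9973 * as.numeric(k)) %% 2147483647L)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

check_fraction <- function(x, name) {
  stopifnot_scalar(x, name)
  if (x < 0 || x > 1)
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# 2D box-filter local mean via integral image; `half` is the half-width in
# pixels.  Edges use the shrunken window (same normalization).
box_mean <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  ii <- apply(apply(m, 2L, cumsum), 1L, cumsum)  # ii[c, r] after second apply
  ii <- t(ii)                                    # back to [row, col]
  ii <- rbind(0, cbind(0, ii))
  r1 <- pmax(seq_len(nr) - half, 1L); r2 <- pmin(seq_len(nr) + half, nr)
  c1 <- pmax(seq_len(nc) - half, 1L); c2 <- pmin(seq_len(nc) + half, nc)
  S <- ii[r2 + 1L, c2 + 1L, drop = FALSE] - ii[r1, c2 + 1L, drop = FALSE] -
       ii[r2 + 1L, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
  area <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  S / area
}

# Low-frequency multiplicative illumination field in [1-amp, 1+amp].
illumination_field <- function(nr, nc, amplitude) {
  if (amplitude <= 0) return(matrix(1, nr, nc))
  fx <- runif(1, 0.5, 1.5) * pi / nc
  fy <- runif(1, 0.5, 1.5) * pi / nr
  phx <- runif(1, 0, 2 * pi); phy <- runif(1, 0, 2 * pi)
  f <- outer(sin(fy * seq_len(nr) + phy), sin(fx * seq_len(nc) + phx))
  1 + amplitude * f / max(abs(f))
}
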