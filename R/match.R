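# Optimal bipartite matching of detected vs annotated cell positions.
#
# The assignment solver is a Jonker-Volgenant style Hungarian algorithm
# (potentials + shortest augmenting path, O(n^3)).  match_cells() first
# decomposes the distance-gated bipartite graph into connected components,
# which for realistic cell spacings are tiny, and solves each component
# with an unmatched-penalty construction that yields the minimum-cost
# maximum-cardinality matching.

# Hungarian algorithm, minimization; cost is n x m with n <= m.
# Returns integer vector a of length n: a[i] = column assigned to row i.
solve_lsap_min <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L); way <- integer(m + 1L)   # index 1 = virtual col 0
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m); used <- logical(m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)            # 1-based positions = cols + 1
      u[p[usedj] + 1L] <- u[p[usedj] + 1L] + delta
      v[usedj] <- v[usedj] - delta
      minv[which(!used[-1L])] <- minv[which(!used[-1L])] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  a <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) a[p[j + 1L]] <- j
  a
}

# connected components of the gated bipartite graph
bipartite_components <- function(edges, nd, na) {
  parent <- seq_len(nd + na)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1L]); b <- find(edges[k, 2L] + nd)
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(nd + na), find, 0L)
}

#' Match detected to annotated cell positions
#'
#' Minimum-cost one-to-one assignment between detected and annotated
#' points, restricted to pairs closer than \code{max_dist_um}; the
#' assignment maximizes the number of matched pairs and, among those,
#' minimizes the total distance.  Unmatched detected points are false
#' positives, unmatched annotated points false negatives.
#'
#' @param detected,annotated 2-column matrices (x, y) in microns (possibly
#'   0 rows).
#' @param max_dist_um gating radius (default 7.5, about one lymphocyte
#'   radius plus localization error).
#' @return object of class \code{match_result}: list with \code{tp},
#'   \code{fp}, \code{fn} and \code{pairs} (data.frame \code{detected},
#'   \code{annotated}, \code{dist_um}).
#' @export
match_cells <- function(detected, annotated, max_dist_um = 7.5) {
  detected <- as_points(detected); annotated <- as_points(annotated)
  nd <- nrow(detected); na <- nrow(annotated)
  pairs <- data.frame(detected = integer(0), annotated = integer(0),
                      dist_um = numeric(0))
  if (nd > 0L && na > 0L) {
    D <- sqrt(outer(detected[, 1], annotated[, 1], "-")^2 +
              outer(detected[, 2], annotated[, 2], "-")^2)
    edges <- which(D <= max_dist_um, arr.ind = TRUE)
    if (nrow(edges)) {
      comp <- bipartite_components(edges, nd, na)
      for (cid in unique(comp[unique(edges[, 1L])])) {
        rows <- which(comp[seq_len(nd)] == cid)
        cols <- which(comp[nd + seq_len(na)] == cid)
        k <- length(rows); l <- length(cols)
        if (k == 0L || l == 0L) next
        BIG <- 1e9; DUMMY <- max_dist_um + 1
        C <- matrix(BIG, k + l, k + l)
        sub <- D[rows, cols, drop = FALSE]
        sub[sub > max_dist_um] <- BIG
        C[seq_len(k), seq_len(l)] <- sub
        C[cbind(seq_len(k), l + seq_len(k))] <- DUMMY
        C[cbind(k + seq_len(l), seq_len(l))] <- DUMMY
        C[k + seq_len(l), l + seq_len(k)] <- 0
        a <- solve_lsap_min(C)
        for (ii in seq_len(k)) {
          j <- a[ii]
          if (j <= l && sub[ii, j] <= max_dist_um)
            pairs <- rbind(pairs, data.frame(
              detected = rows[ii], annotated = cols[j],
              dist_um = D[rows[ii], cols[j]]))
        }
      }
    }
  }
  structure(list(tp = nrow(pairs), fp = nd - nrow(pairs),
                 fn = na - nrow(pairs), pairs = pairs),
            class = "match_result")
}

as_points <- function(p) {
  if (is.null(p) || length(p) == 0L) return(matrix(numeric(0), 0L, 2L))
  if (is.data.frame(p)) {
    nm <- if (all(c("x_um", "y_um") %in% names(p))) c("x_um", "y_um")
          else c("x", "y")
    p <- as.matrix(p[, nm])
  }
  p <- as.matrix(p)
  stopifnot(ncol(p) == 2L)
  p
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("cell matching: TP=%d FP=%d FN=%d (F1=%.3f)\n",
              x$tp, x$fp, x$fn, f1_score(x$tp, x$fp, x$fn)))
  invisible(x)
}
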