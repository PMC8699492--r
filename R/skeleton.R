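# Medial-axis utilities: Guo-Hall thinning and geodesic path extraction on
# the resulting 1-px skeleton. These back both the rod length/width estimator
# and neurite tracing.

#' Skeletonize a binary silhouette
#'
#' Guo-Hall two-subiteration thinning to a (nearly) one-pixel-wide medial
#' representation. Topology-preserving (a connected silhouette yields a
#' connected skeleton) and, unlike Zhang-Suen, it does not progressively
#' erode the ends of diagonal one-pixel lines, so elongated shapes at
#' oblique orientations keep their full medial axis.
#'
#' @param mask logical matrix (TRUE = foreground).
#' @return Logical matrix of the same size containing the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  repeat {
    changed <- FALSE
    for (pass in 0:1) {
      ctr <- p[ri, ci]
      P2 <- p[ri - 1L, ci];      P3 <- p[ri - 1L, ci + 1L]
      P4 <- p[ri, ci + 1L];      P5 <- p[ri + 1L, ci + 1L]
      P6 <- p[ri + 1L, ci];      P7 <- p[ri + 1L, ci - 1L]
      P8 <- p[ri, ci - 1L];      P9 <- p[ri - 1L, ci - 1L]
      C <- (!P2 & (P3 | P4)) + (!P4 & (P5 | P6)) +
           (!P6 & (P7 | P8)) + (!P8 & (P9 | P2))
      N1 <- (P9 | P2) + (P3 | P4) + (P5 | P6) + (P7 | P8)
      N2 <- (P2 | P3) + (P4 | P5) + (P6 | P7) + (P8 | P9)
      N <- pmin(N1, N2)
      m <- if (pass == 0L) (P6 | P7 | !P9) & P8 else (P2 | P3 | !P5) & P4
      del <- ctr & C == 1L & N >= 2L & N <= 3L & !m
      if (any(del)) {
        changed <- TRUE
        sub <- p[ri, ci]; sub[del] <- FALSE; p[ri, ci] <- sub
      }
    }
    if (!changed) break
  }
  p[ri, ci]
}

# Build an igraph over skeleton pixels: vertices = pixels, edges between
# 8-neighbours weighted 1 (axial) or sqrt(2) (diagonal).
# Returns list(coords = n x 2 row/col, graph).
skeleton_graph <- function(skel) {
  coords <- which(skel, arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0L) return(NULL)
  nr <- nrow(skel)
  id <- matrix(0L, nr, ncol(skel))
  id[coords] <- seq_len(n)
  edges <- NULL; w <- NULL
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nb <- cbind(coords[, 1L] + off[1L], coords[, 2L] + off[2L])
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= nr & nb[, 2L] >= 1L & nb[, 2L] <= ncol(skel)
    ok[ok] <- id[nb[ok, , drop = FALSE]] > 0L
    if (any(ok)) {
      edges <- rbind(edges, cbind(id[coords[ok, , drop = FALSE]],
                                  id[nb[ok, , drop = FALSE]]))
      w <- c(w, rep(sqrt(sum(off^2)), sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges), weight = w)
  list(coords = coords, graph = g)
}

# Longest geodesic path in a skeleton (graph diameter by double sweep, exact
# on trees, which thinned skeletons essentially are).
# Returns list(length_px, from, to) with from/to as (row, col).
skeleton_diameter <- function(sg) {
  g <- sg$graph
  if (igraph::vcount(g) == 1L)
    return(list(length_px = 0, from = sg$coords[1L, ], to = sg$coords[1L, ]))
  d1 <- igraph::distances(g, v = 1L)[1L, ]
  d1[!is.finite(d1)] <- -1
  u <- which.max(d1)
  d2 <- igraph::distances(g, v = u)[1L, ]
  d2[!is.finite(d2)] <- -1
  v <- which.max(d2)
  list(length_px = d2[v], from = sg$coords[u, ], to = sg$coords[v, ])
}

# Longest geodesic path from a fixed source vertex; returns the ordered path
# coordinates and its length. Ties between equal-length endpoints broken
# lexicographically by (row, col).
skeleton_longest_from <- function(sg, source_vertex) {
  g <- sg$graph
  d <- igraph::distances(g, v = source_vertex)[1L, ]
  d[!is.finite(d)] <- -1
  best <- max(d)
  cand <- which(d == best)
  if (length(cand) > 1L) {
    oc <- order(sg$coords[cand, 1L], sg$coords[cand, 2L])
    cand <- cand[oc]
  }
  tip <- cand[1L]
  path <- igraph::shortest_paths(g, from = source_vertex, to = tip,
                                 output = "vpath")$vpath[[1L]]
  list(length_px = best, path = sg$coords[as.integer(path), , drop = FALSE])
}

# Euclidean distance map of a padded mask; values are distances (in px) to the
# nearest background pixel.
distance_map <- function(padded) {
  EBImage::distmap(padded * 1L, metric = "euclidean")
}
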