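#' Synthetic epithelial tissue geometry
#'
#' The simulated wing-pouch epithelium is a bounded Voronoi tessellation
#' of a convex, ellipse-like domain, relaxed by Lloyd's algorithm toward
#' near-hexagonal packing. A tissue carries, for every cell, its centroid,
#' polygon, area and a boundary flag, and for every pair of adjacent
#' cells the shared-boundary length `l_ij` that weights gap-junction
#' exchange. Coordinates are normalized so the mean cell diameter
#' (diameter of the area-equivalent circle) is 1; `l_ij` is therefore
#' dimensionless and permeabilities apply as-is.
#'
#' @name tissue
NULL

# Sutherland-Hodgman clip of a convex polygon by the half-plane
# {x : (x - m) . d <= 0}. `labels[k]` tags the edge leaving vertex k
# (0 = domain boundary, otherwise the neighbour index owning the edge);
# edges created by this clip are tagged `lab`.
clip_halfplane <- function(verts, labels, m, d, lab) {
  n <- nrow(verts)
  if (n == 0L) return(list(verts = verts, labels = labels))
  f <- (verts[, 1] - m[1]) * d[1] + (verts[, 2] - m[2]) * d[2]
  if (all(f <= 0)) return(list(verts = verts, labels = labels))
  vx <- numeric(n + 2); vy <- numeric(n + 2); vl <- numeric(n + 2)
  k <- 0L
  for (a in seq_len(n)) {
    b <- if (a == n) 1L else a + 1L
    fa <- f[a]; fb <- f[b]
    if (fa <= 0) {
      k <- k + 1L; vx[k] <- verts[a, 1]; vy[k] <- verts[a, 2]
      vl[k] <- labels[a]
      if (fb > 0) {                      # leaving: emit exit point
        t <- fa / (fa - fb)
        k <- k + 1L
        vx[k] <- verts[a, 1] + t * (verts[b, 1] - verts[a, 1])
        vy[k] <- verts[a, 2] + t * (verts[b, 2] - verts[a, 2])
        vl[k] <- lab                     # edge along the clip line
      }
    } else if (fb <= 0) {                # entering: emit entry point
      t <- fa / (fa - fb)
      k <- k + 1L
      vx[k] <- verts[a, 1] + t * (verts[b, 1] - verts[a, 1])
      vy[k] <- verts[a, 2] + t * (verts[b, 2] - verts[a, 2])
      vl[k] <- labels[a]                 # remainder of the original edge
    }
  }
  list(verts = cbind(vx[seq_len(k)], vy[seq_len(k)]),
       labels = vl[seq_len(k)])
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(colMeans(v))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

ellipse_polygon <- function(aspect = 1.3, n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(aspect * cos(th), sin(th))
}

# bounded Voronoi cells of `points` clipped to convex `domain`;
# neighbours are visited nearest-first and the scan stops once the
# bisector distance exceeds the current polygon's circumradius, which
# makes the restriction exact.
voronoi_cells <- function(points, domain) {
  n <- nrow(points)
  lapply(seq_len(n), function(i) {
    g <- points[i, ]
    verts <- domain
    labels <- rep(0, nrow(domain))
    d2 <- (points[, 1] - g[1])^2 + (points[, 2] - g[2])^2
    ord <- order(d2)
    maxr2 <- max((verts[, 1] - g[1])^2 + (verts[, 2] - g[2])^2)
    for (j in ord) {
      if (j == i) next
      if (d2[j] >= 4 * maxr2) break
      m <- (g + points[j, ]) / 2
      dd <- points[j, ] - g
      cl <- clip_halfplane(verts, labels, m, dd, j)
      verts <- cl$verts; labels <- cl$labels
      if (nrow(verts) < 3L) break
      maxr2 <- max((verts[, 1] - g[1])^2 + (verts[, 2] - g[2])^2)
    }
    list(verts = verts, labels = labels)
  })
}

# assemble a ca_tissue from clipped cells
build_tissue <- function(cells, meta, normalize = TRUE) {
  n <- length(cells)
  polygons <- lapply(cells, `[[`, "verts")
  areas <- vapply(polygons, polygon_area, 0)
  centroids <- t(vapply(polygons, polygon_centroid, c(0, 0)))
  boundary <- vapply(cells, function(cl) any(cl$labels == 0), TRUE)

  ii <- integer(0); jj <- integer(0); ll <- numeric(0)
  for (i in seq_len(n)) {
    v <- cells[[i]]$verts; lab <- cells[[i]]$labels
    m <- nrow(v)
    if (m < 2L) next
    nxt <- c(seq_len(m)[-1], 1L)
    len <- sqrt((v[nxt, 1] - v[, 1])^2 + (v[nxt, 2] - v[, 2])^2)
    sel <- lab > 0 & len > 1e-12
    if (any(sel)) {
      agg <- tapply(len[sel], lab[sel], sum)
      ii <- c(ii, rep.int(i, length(agg)))
      jj <- c(jj, as.integer(names(agg)))
      ll <- c(ll, as.numeric(agg))
    }
  }
  # merge the two directed records of each unordered pair
  key <- paste(pmin(ii, jj), pmax(ii, jj))
  both <- tapply(seq_along(key), key, identity)
  keep <- vapply(both, length, 0L) == 2L
  edges <- do.call(rbind, lapply(both[keep], function(idx) {
    data.frame(i = min(ii[idx[1]], jj[idx[1]]),
               j = max(ii[idx[1]], jj[idx[1]]),
               l = mean(ll[idx]))
  }))
  if (is.null(edges)) {
    edges <- data.frame(i = integer(0), j = integer(0), l = numeric(0))
  } else {
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  }

  if (normalize) {
    dbar <- mean(2 * sqrt(areas / pi))
    centroids <- centroids / dbar
    polygons <- lapply(polygons, function(v) v / dbar)
    areas <- areas / dbar^2
    edges$l <- edges$l / dbar
  }

  t <- list(n_cells = n, centroids = centroids, polygons = polygons,
            areas = areas, edges = edges, boundary = boundary,
            meta = meta)
  class(t) <- "ca_tissue"
  validate_tissue(t)
  t
}

validate_tissue <- function(t) {
  if (t$n_cells < 1L) stop("tissue must contain at least one cell",
                           call. = FALSE)
  e <- t$edges
  if (nrow(e)) {
    if (any(e$l <= 0)) stop("shared-boundary lengths must be positive",
                            call. = FALSE)
    if (any(e$i >= e$j)) stop("edges must be stored once with i < j",
                              call. = FALSE)
    if (anyDuplicated(paste(e$i, e$j)))
      stop("duplicate edge records", call. = FALSE)
    if (any(e$i < 1) || any(e$j > t$n_cells))
      stop("edge indices out of range", call. = FALSE)
  }
  invisible(t)
}

#' Generate a synthetic wing-pouch tissue
#'
#' Samples `n_cells` generator points uniformly in an elliptical,
#' pouch-like domain, computes the bounded Voronoi tessellation, applies
#' `lloyd_iterations` rounds of Lloyd relaxation (each generator moves to
#' its cell centroid), and extracts polygons, areas, adjacency and
#' shared-boundary lengths. Deterministic given `seed`.
#'
#' @param n_cells Number of cells (>= 1).
#' @param lloyd_iterations Rounds of Lloyd relaxation (default 4,
#'   "multiple rounds": enough to reach near-hexagonal interior packing).
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param aspect Semi-axis ratio of the elliptical domain (default 1.3,
#'   pouch-like).
#' @return A `ca_tissue` object.
#' @examples
#' tis <- generate_tissue(60, seed = 1)
#' tis
#' @export
generate_tissue <- function(n_cells, lloyd_iterations = 4, seed = NULL,
                            aspect = 1.3) {
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (lloyd_iterations < 0) stop("lloyd_iterations must be >= 0",
                                 call. = FALSE)
  domain <- ellipse_polygon(aspect)
  pts <- with_seed(seed, {
    th <- stats::runif(n_cells, 0, 2 * pi)
    rad <- sqrt(stats::runif(n_cells))
    cbind(aspect * rad * cos(th), rad * sin(th))
  })
  cells <- voronoi_cells(pts, domain)
  if (lloyd_iterations > 0) {
    for (k in seq_len(lloyd_iterations)) {
      pts <- t(vapply(cells, function(cl) polygon_centroid(cl$verts),
                      c(0, 0)))
      cells <- voronoi_cells(pts, domain)
    }
  }
  build_tissue(cells, meta = list(seed = seed,
                                  lloyd_iterations = lloyd_iterations,
                                  aspect = aspect))
}

#' Voronoi tessellation of given points in a convex domain
#'
#' Lower-level entry point used by [generate_tissue]; useful for passing
#' hand-built point sets (e.g. a regular hexagonal lattice) through the
#' same extraction machinery.
#'
#' @param points Numeric matrix (n x 2) of generator points inside
#'   `domain`.
#' @param domain Convex polygon (m x 2, counterclockwise) to clip
#'   against.
#' @param normalize Rescale so the mean cell diameter is 1 (default
#'   `FALSE` here; [generate_tissue] normalizes).
#' @return A `ca_tissue` object.
#' @export
voronoi_tessellation <- function(points, domain, normalize = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("need at least one point", call. = FALSE)
  build_tissue(voronoi_cells(points, domain),
               meta = list(seed = NULL, lloyd_iterations = 0,
                           aspect = NA),
               normalize = normalize)
}

#' @export
print.ca_tissue <- function(x, ...) {
  nb <- neighbor_counts(x)
  cat("Epithelial tissue:", x$n_cells, "cells,", nrow(x$edges),
      "gap-junction edges\n")
  cat("  interior mean neighbour count:",
      round(mean(nb[!x$boundary]), 2), "\n")
  cat("  total area:", round(sum(x$areas), 2),
      "(mean cell diameter 1)\n")
  invisible(x)
}

#' Per-cell neighbour counts
#' @param tissue A `ca_tissue`.
#' @return Integer vector of length `n_cells`.
#' @export
neighbor_counts <- function(tissue) {
  tabulate(c(tissue$edges$i, tissue$edges$j), nbins = tissue$n_cells)
}

#' Is the adjacency graph connected?
#' @param tissue A `ca_tissue`.
#' @return Logical scalar.
#' @export
tissue_connected <- function(tissue) {
  if (tissue$n_cells == 1L) return(TRUE)
  if (nrow(tissue$edges) == 0L) return(FALSE)
  g <- igraph::graph_from_edgelist(
    as.matrix(tissue$edges[, c("i", "j")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, tissue$n_cells -
                                     igraph::vcount(g)))
  igraph::is_connected(g)
}

#' Save / load a tissue geometry file
#'
#' The geometry file is JSON with cell records (0-based `id`, centroid,
#' polygon, area, boundary flag) and an edge list (`i`, `j`, `l`, also
#' 0-based, one record per unordered pair). The round trip is exact:
#' coordinates are written at full precision.
#'
#' @param tissue A `ca_tissue`.
#' @param path Output (or input) file path.
#' @return `load_tissue` returns a `ca_tissue`; `save_tissue` returns
#'   `path` invisibly.
#' @export
save_tissue <- function(tissue, path) {
  validate_tissue(tissue)
  cells <- lapply(seq_len(tissue$n_cells), function(i) {
    list(id = i - 1L,
         centroid = as.numeric(tissue$centroids[i, ]),
         polygon = apply(tissue$polygons[[i]], 1, as.numeric,
                         simplify = FALSE),
         area = tissue$areas[i],
         boundary = tissue$boundary[i])
  })
  edges <- lapply(seq_len(nrow(tissue$edges)), function(k) {
    list(i = tissue$edges$i[k] - 1L, j = tissue$edges$j[k] - 1L,
         l = tissue$edges$l[k])
  })
  jsonlite::write_json(list(cells = cells, edges = edges), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_tissue
#' @export
load_tissue <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$cells) || length(x$cells) == 0L)
    stop("geometry file contains no cells", call. = FALSE)
  n <- length(x$cells)
  ids <- vapply(x$cells, function(cl) as.integer(cl$id), 0L)
  if (!identical(sort(ids), 0:(n - 1L)))
    stop("cell ids must be 0..N-1", call. = FALSE)
  ord <- order(ids)
  cells <- x$cells[ord]
  centroids <- t(vapply(cells, function(cl) as.numeric(unlist(cl$centroid)),
                        c(0, 0)))
  polygons <- lapply(cells, function(cl) {
    do.call(rbind, lapply(cl$polygon, as.numeric))
  })
  areas <- vapply(cells, function(cl) as.numeric(cl$area), 0)
  boundary <- vapply(cells, function(cl) isTRUE(cl$boundary), TRUE)
  ne <- length(x$edges)
  ei <- integer(ne); ej <- integer(ne); el <- numeric(ne)
  for (k in seq_len(ne)) {
    e <- x$edges[[k]]
    a <- as.integer(e$i) + 1L; b <- as.integer(e$j) + 1L
    if (is.na(a) || is.na(b) || a == b)
      stop("malformed edge record ", k, call. = FALSE)
    ei[k] <- min(a, b); ej[k] <- max(a, b); el[k] <- as.numeric(e$l)
  }
  if (anyDuplicated(paste(ei, ej)))
    stop("edge list contains duplicate (possibly asymmetric) records",
         call. = FALSE)
  edges <- data.frame(i = ei, j = ej, l = el)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  t <- list(n_cells = n, centroids = centroids, polygons = polygons,
            areas = areas, edges = edges, boundary = boundary,
            meta = list(seed = NULL, lloyd_iterations = NA, aspect = NA,
                        source = path))
  class(t) <- "ca_tissue"
  validate_tissue(t)
  t
}

#' Mean cell diameter of a tissue
#'
#' Diameter of the area-equivalent circle, averaged over cells. Equals 1
#' for freshly generated (normalized) tissues; used by the pattern
#' classifier as the propagation length unit.
#'
#' @param tissue A `ca_tissue`.
#' @return Scalar length.
#' @export
mean_cell_diameter <- function(tissue) {
  mean(2 * sqrt(tissue$areas / pi))
}
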