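# shared fixtures and oracles, built in code at test time

baseline <- model_params()

# central finite differences of the single-cell RHS, the oracle for the
# analytic Jacobian
num_jacobian <- function(state, v_plc, params = baseline, leak = NULL,
                         h = 1e-7) {
  J <- matrix(0, 3, 3)
  for (k in 1:3) {
    e <- numeric(3); e[k] <- h
    up <- state + e; dn <- state - e
    J[, k] <- (capouch:::cell_rhs(up[1], up[2], up[3], v_plc, params,
                                  leak) -
                 capouch:::cell_rhs(dn[1], dn[2], dn[3], v_plc, params,
                                    leak)) / (2 * h)
  }
  J
}

# regular hexagonal lattice generators (triangular lattice points whose
# Voronoi cells are regular hexagons with side a / sqrt(3))
hex_lattice_points <- function(nx, ny, a = 1) {
  pts <- NULL
  for (row in seq_len(ny)) {
    y <- (row - 1) * a * sqrt(3) / 2
    off <- if (row %% 2 == 0) a / 2 else 0
    pts <- rbind(pts, cbind((seq_len(nx) - 1) * a + off, y))
  }
  pts
}

rect_domain <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# hand-built minimal tissue: n isolated-or-chained cells with unit
# shared boundaries, unit areas, centroids on a line
toy_tissue <- function(n, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(i = integer(0), j = integer(0), l = numeric(0))
  structure(list(
    n_cells = n,
    centroids = cbind(seq_len(n), rep(0, n)),
    polygons = lapply(seq_len(n), function(i)
      cbind(i + c(-0.5, 0.5, 0.5, -0.5), c(-0.5, -0.5, 0.5, 0.5))),
    areas = rep(1, n),
    edges = edges,
    boundary = rep(TRUE, n),
    meta = list(seed = NULL, lloyd_iterations = 0, aspect = NA)),
    class = "ca_tissue")
}

# relabel tissue cells by permutation perm (new index = perm[old])
permute_tissue <- function(tissue, perm) {
  inv <- order(perm)
  e <- tissue$edges
  pi <- perm[e$i]; pj <- perm[e$j]
  edges <- data.frame(i = pmin(pi, pj), j = pmax(pi, pj), l = e$l)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  t2 <- tissue
  t2$centroids <- tissue$centroids[inv, , drop = FALSE]
  t2$polygons <- tissue$polygons[inv]
  t2$areas <- tissue$areas[inv]
  t2$boundary <- tissue$boundary[inv]
  t2$edges <- edges
  t2
}

# quick uncoupled parameter set
uncoupled <- function(params = baseline) {
  params$Fp <- 0; params$Fc <- 0
  params
}
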