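#' Assign per-cell maximal PLC rates
#'
#' Partitions the tissue into "initiator" cells (high `V_PLC`, capable of
#' autonomous oscillation when above the Hopf threshold) and "standby"
#' cells (baseline `V_PLC`). `n_initiators` distinct cells are chosen
#' uniformly at random; initiator values are drawn uniformly from
#' `initiator_range` and standby values from `standby_range`. A
#' degenerate range `c(x, x)` assigns the constant `x`.
#'
#' @param tissue A `ca_tissue`.
#' @param n_initiators Number of initiator cells, `0 <= n <= n_cells`.
#' @param initiator_range Length-2 numeric `c(lo, hi)`, uM/s.
#' @param standby_range Length-2 numeric `c(lo, hi)`, uM/s.
#' @param seed Integer RNG seed, or `NULL`.
#' @return A `ca_vplc` object: per-cell `v_plc`, logical `is_initiator`,
#'   and the seed and ranges used.
#' @examples
#' tis <- generate_tissue(50, seed = 1)
#' fld <- assign_vplc(tis, 2, c(1.4, 1.5), c(0.1, 0.5), seed = 2)
#' sum(fld$is_initiator)
#' @export
assign_vplc <- function(tissue, n_initiators, initiator_range,
                        standby_range, seed = NULL) {
  n <- tissue$n_cells
  if (n_initiators < 0 || n_initiators > n)
    stop("n_initiators must lie in [0, n_cells]", call. = FALSE)
  for (rg in list(initiator_range, standby_range)) {
    if (length(rg) != 2L || rg[1] > rg[2])
      stop("ranges must be c(lo, hi) with lo <= hi", call. = FALSE)
    if (rg[1] < 0) stop("V_PLC values must be non-negative",
                        call. = FALSE)
  }
  with_seed(seed, {
    is_init <- rep(FALSE, n)
    if (n_initiators > 0)
      is_init[sample.int(n, n_initiators)] <- TRUE
    v <- stats::runif(n, standby_range[1], standby_range[2])
    if (n_initiators > 0)
      v[is_init] <- stats::runif(n_initiators, initiator_range[1],
                                 initiator_range[2])
    out <- list(v_plc = v, is_initiator = is_init, seed = seed,
                initiator_range = initiator_range,
                standby_range = standby_range)
    class(out) <- "ca_vplc"
    out
  })
}

#' @export
print.ca_vplc <- function(x, ...) {
  cat("V_PLC field:", length(x$v_plc), "cells,",
      sum(x$is_initiator), "initiators\n")
  cat("  initiator range [", x$initiator_range[1], ",",
      x$initiator_range[2], "], standby range [",
      x$standby_range[1], ",", x$standby_range[2], "] uM/s\n")
  invisible(x)
}

#' Default initiator count for pattern scenarios
#'
#' A small set of initiator cells ("a small distribution"), 2% of the
#' tissue but at least one.
#'
#' @param n_cells Tissue size.
#' @return Integer count.
#' @export
default_initiator_count <- function(n_cells) {
  max(1L, as.integer(round(0.02 * n_cells)))
}

#' Export a V_PLC field as CSV
#'
#' Columns `cell_id` (0-based), `v_plc`, `is_initiator`.
#'
#' @param field A `ca_vplc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vplc_csv <- function(field, path) {
  utils::write.csv(data.frame(cell_id = seq_along(field$v_plc) - 1L,
                              v_plc = field$v_plc,
                              is_initiator = field$is_initiator),
                   path, row.names = FALSE)
  invisible(path)
}
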