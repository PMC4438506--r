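#' Find all neighbor pairs within a cutoff
#'
#' Cell-list search: particles are binned into cubic cells of the cutoff size
#' and only the 27 adjacent cells are scanned per particle, giving O(N) work
#' on a bounded-density point set. Self-pairs are excluded; the result is
#' symmetric (both `(i, j)` and `(j, i)` are present), which is the form the
#' pairwise SPH operators consume.
#'
#' @param positions N x 3 matrix of coordinates (Angstrom).
#' @param cutoff interaction radius (Angstrom); pairs with distance exactly
#'   equal to the cutoff are included. Must cover the kernel support
#'   (`2 h`) when used for SPH sums.
#' @return Object of class `neighbor_pairs`: list with integer vectors `i`,
#'   `j`, numeric `r` (pair distances) and the `cutoff`.
#' @export
find_neighbors <- function(positions, cutoff) {
  stopifnot(is.matrix(positions), ncol(positions) == 3L,
            is.finite(cutoff), cutoff > 0)
  n <- nrow(positions)
  if (n < 2L)
    return(structure(list(i = integer(), j = integer(), r = numeric(),
                          cutoff = cutoff), class = "neighbor_pairs"))
  cell <- floor(positions / cutoff)
  cell <- sweep(cell, 2L, apply(cell, 2L, min)) + 1  # guard ring at 0
  dims <- apply(cell, 2L, max) + 2
  key <- as.integer(cell[, 1] + dims[1] * (cell[, 2] + dims[2] * cell[, 3]))
  dt <- data.table::data.table(ckey = key, j = seq_len(n))
  data.table::setkey(dt, ckey)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  okey <- as.integer(offs[, 1] + dims[1] * (offs[, 2] + dims[2] * offs[, 3]))
  out_i <- vector("list", length(okey))
  out_j <- vector("list", length(okey))
  out_r <- vector("list", length(okey))
  cut2 <- cutoff^2
  for (m in seq_along(okey)) {
    probe <- data.table::data.table(ckey = key + okey[m], i = seq_len(n))
    cand <- dt[probe, on = "ckey", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(cand)) next
    ii <- cand$i; jj <- cand$j
    keep <- ii != jj
    ii <- ii[keep]; jj <- jj[keep]
    if (!length(ii)) next
    d2 <- (positions[ii, 1] - positions[jj, 1])^2 +
          (positions[ii, 2] - positions[jj, 2])^2 +
          (positions[ii, 3] - positions[jj, 3])^2
    keep <- d2 <= cut2
    out_i[[m]] <- ii[keep]
    out_j[[m]] <- jj[keep]
    out_r[[m]] <- sqrt(d2[keep])
  }
  structure(list(i = unlist(out_i), j = unlist(out_j), r = unlist(out_r),
                 cutoff = cutoff),
            class = "neighbor_pairs")
}

#' Ensure a particle system carries its neighbor structure
#'
#' Computes and caches pairs at the kernel support radius `2 * max(h, h_r)`.
#'
#' @param system a `particle_system`.
#' @param cutoff optional cutoff override (must be at least the kernel
#'   support).
#' @return The system with `$pairs` populated.
#' @export
ensure_neighbors <- function(system, cutoff = NULL) {
  stopifnot(inherits(system, "particle_system"))
  support <- system$kernel$kappa * max(system$kernel$h, system$kernel$h_r)
  if (is.null(cutoff)) cutoff <- support
  if (cutoff < support)
    stop(sprintf("cutoff %g A is below the kernel support %g A", cutoff, support),
         call. = FALSE)
  if (!is.null(system$pairs) && system$pairs$cutoff >= cutoff) return(system)
  system$pairs <- find_neighbors(system$positions, cutoff)
  system
}
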