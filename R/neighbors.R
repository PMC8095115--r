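# Squared cross-distance matrix between two coordinate sets (n x 3, m x 3).
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a * a), rowSums(b * b), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Minimum distance between two atom sets
#' @param a,b numeric matrices (n x 3, m x 3) of coordinates in Angstrom.
#' @return the minimum pairwise Euclidean distance.
#' @export
min_cross_dist <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  sqrt(min(cross_dist2(a, b)))
}

#' Which query atoms lie within a cutoff of any reference atom
#'
#' Cutoff neighbor detection with a closed boundary (a pair at exactly the
#' cutoff counts). Two interchangeable paths are provided: a uniform cell
#' grid of edge equal to the cutoff (queries grouped per cell, candidate
#' reference atoms gathered from the 27 surrounding cells), and quadratic
#' brute force over all pairs. `"auto"` picks brute force when the pair
#' count is small enough that grid bookkeeping costs more than it saves.
#'
#' @param query n x 3 coordinate matrix.
#' @param ref m x 3 coordinate matrix.
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @param method `"auto"`, `"grid"` or `"brute"`.
#' @return logical vector of length n.
#' @export
atoms_within_cutoff <- function(query, ref, cutoff,
                                method = c("auto", "grid", "brute")) {
  method <- match.arg(method)
  query <- as.matrix(query); ref <- as.matrix(ref)
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (nrow(ref) == 0 || nrow(query) == 0) return(rep(FALSE, nrow(query)))
  if (method == "auto")
    method <- if (as.double(nrow(query)) * nrow(ref) <= 5e4) "brute" else "grid"
  cut2 <- cutoff^2
  if (method == "brute")
    return(rowSums(cross_dist2(query, ref) <= cut2) > 0)
  rc <- floor(ref / cutoff)
  qc <- floor(query / cutoff)
  ref_cells <- split(seq_len(nrow(ref)), paste(rc[, 1], rc[, 2], rc[, 3]))
  qgroups <- split(seq_len(nrow(query)), paste(qc[, 1], qc[, 2], qc[, 3]))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- logical(nrow(query))
  for (g in qgroups) {
    cc <- qc[g[1], ]
    keys <- paste(cc[1] + offs[, 1], cc[2] + offs[, 2], cc[3] + offs[, 3])
    cand <- unlist(ref_cells[keys], use.names = FALSE)
    if (length(cand) > 0) {
      d2 <- cross_dist2(query[g, , drop = FALSE], ref[cand, , drop = FALSE])
      out[g] <- rowSums(d2 <= cut2) > 0
    }
  }
  out
}
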