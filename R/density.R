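# Resolve a density selection to heavy-atom indices: an integer vector, a
# ligand_spec (all heavy ligand atoms over its subunits), or a list of
# arguments to select_atoms().
resolve_density_selection <- function(top, selection) {
  idx <- if (inherits(selection, "ligand_spec")) {
    unlist(lapply(ligand_subunits(selection), function(s)
      ligand_atom_idx(top, selection, s, headgroup_only = FALSE)), use.names = FALSE)
  } else if (is.list(selection)) {
    do.call(select_atoms, c(list(top), selection))
  } else {
    as.integer(selection)
  }
  idx <- idx[!top$is_hydrogen[idx]]
  if (length(idx) == 0) stop("density selection resolves to no heavy atom")
  idx
}

# One isotropic Gaussian deposit patch (sd = atom_size, spherically
# truncated at 4 sd), normalized so that (discrete sum) * spacing^3 equals
# `weight` over the deposited (possibly edge-clipped) support. Returns the
# 1-based index vectors and the scaled kernel; the caller accumulates
# in place (keeping the accumulator un-shared avoids array copies).
gaussian_patch <- function(dims, origin, h, center, sigma, weight) {
  r <- ceiling(4 * sigma / h)
  ci <- round((center - origin) / h)
  i <- max(0, ci[1] - r):min(dims[1] - 1, ci[1] + r)
  j <- max(0, ci[2] - r):min(dims[2] - 1, ci[2] + r)
  k <- max(0, ci[3] - r):min(dims[3] - 1, ci[3] + r)
  dx2 <- (origin[1] + h * i - center[1])^2
  dy2 <- (origin[2] + h * j - center[2])^2
  dz2 <- (origin[3] + h * k - center[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  kern <- exp(-d2 / (2 * sigma^2))
  kern[d2 > (4 * sigma)^2] <- 0
  tot <- sum(kern) * h^3
  list(i = i + 1, j = j + 1, k = k + 1,
       kern = if (tot > 0) kern * (weight / tot) else kern)
}

# Grid geometry covering lo..hi padded by `pad`, origin snapped to a
# multiple of the spacing.
density_grid <- function(lo, hi, h, pad) {
  origin <- floor((lo - pad) / h) * h
  top <- ceiling((hi + pad) / h) * h
  dims <- as.integer(round((top - origin) / h)) + 1L
  list(origin = origin, dims = dims)
}

#' Frame-averaged weighted atomic density map
#'
#' Deposits each selected heavy atom, in each frame, as an isotropic
#' Gaussian of standard deviation `atom_size` (spherically truncated at 4
#' standard deviations) on a grid of spacing `resolution`, normalized so
#' that each deposit integrates to the atom's weight (its mass, or 1 in
#' occupancy mode). Per-frame maps are combined by arithmetic averaging.
#' The grid covers the selection's bounding box over all frames, padded by
#' `4 * atom_size`, with the origin snapped to a multiple of the spacing.
#'
#' @param ens an [ensemble()].
#' @param selection atom indices, a [ligand_spec()], or a list of
#'   [select_atoms()] arguments; hydrogens are always excluded.
#' @param resolution grid spacing in Angstrom (default 0.5).
#' @param atom_size Gaussian standard deviation in Angstrom (default 1.0).
#' @param weight_mode `"mass"` (default) or `"occupancy"`.
#' @param frames optional frame subset (1-based indices); default all.
#' @return a [density_map()].
#' @export
atomic_density_map <- function(ens, selection, resolution = 0.5, atom_size = 1.0,
                               weight_mode = c("mass", "occupancy"),
                               frames = NULL) {
  weight_mode <- match.arg(weight_mode)
  if (resolution <= 0) stop("resolution must be > 0")
  if (atom_size <= 0) stop("atom_size must be > 0")
  top <- ens$topology
  idx <- resolve_density_selection(top, selection)
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  sel <- ens$coords[idx, , frames, drop = FALSE]
  g <- density_grid(apply(sel, 2, min), apply(sel, 2, max), resolution,
                    4 * atom_size)
  w <- if (weight_mode == "mass") top$mass[idx] else rep(1, length(idx))
  vals <- array(0, g$dims)
  for (fi in seq_along(frames)) {
    for (a in seq_along(idx)) {
      p <- gaussian_patch(g$dims, g$origin, resolution, sel[a, , fi],
                          atom_size, w[a])
      vals[p$i, p$j, p$k] <- vals[p$i, p$j, p$k] + p$kern
    }
  }
  density_map(g$origin, resolution, vals / length(frames),
              weight_mode = weight_mode, n_frames_averaged = length(frames))
}

#' Correlation between two density maps
#'
#' Resamples map B onto map A's grid by trilinear interpolation and
#' computes the correlation over voxels where either map exceeds
#' `mask_threshold`. The default is the cross-correlation about zero (the
#' density-fit convention used when comparing computed and experimental
#' maps); `center = TRUE` gives the mean-centered Pearson coefficient.
#'
#' @param map_a,map_b [density_map()] objects with overlapping support.
#' @param mask_threshold voxels with `max(A, B) > mask_threshold` enter the
#'   comparison (default 0).
#' @param center subtract voxel means before correlating (default `FALSE`).
#' @return an object of class `map_comparison`: `correlation`,
#'   `n_voxels_compared`, `mask_threshold`, `center`,
#'   `resampling = "trilinear"`.
#' @export
map_correlation <- function(map_a, map_b, mask_threshold = 0, center = FALSE) {
  stopifnot(inherits(map_a, "density_map"), inherits(map_b, "density_map"))
  a <- as.vector(map_a$values)
  b <- sample_map(map_b, voxel_centers(map_a))
  ok <- !is.na(b)
  if (!any(ok)) stop("no overlapping voxels between the two maps")
  mask <- ok & pmax(a, ifelse(is.na(b), -Inf, b)) > mask_threshold
  n <- sum(mask)
  if (n == 0) stop("no overlapping voxels above the mask threshold")
  av <- a[mask]; bv <- b[mask]
  corr <- if (center) {
    if (sd(av) == 0 || sd(bv) == 0)
      stop("constant map over the compared region; centered correlation undefined")
    cor(av, bv)
  } else {
    den <- sqrt(sum(av^2) * sum(bv^2))
    if (den == 0) stop("zero map over the compared region")
    sum(av * bv) / den
  }
  structure(list(correlation = corr, n_voxels_compared = n,
                 mask_threshold = mask_threshold, center = center,
                 resampling = "trilinear"),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("Map correlation: %.4f over %d voxels (mask > %g, %s, trilinear)\n",
              x$correlation, x$n_voxels_compared, x$mask_threshold,
              if (x$center) "centered" else "about zero"))
  invisible(x)
}

# Water-oxygen atom indices of an ensemble topology.
water_oxygen_idx <- function(top) {
  which(top$category == "water" & toupper(top$element) == "O")
}

#' Occupancy map of waters near both a residue and a ligand
#'
#' Per frame, water oxygens simultaneously within `cutoff` of any heavy
#' atom of the anchor residue and any heavy atom of the ligand (on the same
#' subunit, over all subunits) are deposited with weight 1; per-frame maps
#' are averaged. The grid covers the anchor atoms' reference-frame bounding
#' box padded by `cutoff + 4 * atom_size`.
#'
#' @param ens an [ensemble()].
#' @param residue_seq anchor residue sequence number.
#' @param ligand a [ligand_spec()] anchor.
#' @param cutoff shell radius in Angstrom (default 6.0).
#' @param resolution grid spacing in Angstrom (default 0.5).
#' @param atom_size deposit Gaussian standard deviation (default 1.0).
#' @param pairing optional protein-to-ligand subunit map.
#' @return a [density_map()] in occupancy mode. Its integral equals the
#'   mean number of qualifying waters per frame.
#' @export
water_occupancy_map <- function(ens, residue_seq, ligand, cutoff = 6.0,
                                resolution = 0.5, atom_size = 1.0,
                                pairing = NULL) {
  top <- ens$topology
  wat <- water_oxygen_idx(top)
  if (length(wat) == 0) stop("no water in topology")
  check_ligand_resolves(top, ligand)
  res_idx <- lapply(setNames(nm = subunit_ids(top)), function(s)
    select_atoms(top, subunit = s, residue_seq = residue_seq,
                 category = c("protein_backbone", "protein_sidechain"),
                 heavy_only = TRUE))
  subs <- names(res_idx)[lengths(res_idx) > 0]
  if (length(subs) == 0) stop("anchor residue ", residue_seq, " has no heavy atoms")
  pair <- resolve_pairing(subs, ligand_subunits(ligand), pairing)
  lig_idx <- lapply(pair, function(ls)
    ligand_atom_idx(top, ligand, ls, headgroup_only = FALSE))
  anchor_idx <- unique(c(unlist(res_idx[subs]), unlist(lig_idx)))
  ref <- frame_coords(ens, 1)[anchor_idx, , drop = FALSE]
  g <- density_grid(apply(ref, 2, min), apply(ref, 2, max), resolution,
                    cutoff + 4 * atom_size)
  nT <- n_frames(ens)
  vals <- array(0, g$dims)
  for (f in seq_len(nT)) {
    x <- frame_coords(ens, f)
    wxyz <- x[wat, , drop = FALSE]
    qual <- rep(FALSE, length(wat))
    for (s in subs) {
      near_res <- atoms_within_cutoff(wxyz, x[res_idx[[s]], , drop = FALSE], cutoff)
      near_lig <- atoms_within_cutoff(wxyz, x[lig_idx[[s]], , drop = FALSE], cutoff)
      qual <- qual | (near_res & near_lig)
    }
    for (wi in which(qual)) {
      p <- gaussian_patch(g$dims, g$origin, resolution, wxyz[wi, ],
                          atom_size, 1)
      vals[p$i, p$j, p$k] <- vals[p$i, p$j, p$k] + p$kern
    }
  }
  density_map(g$origin, resolution, vals / nT, weight_mode = "occupancy",
              n_frames_averaged = nT)
}

#' Water-bridge occupancy between a residue and a ligand
#'
#' A frame (and subunit) counts a bridge iff some water oxygen is
#' simultaneously within `d_bridge` of a polar (N/O) sidechain heavy atom
#' of the residue and within `d_bridge` of a polar (N/O) heavy atom of the
#' ligand -- a heavy-atom donor-acceptor criterion with no angular term.
#'
#' @param ens an [ensemble()].
#' @param residue_seq residue sequence number; must have at least one polar
#'   sidechain heavy atom.
#' @param ligand a [ligand_spec()].
#' @param d_bridge donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @param pairing optional protein-to-ligand subunit map.
#' @return an object of class `bridge_report`: `residue_seq`,
#'   `residue_name`, `ligand_label`, `d_bridge`, `indicator` (T x S logical
#'   matrix) and `bridge_frequency` (mean of the indicators).
#' @export
water_bridge_frequency <- function(ens, residue_seq, ligand, d_bridge = 3.5,
                                   pairing = NULL) {
  top <- ens$topology
  wat <- water_oxygen_idx(top)
  if (length(wat) == 0) stop("no water in topology")
  check_ligand_resolves(top, ligand)
  polar <- function(idx) idx[toupper(top$element[idx]) %in% c("N", "O")]
  res_idx <- lapply(setNames(nm = subunit_ids(top)), function(s)
    polar(select_atoms(top, subunit = s, residue_seq = residue_seq,
                       category = "protein_sidechain", heavy_only = TRUE)))
  subs <- names(res_idx)[lengths(res_idx) > 0]
  rname <- unique(top$residue_name[top$residue_seq == residue_seq &
                                     startsWith(top$category, "protein")])
  if (length(subs) == 0)
    stop(sprintf("residue %s%d has no polar (N/O) sidechain heavy atom",
                 if (length(rname) > 0) rname[1] else "", residue_seq))
  pair <- resolve_pairing(subs, ligand_subunits(ligand), pairing)
  lig_idx <- lapply(pair, function(ls)
    polar(ligand_atom_idx(top, ligand, ls, headgroup_only = FALSE)))
  if (any(lengths(lig_idx) == 0))
    stop(sprintf("ligand '%s' has no polar (N/O) heavy atom", ligand$label))
  nT <- n_frames(ens)
  ind <- matrix(FALSE, nT, length(subs), dimnames = list(NULL, subs))
  for (f in seq_len(nT)) {
    x <- frame_coords(ens, f)
    wxyz <- x[wat, , drop = FALSE]
    for (s in subs) {
      near_res <- atoms_within_cutoff(wxyz, x[res_idx[[s]], , drop = FALSE], d_bridge)
      if (any(near_res)) {
        near_lig <- atoms_within_cutoff(wxyz[near_res, , drop = FALSE],
                                        x[lig_idx[[s]], , drop = FALSE], d_bridge)
        ind[f, s] <- any(near_lig)
      }
    }
  }
  structure(list(residue_seq = residue_seq,
                 residue_name = if (length(rname) > 0) rname[1] else NA_character_,
                 ligand_label = ligand$label, d_bridge = d_bridge,
                 indicator = ind, bridge_frequency = mean(ind)),
            class = "bridge_report")
}

#' @export
print.bridge_report <- function(x, ...) {
  cat(sprintf("Water bridge %s%d -- %s (d <= %.2f A): frequency %.3f over %d frames x %d subunit(s)\n",
              x$residue_name, x$residue_seq, x$ligand_label, x$d_bridge,
              x$bridge_frequency, nrow(x$indicator), ncol(x$indicator)))
  invisible(x)
}
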