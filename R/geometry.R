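#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `reference`, via singular value decomposition of the weighted
#' covariance matrix. A reflection in the least-squares solution is
#' corrected by a sign flip along the smallest singular axis, so the
#' returned rotation always has determinant +1.
#'
#' @param mobile,reference M x 3 coordinate matrices (M >= 3, non-collinear).
#' @param weights optional nonnegative per-point weights.
#' @return a list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (the weighted fit RMSD). The aligned coordinates are
#'   `mobile %*% t(rotation) + translation` (rows as points).
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  m <- nrow(mobile)
  if (m < 3 || nrow(reference) != m)
    stop("superpose: need matching coordinate sets of at least 3 points")
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m || any(weights < 0) || sum(weights) <= 0)
    stop("superpose: invalid weights")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  mc <- sweep(mobile, 2, cm); rc <- sweep(reference, 2, cr)
  sv_m <- svd(mc * sqrt(w))$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1e-12))
    stop("superpose: degenerate (collinear or coincident) point set")
  h <- crossprod(mc * w, rc)                      # 3 x 3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- mc %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((aligned - rc)^2)))
  list(rotation = rot, translation = as.numeric(cr - rot %*% cm), rmsd = rmsd)
}

# Apply a superpose() transform to an n x 3 coordinate matrix.
apply_transform <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Root-mean-square deviation between two matched coordinate sets
#' @param a,b M x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Minimum-distance time series between residues and a ligand headgroup
#'
#' For each requested residue, the per-frame, per-subunit minimum distance
#' between its sidechain heavy atoms and the heavy headgroup atoms of that
#' subunit's ligand, with the subunit-averaged series and its time mean
#' attached.
#'
#' @param ens an [ensemble()].
#' @param residues integer vector of residue sequence numbers.
#' @param ligand a [ligand_spec()].
#' @param pairing optional protein-to-ligand subunit map (default same chain).
#' @return an object of class `distance_series_set`: a named list `series`
#'   (one entry per residue: `residue_seq`, `residue_name`, `d` the T x S
#'   distance matrix, `subunit_mean` length-T vector, `overall_mean`
#'   scalar) and `errors`, per-residue messages for residues that could not
#'   be measured (no sidechain heavy atoms); such residues do not abort the
#'   whole computation.
#' @export
min_distance_series <- function(ens, residues, ligand, pairing = NULL) {
  top <- ens$topology
  check_ligand_resolves(top, ligand)
  grp <- sidechain_groups(top)
  pair <- resolve_pairing(names(grp), ligand_subunits(ligand), pairing)
  hg_idx <- lapply(pair, function(ls) ligand_atom_idx(top, ligand, ls, headgroup_only = TRUE))
  nT <- n_frames(ens)
  subs <- names(grp)
  out <- list(); errors <- list()
  for (r in residues) {
    idx_by_sub <- lapply(subs, function(s) {
      g <- grp[[s]]
      pos <- match(r, g$residues$residue_seq)
      if (is.na(pos)) integer(0) else g$idx[g$group == pos]
    })
    names(idx_by_sub) <- subs
    if (all(lengths(idx_by_sub) == 0)) {
      errors[[as.character(r)]] <-
        sprintf("residue %d: no sidechain heavy atoms in any subunit", r)
      next
    }
    d <- matrix(NA_real_, nT, length(subs), dimnames = list(NULL, subs))
    for (s in subs) {
      ri <- idx_by_sub[[s]]
      if (length(ri) == 0) next
      href <- hg_idx[[s]]
      for (f in seq_len(nT)) {
        a <- matrix(ens$coords[ri, , f], ncol = 3)
        b <- matrix(ens$coords[href, , f], ncol = 3)
        d[f, s] <- min_cross_dist(a, b)
      }
    }
    sm <- rowMeans(d, na.rm = TRUE)
    nm <- top$residue_name[top$residue_seq == r & top$subunit_id %in% subs][1]
    out[[as.character(r)]] <- list(residue_seq = r, residue_name = nm, d = d,
                                   subunit_mean = sm, overall_mean = mean(sm))
  }
  structure(list(series = out, errors = errors, ligand_label = ligand$label),
            class = "distance_series_set")
}

#' Mean-separation summary of minimum-distance series
#'
#' Tabulates the time-and-subunit mean minimum distance per residue, sorted
#' ascending, and optionally flags residues whose mean exceeds a reference
#' residue's mean by more than a margin (e.g. to exclude residues that sit,
#' on average, several Angstrom farther from the ligand than the true
#' contact shell).
#'
#' @param series a `distance_series_set` from [min_distance_series()].
#' @param margin optional margin in Angstrom; when given, residues with
#'   `overall_mean > reference mean + margin` are flagged.
#' @param reference residue_seq of the reference residue; default the
#'   residue with the smallest overall mean.
#' @return data frame with columns `residue_seq`, `residue_name`,
#'   `overall_mean` and (when `margin` is given) `flagged`.
#' @export
mean_separation_report <- function(series, margin = NULL, reference = NULL) {
  if (length(series$series) == 0) stop("no distance series to summarize")
  tab <- do.call(rbind, lapply(series$series, function(s)
    data.frame(residue_seq = s$residue_seq, residue_name = s$residue_name,
               overall_mean = s$overall_mean, stringsAsFactors = FALSE)))
  tab <- tab[order(tab$overall_mean), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(margin)) {
    ref_mean <- if (is.null(reference)) min(tab$overall_mean) else {
      hit <- tab$residue_seq == reference
      if (!any(hit)) stop("reference residue not present in the series")
      tab$overall_mean[hit][1]
    }
    tab$flagged <- tab$overall_mean > ref_mean + margin
  }
  tab
}

# Resolve the RMSD target per subunit: a ligand_spec (all heavy ligand
# atoms) or an integer vector of residue_seq (all heavy atoms of those
# residues on that subunit).
resolve_target <- function(top, target, subunit) {
  if (inherits(target, "ligand_spec"))
    ligand_atom_idx(top, target, subunit, headgroup_only = FALSE)
  else
    select_atoms(top, subunit = subunit, residue_seq = target, heavy_only = TRUE)
}

#' Per-subunit RMSD time series relative to the initial configuration
#'
#' For each frame and subunit, superposes the frame onto the reference frame
#' using the alignment atom selection of that subunit, applies the fitted
#' transform to the target atoms, and reports their heavy-atom RMSD without
#' further fitting. With `scope = "global"` a single tetramer-wide fit on
#' the union of all subunits' alignment atoms is used instead (the
#' per-subunit target RMSD is still reported separately).
#'
#' @param ens an [ensemble()].
#' @param target a [ligand_spec()] or integer vector of residue sequence
#'   numbers; must resolve to at least one heavy atom per subunit.
#' @param align_on `"site_ca"` (default: C-alpha atoms within `site_radius`
#'   of the target's reference-frame centroid, falling back to all C-alpha
#'   of the subunit if fewer than 3 qualify), `"all_ca"`, or a named list of
#'   atom index vectors per subunit.
#' @param site_radius radius in Angstrom for `"site_ca"` (default 15).
#' @param reference_frame 1-based reference frame index (default 1, the
#'   initial configuration).
#' @param scope `"subunit"` (default) or `"global"`.
#' @param mass_weighted use atomic masses as superposition weights
#'   (default `FALSE`).
#' @return an object of class `rmsd_series`: `values` (T x S matrix of RMSD
#'   in Angstrom), `subunits`, `alignment` (descriptor string),
#'   `reference_frame`.
#' @export
rmsd_series <- function(ens, target, align_on = "site_ca", site_radius = 15,
                        reference_frame = 1, scope = c("subunit", "global"),
                        mass_weighted = FALSE) {
  scope <- match.arg(scope)
  top <- ens$topology
  nT <- n_frames(ens)
  if (reference_frame < 1 || reference_frame > nT)
    stop(sprintf("reference frame index %d out of range [1, %d]", reference_frame, nT))
  subs <- if (inherits(target, "ligand_spec")) {
    prot <- subunit_ids(top)[vapply(subunit_ids(top), function(s)
      any(top$subunit_id == s & startsWith(top$category, "protein")), logical(1))]
    intersect(prot, ligand_subunits(target))
  } else {
    subunit_ids(top)[vapply(subunit_ids(top), function(s)
      length(resolve_target(top, target, s)) > 0, logical(1))]
  }
  if (length(subs) == 0) stop("target resolves on no subunit")
  ref <- frame_coords(ens, reference_frame)

  tgt_idx <- lapply(subs, function(s) resolve_target(top, target, s))
  names(tgt_idx) <- subs
  if (any(lengths(tgt_idx) == 0))
    stop("target must resolve to at least one heavy atom per subunit")

  align_idx <- if (is.list(align_on)) {
    if (!all(subs %in% names(align_on))) stop("align_on list must name every subunit")
    align_on[subs]
  } else {
    lapply(setNames(subs, subs), function(s) {
      ca <- select_atoms(top, subunit = s, atom_name = "CA",
                         category = c("protein_backbone", "protein_sidechain"))
      if (identical(align_on, "site_ca")) {
        cen <- colMeans(ref[tgt_idx[[s]], , drop = FALSE])
        d <- sqrt(rowSums(sweep(ref[ca, , drop = FALSE], 2, cen)^2))
        sel <- ca[d <= site_radius]
        if (length(sel) >= 3) sel else ca
      } else ca
    })
  }
  if (any(lengths(align_idx) < 3))
    stop("alignment selection must resolve to at least 3 atoms per subunit")

  descr <- if (is.list(align_on)) "custom" else
    sprintf("%s%s, %s alignment", align_on,
            if (identical(align_on, "site_ca")) sprintf(" (%g A)", site_radius) else "",
            scope)
  values <- matrix(NA_real_, nT, length(subs), dimnames = list(NULL, subs))
  wts <- function(idx) if (mass_weighted) top$mass[idx] else NULL

  if (scope == "global") {
    gidx <- unlist(align_idx, use.names = FALSE)
    for (f in seq_len(nT)) {
      x <- frame_coords(ens, f)
      fit <- superpose(x[gidx, , drop = FALSE], ref[gidx, , drop = FALSE],
                       weights = wts(gidx))
      for (s in subs) {
        ti <- tgt_idx[[s]]
        values[f, s] <- coord_rmsd(apply_transform(x[ti, , drop = FALSE], fit),
                                   ref[ti, , drop = FALSE])
      }
    }
  } else {
    for (f in seq_len(nT)) {
      x <- frame_coords(ens, f)
      for (s in subs) {
        ai <- align_idx[[s]]; ti <- tgt_idx[[s]]
        fit <- superpose(x[ai, , drop = FALSE], ref[ai, , drop = FALSE],
                         weights = wts(ai))
        values[f, s] <- coord_rmsd(apply_transform(x[ti, , drop = FALSE], fit),
                                   ref[ti, , drop = FALSE])
      }
    }
  }
  structure(list(values = values, subunits = subs, alignment = descr,
                 reference_frame = reference_frame),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("RMSD series: %d frames x %d subunit(s) [%s], ref frame %d\n",
              nrow(x$values), length(x$subunits), x$alignment, x$reference_frame))
  cat("  time-averaged RMSD per subunit (A): ",
      paste(sprintf("%s=%.2f", x$subunits, colMeans(x$values)), collapse = " "), "\n")
  invisible(x)
}

#' Write a frame x subunit time series as TSV
#'
#' Long format with columns `frame`, `subunit`, `value`; used for RMSD and
#' distance series. An XVG flavor (`format = "xvg"`) writes one column per
#' subunit after an `@`-style header for plotting-tool compatibility.
#'
#' @param values T x S numeric matrix with subunit column names.
#' @param path output path.
#' @param format `"tsv"` or `"xvg"`.
#' @param ylab value label for the XVG header.
#' @return invisibly, `path`.
#' @export
write_series_tsv <- function(values, path, format = c("tsv", "xvg"),
                             ylab = "value") {
  format <- match.arg(format)
  con <- file(path, open = "wt")
  on.exit(close(con))
  subs <- colnames(values)
  if (format == "tsv") {
    writeLines("frame\tsubunit\tvalue", con)
    for (s in subs)
      writeLines(sprintf("%d\t%s\t%.6f", seq_len(nrow(values)), s, values[, s]), con)
  } else {
    writeLines(c("@    title \"time series\"",
                 "@    xaxis  label \"frame\"",
                 sprintf("@    yaxis  label \"%s\"", ylab),
                 sprintf("@ s%d legend \"%s\"", seq_along(subs) - 1, subs)), con)
    writeLines(apply(cbind(seq_len(nrow(values)), values), 1, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
  }
  invisible(path)
}
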