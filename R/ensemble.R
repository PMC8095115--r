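#' Construct a structural ensemble
#'
#' An ensemble is a fixed topology plus `T` coordinate frames (N x 3, in
#' Angstrom). Frame 1 is the reference ("initial") configuration for all
#' downstream analyses.
#'
#' @param topology a [topology()] object.
#' @param coords either a numeric array of dimension `c(N, 3, T)` or a list
#'   of `T` N x 3 matrices.
#' @return an object of class `ensemble` with elements `topology` and
#'   `coords` (N x 3 x T array).
#' @export
ensemble <- function(topology, coords) {
  if (!inherits(topology, "topology")) stop("ensemble: topology must be a 'topology' object")
  n <- nrow(topology)
  if (is.list(coords)) {
    if (length(coords) < 1) stop("ensemble: need at least one frame")
    coords <- vapply(coords, function(m) {
      m <- as.matrix(m)
      if (!all(dim(m) == c(n, 3)))
        stop(sprintf("ensemble: frame has %d x %d coordinates, expected %d x 3",
                     nrow(m), ncol(m), n))
      m
    }, matrix(0, n, 3))
    dim(coords) <- c(n, 3, length(coords) / (3L * n))
  }
  if (!is.array(coords) || length(dim(coords)) != 3 ||
      dim(coords)[1] != n || dim(coords)[2] != 3)
    stop(sprintf("ensemble: coords must be an N x 3 x T array with N = %d", n))
  if (dim(coords)[3] < 1) stop("ensemble: need at least one frame (T >= 1)")
  if (!all(is.finite(coords))) stop("ensemble: all coordinates must be finite")
  structure(list(topology = topology, coords = coords), class = "ensemble")
}

#' Number of frames in an ensemble
#' @param ens an `ensemble`.
#' @return integer.
#' @export
n_frames <- function(ens) dim(ens$coords)[3]

#' Number of atoms in an ensemble
#' @param ens an `ensemble`.
#' @return integer.
#' @export
n_atoms <- function(ens) dim(ens$coords)[1]

#' Coordinates of one frame
#' @param ens an `ensemble`.
#' @param frame 1-based frame index (frame 1 is the initial configuration).
#' @return N x 3 numeric matrix.
#' @export
frame_coords <- function(ens, frame) {
  if (frame < 1 || frame > n_frames(ens))
    stop(sprintf("frame index %d out of range [1, %d]", frame, n_frames(ens)))
  ens$coords[, , frame, drop = FALSE][, , 1]
}

#' Bounding-box sanity check
#'
#' Coordinates are taken as stored (pre-imaged); no periodic wrapping is
#' applied anywhere in the package. This check flags frames whose bounding
#' box diagonal exceeds a limit, which usually indicates an un-imaged or
#' corrupted trajectory.
#'
#' @param ens an `ensemble`.
#' @param limit maximum allowed bounding-box diagonal in Angstrom.
#' @return invisibly, an integer vector of offending frame indices; a
#'   warning is raised if any exist.
#' @export
check_bounding_box <- function(ens, limit = 500) {
  diag_len <- vapply(seq_len(n_frames(ens)), function(f) {
    x <- frame_coords(ens, f)
    sqrt(sum((apply(x, 2, max) - apply(x, 2, min))^2))
  }, numeric(1))
  bad <- which(diag_len > limit)
  if (length(bad) > 0)
    warning(sprintf("frame(s) %s have bounding-box diagonal > %g Angstrom; inputs must be pre-imaged",
                    paste(head(bad, 5), collapse = ","), limit))
  invisible(bad)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: %d frames x %d atoms, %d subunit(s)\n",
              n_frames(x), n_atoms(x), length(subunit_ids(x$topology))))
  invisible(x)
}

#' Define a ligand and its headgroup substructure
#'
#' A ligand specification names the ligand residues (one per subunit for a
#' symmetric multimer) and the atom names forming the polar "headgroup"
#' substructure used for contact and distance analyses. Headgroup membership
#' must be given explicitly: it is a chemical definition the coordinate data
#' do not carry.
#'
#' @param label short ligand label (e.g. `"PI"`).
#' @param residues data frame with columns `subunit_id`, `residue_seq`
#'   identifying the ligand residue(s).
#' @param headgroup_atoms nonempty character vector of headgroup atom names.
#' @return an object of class `ligand_spec`.
#' @export
ligand_spec <- function(label, residues, headgroup_atoms) {
  residues <- as.data.frame(residues, stringsAsFactors = FALSE)
  if (!all(c("subunit_id", "residue_seq") %in% names(residues)))
    stop("ligand_spec: residues needs columns subunit_id, residue_seq")
  residues$subunit_id <- as.character(residues$subunit_id)
  residues$residue_seq <- as.integer(residues$residue_seq)
  headgroup_atoms <- as.character(headgroup_atoms)
  if (length(headgroup_atoms) < 1) stop("ligand_spec: headgroup_atoms must be nonempty")
  structure(list(label = as.character(label), residues = residues,
                 headgroup_atoms = headgroup_atoms),
            class = "ligand_spec")
}

#' @export
print.ligand_spec <- function(x, ...) {
  cat(sprintf("Ligand '%s': %d residue(s) on subunit(s) %s; headgroup atoms: %s\n",
              x$label, nrow(x$residues),
              paste(unique(x$residues$subunit_id), collapse = ","),
              paste(x$headgroup_atoms, collapse = ",")))
  invisible(x)
}

# Atom indices of a ligand on one subunit; heavy headgroup atoms only when
# headgroup_only = TRUE. Errors if the headgroup resolves to no heavy atom.
ligand_atom_idx <- function(top, ligand, subunit, headgroup_only = FALSE,
                            heavy_only = TRUE) {
  res <- ligand$residues[ligand$residues$subunit_id == subunit, , drop = FALSE]
  if (nrow(res) == 0) return(integer(0))
  idx <- which(top$subunit_id == subunit &
                 top$residue_seq %in% res$residue_seq)
  if (headgroup_only) idx <- idx[top$atom_name[idx] %in% ligand$headgroup_atoms]
  if (heavy_only) idx <- idx[!top$is_hydrogen[idx]]
  idx
}

# Subunits on which a ligand_spec places ligand residues.
ligand_subunits <- function(ligand) unique(ligand$residues$subunit_id)

# Validate that each ligand residue resolves to >= 1 heavy headgroup atom.
check_ligand_resolves <- function(top, ligand) {
  for (s in ligand_subunits(ligand)) {
    if (length(ligand_atom_idx(top, ligand, s, headgroup_only = TRUE)) < 1)
      stop(sprintf("ligand '%s': no heavy headgroup atom resolves on subunit %s",
                   ligand$label, s))
  }
  invisible(TRUE)
}

#' Write a ligand specification to YAML
#' @param ligand a `ligand_spec`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_ligand_spec <- function(ligand, path) {
  yaml::write_yaml(list(label = ligand$label,
                        residues = lapply(seq_len(nrow(ligand$residues)), function(i)
                          list(subunit_id = ligand$residues$subunit_id[i],
                               residue_seq = ligand$residues$residue_seq[i])),
                        headgroup_atoms = as.list(ligand$headgroup_atoms)),
                   path)
  invisible(path)
}

#' Read a ligand specification from YAML
#' @param path file written by [write_ligand_spec()] (or hand-authored with
#'   the same keys).
#' @return a `ligand_spec`.
#' @export
read_ligand_spec <- function(path) {
  y <- yaml::read_yaml(path)
  res <- do.call(rbind, lapply(y$residues, function(r)
    data.frame(subunit_id = as.character(r$subunit_id),
               residue_seq = as.integer(r$residue_seq),
               stringsAsFactors = FALSE)))
  ligand_spec(y$label, res, unlist(y$headgroup_atoms))
}
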