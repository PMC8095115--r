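# Geometry constants of the schematic tetramer (Angstrom). The proxy
# protein is deliberately not a physical model: the analyses under test are
# purely geometric, so only distances and symmetry matter.
.syn_geom <- list(
  site_radius = 20,      # distance of each binding site from the C4 axis
  d_contact = 3.0,       # designed sidechain-tip -> headgroup distance, contact state
  d_far = 8.0,           # designed distance, non-contact state
  sigma_d = 0.3,         # radial sd of the designed distances
  backbone_radii = c(N = 11.0, CA = 12.5, C = 14.0, O = 15.5),
  sidechain_offsets = c(CB = 2.8, CG = 1.4, tip = 0),
  headgroup_offset = 0.8,
  tail_spacing = 1.4,
  water_park = 18        # parked (non-bridging) water height above the site
)

#' Specification of a synthetic C4-symmetric tetramer ensemble
#'
#' Defines the study conditions of the generator: a tetramer of four
#' symmetry-related subunits (90 degree rotations about z), each carrying a
#' schematic binding site with proxy residues, one bound ligand per
#' subunit, and a toggling bridge water. The defaults encode the designed
#' contrast the generator is built around: eight residues selective for
#' species A (contact probability 0.9 vs 0.1), six residues shared by both
#' species (0.9/0.9, one of them -- a glutamine-like polar residue -- in
#' permanent contact and carrying the water bridge), two selective for B,
#' four background residues, positionally stable A (ligand noise sd 0.5 A)
#' versus unstable B (2.0 A), and bridge occupancy 0.7 over 1000 frames.
#'
#' @param n_subunits number of subunits (fixed C4 design; default 4).
#' @param residues_per_subunit number of proxy residues (default 20).
#' @param ligands named list of species definitions, each a list with
#'   `sigma` (per-coordinate positional noise sd in Angstrom) and
#'   `contact_probs` (named numeric vector residue_seq -> probability;
#'   unnamed residues default to `background_prob`).
#' @param background_prob contact probability of undesigned residues
#'   (default 0.1).
#' @param sigma_protein per-coordinate protein positional noise sd
#'   (default 0: the analyses are benchmarked against a rigid scaffold).
#' @param bridge_residue residue_seq carrying the water bridge (default
#'   409); its contact probability is forced to 1 for both species so the
#'   bridge geometry is well defined in every frame.
#' @param bridge_occupancy designed per-frame bridge probability (default 0.7).
#' @param ligand_n_atoms heavy atoms per ligand including the 3-atom
#'   headgroup triad (default 12).
#' @param n_frames total frames including the noise-free initial
#'   configuration at frame 1 (default 1000).
#' @param seed integer PRNG seed (default 42).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subunits = 4L,
                           residues_per_subunit = 20L,
                           ligands = NULL,
                           background_prob = 0.1,
                           sigma_protein = 0,
                           bridge_residue = 409L,
                           bridge_occupancy = 0.7,
                           ligand_n_atoms = 12L,
                           n_frames = 1000L,
                           seed = 42L) {
  if (bridge_occupancy < 0 || bridge_occupancy > 1)
    stop("bridge_occupancy must be in [0, 1]")
  if (background_prob < 0 || background_prob > 1)
    stop("background_prob must be in [0, 1]")
  if (sigma_protein < 0) stop("sigma_protein must be >= 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (ligand_n_atoms < 3) stop("ligand_n_atoms must be >= 3 (headgroup triad)")
  first_seq <- 401L
  seqs <- seq.int(first_seq, length.out = residues_per_subunit)
  if (is.null(ligands)) {
    sel_a <- seqs[1:8]                      # selective for A
    shared <- seqs[9:14]                    # shared, includes the bridge residue
    sel_b <- seqs[15:16]                    # selective for B
    pa <- setNames(rep(background_prob, length(seqs)), seqs)
    pb <- pa
    pa[as.character(sel_a)] <- 0.9; pb[as.character(sel_a)] <- background_prob
    pa[as.character(shared)] <- 0.9; pb[as.character(shared)] <- 0.9
    pa[as.character(sel_b)] <- background_prob; pb[as.character(sel_b)] <- 0.9
    ligands <- list(A = list(sigma = 0.5, contact_probs = pa),
                    B = list(sigma = 2.0, contact_probs = pb))
  }
  if (is.null(names(ligands)) || any(names(ligands) == ""))
    stop("ligands must be a named list of species")
  for (nm in names(ligands)) {
    lg <- ligands[[nm]]
    if (is.null(lg$sigma) || lg$sigma < 0)
      stop("ligand '", nm, "': sigma must be >= 0")
    p <- lg$contact_probs
    if (!is.null(p) && (any(p < 0) || any(p > 1)))
      stop("ligand '", nm, "': contact probabilities must be in [0, 1]")
  }
  if (!bridge_residue %in% seqs) stop("bridge_residue must be one of the residues")
  # force the bridge residue into permanent contact for every species
  for (nm in names(ligands)) {
    p <- ligands[[nm]]$contact_probs
    if (is.null(p)) p <- setNames(rep(background_prob, length(seqs)), seqs)
    miss <- setdiff(as.character(seqs), names(p))
    p[miss] <- background_prob
    p[as.character(bridge_residue)] <- 1.0
    ligands[[nm]]$contact_probs <- p[as.character(seqs)]
  }
  structure(list(n_subunits = as.integer(n_subunits),
                 residues_per_subunit = as.integer(residues_per_subunit),
                 residue_seqs = seqs, ligands = ligands,
                 background_prob = background_prob,
                 sigma_protein = sigma_protein,
                 bridge_residue = as.integer(bridge_residue),
                 bridge_occupancy = bridge_occupancy,
                 ligand_n_atoms = as.integer(ligand_n_atoms),
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Rotation about z by `ang` radians.
rot_z <- function(ang) {
  matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
}

# Residue direction unit vectors for subunit 1: spread over the octant with
# negative x and y components so the headgroup anchor atom (at the site
# center) is always the nearest headgroup atom -- designed radial distances
# are then exact minimum distances.
residue_directions <- function(n) {
  phi <- seq(190, 260, length.out = n) * pi / 180
  psi <- rep_len(c(-40, -15, 10, 35, -27, 22) * pi / 180, n)
  cbind(cos(psi) * cos(phi), cos(psi) * sin(phi), sin(psi))
}

# Residue names of the proxy site: polar residues get an oxygen sidechain
# tip (name OG), apolar ones a carbon tip (name CD). The bridge residue is
# glutamine-like.
.syn_polar <- c("SER", "THR", "ASN", "GLN", "ASP", "GLU", "TYR", "LYS", "ARG", "HIS")
syn_residue_names <- function(seqs, bridge_residue) {
  pool <- c("ASP", "SER", "LYS", "LEU", "ILE", "VAL", "THR", "PHE", "GLU",
            "MET", "ALA", "TYR", "ASN", "TRP", "ARG", "HIS", "CYS", "PRO")
  nm <- rep_len(pool, length(seqs))
  nm[seqs == bridge_residue] <- "GLN"
  nm
}

#' Generate a synthetic tetramer ensemble with known ground truth
#'
#' Builds the schematic C4 tetramer of [synthetic_spec()] for one ligand
#' species and samples `n_frames` coordinate frames. Frame 1 is the
#' noise-free base configuration (the "initial configuration" reference);
#' in every later frame each designed residue is placed, independently per
#' frame and subunit, at the contact distance (3 A, probability p) or
#' beyond the cutoff shell (8 A, probability 1 - p) along its fixed radial
#' direction with 0.3 A radial noise. The designed distance is realized
#' against the actual, jittered headgroup positions of that frame, so the
#' realized contact states equal the designed Bernoulli draws exactly
#' (when `sigma_protein = 0`) regardless of the ligand noise level.
#' Ligand atoms are jittered with the
#' species' per-coordinate Gaussian noise; the bridge water toggles between
#' a bridging midpoint position and a parked position with the designed
#' occupancy. All random draws are made as whole arrays in one documented
#' order from a single seeded stream, so output is deterministic and
#' independent of assembly-loop order.
#'
#' @param spec a [synthetic_spec()].
#' @param species which ligand species to bind (default the first).
#' @param seed optional seed override (default `spec$seed`, offset by the
#'   species index so the two species' ensembles are independent).
#' @return a list of class `synthetic_ensemble` with elements `ensemble`
#'   ([ensemble()]), `ligand` ([ligand_spec()]) and `truth` (ground-truth
#'   list: `design` residue table with per-species probabilities, designed
#'   classes at threshold 0.5 and expected mean separations; `sigma`;
#'   `bridge_residue`; `bridge_occupancy`; geometry constants).
#' @export
generate_ensemble <- function(spec, species = names(spec$ligands)[1],
                              seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!species %in% names(spec$ligands)) stop("unknown ligand species: ", species)
  gm <- .syn_geom
  S <- spec$n_subunits
  R <- spec$residues_per_subunit
  nT <- spec$n_frames
  seqs <- spec$residue_seqs
  lg <- spec$ligands[[species]]
  p <- unname(lg$contact_probs)
  if (is.null(seed)) seed <- spec$seed + 131L * (match(species, names(spec$ligands)) - 1L)

  rnames <- syn_residue_names(seqs, spec$bridge_residue)
  tipname <- ifelse(rnames %in% .syn_polar, "OG", "CD")
  tipel <- ifelse(rnames %in% .syn_polar, "O", "C")
  u1 <- residue_directions(R)
  chains <- LETTERS[seq_len(S)]
  rots <- lapply(seq_len(S), function(s) rot_z((s - 1) * 2 * pi / S))
  L1 <- c(gm$site_radius, 0, 0)

  # --- topology and base coordinates (subunit 1, then rotated copies) ---
  n_tail <- spec$ligand_n_atoms - 3L
  one_sub <- function() {
    prot <- do.call(rbind, lapply(seq_len(R), function(r) data.frame(
      atom_name = c("N", "CA", "C", "O", "CB", "CG", tipname[r]),
      element = c("N", "C", "C", "O", "C", "C", tipel[r]),
      residue_seq = seqs[r], residue_name = rnames[r],
      stringsAsFactors = FALSE)))
    lig <- data.frame(
      atom_name = c("P1", "O2", "O3", if (n_tail > 0) paste0("C", seq_len(n_tail))),
      element = c("P", "O", "O", rep("C", n_tail)),
      residue_seq = 500L, residue_name = paste0("LG", substr(species, 1, 1)),
      stringsAsFactors = FALSE)
    wat <- data.frame(atom_name = "O", element = "O",
                      residue_seq = c(901L, 902L, 903L), residue_name = "HOH",
                      stringsAsFactors = FALSE)
    rbind(prot, lig, wat)
  }
  sub_tab <- one_sub()
  n_per_sub <- nrow(sub_tab)
  atoms <- do.call(rbind, lapply(seq_len(S), function(s) {
    t <- sub_tab; t$subunit_id <- chains[s]; t
  }))
  atoms$atom_id <- seq_len(nrow(atoms))
  atoms$is_hydrogen <- FALSE
  atoms$category <- rep(c(rep(c("protein_backbone", "protein_backbone",
                                "protein_backbone", "protein_backbone",
                                "protein_sidechain", "protein_sidechain",
                                "protein_sidechain"), R),
                          rep("ligand", spec$ligand_n_atoms),
                          rep("water", 3L)), S)
  top <- topology(atoms)

  # base positions, subunit 1 (sidechain tips at the contact state iff the
  # designed probability >= 0.5 defines the base/initial configuration)
  base_d <- ifelse(p >= 0.5, gm$d_contact, gm$d_far)
  sub1_base <- function(d_tip) {
    out <- matrix(NA_real_, n_per_sub, 3)
    for (r in seq_len(R)) {
      o <- (r - 1) * 7L
      rad <- c(gm$backbone_radii,
               d_tip[r] + gm$sidechain_offsets[c("CB", "CG")], d_tip[r])
      out[o + 1:7, ] <- rep(L1, each = 7) + rad * u1[rep(r, 7), ]
    }
    lo <- R * 7L
    out[lo + 1, ] <- L1
    out[lo + 2, ] <- L1 + c(gm$headgroup_offset, 0, 0)
    out[lo + 3, ] <- L1 + c(0, gm$headgroup_offset, 0)
    if (n_tail > 0) {
      for (jj in seq_len(n_tail))
        out[lo + 3 + jj, ] <- L1 + c(1.5 + gm$tail_spacing * (jj - 1),
                                     0.3 * (-1)^jj, 0.4 * (jj %% 3 - 1))
    }
    wo <- lo + spec$ligand_n_atoms
    out[wo + 1, ] <- L1 + c(0, 0, gm$water_park)        # bridge water, parked
    out[wo + 2, ] <- L1 + c(0, 0, -gm$water_park)       # bulk water
    out[wo + 3, ] <- L1 + c(3, 3, gm$water_park - 2)    # bulk water
    out
  }

  # index helpers within one subunit block
  tip_off <- (seq_len(R) - 1) * 7L + 7L
  cg_off <- tip_off - 1L
  cb_off <- tip_off - 2L
  lig_off <- R * 7L + seq_len(spec$ligand_n_atoms)
  hg_anchor_off <- R * 7L + 1L                     # P1, the nearest headgroup atom
  hg_o2_off <- R * 7L + 2L
  bw_off <- R * 7L + spec$ligand_n_atoms + 1L      # bridge water oxygen
  bridge_r <- match(spec$bridge_residue, seqs)
  prot_off <- seq_len(R * 7L)

  # --- random draws: one stream, whole arrays, fixed documented order ---
  set.seed(seed)
  nS <- nT - 1L
  contact <- array(runif(nS * S * R), c(nS, S, R)) <=
    aperm(array(p, c(R, nS, S)), c(2, 3, 1))
  dnoise <- array(rnorm(nS * S * R, 0, gm$sigma_d), c(nS, S, R))
  lignoise <- array(rnorm(nS * S * spec$ligand_n_atoms * 3, 0, lg$sigma),
                    c(nS, S, spec$ligand_n_atoms, 3))
  protnoise <- if (spec$sigma_protein > 0)
    array(rnorm(nS * S * R * 7 * 3, 0, spec$sigma_protein), c(nS, S, R * 7, 3))
  else NULL
  bridging <- matrix(runif(nS * S), nS, S) <= spec$bridge_occupancy

  # --- frame assembly ---
  base1 <- sub1_base(base_d)
  base_by_sub <- lapply(seq_len(S), function(s) base1 %*% t(rots[[s]]))
  coords <- array(NA_real_, c(nrow(atoms), 3, nT))
  place_bridge <- function(mat, s, is_bridging) {
    tip <- mat[tip_off[bridge_r], ]
    o2 <- mat[hg_o2_off, ]
    if (is_bridging) {
      mat[bw_off, ] <- (tip + o2) / 2
    } else {
      mat[bw_off, ] <- base_by_sub[[s]][bw_off, ]
    }
    mat
  }
  for (s in seq_len(S)) {
    blk <- (s - 1) * n_per_sub
    m <- place_bridge(base_by_sub[[s]], s, spec$bridge_occupancy >= 0.5)
    coords[blk + seq_len(n_per_sub), , 1] <- m
  }
  us_by_sub <- lapply(rots, function(Rz) u1 %*% t(Rz))
  Ls_by_sub <- lapply(rots, function(Rz) as.numeric(Rz %*% L1))
  hg_off <- R * 7L + 1:3
  for (f in seq_len(nS)) {
    for (s in seq_len(S)) {
      blk <- (s - 1) * n_per_sub
      m <- base_by_sub[[s]]
      m[lig_off, ] <- m[lig_off, ] + lignoise[f, s, , ]
      us <- us_by_sub[[s]]
      Ls <- Ls_by_sub[[s]]
      d_tip <- ifelse(contact[f, s, ], gm$d_contact, gm$d_far) + dnoise[f, s, ]
      # Place each sidechain tip along its fixed radial ray so that the
      # minimum distance to the ACTUAL (jittered) headgroup triad equals
      # the designed distance: for each headgroup atom j with perpendicular
      # offset below d, the ray leaves its d-sphere at
      # proj_j + sqrt(d^2 - perp_j^2); taking the maximum over j puts the
      # tip at distance exactly d from the nearest atom and >= d from the
      # rest, so realized contact states equal the designed Bernoulli draws.
      Ha <- m[hg_off, , drop = FALSE]
      Hrel <- sweep(Ha, 2, Ls)
      proj <- us %*% t(Hrel)                              # R x 3
      perp2 <- matrix(rowSums(Hrel^2), R, 3, byrow = TRUE) - proj^2
      perp2[perp2 < 0] <- 0
      root2 <- d_tip^2 - perp2                            # recycles per column
      under <- root2 >= 0
      g <- proj + ifelse(under, sqrt(pmax(root2, 0)), 0)
      xstar <- pmax(g[, 1], g[, 2], g[, 3])
      tip <- matrix(Ls, R, 3, byrow = TRUE) + xstar * us
      # under extreme jitter the exit point can be dominated by an atom the
      # ray never approaches within d, leaving every atom farther than the
      # design; anchor such contact tips directly on the first headgroup
      # atom so the contact still lands inside the cutoff shell
      dmin2 <- pmin((xstar - proj[, 1])^2 + perp2[, 1],
                    (xstar - proj[, 2])^2 + perp2[, 2],
                    (xstar - proj[, 3])^2 + perp2[, 3])
      fb <- contact[f, s, ] & dmin2 > d_tip^2 + 1e-9
      if (any(fb))
        tip[fb, ] <- matrix(Ha[1, ], sum(fb), 3, byrow = TRUE) +
          d_tip[fb] * us[fb, , drop = FALSE]
      m[tip_off, ] <- tip
      m[cg_off, ] <- tip + gm$sidechain_offsets["CG"] * us
      m[cb_off, ] <- tip + gm$sidechain_offsets["CB"] * us
      if (!is.null(protnoise)) m[prot_off, ] <- m[prot_off, ] + protnoise[f, s, , ]
      m <- place_bridge(m, s, bridging[f, s])
      coords[blk + seq_len(n_per_sub), , f + 1] <- m
    }
  }

  ens <- ensemble(top, coords)
  lig_spec <- ligand_spec(species,
                          data.frame(subunit_id = chains, residue_seq = 500L,
                                     stringsAsFactors = FALSE),
                          headgroup_atoms = c("P1", "O2", "O3"))

  probs <- lapply(spec$ligands, function(l) unname(l$contact_probs))
  cls <- rep("background", R)
  if (length(probs) >= 2) {
    pa <- probs[[1]]; pb <- probs[[2]]
    cls <- ifelse(pa >= 0.5 & pb < 0.5, "selective_A",
                  ifelse(pb >= 0.5 & pa < 0.5, "selective_B",
                         ifelse(pa >= 0.5 & pb >= 0.5, "shared", "background")))
  }
  design <- data.frame(residue_seq = seqs, residue_name = rnames,
                       stringsAsFactors = FALSE)
  for (nm in names(probs)) {
    design[[paste0("p_", nm)]] <- probs[[nm]]
    design[[paste0("mean_sep_", nm)]] <-
      probs[[nm]] * gm$d_contact + (1 - probs[[nm]]) * gm$d_far
  }
  design$class <- cls
  truth <- list(design = design,
                sigma = setNames(vapply(spec$ligands, `[[`, numeric(1), "sigma"),
                                 names(spec$ligands)),
                bridge_residue = spec$bridge_residue,
                bridge_occupancy = spec$bridge_occupancy,
                d_contact = gm$d_contact, d_far = gm$d_far,
                sigma_d = gm$sigma_d, species = species, seed = seed)
  structure(list(ensemble = ens, ligand = lig_spec, truth = truth),
            class = "synthetic_ensemble")
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  cat(sprintf("Synthetic tetramer ensemble, species '%s' (seed %d):\n",
              x$truth$species, x$truth$seed))
  print(x$ensemble)
  invisible(x)
}

#' Write a synthetic ensemble to a fixture directory
#'
#' Writes `ensemble.pdb` (multi-model PDB), `ligand.yaml` (the ligand
#' specification) and `ground_truth.yaml` (the designed values) so the
#' fixture can be re-read with [read_structure_ensemble()] and
#' [read_ligand_spec()].
#'
#' @param gen a `synthetic_ensemble` from [generate_ensemble()].
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of the file paths written.
#' @export
write_fixture <- function(gen, dir) {
  stopifnot(inherits(gen, "synthetic_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ensemble = file.path(dir, "ensemble.pdb"),
             ligand = file.path(dir, "ligand.yaml"),
             truth = file.path(dir, "ground_truth.yaml"))
  write_ensemble_pdb(gen$ensemble, paths["ensemble"])
  write_ligand_spec(gen$ligand, paths["ligand"])
  tr <- gen$truth
  tr$design <- lapply(seq_len(nrow(tr$design)), function(i) as.list(tr$design[i, ]))
  tr$sigma <- as.list(tr$sigma)
  yaml::write_yaml(tr, paths["truth"])
  invisible(paths)
}

#' Classification rules for synthetic fixtures
#'
#' The default [classify_rules()] extended with the generator's ligand
#' residue names (`LGA`, `LGB`, ... by species initial).
#'
#' @param species ligand species labels (default `c("A", "B")`).
#' @return a `classify_rules` object.
#' @export
synthetic_rules <- function(species = c("A", "B")) {
  classify_rules(ligand_residues = paste0("LG", substr(species, 1, 1)))
}
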