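# Small programmatic fixtures and independent oracles shared across tests.

# Single-subunit toy system: one alanine whose CB sidechain atom follows
# `sc` (T x 3), one ligand whose single headgroup atom P1 follows `hg`
# (T x 3); optional water oxygen following `wat`. A fixed CA/backbone keeps
# superposition well defined.
toy_site_ensemble <- function(sc, hg, wat = NULL) {
  sc <- matrix(sc, ncol = 3); hg <- matrix(hg, ncol = 3)
  stopifnot(nrow(sc) == nrow(hg))
  atoms <- data.frame(
    atom_id = 1:2, atom_name = c("CA", "CB"), element = "C",
    residue_seq = 1L, residue_name = "ALA", subunit_id = "A",
    stringsAsFactors = FALSE)
  lig <- data.frame(atom_id = 3L, atom_name = "P1", element = "P",
                    residue_seq = 99L, residue_name = "LIG", subunit_id = "A",
                    stringsAsFactors = FALSE)
  tab <- rbind(atoms, lig)
  if (!is.null(wat)) {
    wat <- matrix(wat, ncol = 3)
    tab <- rbind(tab, data.frame(atom_id = 4L, atom_name = "O", element = "O",
                                 residue_seq = 200L, residue_name = "HOH",
                                 subunit_id = "A", stringsAsFactors = FALSE))
  }
  top <- topology(tab, rules = classify_rules(ligand_residues = "LIG"))
  nT <- nrow(sc)
  n <- nrow(tab)
  coords <- array(NA_real_, c(n, 3, nT))
  for (f in seq_len(nT)) {
    coords[1, , f] <- c(0, 0, 10)
    coords[2, , f] <- sc[f, ]
    coords[3, , f] <- hg[f, ]
    if (!is.null(wat)) coords[4, , f] <- wat[f, ]
  }
  ensemble(top, coords)
}

toy_ligand <- function() {
  ligand_spec("L", data.frame(subunit_id = "A", residue_seq = 99L),
              headgroup_atoms = "P1")
}

# Independent O(N^2) contact oracle: TRUE for each query atom within the
# cutoff (closed boundary) of any reference atom. Deliberately written
# without any package helper.
brute_within <- function(query, ref, cutoff) {
  vapply(seq_len(nrow(query)), function(i) {
    any(sqrt((ref[, 1] - query[i, 1])^2 + (ref[, 2] - query[i, 2])^2 +
               (ref[, 3] - query[i, 3])^2) <= cutoff)
  }, logical(1))
}

# Independent brute-force minimum distance.
brute_min_dist <- function(a, b) {
  m <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    m <- min(m, sqrt(sum((a[i, ] - b[j, ])^2)))
  m
}

# A small synthetic spec used where full study-size runs are unnecessary.
quick_spec <- function(n_frames = 120, seed = 7, ...) {
  synthetic_spec(n_frames = n_frames, seed = seed, ...)
}

# Write an A/B fixture pair plus a pipeline config list into `dir`.
make_pipeline_config <- function(dir, n_frames = 40, seed = 5,
                                 with_reference = FALSE) {
  spec <- synthetic_spec(n_frames = n_frames, seed = seed)
  genA <- generate_ensemble(spec, "A")
  genB <- generate_ensemble(spec, "B")
  pA <- write_fixture(genA, file.path(dir, "A"))
  pB <- write_fixture(genB, file.path(dir, "B"))
  conds <- list(
    A = list(ensemble = unname(pA["ensemble"]), ligand = unname(pA["ligand"])),
    B = list(ensemble = unname(pB["ensemble"]), ligand = unname(pB["ligand"])))
  if (with_reference) {
    ref <- atomic_density_map(genA$ensemble, genA$ligand, frames = 1)
    refp <- file.path(dir, "ref_A.dx")
    write_density_map(ref, refp)
    conds$A$reference_map <- refp
  }
  list(cfg = list(conditions = conds,
                  selectivity_pairs = list(c("A", "B")),
                  bridge_residue = 409L,
                  density_stride = 10L,
                  outdir = file.path(dir, "out"),
                  seed = seed),
       truth = genA$truth)
}
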