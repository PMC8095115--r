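single_atom_ens <- function(pos_frames, element = "C", mass = NULL) {
  tab <- data.frame(atom_id = 1L, atom_name = "X1", element = element,
                    residue_seq = 1L, residue_name = "LIG", subunit_id = "A",
                    stringsAsFactors = FALSE)
  if (!is.null(mass)) tab$mass <- mass
  top <- topology(tab, rules = classify_rules(ligand_residues = "LIG"))
  pos_frames <- matrix(pos_frames, ncol = 3)
  coords <- array(NA_real_, c(1, 3, nrow(pos_frames)))
  for (f in seq_len(nrow(pos_frames))) coords[1, , f] <- pos_frames[f, ]
  ensemble(top, coords)
}

test_that("a single atom deposits its full mass", {
  ens <- single_atom_ens(c(0.13, -0.4, 2.2))   # carbon, mass 12.011
  m <- atomic_density_map(ens, 1L)
  expect_lt(abs(map_integral(m) - 12.011) / 12.011, 0.01)
  expect_identical(m$weight_mode, "mass")
  expect_true(all(m$values >= 0))
})

test_that("averaging identical frames is idempotent and linear over frames", {
  ens2 <- single_atom_ens(rbind(c(1, 1, 1), c(1, 1, 1)))
  ens1 <- single_atom_ens(c(1, 1, 1))
  m2 <- atomic_density_map(ens2, 1L)
  m1 <- atomic_density_map(ens1, 1L)
  expect_equal(m2$values, m1$values)
  expect_equal(m2$origin, m1$origin)
  # two swapping atoms keep the grid fixed: T-average equals mean of
  # per-frame maps exactly
  tab <- data.frame(atom_id = 1:2, atom_name = c("X1", "X2"), element = "C",
                    residue_seq = 1L, residue_name = "LIG", subunit_id = "A",
                    stringsAsFactors = FALSE)
  top <- topology(tab, rules = classify_rules(ligand_residues = "LIG"))
  f1 <- rbind(c(0, 0, 0), c(3, 0, 0))
  coords <- array(c(f1, f1[2:1, ]), c(2, 3, 2))
  coords[, , 2] <- f1[2:1, ]
  ens <- ensemble(top, coords)
  mt <- atomic_density_map(ens, 1:2)
  ma <- atomic_density_map(ens, 1:2, frames = 1)
  mb <- atomic_density_map(ens, 1:2, frames = 2)
  expect_equal(mt$values, (ma$values + mb$values) / 2, tolerance = 1e-12)
})

test_that("two atoms deposit the summed mass with peaks at the centers", {
  tab <- data.frame(atom_id = 1:2, atom_name = c("C1", "O1"),
                    element = c("C", "O"), residue_seq = 1L,
                    residue_name = "LIG", subunit_id = "A",
                    stringsAsFactors = FALSE)
  tab$mass <- c(12, 16)
  top <- topology(tab, rules = classify_rules(ligand_residues = "LIG"))
  pos <- rbind(c(0, 0, 0), c(6, 0, 0))
  ens <- ensemble(top, array(pos, c(2, 3, 1)))
  m <- atomic_density_map(ens, 1:2)
  expect_lt(abs(map_integral(m) - 28) / 28, 0.01)
  # strongest voxel near the heavier atom, within one voxel of its center
  peak <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
  peak_xyz <- m$origin + m$spacing * (peak - 1)
  expect_lt(sqrt(sum((peak_xyz - pos[2, ])^2)), m$spacing * sqrt(3) + 1e-9)
})

test_that("hydrogens are excluded and empty selections rejected", {
  tab <- data.frame(atom_id = 1:2, atom_name = c("C1", "H1"),
                    element = c("C", "H"), residue_seq = 1L,
                    residue_name = "LIG", subunit_id = "A",
                    stringsAsFactors = FALSE)
  top <- topology(tab, rules = classify_rules(ligand_residues = "LIG"))
  ens <- ensemble(top, array(rbind(c(0, 0, 0), c(1, 0, 0)), c(2, 3, 1)))
  m <- atomic_density_map(ens, 1:2)
  expect_lt(abs(map_integral(m) - 12.011) / 12.011, 0.01)
  expect_error(atomic_density_map(ens, 2L), "no heavy atom")
  expect_error(atomic_density_map(ens, 1L, resolution = -1), "resolution")
})

test_that("map correlation honors identity, anti-identity and bounds", {
  set.seed(404)
  a <- density_map(c(0, 0, 0), 1, array(runif(64, 0.5, 1), c(4, 4, 4)))
  expect_equal(map_correlation(a, a)$correlation, 1.0)
  # negation about the mean: centered Pearson of -1
  neg <- density_map(c(0, 0, 0), 1, 2 * mean(a$values) - a$values)
  expect_equal(map_correlation(a, neg, center = TRUE)$correlation, -1.0)
  cmp <- map_correlation(a, neg)
  expect_true(cmp$correlation >= -1 && cmp$correlation <= 1)
  expect_gt(cmp$n_voxels_compared, 0)
  # disjoint maps rejected
  far <- density_map(c(100, 100, 100), 1, a$values)
  expect_error(map_correlation(a, far), "no overlapping voxels")
})

test_that("offset-Gaussian correlation follows the analytic overlap decay", {
  mk <- function(pos) atomic_density_map(single_atom_ens(pos), 1L,
                                         resolution = 0.5, atom_size = 1.0,
                                         weight_mode = "occupancy")
  a <- mk(c(0, 0, 0))
  cors <- vapply(c(0, 1, 2, 4), function(d)
    map_correlation(a, mk(c(d, 0, 0)))$correlation, numeric(1))
  expect_true(all(diff(cors) < 0))
  expect_true(all(abs(cors - exp(-c(0, 1, 2, 4)^2 / 4)) < 0.02))
})

test_that("correlation is symmetric under resampling direction within 0.02", {
  mk <- function(pos) atomic_density_map(single_atom_ens(pos), 1L,
                                         resolution = 0.5, atom_size = 1.0)
  a <- mk(c(0, 0, 0)); b <- mk(c(1.3, 0.4, -0.7))
  expect_lt(abs(map_correlation(a, b)$correlation -
                  map_correlation(b, a)$correlation), 0.02)
})

test_that("water occupancy requires proximity to both anchors", {
  nT <- 3
  sc <- matrix(rep(c(0, 0, 0), nT), ncol = 3, byrow = TRUE)
  hg <- matrix(rep(c(4, 0, 0), nT), ncol = 3, byrow = TRUE)
  # water within 6 A of both anchors in every frame
  wat_in <- matrix(rep(c(2, 0, 0), nT), ncol = 3, byrow = TRUE)
  ens_in <- toy_site_ensemble(sc, hg, wat = wat_in)
  m3 <- water_occupancy_map(ens_in, 1, toy_ligand())
  expect_gt(map_integral(m3), 0.9)
  # occupancy is constant across frame counts for a constant water
  ens6 <- toy_site_ensemble(rbind(sc, sc), rbind(hg, hg), wat = rbind(wat_in, wat_in))
  m6 <- water_occupancy_map(ens6, 1, toy_ligand())
  expect_equal(m6$values, m3$values, tolerance = 1e-12)
  # within 6 A of the residue but 10 A from the ligand: excluded
  wat_out <- matrix(rep(c(-6, 0, 0), nT), ncol = 3, byrow = TRUE)
  m0 <- water_occupancy_map(toy_site_ensemble(sc, hg, wat = wat_out), 1, toy_ligand())
  expect_equal(map_integral(m0), 0)
  # no water at all is an error
  expect_error(water_occupancy_map(toy_site_ensemble(sc, hg), 1, toy_ligand()),
               "no water")
})

test_that("water bridges require simultaneous proximity to both polar anchors", {
  nT <- 2
  sc <- matrix(rep(c(0, 0, 0), nT), ncol = 3, byrow = TRUE)
  hg <- matrix(rep(c(5.6, 0, 0), nT), ncol = 3, byrow = TRUE)
  mk_ens <- function(wat, sc_name = "OG", sc_el = "O", res = "SER") {
    tab <- data.frame(
      atom_id = 1:4,
      atom_name = c("CA", sc_name, "O2", "O"),
      element = c("C", sc_el, "O", "O"),
      residue_seq = c(1L, 1L, 99L, 200L),
      residue_name = c(res, res, "LIG", "HOH"),
      subunit_id = "A", stringsAsFactors = FALSE)
    top <- topology(tab, rules = classify_rules(ligand_residues = "LIG"))
    coords <- array(NA_real_, c(4, 3, nT))
    for (f in seq_len(nT)) {
      coords[1, , f] <- c(0, 0, 10); coords[2, , f] <- sc[f, ]
      coords[3, , f] <- hg[f, ]; coords[4, , f] <- wat[f, ]
    }
    ensemble(top, coords)
  }
  lig <- ligand_spec("L", data.frame(subunit_id = "A", residue_seq = 99L), "O2")
  # water at 2.8 A from both polar anchors: bridge
  wat <- matrix(rep(c(2.8, 0, 0), nT), ncol = 3, byrow = TRUE)
  br <- water_bridge_frequency(mk_ens(wat), 1, lig)
  expect_equal(br$bridge_frequency, 1.0)
  # water at 2.8 A from the residue but 5.0 A from the ligand: no bridge
  wat2 <- matrix(rep(c(0.6, -2.734, 0), nT), ncol = 3, byrow = TRUE)
  expect_lt(sqrt(sum((wat2[1, ] - sc[1, ])^2)), 2.81)
  expect_gt(sqrt(sum((wat2[1, ] - hg[1, ])^2)), 4.99)
  br2 <- water_bridge_frequency(mk_ens(wat2), 1, lig)
  expect_equal(br2$bridge_frequency, 0.0)
  # apolar sidechain rejected, naming the residue
  expect_error(water_bridge_frequency(mk_ens(wat, sc_name = "CB", sc_el = "C",
                                             res = "LEU"), 1, lig),
               "LEU1")
})

test_that("designed bridge occupancy is recovered within the binomial envelope", {
  nT <- 400
  gen <- generate_ensemble(quick_spec(n_frames = nT, seed = 9))
  br <- water_bridge_frequency(gen$ensemble, gen$truth$bridge_residue, gen$ligand)
  p <- gen$truth$bridge_occupancy
  expect_lt(abs(br$bridge_frequency - p), 3 * sqrt(p * (1 - p) / nT) + 1 / nT)
})
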