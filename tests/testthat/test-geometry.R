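test_that("minimum distances reproduce closed-form and degenerate cases", {
  # 3-4-5 triangle: sidechain at origin, headgroup at (3,4,0)
  nT <- 2
  sc <- matrix(rep(c(0, 0, 0), nT), ncol = 3, byrow = TRUE)
  hg <- matrix(rep(c(3, 4, 0), nT), ncol = 3, byrow = TRUE)
  ser <- min_distance_series(toy_site_ensemble(sc, hg), 1, toy_ligand())
  expect_equal(ser$series[["1"]]$overall_mean, 5.0)
  expect_equal(unname(ser$series[["1"]]$d[, "A"]), c(5, 5))
  # coincident atoms
  ser0 <- min_distance_series(toy_site_ensemble(sc, sc), 1, toy_ligand())
  expect_equal(ser0$series[["1"]]$overall_mean, 0.0)
})

test_that("minimum distances equal the brute-force oracle on random frames", {
  set.seed(202)
  # 20 atoms per side over 50 frames, multi-atom residue and headgroup
  n_sc <- 20; n_hg <- 20; nT <- 50
  tab <- rbind(
    data.frame(atom_id = 1:2, atom_name = c("N", "CA"), element = c("N", "C"),
               residue_seq = 1L, residue_name = "LYS", subunit_id = "A",
               stringsAsFactors = FALSE),
    data.frame(atom_id = 2 + seq_len(n_sc), atom_name = paste0("C", seq_len(n_sc)),
               element = "C", residue_seq = 1L, residue_name = "LYS",
               subunit_id = "A", stringsAsFactors = FALSE),
    data.frame(atom_id = 2 + n_sc + seq_len(n_hg),
               atom_name = paste0("O", seq_len(n_hg)), element = "O",
               residue_seq = 99L, residue_name = "LIG", subunit_id = "A",
               stringsAsFactors = FALSE))
  top <- topology(tab, rules = classify_rules(ligand_residues = "LIG"))
  coords <- array(runif(nrow(tab) * 3 * nT, -10, 10), c(nrow(tab), 3, nT))
  ens <- ensemble(top, coords)
  lig <- ligand_spec("L", data.frame(subunit_id = "A", residue_seq = 99L),
                     paste0("O", seq_len(n_hg)))
  ser <- min_distance_series(ens, 1, lig)
  sc_rows <- 2 + seq_len(n_sc); hg_rows <- 2 + n_sc + seq_len(n_hg)
  for (f in seq_len(nT)) {
    expect_equal(unname(ser$series[["1"]]$d[f, "A"]),
                 brute_min_dist(coords[sc_rows, , f], coords[hg_rows, , f]))
  }
})

test_that("residues without sidechain heavy atoms give a per-residue error entry", {
  nT <- 2
  sc <- matrix(rep(c(1, 0, 0), nT), ncol = 3, byrow = TRUE)
  ens <- toy_site_ensemble(sc, sc + 1)
  ser <- min_distance_series(ens, c(1, 77), toy_ligand())
  expect_named(ser$series, "1")
  expect_match(ser$errors[["77"]], "no sidechain heavy atoms")
})

test_that("mean-separation report sorts, summarizes and flags by margin", {
  nT <- 4
  sc <- matrix(rep(c(2, 0, 0), nT), ncol = 3, byrow = TRUE)
  hg <- matrix(rep(c(0, 0, 0), nT), ncol = 3, byrow = TRUE)
  ser <- min_distance_series(toy_site_ensemble(sc, hg), 1, toy_ligand())
  rep1 <- mean_separation_report(ser)
  expect_equal(rep1$overall_mean, 2.0)
  # two residues at constant 2 and 6.5 with margin 4: second flagged
  ser$series[["2"]] <- within(ser$series[["1"]], {
    residue_seq <- 2L; d[] <- 6.5; subunit_mean[] <- 6.5; overall_mean <- 6.5
  })
  rep2 <- mean_separation_report(ser, margin = 4)
  expect_equal(rep2$flagged, c(FALSE, TRUE))
  expect_equal(rep2$residue_seq, c(1L, 2L))
})

test_that("designed mean separations are recovered from a noiseless-ligand ensemble", {
  seqs <- as.character(401:420)
  p <- setNames(rep(0, 20), seqs)
  p[c("401")] <- 1            # designed 3 A
  # residue 417 stays at 0 -> designed 8 A
  spec <- synthetic_spec(n_frames = 500, seed = 5,
                         ligands = list(A = list(sigma = 0, contact_probs = p),
                                        B = list(sigma = 0, contact_probs = p)))
  gen <- generate_ensemble(spec, "A")
  ser <- min_distance_series(gen$ensemble, c(401, 417), gen$ligand)
  expect_lt(abs(ser$series[["401"]]$overall_mean - 3.0), 0.1)
  expect_lt(abs(ser$series[["417"]]$overall_mean - 8.0), 0.1)
})

test_that("superposition recovers exact rigid motions and refuses degeneracy", {
  set.seed(301)
  ref <- matrix(rnorm(60, sd = 3), 20, 3)
  # identity
  fit <- superpose(ref, ref)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(fit$rmsd, 1e-12)
  # exact rotation + translation
  th <- pi / 2
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mob <- sweep(ref %*% t(rot), 2, c(1, 2, 3), `+`)
  fit <- superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$rotation %*% rot, diag(3), tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  # applying the returned transform attains the returned fit RMSD
  aligned <- mob %*% t(fit$rotation) +
    matrix(fit$translation, nrow(mob), 3, byrow = TRUE)
  expect_lt(abs(sqrt(mean(rowSums((aligned - ref)^2))) - fit$rmsd), 1e-9)
  # collinear input rejected
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line + 1), "degenerate")
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
})

test_that("superposition agrees with the bio3d reference implementation", {
  set.seed(302)
  for (trial in 1:5) {
    ref <- matrix(rnorm(90, sd = 4), 30, 3)
    mob <- ref + matrix(rnorm(90, sd = 0.5), 30, 3)
    fit <- superpose(mob, ref)
    xyz <- bio3d::fit.xyz(fixed = as.numeric(t(ref)), mobile = as.numeric(t(mob)),
                          fixed.inds = 1:90, mobile.inds = 1:90)
    rmsd_bio3d <- sqrt(mean(rowSums((matrix(xyz, ncol = 3, byrow = TRUE) - ref)^2)))
    expect_equal(fit$rmsd, rmsd_bio3d, tolerance = 1e-8)
  }
})

test_that("noisy-cloud fit RMSD matches the sigma*sqrt(3) expectation", {
  set.seed(303)
  sigma <- 0.1
  rms <- vapply(1:40, function(i) {
    ref <- matrix(rnorm(150, sd = 3), 50, 3)
    th <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    mob <- sweep((ref + matrix(rnorm(150, sd = sigma), 50, 3)) %*% t(rot),
                 2, runif(3, -5, 5), `+`)
    superpose(mob, ref)$rmsd
  }, numeric(1))
  expect_lt(abs(mean(rms) - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.1)
})

test_that("RMSD series is zero at the reference and under rigid co-motion", {
  gen <- generate_ensemble(quick_spec(n_frames = 10))
  rs <- rmsd_series(gen$ensemble, gen$ligand)
  expect_true(all(rs$values[1, ] < 1e-10))
  expect_true(all(rs$values >= 0))
  # a frame that is a rigid motion of frame 1 has RMSD 0 after alignment
  ens <- gen$ensemble
  th <- 0.4
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ens$coords[, , 2] <- sweep(ens$coords[, , 1] %*% t(rot), 2, c(3, -1, 2), `+`)
  rs2 <- rmsd_series(ens, gen$ligand)
  expect_true(all(rs2$values[2, ] < 1e-9))
  # reference frame must exist
  expect_error(rmsd_series(gen$ensemble, gen$ligand, reference_frame = 99),
               "out of range")
})

test_that("RMSD series is invariant under a global rigid motion of any frame", {
  gen <- generate_ensemble(quick_spec(n_frames = 6))
  rs <- rmsd_series(gen$ensemble, gen$ligand)
  ens <- gen$ensemble
  th <- 1.1
  rot <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  for (f in 2:n_frames(ens))
    ens$coords[, , f] <- sweep(ens$coords[, , f] %*% t(rot), 2, c(-4, 8, 1), `+`)
  rs2 <- rmsd_series(ens, gen$ligand)
  expect_equal(rs2$values, rs$values, tolerance = 1e-8)
  # global-alignment variant also runs and is zero at the reference
  rsg <- rmsd_series(gen$ensemble, gen$ligand, scope = "global")
  expect_true(all(rsg$values[1, ] < 1e-10))
})

test_that("ligand noise level is recovered from the RMSD series", {
  spec <- quick_spec(n_frames = 150)
  gen <- generate_ensemble(spec, "A")   # sigma = 0.5
  rs <- rmsd_series(gen$ensemble, gen$ligand)
  expect_lt(abs(mean(rs$values[-1, ]) - 0.5 * sqrt(3)) / (0.5 * sqrt(3)), 0.1)
})
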