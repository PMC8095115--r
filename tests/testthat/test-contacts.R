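test_that("constant geometries give frequency 1 and 0", {
  nT <- 7
  hg <- matrix(rep(c(0, 0, 0), nT), ncol = 3, byrow = TRUE)
  close_sc <- matrix(rep(c(2, 0, 0), nT), ncol = 3, byrow = TRUE)
  far_sc <- matrix(rep(c(8, 0, 0), nT), ncol = 3, byrow = TRUE)
  p1 <- contact_frequencies(toy_site_ensemble(close_sc, hg), toy_ligand())
  expect_equal(contact_frequency(p1, 1), 1.0)
  p0 <- contact_frequencies(toy_site_ensemble(far_sc, hg), toy_ligand())
  expect_equal(contact_frequency(p0, 1), 0.0)
  expect_equal(nrow(p0$combined), 0)
})

test_that("frame-wise contacts match the designed pattern and the brute oracle", {
  # contact in frames {1,3,5,6,8,10} of 10 -> frequency 0.6
  in_contact <- c(1, 3, 5, 6, 8, 10)
  sc <- t(vapply(1:10, function(f)
    if (f %in% in_contact) c(3, 0, 0) else c(7.5, 0, 0), numeric(3)))
  hg <- matrix(rep(c(0, 0, 0), 10), ncol = 3, byrow = TRUE)
  ens <- toy_site_ensemble(sc, hg)
  prof <- contact_frequencies(ens, toy_ligand(), cutoff = 5)
  expect_equal(contact_frequency(prof, 1), 0.6)
  # the same decision from the independent all-pairs oracle
  oracle <- mean(vapply(1:10, function(f)
    brute_within(sc[f, , drop = FALSE], hg[f, , drop = FALSE], 5), logical(1)))
  expect_equal(contact_frequency(prof, 1), oracle)
})

test_that("a pair at exactly the cutoff counts as contact", {
  nT <- 3
  hg <- matrix(rep(c(0, 0, 0), nT), ncol = 3, byrow = TRUE)
  sc <- matrix(rep(c(5, 0, 0), nT), ncol = 3, byrow = TRUE)
  prof <- contact_frequencies(toy_site_ensemble(sc, hg), toy_ligand(), cutoff = 5)
  expect_equal(contact_frequency(prof, 1), 1.0)
})

test_that("grid neighbor search equals brute force on seeded random frames", {
  set.seed(101)
  for (trial in 1:25) {
    nq <- sample(5:120, 1); nr <- sample(3:80, 1)
    q <- matrix(runif(nq * 3, -12, 12), ncol = 3)
    r <- matrix(runif(nr * 3, -12, 12), ncol = 3)
    cutoff <- runif(1, 2, 7)
    expect_identical(atoms_within_cutoff(q, r, cutoff, method = "grid"),
                     atoms_within_cutoff(q, r, cutoff, method = "brute"))
    expect_identical(atoms_within_cutoff(q, r, cutoff, method = "grid"),
                     brute_within(q, r, cutoff))
  }
})

test_that("frequencies are invariant under a rigid motion of every frame", {
  gen <- generate_ensemble(quick_spec(n_frames = 40))
  prof <- contact_frequencies(gen$ensemble, gen$ligand)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(5, -3, 11)
  moved <- gen$ensemble
  for (f in seq_len(n_frames(moved)))
    moved$coords[, , f] <- sweep(moved$coords[, , f] %*% t(rot), 2, shift, `+`)
  prof2 <- contact_frequencies(moved, gen$ligand)
  expect_equal(prof2$combined, prof$combined, tolerance = 1e-12)
  expect_equal(prof2$per_subunit, prof$per_subunit, tolerance = 1e-12)
})

test_that("enlarging the cutoff never decreases any frequency", {
  gen <- generate_ensemble(quick_spec(n_frames = 30))
  cuts <- c(3, 5, 6.5, 9)
  profs <- lapply(cuts, function(cc)
    contact_frequencies(gen$ensemble, gen$ligand, cutoff = cc))
  seqs <- sort(unique(gen$ensemble$topology$residue_seq[
    startsWith(gen$ensemble$topology$category, "protein")]))
  for (i in seq_len(length(cuts) - 1)) {
    f_lo <- vapply(seqs, function(r) contact_frequency(profs[[i]], r), numeric(1))
    f_hi <- vapply(seqs, function(r) contact_frequency(profs[[i + 1]], r), numeric(1))
    expect_true(all(f_hi >= f_lo))
  }
})

test_that("subunit_mean and frame_pooled agree for residues present on all subunits", {
  gen <- generate_ensemble(quick_spec(n_frames = 25))
  pm <- contact_frequencies(gen$ensemble, gen$ligand, combine_mode = "subunit_mean")
  pp <- contact_frequencies(gen$ensemble, gen$ligand, combine_mode = "frame_pooled")
  m <- merge(pm$combined, pp$combined, by = c("residue_seq", "residue_name"))
  expect_gt(nrow(m), 0)
  expect_equal(m$frequency.x, m$frequency.y, tolerance = 1e-12)
})

test_that("glycine-like residues without sidechain heavy atoms never register", {
  tab <- data.frame(atom_id = 1:3,
                    atom_name = c("N", "CA", "P1"),
                    element = c("N", "C", "P"),
                    residue_seq = c(1L, 1L, 99L),
                    residue_name = c("GLY", "GLY", "LIG"),
                    subunit_id = "A", stringsAsFactors = FALSE)
  top <- topology(tab, rules = classify_rules(ligand_residues = "LIG"))
  xyz <- matrix(c(0, 0, 0, 1, 0, 0, 1.5, 0, 0), ncol = 3, byrow = TRUE)
  ens <- ensemble(top, array(xyz, c(3, 3, 1)))
  expect_error(contact_frequencies(ens, toy_ligand()), "no protein sidechain")
})

test_that("ligand/protein subunit mismatch errors unless a pairing map is given", {
  # protein on chain B, ligand on chain A: same-chain pairing is impossible
  tab <- data.frame(atom_id = 1:3,
                    atom_name = c("CA", "CB", "P1"),
                    element = c("C", "C", "P"),
                    residue_seq = c(1L, 1L, 99L),
                    residue_name = c("ALA", "ALA", "LIG"),
                    subunit_id = c("B", "B", "A"), stringsAsFactors = FALSE)
  top <- topology(tab, rules = classify_rules(ligand_residues = "LIG"))
  xyz <- matrix(c(0, 0, 10, 0, 0, 0, 2, 0, 0), ncol = 3, byrow = TRUE)
  ens <- ensemble(top, array(xyz, c(3, 3, 1)))
  lig <- ligand_spec("L", data.frame(subunit_id = "A", residue_seq = 99L), "P1")
  expect_error(contact_frequencies(ens, lig), "pairing")
  # an explicit cross-chain pairing map makes the site analyzable
  prof <- contact_frequencies(ens, lig, pairing = c(B = "A"))
  expect_equal(contact_frequency(prof, 1), 1.0)
})

test_that("empirical frequencies stay inside the 3-sigma binomial envelope", {
  nT <- 200
  ok <- vapply(1:20, function(rep_i) {
    gen <- generate_ensemble(quick_spec(n_frames = nT, seed = 1000 + rep_i))
    prof <- contact_frequencies(gen$ensemble, gen$ligand)
    des <- gen$truth$design
    all(vapply(seq_len(nrow(des)), function(i) {
      p <- des$p_A[i]
      abs(contact_frequency(prof, des$residue_seq[i]) - p) <=
        3 * sqrt(p * (1 - p) / nT) + 1 / nT   # +1/nT: deterministic base frame
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("selectivity classification partitions residues and caps cumulative at 2", {
  genA <- generate_ensemble(quick_spec(n_frames = 80), "A")
  genB <- generate_ensemble(quick_spec(n_frames = 80), "B")
  pa <- contact_frequencies(genA$ensemble, genA$ligand)
  pb <- contact_frequencies(genB$ensemble, genB$ligand)
  sel <- classify_selectivity(pa, pb)
  n_total <- nrow(sel$residues)
  expect_equal(nrow(sel$selective_A) + nrow(sel$selective_B) +
                 nrow(sel$shared) + nrow(sel$neither), n_total)
  expect_true(all(sel$residues$cumulative <= 2))
  expect_true(all(sel$residues$cumulative >= 0))
  # identical profiles: nothing selective, all qualifying residues shared
  self <- classify_selectivity(pa, pa)
  expect_equal(nrow(self$selective_A), 0)
  expect_equal(nrow(self$selective_B), 0)
  expect_setequal(self$shared$residue_seq,
                  pa$combined$residue_seq[pa$combined$frequency >= 0.5])
  # configuration mismatch rejected
  pb2 <- contact_frequencies(genB$ensemble, genB$ligand, cutoff = 4)
  expect_error(classify_selectivity(pa, pb2), "cutoff")
})

test_that("shared-contact extraction returns exactly the designed shared set", {
  genA <- generate_ensemble(quick_spec(n_frames = 150), "A")
  genB <- generate_ensemble(quick_spec(n_frames = 150), "B")
  pa <- contact_frequencies(genA$ensemble, genA$ligand)
  pb <- contact_frequencies(genB$ensemble, genB$ligand)
  shared <- dual_ligand_shared_contacts(pa, pb)
  des <- genA$truth$design
  expect_setequal(shared$residue_seq, des$residue_seq[des$class == "shared"])
  pooled <- contact_frequencies(genA$ensemble, genA$ligand,
                                combine_mode = "frame_pooled")
  expect_error(dual_ligand_shared_contacts(pooled, pooled), "subunit_mean")
})

test_that("contact profiles round-trip through TSV", {
  gen <- generate_ensemble(quick_spec(n_frames = 20))
  prof <- contact_frequencies(gen$ensemble, gen$ligand)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_profile(prof, f)
  back <- read_contact_profile(f)
  expect_equal(back$ligand_label, prof$ligand_label)
  expect_equal(back$cutoff, prof$cutoff)
  expect_equal(back$combine_mode, prof$combine_mode)
  m <- merge(prof$combined, back$combined, by = c("residue_seq", "residue_name"))
  expect_equal(nrow(m), nrow(prof$combined))
  expect_equal(m$frequency.x, m$frequency.y, tolerance = 1e-6)
})
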