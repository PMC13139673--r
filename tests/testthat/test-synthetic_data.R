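test_that("generation is deterministic: same spec and seed, identical bytes", {
  t1 <- make_trimer(n_residues = 20,
                    profile = conf_profile(base = 70, atom_sd = 3),
                    seed = 9)
  t2 <- make_trimer(n_residues = 20,
                    profile = conf_profile(base = 70, atom_sd = 3),
                    seed = 9)
  expect_identical(t1$model$atoms, t2$model$atoms)
  f1 <- tempfile(fileext = ".pdb")
  f2 <- tempfile(fileext = ".pdb")
  write_structure(t1$model, f1)
  write_structure(t2$model, f2)
  expect_identical(readLines(f1), readLines(f2))
  t3 <- make_trimer(n_residues = 20,
                    profile = conf_profile(base = 70, atom_sd = 3),
                    seed = 10)
  expect_false(identical(t1$model$atoms$b, t3$model$atoms$b))
})

test_that("trimer geometry matches its spec: chains, residues, atoms", {
  tri <- make_trimer(n_chains = 3, n_residues = 25)
  expect_equal(chain_ids(tri$model), c("A", "B", "C"))
  rt <- residue_table(tri$model)
  expect_equal(nrow(rt), 75)
  expect_true(all(rt$resid == "ALA"))
  expect_equal(nrow(tri$model$atoms), 75 * 5)  # N, CA, C, O, CB
  expect_error(make_trimer(n_residues = 5), ">= 10")
  # consecutive C-alphas sit at bonded-backbone distances (~3.8 A)
  ca <- tri$model$atoms[tri$model$atoms$elety == "CA" &
                        tri$model$atoms$chain == "A", ]
  d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  expect_true(all(d > 3.0 & d < 4.5))
})

test_that("constant profiles plant the constant; sitewise overrides stick", {
  tri <- make_trimer(n_residues = 15, profile = conf_profile(constant = 50))
  expect_true(all(tri$model$atoms$b == 50))
  tri2 <- make_trimer(n_residues = 15,
                      profile = conf_profile(base = 60,
                                             sitewise = c(`7` = 91.25)))
  expect_true(all(tri2$model$atoms$b[tri2$model$atoms$resno == 7] == 91.25))
  expect_true(all(tri2$model$atoms$b[tri2$model$atoms$resno != 7] == 60))
  expect_equal(tri2$truth$residue_mean$mean_b[
    tri2$truth$residue_mean$resno == 7], rep(91.25, 3))
})

test_that("transformed copies carry exact fixed-frame RMSD ground truth", {
  base <- make_trimer(n_residues = 20)$model
  zero <- make_transformed_copy(base)
  expect_identical(zero$model$atoms[, c("x", "y", "z")],
                   base$atoms[, c("x", "y", "z")])
  expect_equal(zero$expected$rmsd_fixed, 0)
  rigid <- make_transformed_copy(base,
                                 rotation = list(axis = c(0, 1, 0),
                                                 angle = 65),
                                 translation = c(4, 4, -2))
  pr <- pair_calpha(base, rigid$model, selection = "all")
  expect_lt(kabsch(pr$a, pr$b)$rmsd, 1e-9)
  expect_true(rigid$expected$rigid)
  noisy <- make_transformed_copy(base, noise_sd = 0.5, seed = 3)
  prn <- pair_calpha(base, noisy$model, selection = "all")
  expect_equal(rmsd_fixed(prn$a, prn$b), noisy$expected$rmsd_fixed,
               tolerance = 1e-9)
})

test_that("pose-pair templates have the stated element census and spacing", {
  atp <- ligand_template("atp_like")
  census <- table(atp$atoms$elesy)
  expect_equal(unname(census[c("C", "N", "O", "P")]), c(10L, 5L, 13L, 3L),
               ignore_attr = TRUE)
  # same-element spacing supports the analytic-optimum argument
  for (e in names(census)[census >= 2]) {
    idx <- atp$atoms$elesy == e
    expect_gte(min(dist(atp$atoms[idx, c("x", "y", "z")])), 2.2 - 1e-9)
  }
  ph <- ligand_template("phosphate_like")
  expect_equal(sort(ph$atoms$elesy), c("O", "O", "O", "O", "P"))
  expect_equal(nrow(ph$bonds), 4)
})

test_that("pose pairs refuse analytic truth when displacement is too large", {
  expect_error(make_pose_pair("atp_like", "identity",
                              displacement = c(2, 0, 0)),
               "spacing")
})

test_that("the exhaustive oracle is self-consistent and bounded", {
  set.seed(5)
  a <- random_pose(17, max_per_element = 4)
  expect_equal(exhaustive_sym_rmsd(a, a), 0)
  b <- perturbed_pose(a, 18, jitter = 0)
  expect_equal(exhaustive_sym_rmsd(a, b), 0, tolerance = 1e-12)
  big <- ligand_template("atp_like")
  expect_error(exhaustive_sym_rmsd(big, big), "refused")
})

test_that("scenes reject incompatible plants and overlapping residues", {
  expect_error(make_interaction_scene(
    data.frame(resno = 1, aa = "T", kind = "SB")), "cannot carry")
  expect_error(make_interaction_scene(
    data.frame(resno = c(5, 5), aa = c("K", "K"),
               kind = c("SB", "HB"))), "unique")
  expect_error(make_interaction_scene(
    data.frame(resno = 1:13, aa = "K", kind = "SB")), "at most 12")
})

test_that("scene output is well-formed and ground-truth closed", {
  plants <- data.frame(resno = c(7, 19), aa = c("K", "F"),
                       kind = c("SB", "PI_STACK"))
  sc <- make_interaction_scene(plants, seed = 21)
  expect_s3_class(sc$model, "structure_model")
  expect_s3_class(sc$ligand, "ligand_pose")
  expect_equal(sc$truth$resno, c(7L, 19L))
  expect_equal(sort(unique(sc$model$atoms$resno)), c(7L, 19L))
  # scene survives a PDB round trip and re-detection
  f <- tempfile(fileext = ".pdb")
  write_structure(sc$model, f)
  m2 <- read_structure(f)
  rec <- detect_interactions(m2, sc$ligand)
  expect_equal(sort(paste(rec$resno, rec$kind)),
               sort(paste(sc$truth$resno, sc$truth$kind)))
})
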