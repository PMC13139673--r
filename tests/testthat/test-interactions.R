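orth_site <- function() {
  site_definition("orthosteric", c(64, 66, 145, 189, 292, 294, 311),
                  c("K", "K", "K", "T", "N", "R", "K"))
}

test_that("planted contacts of every kind are recovered exactly", {
  plants <- data.frame(
    resno = c(10, 20, 30, 40, 50),
    aa = c("K", "R", "N", "L", "F"),
    kind = c("SB", "SB", "HB", "HI", "PI_STACK"))
  sc <- make_interaction_scene(plants, seed = 4)
  rec <- detect_interactions(sc$model, sc$ligand)
  found <- as.data.frame(rec)[, c("resno", "kind")]
  found <- found[order(found$resno), ]
  rownames(found) <- NULL
  planted <- sc$truth[order(sc$truth$resno), c("resno", "kind")]
  rownames(planted) <- NULL
  expect_equal(found, planted)
  # every record respects its rule's distance cap
  rules <- interaction_rules()
  caps <- c(HB = rules$hb_dist, SB = rules$sb_dist, HI = rules$hi_dist,
            PI_STACK = rules$pi_dist)
  expect_true(all(rec$distance <= caps[rec$kind] + 1e-9))
})

test_that("negative plants (geometry beyond threshold) yield no records", {
  neg <- data.frame(resno = c(11, 21, 31, 41),
                    aa = c("K", "T", "L", "F"),
                    kind = c("SB", "HB", "HI", "PI_STACK"))
  sc <- make_interaction_scene(plants = neg[0, ], negatives = neg,
                               seed = 2)
  rec <- detect_interactions(sc$model, sc$ligand)
  expect_equal(nrow(rec), 0)
  sc0 <- make_interaction_scene(data.frame(resno = integer(0),
                                           aa = character(0),
                                           kind = character(0)))
  expect_equal(nrow(detect_interactions(sc0$model, sc0$ligand)), 0)
})

test_that("a remote ligand produces an empty record list", {
  sc <- make_interaction_scene(data.frame(resno = 5, aa = "K",
                                          kind = "SB"))
  far <- sc$ligand
  far$atoms$x <- far$atoms$x + 500
  expect_equal(nrow(detect_interactions(sc$model, far)), 0)
})

test_that("threshold monotonicity: shrinking rules never adds records", {
  plants <- data.frame(resno = c(10, 20, 30), aa = c("K", "N", "L"),
                       kind = c("SB", "HB", "HI"))
  sc <- make_interaction_scene(plants, seed = 6)
  full <- detect_interactions(sc$model, sc$ligand)
  tight <- detect_interactions(sc$model, sc$ligand,
                               interaction_rules(hb_dist = 2.0,
                                                 sb_dist = 3.0,
                                                 hi_dist = 2.5,
                                                 pi_dist = 3.0))
  loose <- detect_interactions(sc$model, sc$ligand,
                               interaction_rules(hb_dist = 4.5,
                                                 sb_dist = 7.0,
                                                 hi_dist = 5.5,
                                                 pi_dist = 7.0))
  key <- function(r) paste(r$resno, r$kind)
  expect_true(all(key(tight) %in% key(full)))
  expect_true(all(key(full) %in% key(loose)))
})

test_that("records are invariant under a joint rigid motion", {
  plants <- data.frame(resno = c(10, 20, 50), aa = c("K", "N", "F"),
                       kind = c("SB", "HB", "PI_STACK"))
  sc <- make_interaction_scene(plants, seed = 8)
  R <- rotation_about_axis(c(1, 2, 3), 50)
  t <- c(7, -4, 11)
  mv_model <- sc$model
  xyz <- as.matrix(mv_model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  mv_model$atoms[, c("x", "y", "z")] <- xyz
  mv_lig <- sc$ligand
  lxyz <- as.matrix(mv_lig$atoms[, c("x", "y", "z")]) %*% t(R)
  lxyz <- sweep(lxyz, 2, t, "+")
  mv_lig$atoms[, c("x", "y", "z")] <- lxyz
  r0 <- detect_interactions(sc$model, sc$ligand)
  r1 <- detect_interactions(mv_model, mv_lig)
  expect_equal(r1$kind, r0$kind)
  expect_equal(r1$resno, r0$resno)
  expect_equal(r1$distance, r0$distance, tolerance = 1e-9)
})

test_that("detection is deterministic and keeps the shortest contact per kind", {
  plants <- data.frame(resno = c(10, 20), aa = c("K", "L"),
                       kind = c("SB", "HI"))
  sc <- make_interaction_scene(plants, seed = 3)
  r1 <- detect_interactions(sc$model, sc$ligand)
  r2 <- detect_interactions(sc$model, sc$ligand)
  expect_identical(r1, r2)
  expect_false(any(duplicated(paste(r1$chain, r1$resno, r1$kind))))
})

test_that("fingerprints tabulate kinds per key residue with em-dash gaps", {
  rec <- data.frame(kind = c("SB", "SB", "HB"),
                    chain = "A", resno = c(64, 66, 292),
                    aa = c("K", "K", "N"),
                    resid = c("LYS", "LYS", "ASN"),
                    protein_atom = "X", ligand_atom = "Y",
                    distance = 3, angle = NA_real_)
  site <- site_definition("orthosteric", c(64, 66, 189, 292, 294, 311),
                          c("K", "K", "T", "N", "R", "K"))
  fp <- fingerprint(rec, site)
  expect_equal(fp$rows$kinds, c("SB", "SB", "—", "HB", "—", "—"))
  expect_equal(fp$n_key_hit, 3)
  empty <- fingerprint(rec[0, ], site)
  expect_true(all(empty$rows$kinds == "—"))
  expect_equal(empty$n_key_hit, 0)
})

test_that("a planted published-style contact pattern is reproduced end to end", {
  # AF2-model orthosteric pattern: salt bridges at K64/K66/R294/K311,
  # hydrogen bonds at K145/N292, nothing at T189
  plants <- data.frame(
    resno = c(64, 66, 294, 311, 145, 292),
    aa = c("K", "K", "R", "K", "K", "N"),
    kind = c("SB", "SB", "SB", "SB", "HB", "HB"))
  sc <- make_interaction_scene(plants, seed = 10)
  fp <- fingerprint(detect_interactions(sc$model, sc$ligand), orth_site())
  expect_equal(fp$rows$kinds[fp$rows$resno == 64], "SB")
  expect_equal(fp$rows$kinds[fp$rows$resno == 66], "SB")
  expect_equal(fp$rows$kinds[fp$rows$resno == 145], "HB")
  expect_equal(fp$rows$kinds[fp$rows$resno == 189], "—")
  expect_equal(fp$rows$kinds[fp$rows$resno == 292], "HB")
  expect_equal(fp$rows$kinds[fp$rows$resno == 294], "SB")
  expect_equal(fp$rows$kinds[fp$rows$resno == 311], "SB")
  expect_equal(fp$n_key_hit, 6)
})

test_that("fingerprint comparison aligns models and counts key hits", {
  site <- orth_site()
  scA <- make_interaction_scene(
    data.frame(resno = c(64, 66, 292), aa = c("K", "K", "N"),
               kind = c("SB", "SB", "HB")), seed = 1)
  scB <- make_interaction_scene(
    data.frame(resno = 66, aa = "K", kind = "HB"), seed = 2)
  fpA <- fingerprint(detect_interactions(scA$model, scA$ligand), site)
  fpB <- fingerprint(detect_interactions(scB$model, scB$ligand), site)
  tab <- compare_fingerprints(list(A = fpA, B = fpB))
  expect_equal(colnames(tab), c("A", "B"))
  expect_equal(attr(tab, "n_key_hit"), c(A = 3L, B = 1L))
  expect_equal(tab["K66", "A"], "SB")
  expect_equal(tab["K66", "B"], "HB")
  same <- compare_fingerprints(list(x = fpA, y = fpA))
  expect_equal(same$x, same$y)
  other <- fingerprint(detect_interactions(scB$model, scB$ligand),
                       site_definition("allo", 95, "F"))
  expect_error(compare_fingerprints(list(A = fpA, B = other)),
               "same site")
})

test_that("ligand rings are perceived from inferred bonds when absent", {
  # benzene with no bond block: bonds inferred from covalent radii
  ring <- ligand_pose(data.frame(
    elety = paste0("C", 1:6), elesy = "C",
    x = 1.39 * cos(seq(0, 5) * pi / 3),
    y = 1.39 * sin(seq(0, 5) * pi / 3), z = 0))
  cls <- foldsite:::.ligand_classes(ring)
  expect_equal(length(cls$rings), 1)
  expect_equal(sort(cls$rings[[1]]), 1:6)
})
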