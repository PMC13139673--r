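two_atom_pose <- function(x1, x2) {
  ligand_pose(data.frame(elety = c("O1", "O2"), elesy = "O",
                         x = c(x1[1], x2[1]), y = c(x1[2], x2[2]),
                         z = c(x1[3], x2[3]), stringsAsFactors = FALSE))
}

test_that("naive RMSD follows the identity-mapping formula", {
  a <- two_atom_pose(c(0, 0, 0), c(2, 0, 0))
  expect_equal(naive_rmsd(a, a), 0)
  b <- two_atom_pose(c(0, 0, 0), c(2, 1, 0))  # one atom displaced 1 A
  expect_equal(naive_rmsd(a, b), sqrt(1 / 2))
  pp <- make_pose_pair("atp_like", "identity",
                       displacement = c(0.4, -0.3, 0.2), seed = 2)
  expect_equal(naive_rmsd(pp$poseA, pp$poseB), pp$truth$naive_rmsd,
               tolerance = 1e-9)
})

test_that("naive RMSD refuses mismatched element sequences", {
  a <- ligand_pose(data.frame(elety = c("O1", "N1"), elesy = c("O", "N"),
                              x = 0:1, y = 0, z = 0))
  b <- ligand_pose(data.frame(elety = c("N1", "O1"), elesy = c("N", "O"),
                              x = 0:1, y = 0, z = 0))
  expect_error(naive_rmsd(a, b), "symmetry_rmsd")
})

test_that("the assignment solver handles the worked 2x2 cases", {
  sol <- solve_assignment(rbind(c(1, 2), c(3, 1)))
  expect_equal(sol$pairs[, 2], c(1, 2))
  expect_equal(sol$cost, 2)
  z <- matrix(5, 4, 4)
  diag(z) <- 0
  solz <- solve_assignment(z)
  expect_equal(solz$pairs[, 2], 1:4)
  expect_equal(solz$cost, 0)
})

test_that("assignment ties break toward the lexicographically smallest pairing", {
  sol <- solve_assignment(matrix(1, 3, 3))
  expect_equal(sol$pairs[, 2], 1:3)
  # row 1 prefers column 1 whenever an optimal completion allows it
  cost <- rbind(c(0, 0, 5), c(0, 0, 5), c(5, 5, 0))
  expect_equal(solve_assignment(cost)$pairs[, 2], c(1, 2, 3))
})

test_that("assignment solutions equal the exhaustive minimum on random matrices", {
  set.seed(100)
  for (i in 1:100) {
    n <- 6
    cost <- matrix(runif(n * n, 0, 10), n, n)
    sol <- solve_assignment(cost)
    brute <- min(vapply(foldsite:::.permutations(n), function(p)
      sum(cost[cbind(1:n, unlist(p))]), numeric(1)))
    expect_equal(sol$cost, brute, tolerance = 1e-9)
    expect_equal(sum(cost[sol$pairs]), sol$cost, tolerance = 1e-12)
  }
})

test_that("the solver validates its input", {
  expect_error(solve_assignment(matrix(1, 2, 3)), "square")
  expect_error(solve_assignment(rbind(c(-1, 2), c(3, 1))),
               "non-negative")
})

test_that("swapped equivalent atoms inflate naive but not symmetry-corrected RMSD", {
  a <- two_atom_pose(c(1, 0, 0), c(-1, 0, 0))
  b <- two_atom_pose(c(-1, 0, 0), c(1, 0, 0))
  r <- symmetry_rmsd(a, b)
  expect_equal(r$naive_rmsd, 2)
  expect_equal(r$sym_rmsd, 0)
  ident <- symmetry_rmsd(a, a)
  expect_equal(ident$sym_rmsd, 0)
  expect_true(ident$passes_redock)
})

test_that("hydrogens are excluded by default and restored on request", {
  at <- data.frame(elety = c("O1", "H1"), elesy = c("O", "H"),
                   x = c(0, 0), y = 0, z = 0)
  a <- ligand_pose(at)
  bt <- at
  bt$x <- c(0, 3)
  b <- ligand_pose(bt)
  expect_equal(symmetry_rmsd(a, b)$sym_rmsd, 0)
  expect_equal(symmetry_rmsd(a, b, heavy_only = FALSE)$sym_rmsd,
               sqrt(9 / 2))
})

test_that("element multiset mismatches abort with the differing elements", {
  a <- ligand_pose(data.frame(elety = "O1", elesy = "O", x = 0, y = 0,
                              z = 0))
  b <- ligand_pose(data.frame(elety = "N1", elesy = "N", x = 0, y = 0,
                              z = 0))
  expect_error(symmetry_rmsd(a, b), "N|O")
})

test_that("Hungarian symmetry RMSD equals the exhaustive oracle on random pairs", {
  for (seed in 1:50) {
    a <- random_pose(seed)
    b <- perturbed_pose(a, seed + 1000)
    r <- symmetry_rmsd(a, b)
    expect_equal(r$sym_rmsd, exhaustive_sym_rmsd(a, b), tolerance = 1e-9)
    expect_lte(r$sym_rmsd, r$naive_rmsd + 1e-12)
  }
})

test_that("symmetry RMSD is symmetric, permutation-blind, and translation-bounded", {
  for (seed in c(2, 12, 22)) {
    a <- random_pose(seed)
    b <- perturbed_pose(a, seed + 500)
    expect_equal(symmetry_rmsd(a, b)$sym_rmsd,
                 symmetry_rmsd(b, a)$sym_rmsd, tolerance = 1e-9)
    perm <- perturbed_pose(a, seed + 900, jitter = 0)
    expect_lt(symmetry_rmsd(a, perm)$sym_rmsd, 1e-12)
    t <- c(0.9, -0.4, 0.3)
    bt <- b
    bt$atoms$x <- bt$atoms$x + t[1]
    bt$atoms$y <- bt$atoms$y + t[2]
    bt$atoms$z <- bt$atoms$z + t[3]
    expect_lte(symmetry_rmsd(a, bt)$sym_rmsd,
               symmetry_rmsd(a, b)$sym_rmsd + sqrt(sum(t^2)) + 1e-9)
  }
})

test_that("generated pose pairs carry consistent oracle ground truth", {
  pp <- make_pose_pair("phosphate_like", "swap_equivalents")
  # two O at +/-1.5 swap (displacement 2r = 3 each), pooled over 5 atoms
  expect_equal(pp$truth$naive_rmsd, sqrt(2 * 3^2 / 5))
  expect_equal(pp$truth$sym_rmsd, 0)
  r <- symmetry_rmsd(pp$poseA, pp$poseB)
  expect_equal(r$naive_rmsd, pp$truth$naive_rmsd, tolerance = 1e-9)
  expect_equal(r$sym_rmsd, pp$truth$sym_rmsd, tolerance = 1e-9)
  # uniform displacement: naive = sym = |t|
  pp2 <- make_pose_pair("phosphate_like", "identity",
                        displacement = c(0, 0, 1))
  expect_equal(pp2$truth$naive_rmsd, 1)
  expect_equal(pp2$truth$sym_rmsd, 1)
  r2 <- symmetry_rmsd(pp2$poseA, pp2$poseB)
  expect_equal(r2$sym_rmsd, 1, tolerance = 1e-9)
  # large-class template with analytic truth
  pp3 <- make_pose_pair("atp_like", "random_element_preserving",
                        displacement = c(0.3, 0.2, 0.1), seed = 5)
  expect_equal(pp3$truth$sym_method, "analytic")
  r3 <- symmetry_rmsd(pp3$poseA, pp3$poseB)
  expect_equal(r3$sym_rmsd, pp3$truth$sym_rmsd, tolerance = 1e-9)
})

test_that("redocking classification is strictly below-threshold", {
  mk <- function(val) structure(list(sym_rmsd = val, naive_rmsd = val,
                                     threshold = 2.0,
                                     passes_redock = val < 2.0),
                                class = "sym_rmsd_result")
  expect_equal(classify_redock(mk(0.5)), "satisfactory")
  expect_equal(classify_redock(mk(2.0)), "unsatisfactory")
  expect_equal(classify_redock(mk(3.7)), "unsatisfactory")
})

test_that("grid boxes center on the ligand geometric center", {
  p <- ligand_pose(data.frame(elety = paste0("C", 1:3), elesy = "C",
                              x = c(0, 2, 1), y = c(0, 0, 3), z = 0))
  g <- grid_from_ligand(p)
  expect_equal(g$center, c(1, 1, 0), ignore_attr = TRUE)
  expect_equal(g$dims, c(40, 30, 40))
  single <- ligand_pose(data.frame(elety = "P1", elesy = "P", x = 4,
                                   y = 5, z = 6))
  expect_equal(grid_from_ligand(single)$center, c(4, 5, 6),
               ignore_attr = TRUE)
  expect_error(grid_from_ligand(p, dims = c(40, -1, 40)), "positive")
  h_only <- ligand_pose(data.frame(elety = "H1", elesy = "H", x = 0,
                                   y = 0, z = 0))
  expect_error(grid_from_ligand(h_only), "heavy")
})
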