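# synthetic_data: fixtures with analytic ground truth for every stage.
#
# The generator builds toy homotrimers (ideal alpha-helical poly-alanine,
# C3-arranged) with planted per-residue or per-atom confidence, rigidly
# transformed/noised copies with known RMSD, ligand pose pairs related by
# element-preserving permutations plus rigid motion, and binding-site
# scenes with planted contacts.  Every output ships with the analytic or
# exhaustive-oracle value its consuming test asserts against; no ground
# truth is derived from the modules under test.

# ---- ideal helix backbone (NeRF internal -> cartesian) ----

# Place atom d bonded to c with given bond length, angle a(b,c,d) and
# torsion (a,b,c,d), all in degrees.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180
  torsion <- torsion * pi / 180
  bc <- .normalize(c - b)
  n <- .normalize(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  as.numeric(cbind(bc, m, n) %*% d2 + c)
}

# Poly-alanine helix with ideal phi/psi (-57, -47); returns one chain's
# atom table (N, CA, C, O, CB per residue).
.helix_chain <- function(n_residues, phi = -57, psi = -47) {
  rows <- vector("list", n_residues * 5L)
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  th <- (180 - 111.2) * pi / 180
  C <- CA + 1.525 * c(cos(th), sin(th), 0)
  k <- 0L
  addr <- function(elety, elesy, p, resno) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(elety = elety, elesy = elesy, x = p[1],
                             y = p[2], z = p[3], resno = resno,
                             stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_residues)) {
    O <- .place_atom(N, CA, C, 1.231, 120.5, psi + 180)
    CB <- .place_atom(C, N, CA, 1.530, 110.5, phi + 122)
    addr("N", "N", N, i)
    addr("CA", "C", CA, i)
    addr("C", "C", C, i)
    addr("O", "O", O, i)
    addr("CB", "C", CB, i)
    if (i < n_residues) {
      N1 <- .place_atom(N, CA, C, 1.329, 116.2, psi)
      CA1 <- .place_atom(CA, C, N1, 1.458, 121.7, 180)
      C1 <- .place_atom(C, N1, CA1, 1.525, 111.2, phi)
      N <- N1; CA <- CA1; C <- C1
    }
  }
  do.call(rbind, rows)
}

#' Confidence profile specification
#'
#' Describes how per-residue/per-atom B-values (pLDDT) are planted in a
#' synthetic model: a flat baseline, optional per-residue overrides, and
#' optional per-atom Gaussian noise.
#'
#' @param constant if given, every residue gets this value (shorthand for
#'   \code{base = constant} with no overrides).
#' @param base baseline pLDDT for residues without an override.
#' @param sitewise named numeric vector, names = residue numbers, giving
#'   per-residue values.
#' @param atom_sd standard deviation of per-atom Gaussian noise (0 gives
#'   AF2-style files where all atoms of a residue share one value).
#' @return object of class \code{conf_profile}.
#' @export
conf_profile <- function(constant = NULL, base = 70, sitewise = NULL,
                         atom_sd = 0) {
  if (!is.null(constant)) {
    base <- constant
    sitewise <- NULL
  }
  if (!is.null(sitewise) && is.null(names(sitewise)))
    stop("sitewise must be a named vector (names = residue numbers)")
  structure(list(base = base, sitewise = sitewise, atom_sd = atom_sd),
            class = "conf_profile")
}

#' Generate a synthetic homotrimer with planted confidence
#'
#' Builds an ideal alpha-helical poly-alanine chain, arranges
#' \code{n_chains} copies with C3(-like) symmetry about the z axis, and
#' plants B-values according to \code{profile}.  The returned ground
#' truth records the per-residue mean actually written, independently of
#' any downstream extraction code.
#'
#' @param n_chains number of chains (default 3).
#' @param n_residues residues per chain (>= 10, so neighbour windows have
#'   room).
#' @param profile a \code{\link{conf_profile}}.
#' @param seed RNG seed for the per-atom noise stream.
#' @param id model label.
#' @return list with \code{model} (a \code{\link{structure_model}}) and
#'   \code{truth} (list: \code{residue_mean} data.frame with the written
#'   per-residue means, \code{seed}, \code{profile}).
#' @export
make_trimer <- function(n_chains = 3, n_residues = 60,
                        profile = conf_profile(), seed = 1,
                        id = "synthetic_trimer") {
  if (n_residues < 10) stop("n_residues must be >= 10")
  stopifnot(inherits(profile, "conf_profile"))
  set.seed(seed)
  base_chain <- .helix_chain(n_residues)
  chains <- LETTERS[seq_len(n_chains)]
  all_atoms <- vector("list", n_chains)
  truth_rows <- vector("list", 0L)
  res_values <- rep(profile$base, n_residues)
  if (!is.null(profile$sitewise)) {
    idx <- as.integer(names(profile$sitewise))
    ok <- idx >= 1 & idx <= n_residues
    res_values[idx[ok]] <- profile$sitewise[ok]
  }
  for (ci in seq_len(n_chains)) {
    at <- base_chain
    xyz <- as.matrix(at[, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, c(16, 0, 0), "+")   # off-axis, then C3 rotate
    R <- rotation_about_axis(c(0, 0, 1), 360 * (ci - 1) / n_chains)
    xyz <- xyz %*% t(R)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    b <- res_values[at$resno]
    if (profile$atom_sd > 0)
      b <- b + stats::rnorm(nrow(at), 0, profile$atom_sd)
    b <- pmin(100, pmax(0, b))
    at$b <- round(b, 2)    # PDB B-factor field precision
    all_atoms[[ci]] <- data.frame(
      type = "ATOM", eleno = 0L, elety = at$elety, altloc = "",
      resid = "ALA", aa = "A", chain = chains[ci], resno = at$resno,
      insert = "", x = at$x, y = at$y, z = at$z, o = 1, b = at$b,
      elesy = at$elesy, stringsAsFactors = FALSE)
    truth_rows[[ci]] <- data.frame(
      chain = chains[ci], resno = seq_len(n_residues),
      mean_b = as.numeric(tapply(at$b, at$resno, mean)),
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, all_atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  model <- structure_model(atoms, id = id,
                           metadata = list(generator = "make_trimer",
                                           seed = seed),
                           predicted = TRUE)
  list(model = model,
       truth = list(residue_mean = do.call(rbind, truth_rows),
                    seed = seed, profile = profile))
}

#' Ground-truth windowed site means
#'
#' Computes, from a generator truth table alone, the windowed per-residue
#' means and global average that \code{\link{site_confidence}} should
#' report -- an independent re-derivation used to validate the confidence
#' module against planted profiles.
#'
#' @param truth the \code{truth} element of \code{\link{make_trimer}}.
#' @param resnos key residue numbers.
#' @param neighbor_offsets window offsets (0 excluded, implicit).
#' @param chains chains to average over (default: all in the truth).
#' @return list with \code{per_residue} (named numeric) and
#'   \code{global_average}.
#' @export
truth_site_means <- function(truth, resnos,
                             neighbor_offsets = c(-3L, -2L, -1L, 1L, 2L),
                             chains = NULL) {
  tab <- truth$residue_mean
  chains <- chains %||% unique(tab$chain)
  per <- vapply(resnos, function(rn) {
    vals <- vapply(chains, function(ch) {
      sub <- tab[tab$chain == ch, ]
      window <- c(rn, rn + neighbor_offsets)
      window <- window[window %in% sub$resno]
      if (length(window) == 0) return(NA_real_)
      mean(sub$mean_b[match(window, sub$resno)])
    }, numeric(1))
    mean(vals[!is.na(vals)])
  }, numeric(1))
  names(per) <- as.character(resnos)
  list(per_residue = per, global_average = mean(per))
}

#' Rigidly transformed / noised copy with known RMSD
#'
#' Applies a rotation, a translation and optional per-coordinate Gaussian
#' noise to every atom of a model.  The expected fixed-frame RMSD is
#' computed analytically from the displacement vectors actually drawn;
#' for a pure rigid motion the Kabsch RMSD is 0 by construction.
#'
#' @param model a \code{\link{structure_model}}.
#' @param rotation list(axis, angle) in degrees, or NULL.
#' @param translation length-3 numeric.
#' @param noise_sd per-coordinate Gaussian noise sd (A).
#' @param seed RNG seed for the noise stream.
#' @return list with \code{model} (the copy) and \code{expected} (list:
#'   \code{rmsd_fixed} of the drawn displacements, \code{rigid} flag).
#' @export
make_transformed_copy <- function(model, rotation = NULL,
                                  translation = c(0, 0, 0), noise_sd = 0,
                                  seed = 1) {
  set.seed(seed)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- xyz
  if (!is.null(rotation))
    new <- new %*% t(rotation_about_axis(rotation$axis, rotation$angle))
  new <- sweep(new, 2, as.numeric(translation), "+")
  if (noise_sd > 0)
    new <- new + matrix(stats::rnorm(length(new), 0, noise_sd),
                        nrow(new), 3)
  disp <- new - xyz
  out <- model
  out$atoms$x <- new[, 1]; out$atoms$y <- new[, 2]; out$atoms$z <- new[, 3]
  out$id <- paste0(model$id, "_copy")
  list(model = out,
       expected = list(rmsd_fixed = sqrt(mean(rowSums(disp^2))),
                       rigid = noise_sd == 0))
}

# ---- ligand templates ----

# Deterministic pseudo-molecule coordinates: atoms on a 2.2 A grid, so
# same-element atoms are never closer than 2.2 A (needed for the
# analytic-optimum argument in make_pose_pair).
.grid_coords <- function(n, spacing = 2.2) {
  side <- ceiling(n^(1 / 3))
  g <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                             z = seq_len(side)))[seq_len(n), , drop = FALSE]
  g * spacing
}

#' Built-in ligand templates
#'
#' \code{"atp_like"} is an element-multiset stand-in for an ATP heavy-atom
#' set (10 C, 5 N, 13 O, 3 P) with deterministic, well-separated 3D
#' coordinates; no chemical validity is claimed.  \code{"phosphate_like"}
#' is a phosphate with its four oxygens on the axes, the canonical
#' symmetric-atom test case.
#'
#' @param template "atp_like" or "phosphate_like", or a data.frame of
#'   atoms passed through unchanged.
#' @return a \code{\link{ligand_pose}}.
#' @export
ligand_template <- function(template = c("atp_like", "phosphate_like")) {
  if (is.data.frame(template)) return(ligand_pose(template))
  template <- match.arg(template)
  if (template == "phosphate_like") {
    atoms <- data.frame(
      elety = c("P1", "O1", "O2", "O3", "O4"),
      elesy = c("P", "O", "O", "O", "O"),
      x = c(0, 1.5, -1.5, 0, 0), y = c(0, 0, 0, 1.5, -1.5),
      z = 0, stringsAsFactors = FALSE)
    bonds <- cbind(1L, 2:5)
  } else {
    el <- c(rep("C", 10), rep("N", 5), rep("O", 13), rep("P", 3))
    xyz <- .grid_coords(length(el))
    atoms <- data.frame(
      elety = paste0(el, stats::ave(seq_along(el), el, FUN = seq_along)),
      elesy = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE)
    bonds <- NULL
  }
  ligand_pose(atoms, label = template, bonds = bonds)
}

#' Exhaustive-permutation symmetry-corrected RMSD (oracle)
#'
#' Brute-force minimum of the pooled sum of squared distances over all
#' element-preserving atom permutations, enumerated per element class.
#' Feasible only for small classes; this is the independent oracle the
#' Hungarian implementation is validated against, kept deliberately free
#' of any assignment-solver code.
#'
#' @param poseA,poseB \code{\link{ligand_pose}} objects with identical
#'   element multisets.
#' @param heavy_only drop hydrogens first (default TRUE).
#' @param max_class_size refuse classes larger than this (default 8).
#' @return scalar RMSD in Angstrom.
#' @export
exhaustive_sym_rmsd <- function(poseA, poseB, heavy_only = TRUE,
                                max_class_size = 8L) {
  if (heavy_only) {
    poseA <- .heavy(poseA)
    poseB <- .heavy(poseB)
  }
  ea <- poseA$atoms$elesy
  eb <- poseB$atoms$elesy
  if (!identical(sort(ea), sort(eb)))
    stop("element multisets differ")
  A <- .pose_xyz(poseA)
  B <- .pose_xyz(poseB)
  total <- 0
  for (el in unique(ea)) {
    ia <- which(ea == el)
    ib <- which(eb == el)
    m <- length(ia)
    if (m > max_class_size)
      stop("element class ", el, " has ", m,
           " atoms; exhaustive search refused")
    best <- Inf
    for (p in .permutations(m)) {
      cost <- sum((A[ia, , drop = FALSE] -
                   B[ib[unlist(p)], , drop = FALSE])^2)
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  sqrt(total / nrow(A))
}

#' Generate a ligand pose pair with known naive and symmetry-corrected RMSD
#'
#' Pose B is an element-preserving permutation of pose A plus a uniform
#' rigid displacement.  The ground-truth naive RMSD follows from the
#' drawn displacements by the plain formula; the ground-truth
#' symmetry-corrected RMSD comes from the exhaustive permutation oracle
#' when every element class has at most \code{oracle_limit} atoms, and
#' otherwise (large classes, e.g. the 13 oxygens of the ATP-like
#' template) analytically as the displacement norm, which is provably
#' optimal because the templates keep same-element atoms more than twice
#' the displacement apart.
#'
#' @param template passed to \code{\link{ligand_template}}.
#' @param permutation "identity", "swap_equivalents" (swap the first two
#'   atoms of the first multi-atom element) or
#'   "random_element_preserving".
#' @param displacement length-3 numeric applied uniformly to pose B.
#' @param seed RNG seed (random permutations).
#' @param oracle_limit largest element class the exhaustive oracle will
#'   enumerate (default 6).
#' @return list with \code{poseA}, \code{poseB} and \code{truth} (list:
#'   \code{naive_rmsd}, \code{sym_rmsd}, \code{sym_method}).
#' @export
make_pose_pair <- function(template = "phosphate_like",
                           permutation = c("identity", "swap_equivalents",
                                           "random_element_preserving"),
                           displacement = c(0, 0, 0), seed = 1,
                           oracle_limit = 6L) {
  permutation <- match.arg(permutation)
  set.seed(seed)
  poseA <- if (inherits(template, "ligand_pose")) template
           else ligand_template(template)
  el <- poseA$atoms$elesy
  n <- length(el)
  perm <- seq_len(n)
  if (permutation == "swap_equivalents") {
    tab <- table(el)
    multi <- names(tab)[tab >= 2]
    if (length(multi) == 0)
      stop("template has no element with >= 2 atoms to swap")
    idx <- which(el == multi[1])[1:2]
    perm[idx] <- rev(perm[idx])
  } else if (permutation == "random_element_preserving") {
    for (e in unique(el)) {
      idx <- which(el == e)
      if (length(idx) > 1) perm[idx] <- idx[sample(length(idx))]
    }
  }
  displacement <- as.numeric(displacement)
  A <- .pose_xyz(poseA)
  Bxyz <- sweep(A[perm, , drop = FALSE], 2, displacement, "+")
  batoms <- poseA$atoms[perm, , drop = FALSE]
  batoms$x <- Bxyz[, 1]; batoms$y <- Bxyz[, 2]; batoms$z <- Bxyz[, 3]
  poseB <- ligand_pose(batoms, label = paste0(poseA$label, "_perm"))
  # naive truth: identity-index displacement vectors, plain formula
  disp <- Bxyz - A
  naive <- sqrt(mean(rowSums(disp^2)))
  # sym truth
  tnorm <- sqrt(sum(displacement^2))
  classes <- table(el[!(el %in% c("H", "D"))])
  if (max(classes) <= oracle_limit) {
    sym <- exhaustive_sym_rmsd(poseA, poseB)
    method <- "exhaustive"
  } else {
    dmin <- min(vapply(names(classes)[classes >= 2], function(e) {
      idx <- which(el == e)
      min(stats::dist(A[idx, , drop = FALSE]))
    }, numeric(1)))
    if (dmin <= 2 * tnorm)
      stop("analytic ground truth requires same-element spacing > twice ",
           "the displacement; reduce the displacement or use a template ",
           "with <= ", oracle_limit, " atoms per element")
    sym <- tnorm
    method <- "analytic"
  }
  list(poseA = poseA, poseB = poseB,
       truth = list(naive_rmsd = naive, sym_rmsd = sym,
                    sym_method = method, permutation = perm,
                    displacement = displacement))
}

# ---- planted interaction scenes ----

# Side-chain templates in a local frame: interaction anchor at the
# origin, residue body extending toward +x (mapped outward, away from
# the ligand).  Coordinates are plausible, not stereochemically exact.
.SC_TEMPLATES <- list(
  LYS = list(anchor = "NZ", atoms = data.frame(
    elety = c("NZ", "CE", "CD", "CG", "CB", "CA", "N", "C", "O"),
    elesy = c("N", "C", "C", "C", "C", "C", "N", "C", "O"),
    x = c(0, 1.3, 2.6, 3.9, 5.2, 6.5, 7.0, 7.5, 8.7),
    y = c(0, 0.5, -0.2, 0.5, -0.2, 0.5, 1.6, -0.5, -0.5),
    z = c(0, 0, 0, 0, 0, 0, 0.8, -0.5, -0.5),
    stringsAsFactors = FALSE)),
  ARG = list(anchor = "CZ", atoms = data.frame(
    elety = c("CZ", "NH1", "NH2", "NE", "CD", "CG", "CB", "CA", "N",
              "C", "O"),
    elesy = c("C", "N", "N", "N", "C", "C", "C", "C", "N", "C", "O"),
    x = c(0, -0.6, -0.6, 1.3, 2.6, 3.9, 5.2, 6.5, 7.0, 7.5, 8.7),
    y = c(0, 1.1, -1.1, 0.3, -0.4, 0.3, -0.4, 0.3, 1.4, -0.7, -0.7),
    z = c(0, 0, 0, 0, 0, 0, 0, 0, 0.8, -0.5, -0.5),
    stringsAsFactors = FALSE)),
  ASN = list(anchor = "ND2", atoms = data.frame(
    elety = c("ND2", "CG", "OD1", "CB", "CA", "N", "C", "O"),
    elesy = c("N", "C", "O", "C", "C", "N", "C", "O"),
    x = c(0, 1.2, 1.6, 2.4, 3.8, 4.3, 4.8, 6.0),
    y = c(0, 0.4, 1.5, -0.5, 0, 1.1, -1.0, -1.0),
    z = c(0, 0, 0, 0, 0, 0.8, -0.5, -0.5),
    stringsAsFactors = FALSE)),
  THR = list(anchor = "OG1", atoms = data.frame(
    elety = c("OG1", "CB", "CG2", "CA", "N", "C", "O"),
    elesy = c("O", "C", "C", "C", "N", "C", "O"),
    x = c(0, 1.3, 1.8, 2.6, 3.1, 3.6, 4.8),
    y = c(0, 0.5, 1.6, -0.4, 0.7, -1.5, -1.5),
    z = c(0, 0, 0.9, 0, 0.8, -0.5, -0.5),
    stringsAsFactors = FALSE)),
  SER = list(anchor = "OG", atoms = data.frame(
    elety = c("OG", "CB", "CA", "N", "C", "O"),
    elesy = c("O", "C", "C", "N", "C", "O"),
    x = c(0, 1.3, 2.6, 3.1, 3.6, 4.8),
    y = c(0, 0.5, -0.4, 0.7, -1.5, -1.5),
    z = c(0, 0, 0, 0.8, -0.5, -0.5),
    stringsAsFactors = FALSE)),
  LEU = list(anchor = "CD1", atoms = data.frame(
    elety = c("CD1", "CG", "CD2", "CB", "CA", "N", "C", "O"),
    elesy = c("C", "C", "C", "C", "C", "N", "C", "O"),
    x = c(0, 1.3, 1.8, 2.6, 3.9, 4.4, 4.9, 6.1),
    y = c(0, 0.5, 1.6, -0.4, 0.3, 1.4, -0.8, -0.8),
    z = c(0, 0, 0.9, 0, 0, 0.8, -0.5, -0.5),
    stringsAsFactors = FALSE)),
  PHE = list(anchor = "ring", atoms = data.frame(
    elety = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CB", "CA", "N",
              "C", "O"),
    elesy = c("C", "C", "C", "C", "C", "C", "C", "C", "N", "C", "O"),
    x = c(0, 0, 0, 0, 0, 0, 0.8, 2.1, 2.6, 3.1, 4.3),
    y = c(1.39, 0.695, -0.695, -1.39, -0.695, 0.695, 2.6, 3.0, 4.1,
          1.9, 1.9),
    z = c(0, 1.204, 1.204, 0, -1.204, -1.204, 0, 0, 0.8, -0.5, -0.5),
    stringsAsFactors = FALSE)),
  TYR = list(anchor = "ring", atoms = data.frame(
    elety = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "OH", "CB", "CA",
              "N", "C", "O"),
    elesy = c("C", "C", "C", "C", "C", "C", "O", "C", "C", "N", "C", "O"),
    x = c(0, 0, 0, 0, 0, 0, 0, 0.8, 2.1, 2.6, 3.1, 4.3),
    y = c(1.39, 0.695, -0.695, -1.39, -0.695, 0.695, -2.76, 2.6, 3.0,
          4.1, 1.9, 1.9),
    z = c(0, 1.204, 1.204, 0, -1.204, -1.204, 0, 0, 0, 0.8, -0.5, -0.5),
    stringsAsFactors = FALSE)))

# Ligand fragments: anchor at origin, body extending +x (mapped toward
# the scene center).  "anchor" is the atom (or ring centroid) whose
# distance to the residue anchor is planted.
.FRAG_TEMPLATES <- list(
  phosphate = list(atoms = data.frame(
    elety = c("O1", "P1", "O2", "O3", "O4"),
    elesy = c("O", "P", "O", "O", "O"),
    x = c(0, 1.5, 2.25, 2.25, 2.0), y = c(0, 0, 1.3, -1.3, 0),
    z = c(0, 0, 0, 0, -1.4), stringsAsFactors = FALSE),
    bonds = cbind(2L, c(1L, 3L, 4L, 5L)), anchor = 1L),
  carbonyl = list(atoms = data.frame(
    elety = c("O1", "C1", "C2", "C3"),
    elesy = c("O", "C", "C", "C"),
    x = c(0, 1.23, 2.0, 2.0), y = c(0, 0, 1.25, -1.25), z = 0,
    stringsAsFactors = FALSE),
    bonds = cbind(c(2L, 2L, 2L), c(1L, 3L, 4L)), anchor = 1L),
  ethane = list(atoms = data.frame(
    elety = c("C1", "C2"), elesy = c("C", "C"),
    x = c(0, 1.5), y = 0, z = 0, stringsAsFactors = FALSE),
    bonds = cbind(1L, 2L), anchor = 1L),
  benzene = list(atoms = data.frame(
    elety = paste0("C", 1:6), elesy = "C",
    x = 0,
    y = 1.39 * cos(seq(0, 5) * pi / 3),
    z = 1.39 * sin(seq(0, 5) * pi / 3), stringsAsFactors = FALSE),
    bonds = cbind(1:6, c(2:6, 1L)), anchor = 0L))  # anchor 0 = centroid

# kind -> (allowed residue templates, fragment, anchor distance rule)
.SCENE_KIND <- list(
  SB = list(res = c(K = "LYS", R = "ARG"), frag = "phosphate",
            rule = "sb_dist"),
  HB = list(res = c(N = "ASN", T = "THR", S = "SER", K = "LYS"),
            frag = "carbonyl", rule = "hb_dist"),
  HI = list(res = c(L = "LEU"), frag = "ethane", rule = "hi_dist"),
  PI_STACK = list(res = c(F = "PHE", Y = "TYR"), frag = "benzene",
                  rule = "pi_dist"))

# Icosahedron vertex directions (12 well-separated unit vectors).
.ico_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v / sqrt(rowSums(v^2))
}

# Orthonormal frame with first axis u.
.frame_from <- function(u) {
  u <- .normalize(u)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- .normalize(.cross3(u, ref))
  w <- .cross3(u, v)
  cbind(u, v, w)
}

#' Generate a binding-site scene with planted interactions
#'
#' Places real side-chain templates (Lys, Arg, Asn, Thr, Ser, Leu, Phe,
#' Tyr) and matching ligand fragments on well-separated directions around
#' a common center, at geometries 0.5 A inside the rule threshold for
#' positive plants and 1.0 A outside it for negative plants.  The planted
#' truth lists exactly the positive (residue, kind) pairs;
#' \code{\link{detect_interactions}} on the scene must recover them with
#' no extras.
#'
#' @param plants data.frame with columns \code{resno}, \code{aa}
#'   (one-letter; must suit the kind: SB needs K/R, HB needs N/T/S/K, HI
#'   needs L, PI_STACK needs F/Y) and \code{kind}.
#' @param negatives optional data.frame of the same shape, planted
#'   outside the thresholds.
#' @param rules the \code{\link{interaction_rules}} whose thresholds the
#'   geometry is planted against.
#' @param seed RNG seed (direction jitter on placement retries).
#' @param r_anchor radius at which residue anchors sit (A).
#' @return list with \code{model} (single-chain
#'   \code{\link{structure_model}}), \code{ligand}
#'   (\code{\link{ligand_pose}} with bonds) and \code{truth} (data.frame
#'   resno, aa, kind of the positive plants).
#' @export
make_interaction_scene <- function(plants, negatives = NULL,
                                   rules = interaction_rules(), seed = 1,
                                   r_anchor = 12) {
  set.seed(seed)
  plants <- as.data.frame(plants)
  negatives <- if (is.null(negatives)) plants[0, , drop = FALSE]
               else as.data.frame(negatives)
  all_plants <- rbind(
    if (nrow(plants)) cbind(plants, positive = TRUE),
    if (nrow(negatives)) cbind(negatives, positive = FALSE))
  n <- if (is.null(all_plants)) 0L else nrow(all_plants)
  if (n == 0) {
    # empty scene: a lone glycine-like stub far from a lone carbon
    model <- structure_model(data.frame(
      type = "ATOM", eleno = 1:2, elety = c("N", "CA"), altloc = "",
      resid = "GLY", aa = "G", chain = "A", resno = 1L, insert = "",
      x = c(50, 51.4), y = 0, z = 0, o = 1, b = 50,
      elesy = c("N", "C"), stringsAsFactors = FALSE), id = "scene")
    lig <- ligand_pose(data.frame(elety = "C1", elesy = "C", x = 0,
                                  y = 0, z = 0), label = "scene_ligand")
    return(list(model = model, ligand = lig,
                truth = data.frame(resno = integer(0), aa = character(0),
                                   kind = character(0))))
  }
  if (n > 12) stop("at most 12 plants per scene")
  if (anyDuplicated(all_plants$resno))
    stop("plant residue numbers must be unique")
  dirs <- .ico_directions()
  for (attempt in seq_len(100)) {
    if (attempt > 1) {
      J <- .random_rotation()
      dirs <- dirs %*% t(J)
    }
    res_rows <- list()
    lig_rows <- list()
    lig_bonds <- NULL
    ok <- TRUE
    group_xyz <- list()
    for (k in seq_len(n)) {
      kind <- as.character(all_plants$kind[k])
      aa <- toupper(as.character(all_plants$aa[k]))
      rn <- as.integer(all_plants$resno[k])
      spec_k <- .SCENE_KIND[[kind]]
      if (is.null(spec_k)) stop("unknown interaction kind: ", kind)
      if (!aa %in% names(spec_k$res))
        stop("residue type ", aa, " cannot carry a planted ", kind,
             " (supported: ", paste(names(spec_k$res), collapse = "/"),
             ")")
      r3 <- spec_k$res[[aa]]
      tpl <- .SC_TEMPLATES[[r3]]
      frag <- .FRAG_TEMPLATES[[spec_k$frag]]
      d_plant <- if (all_plants$positive[k])
        rules[[spec_k$rule]] - 0.5 else rules[[spec_k$rule]] + 1.0
      u <- dirs[k, ]
      Fout <- .frame_from(u)    # +x -> outward
      Fin <- .frame_from(-u)    # +x -> inward
      # residue: anchor at r_anchor * u, body outward
      rxyz <- as.matrix(tpl$atoms[, c("x", "y", "z")]) %*% t(Fout)
      rxyz <- unname(sweep(rxyz, 2, r_anchor * u, "+"))
      res_rows[[k]] <- data.frame(
        type = "ATOM", eleno = 0L, elety = tpl$atoms$elety, altloc = "",
        resid = r3, aa = .aa321(r3), chain = "A", resno = rn,
        insert = "", x = rxyz[, 1], y = rxyz[, 2], z = rxyz[, 3],
        o = 1, b = 80, elesy = tpl$atoms$elesy, stringsAsFactors = FALSE)
      # fragment: anchor at (r_anchor - d_plant) * u, body inward
      fxyz <- as.matrix(frag$atoms[, c("x", "y", "z")])
      if (kind == "PI_STACK")   # tilt the ligand ring by 5 degrees
        fxyz <- fxyz %*% t(rotation_about_axis(c(0, 1, 0), 5))
      fxyz <- fxyz %*% t(Fin)
      fxyz <- unname(sweep(fxyz, 2, (r_anchor - d_plant) * u, "+"))
      off <- sum(vapply(lig_rows, nrow, integer(1)))
      lig_rows[[length(lig_rows) + 1L]] <- data.frame(
        elety = paste0(frag$atoms$elety, "_", k),
        elesy = frag$atoms$elesy,
        x = fxyz[, 1], y = fxyz[, 2], z = fxyz[, 3],
        stringsAsFactors = FALSE)
      if (!is.null(frag$bonds))
        lig_bonds <- rbind(lig_bonds, frag$bonds + off)
      group_xyz[[k]] <- rbind(rxyz, fxyz)
    }
    # steric check between distinct planted groups
    clash <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        di <- group_xyz[[i]]; dj <- group_xyz[[j]]
        dmin <- min(sqrt(pmax(0,
                    outer(rowSums(di^2), rep(1, nrow(dj))) +
                    outer(rep(1, nrow(di)), rowSums(dj^2)) -
                    2 * di %*% t(dj))))
        if (is.finite(dmin) && dmin < 1.5) clash <- TRUE
      }
      if (clash) break
    }
    if (!clash) {
      atoms <- do.call(rbind, res_rows)
      atoms$eleno <- seq_len(nrow(atoms))
      model <- structure_model(atoms, id = "scene",
                               metadata = list(seed = seed),
                               predicted = TRUE)
      lig <- ligand_pose(do.call(rbind, lig_rows),
                         label = "scene_ligand", bonds = lig_bonds)
      truth <- data.frame(resno = as.integer(plants$resno),
                          aa = toupper(as.character(plants$aa)),
                          kind = as.character(plants$kind),
                          stringsAsFactors = FALSE)
      return(list(model = model, ligand = lig, truth = truth))
    }
  }
  stop("could not place planted groups without steric overlap after ",
       "100 attempts")
}
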