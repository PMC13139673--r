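# Fixtures built in code: PDB/SDF text writers for hand-crafted cases.

# One fixed-width PDB ATOM/HETATM line.
pdb_line <- function(eleno = 1, elety = "CA", type = "ATOM", altloc = "",
                     resid = "ALA", chain = "A", resno = 1, x = 0, y = 0,
                     z = 0, occ = 1, b = 0, elesy = "C") {
  name <- if (nchar(elety) < 4) sprintf(" %-3s", elety)
          else sprintf("%-4s", elety)
  sprintf("%-6s%5d %s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, eleno, name, altloc, resid, chain, resno, x, y, z, occ,
          b, elesy)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# HETATM block for an ATP molecule with the standard 47-atom component
# (31 heavy atoms + 16 hydrogens); coordinates are placeholders on a
# grid, only the count and the element census matter.
write_atp_pdb <- function(path = tempfile(fileext = ".pdb")) {
  heavy <- c("PG", "O1G", "O2G", "O3G", "PB", "O1B", "O2B", "O3B", "PA",
             "O1A", "O2A", "O3A", "O5'", "C5'", "C4'", "O4'", "C3'",
             "O3'", "C2'", "O2'", "C1'", "N9", "C8", "N7", "C5", "C6",
             "N6", "N1", "C2", "N3", "C4")
  hyd <- c("H5'", "H5''", "H4'", "H3'", "HO3'", "H2'", "HO2'", "H1'",
           "H8", "H61", "H62", "H2", "HOG2", "HOG3", "HOB2", "HOA2")
  names_all <- c(heavy, hyd)
  elesy <- c(substr(gsub("[0-9']", "", heavy), 1, 1), rep("H", 16))
  lines <- vapply(seq_along(names_all), function(i)
    pdb_line(i, names_all[i], type = "HETATM", resid = "ATP",
             chain = "A", resno = 501, x = (i %% 7) * 1.6,
             y = (i %% 5) * 1.7, z = (i %% 3) * 1.8, elesy = elesy[i]),
    character(1))
  write_pdb_fixture(lines, path)
}

# Minimal single-molecule SDF (V2000) text.
write_sdf_fixture <- function(elements, xyz,
                              bonds = NULL,
                              path = tempfile(fileext = ".sdf"),
                              n_copies = 1) {
  block <- c(
    "mol", "  fixture", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            length(elements), if (is.null(bonds)) 0L else nrow(bonds)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            xyz[, 1], xyz[, 2], xyz[, 3], elements),
    if (!is.null(bonds))
      sprintf("%3d%3d%3d  0", bonds[, 1], bonds[, 2],
              rep(1L, nrow(bonds))),
    "M  END", "$$$$")
  writeLines(rep(block, n_copies), path)
  path
}

# Random small structure model for round-trip properties.
random_model <- function(seed) {
  set.seed(seed)
  make_trimer(n_chains = sample(1:3, 1),
              n_residues = sample(10:20, 1),
              profile = conf_profile(base = runif(1, 40, 95),
                                     atom_sd = runif(1, 0, 4)),
              seed = seed)$model
}

# Random ligand pose: n atoms per element class drawn on a box.
random_pose <- function(seed, max_per_element = 5,
                        elements = c("C", "N", "O", "P")) {
  set.seed(seed)
  counts <- sample(1:max_per_element, length(elements), replace = TRUE)
  el <- rep(elements, counts)
  n <- length(el)
  ligand_pose(data.frame(
    elety = paste0(el, seq_len(n)), elesy = el,
    x = runif(n, -6, 6), y = runif(n, -6, 6), z = runif(n, -6, 6),
    stringsAsFactors = FALSE), label = paste0("rand", seed))
}

# Element-preserving random shuffle + jitter of a pose.
perturbed_pose <- function(pose, seed, jitter = 0.8) {
  set.seed(seed)
  el <- pose$atoms$elesy
  perm <- seq_along(el)
  for (e in unique(el)) {
    idx <- which(el == e)
    if (length(idx) > 1) perm[idx] <- idx[sample(length(idx))]
  }
  atoms <- pose$atoms[perm, , drop = FALSE]
  atoms$x <- atoms$x + rnorm(nrow(atoms), 0, jitter)
  atoms$y <- atoms$y + rnorm(nrow(atoms), 0, jitter)
  atoms$z <- atoms$z + rnorm(nrow(atoms), 0, jitter)
  ligand_pose(atoms, label = paste0(pose$label, "_p"))
}
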