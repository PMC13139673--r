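# interactions: geometric detection of protein-ligand contacts (hydrogen
# bonds, salt bridges, hydrophobic contacts, pi-stacking) and key-residue
# interaction fingerprints.
#
# The detector re-implements the geometric role of a protein-ligand
# interaction profiler with explicit, configurable thresholds, so the
# same analysis is reproducible without an external web service.  It runs
# hydrogen-free by default: hydrogen-bond detection then uses heavy-atom
# donor-acceptor distance alone, and the donor angle is checked only when
# explicit hydrogens are present.

#' Geometric interaction rules
#'
#' Distance and angle thresholds for the four detected contact classes.
#' Defaults follow the published geometric criteria of the standard
#' profiling tools: hydrogen bonds at donor-acceptor <= 3.6 A (donor
#' angle >= 100 degrees when hydrogens are present), salt bridges at
#' charged-center distance <= 5.5 A, hydrophobic carbon-carbon contacts
#' at <= 4.0 A, and aromatic stacking at ring-centroid distance <= 5.5 A
#' with interplanar angle <= 30 degrees (parallel) or between 60 and 90
#' degrees (T-shaped).
#'
#' @param hb_dist,hb_angle_min hydrogen-bond thresholds (A, degrees).
#' @param sb_dist salt-bridge charged-center distance (A).
#' @param hi_dist hydrophobic carbon-carbon distance (A).
#' @param pi_dist,pi_parallel_max,pi_tshape_min,pi_tshape_max
#'   pi-stacking centroid distance (A) and interplanar angle windows
#'   (degrees).
#' @return object of class \code{interaction_rules}.
#' @export
interaction_rules <- function(hb_dist = 3.6, hb_angle_min = 100,
                              sb_dist = 5.5, hi_dist = 4.0,
                              pi_dist = 5.5, pi_parallel_max = 30,
                              pi_tshape_min = 60, pi_tshape_max = 90) {
  vals <- c(hb_dist = hb_dist, sb_dist = sb_dist, hi_dist = hi_dist,
            pi_dist = pi_dist)
  if (any(vals <= 0)) stop("distance thresholds must be positive")
  angles <- c(hb_angle_min, pi_parallel_max, pi_tshape_min, pi_tshape_max)
  if (any(angles < 0 | angles > 180))
    stop("angle bounds must lie in [0, 180] degrees")
  structure(list(hb_dist = hb_dist, hb_angle_min = hb_angle_min,
                 sb_dist = sb_dist, hi_dist = hi_dist, pi_dist = pi_dist,
                 pi_parallel_max = pi_parallel_max,
                 pi_tshape_min = pi_tshape_min,
                 pi_tshape_max = pi_tshape_max),
            class = "interaction_rules")
}

# ---- protein atom chemistry tables (heavy atoms, standard residues) ----

.PROT_DONOR_SC <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  SER = "OG", THR = "OG1", TYR = "OH", TRP = "NE1", HIS = c("ND1", "NE2"),
  CYS = "SG")

.PROT_ACCEPTOR_SC <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))

# positive / negative charged centers: atom sets whose centroid is the
# charge center
.PROT_POS <- list(LYS = "NZ", ARG = "CZ", HIS = c("ND1", "NE2"))
.PROT_NEG <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# side-chain carbons bonded only to carbon (or hydrogen)
.PROT_APOLAR <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), PRO = c("CB", "CG"), MET = "CB",
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  TRP = c("CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"), THR = "CG2",
  GLN = c("CB", "CG"), GLU = c("CB", "CG"), ASP = "CB", ASN = "CB",
  HIS = "CB", CYS = "CB")

.PROT_RINGS <- list(
  PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))

# covalent radii (A) for bond inference
.COV_RADII <- c(H = 0.31, D = 0.31, C = 0.76, N = 0.71, O = 0.66,
                P = 1.07, S = 1.05, F = 0.57, Cl = 1.02, Br = 1.20,
                I = 1.39, B = 0.84, Se = 1.20, Si = 1.11)

# Infer covalent bonds from interatomic distances (<= 1.25 x sum of
# covalent radii).
.infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(NULL)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- .COV_RADII[atoms$elesy]
  r[is.na(r)] <- 0.9
  out <- NULL
  for (i in seq_len(n - 1)) {
    d <- sqrt(rowSums((xyz[(i + 1):n, , drop = FALSE] -
                       matrix(xyz[i, ], n - i, 3, byrow = TRUE))^2))
    hit <- which(d <= 1.25 * (r[i] + r[(i + 1):n]) & d > 0.4)
    if (length(hit)) out <- rbind(out, cbind(i, i + hit))
  }
  out
}

# Ligand chemistry: returns list(acceptors, donors, negative, positive,
# apolar, rings, has_bond_info) with atom indices; rings is a list of
# integer vectors.
.ligand_classes <- function(pose) {
  atoms <- pose$atoms
  el <- atoms$elesy
  n <- nrow(atoms)
  bonds <- pose$bonds
  has_bond_info <- !is.null(bonds)
  if (!has_bond_info) bonds <- .infer_bonds(atoms)
  nb <- vector("list", n)
  if (!is.null(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  heavy_nb <- lapply(nb, function(v) v[!(el[v] %in% c("H", "D"))])
  has_h <- any(el %in% c("H", "D"))
  is_NO <- el %in% c("N", "O")
  acceptors <- which(is_NO & vapply(seq_len(n), function(i)
    !(el[i] == "N" && length(heavy_nb[[i]]) >= 4), logical(1)))
  donors <- if (has_h) {
    which(is_NO & vapply(seq_len(n), function(i)
      any(el[nb[[i]]] %in% c("H", "D")), logical(1)))
  } else which(is_NO)
  # formal-charge inference; explicit charge column overrides
  negative <- integer(0)
  positive <- integer(0)
  for (i in seq_len(n)) {
    if (el[i] == "O") {
      hn <- heavy_nb[[i]]
      if (any(el[hn] == "P")) negative <- c(negative, i)
      else if (any(vapply(hn, function(j)
        el[j] == "C" && sum(el[heavy_nb[[j]]] == "O") >= 2, logical(1))))
        negative <- c(negative, i)
    } else if (el[i] == "N" && length(heavy_nb[[i]]) >= 4) {
      positive <- c(positive, i)
    }
  }
  if (!is.null(atoms$charge)) {
    ch <- atoms$charge
    negative <- union(negative, which(!is.na(ch) & ch < 0))
    positive <- union(positive, which(!is.na(ch) & ch > 0))
    negative <- setdiff(negative, which(!is.na(ch) & ch >= 0))
    positive <- setdiff(positive, which(!is.na(ch) & ch <= 0))
  }
  apolar <- which(el == "C" & vapply(seq_len(n), function(i)
    !any(el[heavy_nb[[i]]] %in% c("N", "O", "P", "S")), logical(1)))
  rings <- .find_rings(n, bonds, el,
                       as.matrix(atoms[, c("x", "y", "z")]))
  list(acceptors = acceptors, donors = donors, negative = negative,
       positive = positive, apolar = apolar, rings = rings,
       has_bond_info = has_bond_info, neighbors = nb)
}

# Aromatic-ring proxy: 5- or 6-cycles of C/N atoms, coplanar within
# 0.2 A.  Smallest cycles are collected through each edge's shortest
# alternative path.
.find_rings <- function(n_atoms, bonds, el, xyz) {
  if (is.null(bonds) || nrow(bonds) < 3) return(list())
  g <- igraph::graph_from_edgelist(bonds[, 1:2, drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < n_atoms)
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, i, j)$vpath[[1]])
    if (length(sp) == 0) next
    cyc <- as.integer(sp)
    if (length(cyc) < 3 || length(cyc) > 6) next
    key <- paste(sort(cyc), collapse = "-")
    if (key %in% seen) next
    seen <- c(key, seen)
    if (!(length(cyc) %in% c(5L, 6L))) next
    if (!all(el[cyc] %in% c("C", "N"))) next
    pts <- xyz[cyc, , drop = FALSE]
    ctr <- colMeans(pts)
    dev <- svd(sweep(pts, 2, ctr))$d[3]
    # largest out-of-plane deviation ~ third singular value / sqrt(n)
    if (dev / sqrt(length(cyc)) > 0.2) next
    rings[[length(rings) + 1L]] <- cyc
  }
  rings
}

# Ring centroid and unit normal from an m x 3 coordinate block.
.ring_geometry <- function(pts) {
  ctr <- colMeans(pts)
  s <- svd(sweep(pts, 2, ctr))
  list(centroid = ctr, normal = s$v[, 3])
}

# Angle between ring planes, folded to [0, 90] degrees.
.interplanar_angle <- function(n1, n2) {
  cosang <- abs(sum(n1 * n2)) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

.angle_deg <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Detect protein-ligand interactions
#'
#' Deterministic geometric sweep over residue/ligand atom pairs applying
#' the thresholds in \code{rules}.  Hydrogen bonds are detected between
#' protein donors and ligand N/O acceptors (and vice versa) on heavy-atom
#' distance, with the explicit D-H...A donor angle enforced only when
#' hydrogens are present.  Salt bridges pair protein charged centers
#' (Lys NZ, Arg guanidinium CZ, His ring; Asp/Glu carboxylates) with
#' oppositely charged ligand atoms (phosphate/carboxylate oxygens
#' negative, quaternary or explicitly charged amines positive).
#' Hydrophobic contacts pair apolar carbons.  Pi-stacking pairs aromatic
#' rings (Phe/Tyr/Trp/His side chains; ligand rings perceived from the
#' bond graph, inferred from covalent radii when absent) on centroid
#' distance and interplanar angle.  Per (residue, kind), only the
#' shortest contact is kept.
#'
#' @param protein a \code{\link{structure_model}}.
#' @param ligand a \code{\link{ligand_pose}} placed in the protein frame.
#' @param rules an \code{\link{interaction_rules}} object.
#' @return data.frame of class \code{interaction_records}: columns
#'   \code{kind} (HB/SB/HI/PI_STACK), \code{chain}, \code{resno},
#'   \code{aa}, \code{resid}, \code{protein_atom}, \code{ligand_atom},
#'   \code{distance}, \code{angle} (degrees or NA).
#' @export
detect_interactions <- function(protein, ligand,
                                rules = interaction_rules()) {
  stopifnot(inherits(protein, "structure_model"),
            inherits(ligand, "ligand_pose"))
  lc <- .ligand_classes(ligand)
  if (!lc$has_bond_info && length(lc$rings) == 0 &&
      sum(ligand$atoms$elesy == "C") >= 5)
    warning("ligand has no bond information and no detectable rings; ",
            "pi-stacking detection skipped for it")
  L <- .pose_xyz(ligand)
  lat <- ligand$atoms
  prot <- protein$atoms
  prot <- prot[!(prot$elesy %in% c("H", "D")) | TRUE, , drop = FALSE]
  # prefilter residues by bounding distance
  reach <- max(rules$hb_dist, rules$sb_dist, rules$hi_dist,
               rules$pi_dist) + 3
  lmin <- apply(L, 2, min) - reach
  lmax <- apply(L, 2, max) + reach
  near <- prot$x >= lmin[1] & prot$x <= lmax[1] &
          prot$y >= lmin[2] & prot$y <= lmax[2] &
          prot$z >= lmin[3] & prot$z <= lmax[3]
  keys <- unique(paste(prot$chain, prot$resno, prot$insert,
                       sep = "\r")[near])
  rec <- list()
  add <- function(kind, ch, rn, aa, resid, patom, latom, dist,
                  angle = NA_real_) {
    rec[[length(rec) + 1L]] <<- data.frame(
      kind = kind, chain = ch, resno = rn, aa = aa, resid = resid,
      protein_atom = patom, ligand_atom = latom, distance = dist,
      angle = angle, stringsAsFactors = FALSE)
  }
  prot_key <- paste(prot$chain, prot$resno, prot$insert, sep = "\r")
  hfree_l <- length(lc$donors) > 0 && !any(lat$elesy %in% c("H", "D"))
  for (key in keys) {
    res <- prot[prot_key == key, , drop = FALSE]
    res_heavy <- res[!(res$elesy %in% c("H", "D")), , drop = FALSE]
    rn <- res$resno[1]; ch <- res$chain[1]
    r3 <- toupper(res$resid[1]); aa1 <- res$aa[1]
    rxyz <- as.matrix(res_heavy[, c("x", "y", "z")])
    res_h <- res[res$elesy %in% c("H", "D"), , drop = FALSE]
    # --- hydrogen bonds ---
    donors <- c(if (r3 != "PRO") "N", .PROT_DONOR_SC[[r3]])
    acceptors <- c("O", "OXT", .PROT_ACCEPTOR_SC[[r3]])
    for (dn in intersect(donors, res_heavy$elety)) {
      dpos <- rxyz[match(dn, res_heavy$elety), ]
      for (ai in lc$acceptors) {
        d <- sqrt(sum((dpos - L[ai, ])^2))
        if (d > rules$hb_dist) next
        ang <- NA_real_
        if (nrow(res_h) > 0) {
          hxyz <- as.matrix(res_h[, c("x", "y", "z")])
          hd <- sqrt(rowSums(sweep(hxyz, 2, dpos)^2))
          att <- which(hd < 1.3)
          if (length(att)) {
            ang <- max(vapply(att, function(h)
              .angle_deg(dpos, hxyz[h, ], L[ai, ]), numeric(1)))
            if (ang < rules$hb_angle_min) next
          }
        }
        add("HB", ch, rn, aa1, r3, dn, lat$elety[ai], d, ang)
      }
    }
    for (ac in intersect(acceptors, res_heavy$elety)) {
      apos <- rxyz[match(ac, res_heavy$elety), ]
      for (di in lc$donors) {
        d <- sqrt(sum((apos - L[di, ])^2))
        if (d > rules$hb_dist) next
        ang <- NA_real_
        if (!hfree_l) {
          hs <- lc$neighbors[[di]]
          hs <- hs[lat$elesy[hs] %in% c("H", "D")]
          if (length(hs)) {
            ang <- max(vapply(hs, function(h)
              .angle_deg(L[di, ], L[h, ], apos), numeric(1)))
            if (ang < rules$hb_angle_min) next
          }
        }
        add("HB", ch, rn, aa1, r3, ac, lat$elety[di], d, ang)
      }
    }
    # --- salt bridges ---
    pos_atoms <- .PROT_POS[[r3]]
    if (!is.null(pos_atoms) && all(pos_atoms %in% res_heavy$elety)) {
      ctr <- colMeans(rxyz[match(pos_atoms, res_heavy$elety), ,
                           drop = FALSE])
      for (ni in lc$negative) {
        d <- sqrt(sum((ctr - L[ni, ])^2))
        if (d <= rules$sb_dist)
          add("SB", ch, rn, aa1, r3, paste(pos_atoms, collapse = "/"),
              lat$elety[ni], d)
      }
    }
    neg_atoms <- .PROT_NEG[[r3]]
    if (!is.null(neg_atoms) && all(neg_atoms %in% res_heavy$elety)) {
      ctr <- colMeans(rxyz[match(neg_atoms, res_heavy$elety), ,
                           drop = FALSE])
      for (pi_ in lc$positive) {
        d <- sqrt(sum((ctr - L[pi_, ])^2))
        if (d <= rules$sb_dist)
          add("SB", ch, rn, aa1, r3, paste(neg_atoms, collapse = "/"),
              lat$elety[pi_], d)
      }
    }
    # --- hydrophobic contacts ---
    apolar <- intersect(.PROT_APOLAR[[r3]] %||% character(0),
                        res_heavy$elety)
    if (length(apolar) && length(lc$apolar)) {
      pxyz <- rxyz[match(apolar, res_heavy$elety), , drop = FALSE]
      for (q in seq_along(apolar)) {
        dd <- sqrt(rowSums(sweep(L[lc$apolar, , drop = FALSE], 2,
                                 pxyz[q, ])^2))
        hit <- which(dd <= rules$hi_dist)
        for (h in hit)
          add("HI", ch, rn, aa1, r3, apolar[q],
              lat$elety[lc$apolar[h]], dd[h])
      }
    }
    # --- pi-stacking ---
    prings <- .PROT_RINGS[[r3]]
    if (!is.null(prings) && length(lc$rings)) {
      for (ratoms in prings) {
        if (!all(ratoms %in% res_heavy$elety)) next
        pg <- .ring_geometry(rxyz[match(ratoms, res_heavy$elety), ,
                                  drop = FALSE])
        for (ring in lc$rings) {
          lg <- .ring_geometry(L[ring, , drop = FALSE])
          d <- sqrt(sum((pg$centroid - lg$centroid)^2))
          if (d > rules$pi_dist) next
          ang <- .interplanar_angle(pg$normal, lg$normal)
          if (ang <= rules$pi_parallel_max ||
              (ang >= rules$pi_tshape_min && ang <= rules$pi_tshape_max))
            add("PI_STACK", ch, rn, aa1, r3,
                paste0("ring:", ratoms[1]),
                paste0("ring:", lat$elety[ring[1]]), d, ang)
        }
      }
    }
  }
  if (length(rec) == 0) {
    out <- data.frame(kind = character(0), chain = character(0),
                      resno = integer(0), aa = character(0),
                      resid = character(0), protein_atom = character(0),
                      ligand_atom = character(0), distance = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rec)
    # duplicate suppression: shortest contact per (chain, residue, kind)
    dkey <- paste(out$chain, out$resno, out$kind, sep = "\r")
    ord <- order(dkey, out$distance)
    out <- out[ord, , drop = FALSE][!duplicated(sort(dkey)), , drop = FALSE]
    out <- out[order(out$chain, out$resno,
                     match(out$kind, c("HB", "SB", "HI", "PI_STACK"))), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("interaction_records", "data.frame")
  out
}

# Table codes for interaction kinds.
.KIND_CODE <- c(HB = "HB", SB = "SB", HI = "HI", PI_STACK = "π-s")

#' Key-residue interaction fingerprint
#'
#' Collapses detected interaction records into one row per key residue of
#' a site definition, listing the contact kinds found (codes HB, SB, HI,
#' and the pi-stacking code), with an em-dash for residues without any
#' contact -- the standard per-residue fingerprint table layout.
#'
#' @param records \code{\link{detect_interactions}} output.
#' @param site a \code{\link{site_definition}}.
#' @return object of class \code{fingerprint_report}: list with
#'   \code{rows} (data.frame label, resno, aa, kinds), \code{n_key_hit},
#'   \code{site}.
#' @export
fingerprint <- function(records, site) {
  stopifnot(inherits(site, "site_definition"))
  kinds_for <- function(rn) {
    k <- unique(records$kind[records$resno == rn])
    k <- k[order(match(k, names(.KIND_CODE)))]
    if (length(k) == 0) "—" else
      paste(.KIND_CODE[k], collapse = ", ")
  }
  rows <- data.frame(
    label = paste0(site$aa, site$resno), resno = site$resno,
    aa = site$aa,
    kinds = vapply(site$resno, kinds_for, character(1)),
    stringsAsFactors = FALSE)
  structure(list(rows = rows,
                 n_key_hit = sum(rows$kinds != "—"),
                 site = site),
            class = "fingerprint_report")
}

#' @export
print.fingerprint_report <- function(x, ...) {
  cat(sprintf("interaction fingerprint over site '%s' (%d/%d key residues hit)\n",
              x$site$name, x$n_key_hit, nrow(x$rows)))
  for (i in seq_len(nrow(x$rows)))
    cat(sprintf("  %-6s %s\n", x$rows$label[i], x$rows$kinds[i]))
  invisible(x)
}

#' Compare fingerprints across models
#'
#' Key residues x models table of interaction codes, with a per-model
#' count of key residues hit -- the multi-model comparison layout used to
#' contrast docking results across structural models.
#'
#' @param reports named list of \code{\link{fingerprint_report}} objects
#'   sharing one site definition.
#' @return data.frame (rownames = key residue labels, one column per
#'   model) with attribute \code{n_key_hit} (named integer vector).
#' @export
compare_fingerprints <- function(reports) {
  if (length(reports) == 0) stop("no reports to compare")
  if (is.null(names(reports)))
    names(reports) <- paste0("model", seq_along(reports))
  ref <- reports[[1]]$site
  for (r in reports) {
    if (!identical(r$site$resno, ref$resno) ||
        !identical(r$site$aa, ref$aa))
      stop("all reports must share the same site definition")
  }
  tab <- data.frame(lapply(reports, function(r) r$rows$kinds),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(tab) <- reports[[1]]$rows$label
  attr(tab, "n_key_hit") <- vapply(reports, function(r) r$n_key_hit,
                                   integer(1))
  tab
}

#' Write a fingerprint comparison as TSV
#'
#' @param tab \code{\link{compare_fingerprints}} output.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_fingerprint_table <- function(tab, path) {
  out <- data.frame(`Key residues` = rownames(tab), tab,
                    check.names = FALSE, stringsAsFactors = FALSE)
  nk <- attr(tab, "n_key_hit")
  if (!is.null(nk))
    out <- rbind(out, c("Key residues hit", as.character(nk)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
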