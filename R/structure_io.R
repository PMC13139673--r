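# structure_io: ingestion and export of macromolecular models and ligand
# poses.  Parsing of the standard formats is delegated to bio3d (PDB,
# mmCIF) and ChemmineR (SDF V2000); this module normalises their output
# into one flat atom table per model.

#' Construct a structure model
#'
#' A \code{structure_model} is the package's uniform container for a
#' parsed macromolecular model: one atom per row of \code{atoms}, grouped
#' hierarchically by chain and author residue number.  Predicted models
#' (AlphaFold-style) carry per-residue or per-atom confidence (pLDDT,
#' 0-100) in the \code{b} column; experimental structures carry real
#' B-factors there and are flagged \code{predicted = FALSE}, which
#' disables the confidence operations.
#'
#' @param atoms data.frame with columns \code{type} ("ATOM"/"HETATM"),
#'   \code{eleno}, \code{elety} (atom name), \code{altloc}, \code{resid}
#'   (3-letter or ligand code), \code{aa} (1-letter), \code{chain},
#'   \code{resno} (author numbering), \code{insert}, \code{x}, \code{y},
#'   \code{z}, \code{o} (occupancy), \code{b}, \code{elesy} (element).
#' @param id model label.
#' @param metadata free-form list; may carry ingested pTM/ipTM/PAE values
#'   (never computed here).
#' @param predicted logical; TRUE marks the B-factor channel as pLDDT.
#' @return object of class \code{structure_model}.
#' @export
structure_model <- function(atoms, id = "model", metadata = list(),
                            predicted = TRUE) {
  required <- c("type", "eleno", "elety", "altloc", "resid", "aa", "chain",
                "resno", "insert", "x", "y", "z", "o", "b", "elesy")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty model: no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  if (any(occ < 0 | occ > 1)) stop("occupancy outside [0, 1]")
  atoms$o <- occ
  bad <- !.is_valid_element(atoms$elesy)
  if (any(bad))
    stop("invalid element symbol(s): ",
         paste(unique(atoms$elesy[bad]), collapse = ", "))
  atoms$elesy <- .element_case(atoms$elesy)
  # residues ordered by (resno, insert) within each chain
  ord <- order(match(atoms$chain, unique(atoms$chain)), atoms$resno,
               atoms$insert)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, metadata = metadata,
                 predicted = isTRUE(predicted)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  nres <- sum(!duplicated(x$atoms[, c("chain", "resno", "insert")]))
  cat(sprintf("structure_model '%s': %d chain(s) [%s], %d residues, %d atoms%s\n",
              x$id, length(ch), paste(ch, collapse = ","), nres,
              nrow(x$atoms),
              if (x$predicted) " (predicted; B = pLDDT)" else " (experimental)"))
  invisible(x)
}

#' Chain identifiers of a model, in file order
#' @param model a \code{structure_model}.
#' @return character vector of chain ids.
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Residue table of a model
#'
#' One row per (chain, resno, insert) with the residue code and atom count.
#' @param model a \code{structure_model}.
#' @return data.frame with columns chain, resno, insert, resid, aa, n_atoms.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    insert = a$insert[first], resid = a$resid[first],
                    aa = a$aa[first], stringsAsFactors = FALSE)
  out$n_atoms <- as.integer(table(factor(key, levels = key[first])))
  rownames(out) <- NULL
  out
}

# Altloc resolution: for each (chain, resno, insert, elety) keep the
# highest-occupancy conformer; ties resolved toward altloc "A" (then
# alphabetically).
.filter_altloc <- function(atoms) {
  alt <- atoms$altloc
  alt[is.na(alt)] <- ""
  atoms$altloc <- alt
  if (all(alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
               sep = "\r")
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  # altloc "" sorts before "A" so un-lettered conformers win ties
  ord <- order(key, -occ, alt)
  keep <- !duplicated(key[ord])
  atoms[sort(seq_len(nrow(atoms))[ord][keep]), , drop = FALSE]
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdb = "pdb", ent = "pdb",
         cif = "mmcif", mmcif = "mmcif",
         sdf = "sdf", mol = "sdf",
         stop("cannot guess format from extension '", ext,
              "'; pass format= explicitly"))
}

#' Read a macromolecular structure
#'
#' Parses a PDB or mmCIF file (via bio3d) into a
#' \code{\link{structure_model}}.  All ATOM/HETATM records are kept; for
#' alternate locations only the highest-occupancy conformer is retained
#' (tie broken toward altloc 'A').  Elements missing from the file are
#' inferred from atom names (\code{\link{infer_element}}).  The mmCIF
#' \code{B_iso_or_equiv} column is read as the confidence channel.
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (extension-based).
#' @param predicted logical; TRUE (default) treats the B-factor column as
#'   pLDDT.  Set FALSE for experimental structures.
#' @param id model label; defaults to the file base name.
#' @return a \code{\link{structure_model}}.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeLines(paste0("ATOM      1  CA  ALA A   1       1.000   2.000",
#'                   "   3.000  1.00 90.00           C"), f)
#' m <- read_structure(f)
#' m$atoms$b  # 90
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           predicted = TRUE, id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guess_format(path)
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("empty model: no atoms in ", path)
  atoms <- data.frame(
    type = a$type,
    eleno = a$eleno,
    elety = trimws(a$elety),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resid = trimws(a$resid),
    aa = .aa321(trimws(a$resid)),
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    elesy = if (!is.null(a$elesy)) trimws(a$elesy) else "",
    stringsAsFactors = FALSE)
  atoms <- .filter_altloc(atoms)
  miss <- is.na(atoms$elesy) | atoms$elesy == ""
  if (any(miss))
    atoms$elesy[miss] <- infer_element(atoms$elety[miss],
                                       atoms$type[miss] == "HETATM",
                                       atoms$resid[miss])
  if (any(atoms$insert != ""))
    warning("non-empty insertion codes found; predicted models are ",
            "expected to have none")
  structure_model(atoms, id = id %||% tools::file_path_sans_ext(basename(path)),
                  metadata = list(source = path, format = format),
                  predicted = predicted)
}

#' Write a structure model
#'
#' PDB output goes through bio3d; mmCIF output writes a minimal
#' \code{atom_site} loop.  Round-tripping through
#' \code{\link{read_structure}} preserves atom counts, names, residue
#' numbering, chain ids and coordinates to format precision (PDB: 3
#' decimals).
#'
#' @param model a \code{\link{structure_model}}.
#' @param path output path.
#' @param format "pdb" or "mmcif".
#' @return invisibly, \code{path}.
#' @export
write_structure <- function(model, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  a <- model$atoms
  if (format == "pdb") {
    xyz <- c(a$x, a$y, a$z)
    if (any(a$x < -999.999 | a$x > 9999.999 |
            a$y < -999.999 | a$y > 9999.999 |
            a$z < -999.999 | a$z > 9999.999))
      stop("coordinates exceed the fixed-width PDB field range ",
           "(-999.999 to 9999.999)")
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = a$type, resno = a$resno, resid = a$resid,
                     eleno = a$eleno, elety = a$elety, chain = a$chain,
                     insert = ifelse(a$insert == "", NA, a$insert),
                     alt = ifelse(a$altloc == "", NA, a$altloc),
                     o = a$o, b = a$b, elesy = a$elesy)
  } else {
    # canonical PDBx/mmCIF atom_site loop (the column set and order of
    # standard depositions, which downstream parsers rely on)
    lines <- c(
      paste0("data_", gsub("[^A-Za-z0-9_-]", "_", model$id)),
      "#", "loop_",
      "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
      "_atom_site.label_atom_id", "_atom_site.label_alt_id",
      "_atom_site.label_comp_id", "_atom_site.label_asym_id",
      "_atom_site.label_entity_id", "_atom_site.label_seq_id",
      "_atom_site.pdbx_PDB_ins_code",
      "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
      "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
      "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
      "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
      "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
      sprintf(paste("%-6s %5d %-2s %-4s %1s %-3s %1s 1 %5d %1s",
                    "%9.3f %9.3f %9.3f %5.2f %7.2f ? %5d %-3s %1s %-4s 1"),
              a$type, seq_len(nrow(a)), a$elesy, a$elety,
              ifelse(a$altloc == "", ".", a$altloc), a$resid, a$chain,
              a$resno, ifelse(a$insert == "", "?", a$insert),
              a$x, a$y, a$z, a$o, a$b,
              a$resno, a$resid, a$chain, a$elety),
      "#")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Construct a ligand pose
#'
#' @param atoms data.frame with columns \code{elety}, \code{elesy},
#'   \code{x}, \code{y}, \code{z} (optionally \code{charge}).
#' @param label pose label.
#' @param bonds optional 2-column integer matrix of atom-index pairs.
#' @return object of class \code{ligand_pose}.
#' @export
ligand_pose <- function(atoms, label = "ligand", bonds = NULL) {
  if (nrow(atoms) < 1) stop("a ligand pose needs at least one atom")
  need <- c("elety", "elesy", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("pose atoms lack column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !.is_valid_element(atoms$elesy)
  if (any(bad)) stop("invalid element symbol(s): ",
                     paste(unique(atoms$elesy[bad]), collapse = ", "))
  atoms$elesy <- .element_case(atoms$elesy)
  if (!is.null(bonds)) {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) != 2) stop("bonds must be a 2-column matrix")
    storage.mode(bonds) <- "integer"
    if (any(bonds < 1 | bonds > nrow(atoms)))
      stop("bond indices out of range")
  }
  rownames(atoms) <- NULL
  structure(list(label = label, atoms = atoms, bonds = bonds),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  tab <- table(x$atoms$elesy)
  cat(sprintf("ligand_pose '%s': %d atoms (%s)%s\n", x$label,
              nrow(x$atoms),
              paste(names(tab), tab, sep = ":", collapse = " "),
              if (is.null(x$bonds)) "" else
                sprintf(", %d bonds", nrow(x$bonds))))
  invisible(x)
}

#' Read a ligand pose
#'
#' SDF V2000 files are parsed through ChemmineR (the bond block, when
#' present, populates the pose's bond list); PDB files are parsed through
#' bio3d with all ATOM/HETATM atoms taken as the ligand.  Only
#' single-molecule SDF records are accepted.
#'
#' @param path file path.
#' @param format "sdf", "pdb" or "auto".
#' @param label pose label; defaults to the file base name.
#' @return a \code{\link{ligand_pose}}.
#' @export
read_ligand <- function(path, format = c("auto", "sdf", "pdb"),
                        label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guess_format(path)
  label <- label %||% tools::file_path_sans_ext(basename(path))
  if (format == "sdf") {
    if (!requireNamespace("ChemmineR", quietly = TRUE))
      stop("reading SDF requires the ChemmineR package")
    if (file.info(path)$size == 0) stop("empty file: ", path)
    set <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                    error = function(e) stop("failed to parse SDF '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
    if (length(set) == 0) stop("failed to parse SDF '", path,
                               "': no molecule records")
    if (length(set) > 1)
      stop("multi-molecule SDF (", length(set), " records); extract the ",
           "record of interest into its own file first")
    ab <- ChemmineR::atomblock(set[[1]])
    if (is.null(ab) || nrow(ab) == 0) stop("SDF record has no atoms")
    elesy <- sub("_[0-9]+$", "", rownames(ab))
    atoms <- data.frame(elety = rownames(ab), elesy = elesy,
                        x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        stringsAsFactors = FALSE)
    bb <- ChemmineR::bondblock(set[[1]])
    bonds <- if (!is.null(bb) && nrow(bb) > 0)
      cbind(as.integer(bb[, 1]), as.integer(bb[, 2])) else NULL
    ligand_pose(atoms, label = label, bonds = bonds)
  } else {
    m <- read_structure(path, format = "pdb", predicted = FALSE,
                        id = label)
    a <- m$atoms
    ligand_pose(data.frame(elety = a$elety, elesy = a$elesy,
                           x = a$x, y = a$y, z = a$z,
                           stringsAsFactors = FALSE),
                label = label)
  }
}

# Heavy-atom (non-hydrogen) filter for poses.
.heavy <- function(pose) {
  keep <- !(toupper(pose$atoms$elesy) %in% c("H", "D"))
  atoms <- pose$atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0) stop("pose '", pose$label, "' has no heavy atoms")
  bonds <- pose$bonds
  if (!is.null(bonds)) {
    idx <- which(keep)
    map <- match(seq_along(keep), idx)
    ok <- bonds[, 1] %in% idx & bonds[, 2] %in% idx
    bonds <- cbind(map[bonds[ok, 1]], map[bonds[ok, 2]])
    if (nrow(bonds) == 0) bonds <- NULL
  }
  ligand_pose(atoms, label = pose$label, bonds = bonds)
}

# Coordinate matrix of a pose.
.pose_xyz <- function(pose) as.matrix(pose$atoms[, c("x", "y", "z")])
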