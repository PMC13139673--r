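# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Chemical elements accepted in atom records.
.ELEMENTS <- c(
  "H", "D", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE", "NA", "MG",
  "AL", "SI", "P", "S", "CL", "AR", "K", "CA", "SC", "TI", "V", "CR", "MN",
  "FE", "CO", "NI", "CU", "ZN", "GA", "GE", "AS", "SE", "BR", "KR", "RB",
  "SR", "MO", "RU", "PD", "AG", "CD", "I", "XE", "CS", "BA", "W", "PT",
  "AU", "HG", "PB"
)

# Title-case an element symbol ("CL" -> "Cl").
.element_case <- function(x) {
  x <- toupper(trimws(x))
  ifelse(nchar(x) > 1,
         paste0(substr(x, 1, 1), tolower(substr(x, 2, nchar(x)))),
         x)
}

.is_valid_element <- function(x) toupper(trimws(x)) %in% .ELEMENTS

# Atom names of the 20 standard amino acids (heavy atoms); element is the
# leading letter for all of them.  Used both for inference and as the
# reference lookup the tests compare against.
.AA_ATOM_ELEMENTS <- local({
  nm <- c(
    "N", "CA", "C", "O", "OXT", "CB", "CG", "CG1", "CG2", "CD", "CD1",
    "CD2", "CE", "CE1", "CE2", "CE3", "CZ", "CZ2", "CZ3", "CH2", "ND1",
    "ND2", "NE", "NE1", "NE2", "NZ", "NH1", "NH2", "OD1", "OD2", "OE1",
    "OE2", "OG", "OG1", "OH", "SD", "SG"
  )
  stats::setNames(substr(nm, 1, 1), nm)
})

# Two-letter element symbols that occur as leading characters of hetero
# atom names (ions, halogens in ligands).
.TWO_LETTER_HET <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE", "SI",
                     "CU", "CO", "NI", "CD", "HG", "LI", "BE", "AL")

#' Infer chemical elements from atom names
#'
#' PDB-style atom names encode the element in their leading characters.
#' For atoms of standard amino acids the element is resolved through a
#' fixed lookup of canonical heavy-atom names; hydrogens (names starting
#' with H or a digit-prefixed H, e.g. \code{"1HB"}) map to H.  For hetero
#' atoms a two-letter symbol (Cl, Br, Fe, ...) is recognised when the
#' digit-stripped name starts with one; the residue code \code{"CA"}
#' marks a calcium ion as opposed to an alpha-carbon.
#'
#' @param elety character vector of atom names.
#' @param hetero logical vector (recycled) marking HETATM records.
#' @param resid optional residue codes, used to disambiguate ions.
#' @return character vector of element symbols (title case).
#' @examples
#' infer_element(c("CA", "NZ", "OD1", "1HB"))
#' infer_element("CL1", hetero = TRUE)
#' @export
infer_element <- function(elety, hetero = FALSE, resid = NULL) {
  elety <- trimws(elety)
  hetero <- rep_len(hetero, length(elety))
  if (!is.null(resid)) resid <- rep_len(trimws(resid), length(elety))
  stripped <- toupper(gsub("[0-9']", "", elety))
  out <- character(length(elety))
  for (i in seq_along(elety)) {
    s <- stripped[i]
    if (s == "") stop("cannot infer element from atom name '", elety[i], "'")
    if (!hetero[i] && s %in% names(.AA_ATOM_ELEMENTS)) {
      out[i] <- .AA_ATOM_ELEMENTS[[s]]
    } else if (substr(s, 1, 1) == "H") {
      out[i] <- "H"
    } else if (hetero[i] && !is.null(resid) && resid[i] %in% c("CA", "ZN",
               "MG", "NA", "CL", "FE", "MN", "K") && s == resid[i]) {
      out[i] <- .element_case(resid[i])
    } else if (hetero[i] && nchar(s) >= 2 &&
               substr(s, 1, 2) %in% .TWO_LETTER_HET) {
      out[i] <- .element_case(substr(s, 1, 2))
    } else {
      out[i] <- substr(s, 1, 1)
    }
  }
  bad <- !.is_valid_element(out)
  if (any(bad))
    stop("could not infer a valid element for atom name(s): ",
         paste(unique(elety[bad]), collapse = ", "))
  .element_case(out)
}

# 3-letter -> 1-letter amino-acid code; non-standard codes pass through
# unchanged (ligand codes keep their identity).
.aa321 <- function(resid) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- tab[toupper(resid)]
  unname(ifelse(is.na(out), resid, out))
}

.aa123 <- function(aa) {
  tab <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  out <- tab[toupper(aa)]
  unname(ifelse(is.na(out), aa, out))
}

# Cross product of two 3-vectors.
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Rotation matrix about an arbitrary axis (Rodrigues), angle in degrees.
rotation_about_axis <- function(axis, angle_deg) {
  k <- .normalize(as.numeric(axis))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Deterministic unit quaternion -> rotation matrix for random rotations.
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# All permutations of 1..n as a list (n small).
.permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .permutations(n - 1L)
  out <- vector("list", 0L)
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
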