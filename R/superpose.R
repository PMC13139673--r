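# superpose: optimal rigid-body (Kabsch) superposition and C-alpha RMSD
# matrices between models.

#' Construct a coordinate set
#'
#' An ordered list of 3D points with parallel atom labels, the unit of
#' currency of the superposition operations.
#'
#' @param points numeric N x 3 matrix (Angstrom).
#' @param labels optional data.frame with columns \code{chain},
#'   \code{resno}, \code{elety}, one row per point.
#' @return object of class \code{coordinate_set}.
#' @export
coordinate_set <- function(points, labels = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an N x 3 matrix")
  if (nrow(points) < 1) stop("a coordinate set needs at least one point")
  if (!all(is.finite(points))) stop("non-finite coordinates")
  if (is.null(labels)) {
    labels <- data.frame(chain = "A", resno = seq_len(nrow(points)),
                         elety = "CA", stringsAsFactors = FALSE)
  }
  if (nrow(labels) != nrow(points))
    stop("points and labels must have the same length")
  structure(list(points = unname(points), labels = labels),
            class = "coordinate_set")
}

.as_points <- function(x) {
  if (inherits(x, "coordinate_set")) x$points else as.matrix(x)
}

#' Pair C-alpha atoms between two models
#'
#' Atoms are paired on the intersection of (chain position, residue
#' number, insertion code): the k-th chain of one model is matched with
#' the k-th chain of the other, and within each chain pair the shared
#' residue numbers are kept.  Models built from the same sequence but
#' missing different regions therefore pair on what both resolve.  No
#' sequence alignment is attempted.
#'
#' @param modelA,modelB \code{\link{structure_model}} objects.
#' @param selection "calpha" (default) or "all" (all shared atom names
#'   per residue).
#' @param chain_shift rotate model B's chain order by this many positions
#'   before pairing (used by the C3-symmetry search in
#'   \code{\link{model_rmsd}}).
#' @return list with \code{a} and \code{b}, both
#'   \code{\link{coordinate_set}} objects of equal length.
#' @export
pair_calpha <- function(modelA, modelB, selection = c("calpha", "all"),
                        chain_shift = 0L) {
  selection <- match.arg(selection)
  pick <- function(m) {
    a <- m$atoms
    if (selection == "calpha") a <- a[a$elety == "CA", , drop = FALSE]
    a <- a[!(toupper(a$elesy) %in% c("H", "D")), , drop = FALSE]
    if (nrow(a) == 0) stop("model '", m$id, "' has no atoms to pair ",
                           "(selection '", selection, "')")
    a
  }
  aa <- pick(modelA)
  ab <- pick(modelB)
  cha <- unique(aa$chain)
  chb <- unique(ab$chain)
  if (chain_shift != 0L) {
    if (length(chb) == 0) stop("no chains in model B")
    s <- ((chain_shift %% length(chb)) + length(chb)) %% length(chb)
    chb <- c(chb[-seq_len(s)], chb[seq_len(s)])
    if (s == 0) chb <- unique(ab$chain)
  }
  n_common <- min(length(cha), length(chb))
  pa <- list(); pb <- list()
  for (k in seq_len(n_common)) {
    sa <- aa[aa$chain == cha[k], , drop = FALSE]
    sb <- ab[ab$chain == chb[k], , drop = FALSE]
    ka <- paste(sa$resno, sa$insert, sa$elety, sep = "\r")
    kb <- paste(sb$resno, sb$insert, sb$elety, sep = "\r")
    common <- intersect(ka, kb)
    if (length(common) == 0) next
    sa <- sa[match(common, ka), , drop = FALSE]
    sb <- sb[match(common, kb), , drop = FALSE]
    pa[[length(pa) + 1L]] <- sa
    pb[[length(pb) + 1L]] <- sb
  }
  if (length(pa) == 0) stop("no atoms could be paired between '",
                            modelA$id, "' and '", modelB$id, "'")
  sa <- do.call(rbind, pa)
  sb <- do.call(rbind, pb)
  lab <- function(s) data.frame(chain = s$chain, resno = s$resno,
                                elety = s$elety, stringsAsFactors = FALSE)
  list(a = coordinate_set(as.matrix(sa[, c("x", "y", "z")]), lab(sa)),
       b = coordinate_set(as.matrix(sb[, c("x", "y", "z")]), lab(sb)))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two equal-length paired point sets, via SVD of the covariance matrix
#' with reflection correction (the sign of the smallest singular value is
#' flipped when the raw solution is improper, so the returned rotation
#' always has determinant +1).
#'
#' @param setA mobile \code{\link{coordinate_set}} (or N x 3 matrix).
#' @param setB reference set of the same length.
#' @return object of class \code{superposition_result}: list with
#'   \code{rotation} (3 x 3, det +1), \code{translation} (length 3;
#'   the fitted mobile is \code{rotation \%*\% x + translation}),
#'   \code{rmsd}, \code{n_paired}, and \code{non_unique} (TRUE when fewer
#'   than 3 non-collinear points determine the rotation).
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' R <- rotation_about_axis(c(0, 0, 1), 90)
#' b <- t(R %*% t(a)) + rep(c(1, 2, 3), each = 10)
#' kabsch(a, b)$rmsd  # ~0
#' @export
kabsch <- function(setA, setB) {
  A <- .as_points(setA)
  B <- .as_points(setB)
  if (nrow(A) != nrow(B)) stop("paired sets must have equal lengths")
  n <- nrow(A)
  if (n < 1) stop("at least one paired point is required")
  am <- colMeans(A)
  bm <- colMeans(B)
  Ac <- sweep(A, 2, am)
  Bc <- sweep(B, 2, bm)
  H <- crossprod(Ac, Bc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Bc)^2)))
  # uniqueness: need >= 3 points spanning a plane
  sv <- svd(Ac, nu = 0, nv = 0)$d
  non_unique <- n < 3 || (length(sv) >= 2 && sv[2] < 1e-8 * max(sv[1], 1))
  structure(list(rotation = R, translation = as.numeric(bm - R %*% am),
                 rmsd = rmsd, n_paired = n, non_unique = non_unique),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition: n = %d, RMSD = %.4f A%s\n", x$n_paired,
              x$rmsd, if (x$non_unique) " (rotation not unique)" else ""))
  invisible(x)
}

#' Apply a superposition to a structure model
#'
#' @param model a \code{\link{structure_model}}.
#' @param fit a \code{\link{kabsch}} result.
#' @return the transformed model.
#' @export
apply_superposition <- function(model, fit) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- sweep(xyz %*% t(fit$rotation), 2, fit$translation, "+")
  model$atoms$x <- new[, 1]
  model$atoms$y <- new[, 2]
  model$atoms$z <- new[, 3]
  model
}

#' Fixed-frame RMSD
#'
#' Plain root-mean-square of paired interatomic distances,
#' \code{sqrt(mean(|r_i - r_i_ref|^2))}, with no fitting: both sets are
#' taken in the frame they are in.
#'
#' @param setA,setB equal-length \code{\link{coordinate_set}} objects or
#'   N x 3 matrices.
#' @return scalar RMSD in Angstrom.
#' @examples
#' rmsd_fixed(rbind(c(0, 0, 0), c(1, 0, 0)),
#'            rbind(c(0, 0, 0), c(1, 0, 1)))  # sqrt(1/2)
#' @export
rmsd_fixed <- function(setA, setB) {
  A <- .as_points(setA)
  B <- .as_points(setB)
  if (nrow(A) != nrow(B)) stop("paired sets must have equal lengths")
  if (nrow(A) < 1) stop("at least one paired point is required")
  sqrt(mean(rowSums((A - B)^2)))
}

#' Superposition RMSD between two models
#'
#' Pairs atoms (\code{\link{pair_calpha}}), superposes (Kabsch) and
#' returns the fitted RMSD.  With \code{trimer_symmetry = TRUE} and equal
#' chain counts, all cyclic chain-order shifts of model B are tried and
#' the minimal-RMSD pairing is reported -- the chain correspondence of a
#' C3-symmetric homotrimer is not fixed by file order.  Set
#' \code{full_permutations = TRUE} to search all chain orderings instead
#' of the cyclic subgroup.
#'
#' @param modelA,modelB \code{\link{structure_model}} objects.
#' @param selection "calpha" (default) or "all".
#' @param trimer_symmetry try cyclic chain permutations.
#' @param full_permutations try all chain permutations (implies the
#'   symmetry search).
#' @return a \code{\link{kabsch}} result with attribute
#'   \code{chain_shift} (or \code{chain_order}) recording the winning
#'   correspondence.
#' @export
model_rmsd <- function(modelA, modelB, selection = c("calpha", "all"),
                       trimer_symmetry = FALSE,
                       full_permutations = FALSE) {
  selection <- match.arg(selection)
  nB <- length(chain_ids(modelB))
  if (full_permutations && nB <= 6) {
    chb <- chain_ids(modelB)
    best <- NULL
    for (p in .permutations(nB)) {
      mB <- modelB
      mB$atoms <- do.call(rbind, lapply(chb[unlist(p)], function(ch)
        modelB$atoms[modelB$atoms$chain == ch, , drop = FALSE]))
      pr <- pair_calpha(modelA, mB, selection)
      fit <- kabsch(pr$a, pr$b)
      if (is.null(best) || fit$rmsd < best$rmsd) {
        best <- fit
        attr(best, "chain_order") <- chb[unlist(p)]
      }
    }
    return(best)
  }
  shifts <- if (trimer_symmetry &&
                length(chain_ids(modelA)) == nB) seq_len(nB) - 1L else 0L
  best <- NULL
  for (s in shifts) {
    pr <- pair_calpha(modelA, modelB, selection, chain_shift = s)
    fit <- kabsch(pr$a, pr$b)
    if (is.null(best) || fit$rmsd < best$rmsd) {
      best <- fit
      attr(best, "chain_shift") <- s
    }
  }
  best
}

#' All-pairs RMSD matrix
#'
#' Kabsch RMSD after C-alpha pairing for every pair of models: the
#' standard square comparison table with a zero diagonal.  A pair that
#' cannot be paired yields \code{NA} (flagged missing), never zero.
#'
#' @param models list of \code{\link{structure_model}} objects (>= 2);
#'   names (or model ids) label the rows/columns.
#' @param selection,trimer_symmetry passed to \code{\link{model_rmsd}}.
#' @return symmetric numeric matrix with model labels as dimnames.
#' @export
rmsd_matrix <- function(models, selection = "calpha",
                        trimer_symmetry = FALSE) {
  if (length(models) < 2) stop("need at least two models")
  ids <- names(models) %||% vapply(models, function(m) m$id, character(1))
  if (is.null(names(models))) names(models) <- ids
  n <- length(models)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- tryCatch(
        model_rmsd(models[[i]], models[[j]], selection = selection,
                   trimer_symmetry = trimer_symmetry)$rmsd,
        error = function(e) NA_real_)
      M[i, j] <- r
      M[j, i] <- r
    }
  }
  M
}

#' Write an RMSD matrix as TSV
#'
#' Square table with model ids as header and first column, values rounded
#' to 3 decimals (the conventional reporting precision).
#'
#' @param M matrix from \code{\link{rmsd_matrix}}.
#' @param path output path.
#' @param digits rounding (default 3).
#' @return invisibly, \code{path}.
#' @export
write_rmsd_matrix <- function(M, path, digits = 3) {
  df <- data.frame(Models = rownames(M), round(M, digits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
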