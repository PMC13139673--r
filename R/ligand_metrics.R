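# ligand_metrics: naive and symmetry-corrected ligand-pose RMSD, the
# 2.0 A redocking criterion, and docking-grid definition.
#
# Docked poses and crystal ligands share the receptor frame, so pose RMSD
# is computed without any rigid fitting.  Chemically equivalent atoms
# (e.g. the oxygens of a phosphate) may be indexed differently in two
# poses; the symmetry-corrected RMSD removes that artificial inflation by
# choosing, per chemical element, the atom correspondence minimizing the
# total sum of squared distances (a linear assignment problem, solved
# exactly by the Hungarian/Munkres method).

#' Naive (identity-mapping) pose RMSD
#'
#' RMSD between two poses under the file atom order, with no fitting.
#' Requires the same ordered element sequence; use
#' \code{\link{symmetry_rmsd}} when the poses enumerate equivalent atoms
#' differently.
#'
#' @param poseA,poseB \code{\link{ligand_pose}} objects.
#' @param heavy_only drop hydrogens first (default TRUE; docking outputs
#'   and crystal references rarely agree on hydrogen placement).
#' @return scalar RMSD in Angstrom.
#' @export
naive_rmsd <- function(poseA, poseB, heavy_only = TRUE) {
  if (heavy_only) {
    poseA <- .heavy(poseA)
    poseB <- .heavy(poseB)
  }
  ea <- poseA$atoms$elesy
  eb <- poseB$atoms$elesy
  if (length(ea) != length(eb) || any(ea != eb))
    stop("poses differ in ordered element sequence; use symmetry_rmsd() ",
         "for element-wise optimal matching")
  rmsd_fixed(.pose_xyz(poseA), .pose_xyz(poseB))
}

#' Solve a linear assignment problem
#'
#' Exact minimum-cost bipartite matching by the Hungarian (Munkres)
#' method in its O(n^3) potential/augmenting-path form.  Among equally
#' optimal assignments the lexicographically smallest pair list is
#' returned (row 1 gets the smallest usable column, then row 2, ...), so
#' results are deterministic under ties.
#'
#' @param cost square numeric matrix of non-negative costs.
#' @return list with \code{pairs} (2-column matrix, row i assigned to
#'   column \code{pairs[i, 2]}) and \code{cost} (the minimal total).
#' @examples
#' solve_assignment(rbind(c(1, 2), c(3, 1)))  # diagonal, cost 2
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (nrow(cost) != ncol(cost))
    stop("cost matrix must be square (per-element atom classes are ",
         "equal-sized)")
  if (any(!is.finite(cost))) stop("cost entries must be finite")
  if (any(cost < 0)) stop("cost entries must be non-negative")
  n <- nrow(cost)
  if (n == 1) return(list(pairs = cbind(1L, 1L), cost = cost[1, 1]))
  total <- .hungarian_cost(cost)
  tol <- 1e-9 * max(1, abs(total))
  # lexicographic refinement: fix rows in order, smallest feasible column
  free <- seq_len(n)
  assign <- integer(n)
  acc <- 0
  for (i in seq_len(n)) {
    rest_rows <- if (i < n) (i + 1):n else integer(0)
    for (j in free) {
      rest_cols <- setdiff(free, j)
      rest <- if (length(rest_rows))
        .hungarian_cost(cost[rest_rows, rest_cols, drop = FALSE]) else 0
      if (acc + cost[i, j] + rest <= total + tol) {
        assign[i] <- j
        acc <- acc + cost[i, j]
        free <- rest_cols
        break
      }
    }
    if (assign[i] == 0L) stop("internal error: assignment refinement failed")
  }
  list(pairs = cbind(seq_len(n), assign), cost = acc)
}

# Minimal total cost of a square assignment problem (e-maxx formulation
# with row/column potentials and shortest augmenting paths).
.hungarian_cost <- function(cost) {
  n <- nrow(cost)
  if (n == 0) return(0)
  if (n == 1) return(cost[1, 1])
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1)        # column potentials, index j+1 (col 0 dummy)
  p <- integer(n + 1)        # p[j+1]: row assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      cur <- cost[i0, ] - u[i0] - v[2:(n + 1)]
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          if (cur[j] < minv[j + 1L]) {
            minv[j + 1L] <- cur[j]
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  s <- 0
  for (j in seq_len(n)) s <- s + cost[p[j + 1L], j]
  s
}

#' Symmetry-corrected pose RMSD
#'
#' For each chemical element shared by the two poses, a cost matrix of
#' squared Euclidean distances is built and the Hungarian method finds
#' the one-to-one atom correspondence minimizing the total sum of squared
#' distances; the pooled optimal pairs give
#' \code{sym_rmsd = sqrt(total_cost / N)}.  No rigid fitting is applied:
#' poses are compared in the shared receptor frame.  The result also
#' carries the naive (identity-mapping) RMSD when the ordered element
#' sequences agree, and the redocking verdict at \code{threshold}.
#'
#' @param poseA,poseB \code{\link{ligand_pose}} objects with identical
#'   element multisets (after hydrogen filtering).
#' @param heavy_only drop hydrogens first (default TRUE).
#' @param threshold redocking success cutoff in Angstrom (default 2.0,
#'   the conventional criterion; strict "below").
#' @return object of class \code{sym_rmsd_result}: list with
#'   \code{sym_rmsd}, \code{naive_rmsd} (NA when undefined),
#'   \code{assignment} (pairs data.frame + total_cost),
#'   \code{passes_redock}, \code{threshold}, \code{n_atoms}.
#' @examples
#' a <- ligand_pose(data.frame(elety = c("O1", "O2"), elesy = "O",
#'                             x = c(1, -1), y = 0, z = 0))
#' b <- ligand_pose(data.frame(elety = c("O1", "O2"), elesy = "O",
#'                             x = c(-1, 1), y = 0, z = 0))
#' r <- symmetry_rmsd(a, b)
#' c(r$naive_rmsd, r$sym_rmsd)  # 2, 0
#' @export
symmetry_rmsd <- function(poseA, poseB, heavy_only = TRUE,
                          threshold = 2.0) {
  if (heavy_only) {
    poseA <- .heavy(poseA)
    poseB <- .heavy(poseB)
  }
  ea <- poseA$atoms$elesy
  eb <- poseB$atoms$elesy
  ta <- table(ea)
  tb <- table(eb)
  if (!identical(sort(names(ta)), sort(names(tb))) ||
      !all(ta[sort(names(ta))] == tb[sort(names(ta))])) {
    alln <- union(names(ta), names(tb))
    diffel <- alln[sapply(alln, function(e)
      (if (e %in% names(ta)) ta[[e]] else 0L) !=
      (if (e %in% names(tb)) tb[[e]] else 0L))]
    stop("element multisets differ between poses (", poseA$label, " vs ",
         poseB$label, "): ", paste(diffel, collapse = ", "))
  }
  A <- .pose_xyz(poseA)
  B <- .pose_xyz(poseB)
  naive <- if (length(ea) == length(eb) && all(ea == eb))
    rmsd_fixed(A, B) else NA_real_
  pairs <- NULL
  total <- 0
  for (el in sort(names(ta))) {
    ia <- which(ea == el)
    ib <- which(eb == el)
    if (length(ia) == 1L) {
      d2 <- sum((A[ia, ] - B[ib, ])^2)
      pairs <- rbind(pairs, data.frame(element = el, a_idx = ia,
                                       b_idx = ib, dist = sqrt(d2)))
      total <- total + d2
    } else {
      D2 <- outer(seq_along(ia), seq_along(ib), function(i, j)
        rowSums((A[ia[i], , drop = FALSE] - B[ib[j], , drop = FALSE])^2))
      sol <- solve_assignment(D2)
      total <- total + sol$cost
      pairs <- rbind(pairs, data.frame(
        element = el, a_idx = ia[sol$pairs[, 1]],
        b_idx = ib[sol$pairs[, 2]],
        dist = sqrt(D2[sol$pairs])))
    }
  }
  pairs <- pairs[order(pairs$a_idx), , drop = FALSE]
  rownames(pairs) <- NULL
  sym <- sqrt(total / nrow(A))
  structure(list(sym_rmsd = sym, naive_rmsd = naive,
                 assignment = list(pairs = pairs, total_cost = total),
                 passes_redock = sym < threshold, threshold = threshold,
                 n_atoms = nrow(A)),
            class = "sym_rmsd_result")
}

#' @export
print.sym_rmsd_result <- function(x, ...) {
  cat(sprintf("pose RMSD over %d atoms: sym = %.4f A, naive = %s A -> %s (threshold %.1f A)\n",
              x$n_atoms, x$sym_rmsd,
              if (is.na(x$naive_rmsd)) "n/a" else sprintf("%.4f", x$naive_rmsd),
              classify_redock(x), x$threshold))
  invisible(x)
}

#' Classify a redocking result
#'
#' The conventional criterion: a pose reproduces the crystallographic
#' binding mode satisfactorily when its (symmetry-corrected) RMSD is
#' strictly below the threshold, 2.0 A by default.  An RMSD exactly at
#' the threshold is unsatisfactory.
#'
#' @param result a \code{\link{symmetry_rmsd}} result.
#' @return "satisfactory" or "unsatisfactory".
#' @export
classify_redock <- function(result) {
  stopifnot(inherits(result, "sym_rmsd_result"))
  if (result$sym_rmsd < result$threshold) "satisfactory" else "unsatisfactory"
}

#' Docking grid box from a ligand's geometric center
#'
#' The grid is centered on the unweighted mean of the ligand's (heavy,
#' by default) atom coordinates, with the stated edge lengths -- the
#' standard way a redocking grid is derived from a cocrystallized ligand.
#' The default 40 x 30 x 40 A box encompasses a receptor binding pocket
#' plus surrounding interacting residues.
#'
#' @param pose a \code{\link{ligand_pose}}.
#' @param dims edge lengths in Angstrom (default \code{c(40, 30, 40)}).
#' @param heavy_only center on heavy atoms only (default TRUE).
#' @return object of class \code{grid_box}: list with \code{center} and
#'   \code{dims}.
#' @examples
#' p <- ligand_pose(data.frame(elety = "C", elesy = "C",
#'                             x = c(0, 2, 1), y = c(0, 0, 3), z = 0))
#' grid_from_ligand(p)$center  # (1, 1, 0)
#' @export
grid_from_ligand <- function(pose, dims = c(40, 30, 40),
                             heavy_only = TRUE) {
  stopifnot(inherits(pose, "ligand_pose"))
  dims <- as.numeric(dims)
  if (length(dims) != 3 || any(!is.finite(dims)) || any(dims <= 0))
    stop("dims must be three strictly positive lengths")
  if (heavy_only) pose <- .heavy(pose)
  structure(list(center = colMeans(.pose_xyz(pose)), dims = dims),
            class = "grid_box")
}

#' @export
print.grid_box <- function(x, ...) {
  cat(sprintf("grid box: center (%.3f, %.3f, %.3f), dims %g x %g x %g A\n",
              x$center[1], x$center[2], x$center[3],
              x$dims[1], x$dims[2], x$dims[3]))
  invisible(x)
}
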