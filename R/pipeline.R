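# pipeline: orchestration of the full model-assessment run -- RMSD
# matrix, site confidence reports, redocking validation and interaction
# fingerprints -- from one config, with per-stage isolation (a failing
# stage is recorded and skipped, it does not abort the rest).

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

#' Run the full assessment pipeline
#'
#' Given structural models, site definitions and ligand pose pairs, runs
#' every assessment stage and writes one directory of reports: the
#' all-pairs C-alpha RMSD matrix (TSV), a site-confidence report per
#' model and site (TSV + JSON), a redocking summary with
#' symmetry-corrected RMSDs and pass flags (JSON), an interaction
#' fingerprint comparison (TSV), a provenance block (JSON: config hash,
#' seed, input digests) and a Markdown summary.  Stages are independent:
#' failures are logged per stage and reported as such.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{models}{named list of model file paths, or named list of
#'       \code{\link{structure_model}} objects.}
#'     \item{experimental}{optional character vector of model labels to
#'       flag experimental (confidence stages skip them).}
#'     \item{sites}{named list of site config paths or
#'       \code{\link{site_definition}} objects; default
#'       \code{\link{p2x7_sites}}.}
#'     \item{neighbor_offsets}{window offsets applied to all sites (optional).}
#'     \item{chain_policy}{"average_all" (default) or a chain id.}
#'     \item{poses}{list of entries \code{list(label, ref, pose)} --
#'       paths or \code{\link{ligand_pose}} objects.}
#'     \item{redock_threshold}{default 2.0.}
#'     \item{fingerprints}{list of entries
#'       \code{list(model, ligand, site)} referring to labels above.}
#'     \item{rules}{optional overrides passed to
#'       \code{\link{interaction_rules}}.}
#'     \item{trimer_symmetry}{search cyclic chain permutations in the
#'       RMSD matrix (default FALSE).}
#'     \item{seed}{seed for any simulation steps (default 1).}
#'   }
#' @param output_dir directory for reports; created if absent.  NULL
#'   skips file output.
#' @return object of class \code{assessment_report}: list with
#'   \code{rmsd_matrix}, \code{confidence}, \code{redocking},
#'   \code{fingerprints}, \code{provenance}, \code{errors}.
#' @export
run_assessment <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- tryCatch(yaml::read_yaml(config),
                       error = function(e) stop("config parse error: ",
                                                conditionMessage(e),
                                                call. = FALSE))
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1
  set.seed(seed)
  errors <- list()
  note_err <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    message("stage '", stage, "' failed: ", conditionMessage(e))
    NULL
  }

  load_model <- function(m, label) {
    if (inherits(m, "structure_model")) return(m)
    read_structure(m, predicted = !(label %in% (config$experimental %||%
                                                character(0))),
                   id = label)
  }
  models <- list()
  if (!is.null(config$models)) {
    if (is.null(names(config$models))) stop("models must be named")
    if (anyDuplicated(names(config$models))) stop("model labels must be unique")
    models <- lapply(seq_along(config$models), function(i)
      load_model(config$models[[i]], names(config$models)[i]))
    names(models) <- names(config$models)
  }

  sites <- config$sites %||% p2x7_sites()
  sites <- lapply(sites, function(s)
    if (inherits(s, "site_definition")) s else read_site_definition(s))
  if (!is.null(config$neighbor_offsets)) {
    sites <- lapply(sites, function(s) {
      s$neighbor_offsets <- as.integer(config$neighbor_offsets)
      s
    })
  }

  # stage 1: RMSD matrix
  M <- NULL
  if (length(models) >= 2) {
    M <- tryCatch(rmsd_matrix(models,
                              trimer_symmetry = isTRUE(config$trimer_symmetry)),
                  error = function(e) note_err("rmsd_matrix", e))
  }

  # stage 2: site confidence per predicted model x site
  conf_reports <- list()
  for (lab in names(models)) {
    m <- models[[lab]]
    if (!m$predicted) next
    cm <- tryCatch(residue_confidence(m),
                   error = function(e) note_err(paste0("confidence:", lab), e))
    if (is.null(cm)) next
    for (sn in names(sites)) {
      key <- paste(lab, sn, sep = ".")
      conf_reports[[key]] <- tryCatch(
        site_confidence(cm, m, sites[[sn]],
                        chain_policy = config$chain_policy %||% "average_all"),
        error = function(e) note_err(paste0("site_confidence:", key), e))
    }
  }

  # stage 3: redocking validation
  redock <- list()
  thr <- config$redock_threshold %||% 2.0
  for (entry in config$poses %||% list()) {
    lab <- entry$label %||% "pose"
    redock[[lab]] <- tryCatch({
      ref <- if (inherits(entry$ref, "ligand_pose")) entry$ref
             else read_ligand(entry$ref)
      pose <- if (inherits(entry$pose, "ligand_pose")) entry$pose
              else read_ligand(entry$pose)
      r <- symmetry_rmsd(ref, pose, threshold = thr)
      list(sym_rmsd = r$sym_rmsd, naive_rmsd = r$naive_rmsd,
           passes = r$passes_redock, verdict = classify_redock(r),
           threshold = thr, n_atoms = r$n_atoms,
           grid = unclass(grid_from_ligand(ref)))
    }, error = function(e) note_err(paste0("redock:", lab), e))
  }

  # stage 4: interaction fingerprints
  rules <- do.call(interaction_rules, config$rules %||% list())
  fp_reports <- list()
  for (entry in config$fingerprints %||% list()) {
    key <- paste(entry$model, entry$site, sep = ".")
    fp_reports[[key]] <- tryCatch({
      lig <- if (inherits(entry$ligand, "ligand_pose")) entry$ligand
             else read_ligand(entry$ligand)
      rec <- detect_interactions(models[[entry$model]], lig, rules)
      fingerprint(rec, sites[[entry$site]])
    }, error = function(e) note_err(paste0("fingerprint:", key), e))
  }
  fp_tables <- list()
  for (sn in unique(vapply(config$fingerprints %||% list(),
                           function(e) e$site, character(1)))) {
    keys <- grep(paste0("\\.", sn, "$"), names(fp_reports), value = TRUE)
    reps <- Filter(Negate(is.null), fp_reports[keys])
    if (length(reps))
      fp_tables[[sn]] <- compare_fingerprints(
        stats::setNames(reps, sub(paste0("\\.", sn, "$"), "", names(reps))))
  }

  input_digests <- if (!is.null(config$models) &&
                       all(vapply(config$models, is.character, logical(1))))
    vapply(config$models, function(p) unname(tools::md5sum(p)),
           character(1)) else NULL
  provenance <- list(
    package_version = as.character(utils::packageVersion("foldsite")),
    config_hash = .config_hash(config), seed = seed,
    input_digests = as.list(input_digests %||% list()))

  report <- structure(list(rmsd_matrix = M, confidence = conf_reports,
                           redocking = redock, fingerprints = fp_tables,
                           provenance = provenance, errors = errors),
                      class = "assessment_report")
  if (!is.null(output_dir)) write_assessment(report, output_dir)
  report
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("assessment report\n")
  if (!is.null(x$rmsd_matrix)) {
    cat("  RMSD matrix (A):\n")
    print(round(x$rmsd_matrix, 3))
  }
  for (key in names(x$confidence)) {
    r <- x$confidence[[key]]
    if (!is.null(r))
      cat(sprintf("  %s: global average pLDDT %.2f\n", key,
                  r$global_average))
  }
  for (lab in names(x$redocking)) {
    r <- x$redocking[[lab]]
    if (!is.null(r))
      cat(sprintf("  redock %s: sym RMSD %.3f A (%s)\n", lab,
                  r$sym_rmsd, r$verdict))
  }
  for (sn in names(x$fingerprints)) {
    cat(sprintf("  fingerprints (%s): key residues hit: %s\n", sn,
                paste(names(attr(x$fingerprints[[sn]], "n_key_hit")),
                      attr(x$fingerprints[[sn]], "n_key_hit"),
                      sep = "=", collapse = ", ")))
  }
  if (length(x$errors))
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Write an assessment report to disk
#'
#' One directory per run: \code{rmsd_matrix.tsv},
#' \code{confidence_<model>_<site>.tsv/.json}, \code{redocking.json},
#' \code{fingerprints_<site>.tsv}, \code{provenance.json} and a
#' \code{summary.md} mirroring the usual table layouts.
#'
#' @param report an \code{\link{run_assessment}} result.
#' @param output_dir target directory (created if absent).
#' @return invisibly, \code{output_dir}.
#' @export
write_assessment <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  md <- c("# Model assessment report", "")
  if (!is.null(report$rmsd_matrix)) {
    write_rmsd_matrix(report$rmsd_matrix,
                      file.path(output_dir, "rmsd_matrix.tsv"))
    md <- c(md, "## Superposition RMSD matrix (A)", "",
            paste0("| Models | ",
                   paste(colnames(report$rmsd_matrix), collapse = " | "),
                   " |"),
            paste0("|", paste(rep("---", ncol(report$rmsd_matrix) + 1),
                              collapse = "|"), "|"),
            vapply(rownames(report$rmsd_matrix), function(rn)
              paste0("| ", rn, " | ",
                     paste(sprintf("%.3f", report$rmsd_matrix[rn, ]),
                           collapse = " | "), " |"), character(1)),
            "")
  }
  for (key in names(report$confidence)) {
    r <- report$confidence[[key]]
    if (is.null(r)) next
    base <- file.path(output_dir, paste0("confidence_", gsub("\\.", "_", key)))
    write_site_report(r, paste0(base, ".tsv"), "tsv")
    write_site_report(r, paste0(base, ".json"), "json")
    md <- c(md, sprintf("## Site confidence: %s", key), "",
            "| Residue | pLDDT (mean) |", "|---|---|",
            sprintf("| %s | %.2f |", r$per_residue$label,
                    r$per_residue$conf),
            sprintf("| Global average | %.2f |", r$global_average), "")
  }
  if (length(report$redocking)) {
    jsonlite::write_json(report$redocking,
                         file.path(output_dir, "redocking.json"),
                         auto_unbox = TRUE, digits = NA)
    md <- c(md, "## Redocking validation", "",
            "| Pose | sym RMSD (A) | naive RMSD (A) | verdict |",
            "|---|---|---|---|",
            vapply(names(report$redocking), function(lab) {
              r <- report$redocking[[lab]]
              if (is.null(r)) return(sprintf("| %s | failed | | |", lab))
              sprintf("| %s | %.3f | %s | %s |", lab, r$sym_rmsd,
                      if (is.na(r$naive_rmsd)) "n/a"
                      else sprintf("%.3f", r$naive_rmsd), r$verdict)
            }, character(1)), "")
  }
  for (sn in names(report$fingerprints)) {
    tab <- report$fingerprints[[sn]]
    write_fingerprint_table(tab,
                            file.path(output_dir,
                                      paste0("fingerprints_", sn, ".tsv")))
    md <- c(md, sprintf("## Interaction fingerprints: %s site", sn), "",
            paste0("| Key residues | ", paste(colnames(tab),
                                              collapse = " | "), " |"),
            paste0("|", paste(rep("---", ncol(tab) + 1), collapse = "|"),
                   "|"),
            vapply(rownames(tab), function(rn)
              paste0("| ", rn, " | ",
                     paste(unlist(tab[rn, ]), collapse = " | "), " |"),
              character(1)), "")
  }
  jsonlite::write_json(report$provenance,
                       file.path(output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(report$errors))
    md <- c(md, "## Failed stages", "",
            paste0("- ", names(report$errors), ": ",
                   unlist(report$errors)), "")
  writeLines(md, file.path(output_dir, "summary.md"))
  invisible(output_dir)
}
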