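# confidence: per-residue pLDDT extraction and binding-site aggregation.
#
# Predicted models deposit pLDDT (0-100) in the B-factor channel: AF2-style
# files repeat one value across all atoms of a residue, AF3-style files
# carry genuinely per-atom values.  Averaging over a residue's atoms is
# exact for the former and the defined convention for the latter, so one
# code path serves both.

#' Per-residue confidence map
#'
#' Extracts the pLDDT confidence of every residue of a predicted model
#' from the B-factor channel.
#'
#' @param model a \code{\link{structure_model}} flagged predicted.
#' @param mode "atom_mean" (unweighted mean over the residue's atoms;
#'   default) or "ca_only" (the C-alpha value).  For residue-level
#'   (AF2-style) files both agree.
#' @return data.frame of class \code{confidence_map} with columns
#'   \code{chain}, \code{resno}, \code{insert}, \code{aa}, \code{conf}.
#'   Residues lacking the requested atoms are dropped with a warning.
#' @examples
#' tri <- make_trimer(n_residues = 12, profile = conf_profile(constant = 77.73))
#' cm <- residue_confidence(tri$model)
#' all(cm$conf == 77.73)
#' @export
residue_confidence <- function(model, mode = c("atom_mean", "ca_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "structure_model"))
  if (!model$predicted)
    stop("model '", model$id, "' is flagged experimental; its B-factor ",
         "channel is not a confidence score")
  a <- model$atoms
  if (mode == "ca_only") a <- a[a$elety == "CA", , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms available for mode '", mode, "'")
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  conf <- as.numeric(tapply(a$b, factor(key, levels = key[first]), mean))
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    insert = a$insert[first], aa = a$aa[first],
                    conf = conf, stringsAsFactors = FALSE)
  dropped <- !is.finite(out$conf)
  if (any(dropped)) {
    warning(sum(dropped), " residue(s) had no usable confidence values ",
            "and were excluded")
    out <- out[!dropped, , drop = FALSE]
  }
  if (any(out$conf < 0 | out$conf > 100))
    warning("confidence values outside [0, 100]; is this really a ",
            "pLDDT-annotated model?")
  rownames(out) <- NULL
  class(out) <- c("confidence_map", "data.frame")
  out
}

#' Define a binding site
#'
#' A named set of key residues (author numbering plus the expected
#' one-letter code, used to catch numbering drift) together with the
#' sequence-neighbour window used when aggregating confidence.
#'
#' @param name site name, e.g. "orthosteric".
#' @param resno integer vector of key residue numbers.
#' @param aa expected one-letter codes, parallel to \code{resno}.
#' @param neighbor_offsets signed integer offsets defining each key
#'   residue's window (0 is implicit and must not be listed).  The default
#'   \code{c(-3, -2, -1, 1, 2)} takes the five nearest sequence
#'   neighbours, tie toward the N-terminus; use \code{integer(0)} to
#'   evaluate the bare residue values.
#' @return object of class \code{site_definition}.
#' @export
site_definition <- function(name, resno, aa,
                            neighbor_offsets = c(-3L, -2L, -1L, 1L, 2L)) {
  resno <- as.integer(resno)
  if (length(resno) == 0) stop("a site needs at least one key residue")
  if (any(resno <= 0)) stop("residue numbers must be positive")
  if (length(aa) != length(resno)) stop("resno and aa lengths differ")
  neighbor_offsets <- as.integer(neighbor_offsets)
  if (any(neighbor_offsets == 0L)) stop("neighbor_offsets must exclude 0")
  structure(list(name = name, resno = resno, aa = toupper(aa),
                 neighbor_offsets = neighbor_offsets),
            class = "site_definition")
}

#' @export
print.site_definition <- function(x, ...) {
  cat(sprintf("site '%s': %s; window offsets {%s}\n", x$name,
              paste0(x$aa, x$resno, collapse = ", "),
              paste(x$neighbor_offsets, collapse = ", ")))
  invisible(x)
}

#' Built-in hP2X7 binding-site definitions
#'
#' Key residues of the human P2X7 receptor: the orthosteric (ATP) site
#' K64, K66, T189, N292, R294, K311 and the allosteric (antagonist) site
#' F88, F95, F103, M105, F293 plus position 312.  Published residue lists
#' disagree on position 312 (valine in the key-residue list, alanine in
#' some interaction tables), so both variants are available.
#'
#' @param neighbor_offsets passed to \code{\link{site_definition}}.
#' @param allosteric_variant "V312" (default) or "A312".
#' @return named list of two \code{\link{site_definition}} objects.
#' @examples
#' p2x7_sites(neighbor_offsets = integer(0))$orthosteric
#' @export
p2x7_sites <- function(neighbor_offsets = c(-3L, -2L, -1L, 1L, 2L),
                       allosteric_variant = c("V312", "A312")) {
  allosteric_variant <- match.arg(allosteric_variant)
  aa312 <- if (allosteric_variant == "V312") "V" else "A"
  list(
    orthosteric = site_definition(
      "orthosteric", c(64, 66, 189, 292, 294, 311),
      c("K", "K", "T", "N", "R", "K"), neighbor_offsets),
    allosteric = site_definition(
      "allosteric", c(88, 95, 103, 105, 293, 312),
      c("F", "F", "F", "M", "F", aa312), neighbor_offsets))
}

#' Read a site definition from a config file
#'
#' YAML config with fields \code{name}, \code{residues} (list of
#' "K64"-style labels or of \code{\{resno, aa\}} pairs) and optional
#' \code{neighbor_offsets}.
#'
#' @param path YAML file path.
#' @return a \code{\link{site_definition}}.
#' @export
read_site_definition <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name) || is.null(cfg$residues))
    stop("site config needs 'name' and 'residues'")
  res <- cfg$residues
  if (is.character(res)) {
    aa <- toupper(substr(res, 1, 1))
    resno <- as.integer(sub("^[A-Za-z]", "", res))
  } else {
    resno <- vapply(res, function(r) as.integer(r$resno), integer(1))
    aa <- vapply(res, function(r) as.character(r$aa), character(1))
  }
  site_definition(cfg$name, resno, aa,
                  neighbor_offsets = as.integer(
                    cfg$neighbor_offsets %||% c(-3, -2, -1, 1, 2)))
}

#' Aggregate per-residue means into a site global average
#'
#' Plain arithmetic mean of the per-residue confidence values; the
#' reporting convention rounds to 2 decimals.
#'
#' @param per_residue_means non-empty numeric vector.
#' @param digits rounding for the reported value; NULL for full precision.
#' @return scalar.
#' @examples
#' aggregate_global_mean(c(90.65, 90.94, 92.86, 80.30, 86.87, 93.78))  # 89.23
#' @export
aggregate_global_mean <- function(per_residue_means, digits = 2) {
  x <- as.numeric(per_residue_means)
  if (length(x) == 0) stop("empty value list")
  if (any(!is.finite(x))) stop("non-finite confidence values")
  m <- mean(x)
  if (!is.null(digits)) round(m, digits) else m
}

#' Site confidence report
#'
#' Aggregates a confidence map over a site's key residues.  Each key
#' residue's value is the mean confidence over its window (the residue
#' plus its \code{neighbor_offsets}, clipped to residues present in the
#' chain), averaged across chains according to \code{chain_policy}.  The
#' site global average is the mean of the key residues' values.
#'
#' The expected one-letter code of every key residue is checked against
#' the model; a mismatch aborts, catching numbering drift between models.
#'
#' @param conf a \code{\link{residue_confidence}} map.
#' @param model the source \code{\link{structure_model}}.
#' @param site a \code{\link{site_definition}}.
#' @param chain_policy "average_all" (default; per-chain values averaged
#'   over every chain containing the residue -- the homotrimer reporting
#'   convention) or a single chain id.
#' @return object of class \code{site_confidence_report}: a list with
#'   \code{per_residue} (data.frame: label, resno, aa, conf, n_chains,
#'   window_size), \code{global_average}, \code{n_chains_used},
#'   \code{missing}, \code{site}.
#' @examples
#' tri <- make_trimer(n_residues = 30, profile = conf_profile(constant = 50))
#' site <- site_definition("toy", c(10, 20), c("A", "A"))
#' site_confidence(residue_confidence(tri$model), tri$model, site)
#' @export
site_confidence <- function(conf, model, site,
                            chain_policy = "average_all") {
  stopifnot(inherits(site, "site_definition"))
  chains <- chain_ids(model)
  if (!identical(chain_policy, "average_all")) {
    if (!chain_policy %in% chains)
      stop("chain '", chain_policy, "' not present in model")
    chains <- chain_policy
  }
  rt <- residue_table(model)
  per_res <- vector("list", length(site$resno))
  missing <- character(0)
  for (k in seq_along(site$resno)) {
    rn <- site$resno[k]
    expected <- site$aa[k]
    vals <- numeric(0)
    wsize <- integer(0)
    for (ch in chains) {
      sub <- conf[conf$chain == ch, , drop = FALSE]
      if (!rn %in% sub$resno) next
      found <- rt$aa[rt$chain == ch & rt$resno == rn][1]
      if (!is.na(found) && toupper(found) != expected)
        stop("site '", site$name, "': residue ", rn, " in chain ", ch,
             " is ", found, ", expected ", expected,
             " -- numbering drift?")
      window <- c(rn, rn + site$neighbor_offsets)
      window <- window[window %in% sub$resno]
      vals <- c(vals, mean(sub$conf[match(window, sub$resno)]))
      wsize <- c(wsize, length(window))
    }
    if (length(vals) == 0) {
      missing <- c(missing, paste0(expected, rn))
      per_res[[k]] <- NULL
    } else {
      per_res[[k]] <- data.frame(
        label = paste0(expected, rn), resno = rn, aa = expected,
        conf = mean(vals), n_chains = length(vals),
        window_size = as.integer(round(mean(wsize))),
        stringsAsFactors = FALSE)
    }
  }
  per_res <- do.call(rbind, per_res)
  if (is.null(per_res) || nrow(per_res) == 0)
    stop("site '", site$name, "': no key residue found in any chain")
  rownames(per_res) <- NULL
  structure(list(per_residue = per_res,
                 global_average = mean(per_res$conf),
                 n_chains_used = max(per_res$n_chains),
                 missing = missing, site = site, model_id = model$id),
            class = "site_confidence_report")
}

#' @export
print.site_confidence_report <- function(x, digits = 2, ...) {
  cat(sprintf("site confidence: '%s' on model '%s' (%d chain(s) averaged)\n",
              x$site$name, x$model_id, x$n_chains_used))
  df <- x$per_residue
  cat(sprintf("  %-6s %8s\n", "Residue", "pLDDT"))
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-6s %8.2f\n", df$label[i], round(df$conf[i], digits)))
  cat(sprintf("  %-6s %8.2f\n", "Global", round(x$global_average, digits)))
  if (length(x$missing))
    cat("  missing residues:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Rank site residues by confidence
#'
#' Orders a site report's per-residue values descending; ties are broken
#' by residue number ascending.
#'
#' @param report a \code{\link{site_confidence_report}}, or a data.frame
#'   with columns \code{label}, \code{resno}, \code{conf}.
#' @return data.frame (label, resno, conf) in rank order.
#' @export
rank_site_residues <- function(report) {
  df <- if (inherits(report, "site_confidence_report"))
    report$per_residue else as.data.frame(report)
  if (nrow(df) == 0) stop("empty report")
  df <- df[order(-df$conf, df$resno), c("label", "resno", "conf")]
  rownames(df) <- NULL
  df
}

#' Write a site confidence report as TSV or JSON
#'
#' TSV mirrors the two-column per-residue layout (Residue, pLDDT mean)
#' with a trailing global-average row; JSON carries the same content
#' structured.
#'
#' @param report a \code{\link{site_confidence_report}}.
#' @param path output path.
#' @param format "tsv" or "json".
#' @param digits reporting precision (default 2 decimals).
#' @return invisibly, \code{path}.
#' @export
write_site_report <- function(report, path, format = c("tsv", "json"),
                              digits = 2) {
  format <- match.arg(format)
  df <- report$per_residue
  if (format == "tsv") {
    out <- data.frame(Residue = c(df$label, "Global average"),
                      pLDDT.mean = round(c(df$conf, report$global_average),
                                         digits))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(list(
      site = report$site$name, model = report$model_id,
      per_residue = data.frame(residue = df$label,
                               plddt_mean = round(df$conf, digits)),
      global_average = round(report$global_average, digits),
      n_chains_used = report$n_chains_used,
      missing = report$missing), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
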