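# Published reference data shipped with the package.

#' Published per-residue pLDDT values for the hP2X7 binding sites
#'
#' The reported mean pLDDT of each key residue of the human P2X7
#' receptor's orthosteric and allosteric binding sites, for the AF2 and
#' AF3 models of the published assessment.  These serve as worked-example
#' inputs: aggregating a model/site group with
#' \code{\link{aggregate_global_mean}} reproduces the reported site
#' global averages (AF2 orthosteric 89.23, AF2 allosteric 87.30, AF3
#' orthosteric 85.79), and \code{\link{rank_site_residues}} reproduces
#' the reported extreme residues.
#'
#' @param model optional filter, "AF2" or "AF3".
#' @param site optional filter, "orthosteric" or "allosteric".
#' @return data.frame with columns \code{model}, \code{site},
#'   \code{resno}, \code{aa}, \code{plddt}.
#' @examples
#' ref <- p2x7_reference_plddt("AF2", "orthosteric")
#' aggregate_global_mean(ref$plddt)  # 89.23
#' @export
p2x7_reference_plddt <- function(model = NULL, site = NULL) {
  path <- system.file("extdata", "p2x7_site_plddt.tsv",
                      package = "foldsite", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "integer", "character",
                                          "numeric"))
  if (!is.null(model)) tab <- tab[tab$model == model, , drop = FALSE]
  if (!is.null(site)) tab <- tab[tab$site == site, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
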