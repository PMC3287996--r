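#' Bundled example data
#'
#' `footprintr_extdata()` resolves a file shipped with the package.
#' Available files:
#' \describe{
#'   \item{`tf_matrices_synthetic.jaspar`}{Representative count matrices
#'     for Sp1, HNF-1, NF-Y and CREB in JASPAR text format.  These are
#'     synthetic reconstructions built from each factor's published
#'     consensus binding sites (GC-box core for Sp1, the palindromic
#'     GTTAATNATTAAC for HNF-1, the CCAAT box for NF-Y, the CRE
#'     TGACGTCA for CREB), not copies of any proprietary or curated
#'     database matrix; motif inventories obtained with them will differ
#'     from database-specific results.}
#'   \item{`nags_site_mutations.tsv`}{Published wild-type and mutated
#'     transcription-factor binding sites from the human NAGS promoter
#'     (Sp1, CREB) and enhancer (HNF-1, NF-Y), for the motif-loss check.}
#' }
#'
#' @param name file name; with no argument, lists available files.
#' @return a file path (or a character vector of file names).
#' @export
footprintr_extdata <- function(name = NULL) {
  dir <- system.file("extdata", package = "footprintr")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) stop("no bundled file called '", name, "'")
  path
}

#' Wild-type/mutant binding-site table for the NAGS regulatory regions
#'
#' @return data frame with columns `factor`, `wt`, `mut`; see
#'   [check_mutation_table()].
#' @export
nags_mutation_sites <- function() {
  read.table(footprintr_extdata("nags_site_mutations.tsv"), sep = "\t",
             header = TRUE, stringsAsFactors = FALSE)
}

#' Bundled representative transcription-factor matrices
#'
#' Loads the synthetic Sp1/HNF-1/NF-Y/CREB count matrices shipped with
#' the package (see [footprintr_extdata()] for their provenance).
#'
#' @param pseudocount per-cell pseudocount (default 0.25).
#' @return named list of [pwm()] objects.
#' @export
bundled_pwms <- function(pseudocount = 0.25) {
  load_pwms(footprintr_extdata("tf_matrices_synthetic.jaspar"), pseudocount)
}
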