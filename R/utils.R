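#' @useDynLib footprintr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rpois rgeom setNames uniroot
#' @importFrom utils read.table write.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised over its input; `N` complements to `N`, the gap character
#' `-` is preserved.
#'
#' @param x character vector of DNA strings over `A,C,G,T,N,-`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN-", "TGCAN-",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# encode a DNA string as integers A=1 C=2 G=3 T=4 N=5
encode_dna_int <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], c(DNA_BASES, "N"))
  v[is.na(v)] <- 5L
  v
}

assert_dna <- function(s, what = "sequence") {
  bad <- gsub("[ACGTN]", "", s)
  if (any(nzchar(bad))) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: '%s'",
                 what, substr(bad[nzchar(bad)][1], 1, 10)), call. = FALSE)
  }
  invisible(s)
}

# random DNA string from a base composition
random_dna <- function(n, composition = stats::setNames(rep(0.25, 4), DNA_BASES)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = composition[DNA_BASES]),
        collapse = "")
}
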