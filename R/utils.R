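# Shared validation helpers and small population-genetics utilities.

.check_finite_positive <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  }
  if (allow_zero) {
    if (any(x < 0)) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  } else {
    if (any(x <= 0)) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

#' Expected heterozygosity under Hardy-Weinberg equilibrium
#'
#' For a biallelic marker with minor allele frequency `maf`, the expected
#' proportion of heterozygous individuals is `2 * maf * (1 - maf)`. Used to
#' size SNP panels for allele-specific screens: at MAF 0.1 roughly 18% of
#' unrelated individuals are informative.
#'
#' @param maf Minor allele frequency in `[0, 0.5]`.
#' @return Expected heterozygosity in `[0, 0.5]`.
#' @examples
#' expected_heterozygosity(0.1) # 0.18
#' @export
expected_heterozygosity <- function(maf) {
  if (!is.numeric(maf) || any(!is.finite(maf)) || any(maf < 0) || any(maf > 0.5)) {
    stop("'maf' must be in [0, 0.5]", call. = FALSE)
  }
  2 * maf * (1 - maf)
}

# IUPAC nucleotide code -> the set of concrete bases it stands for.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
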