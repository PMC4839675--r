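# Allele-specific methylation from enzyme-digest SNuPE genotypes.
#
# HhaI cuts only unmethylated GCGC sites, so after HhaI digestion only the
# methylated allele of a heterozygous SNP remains amplifiable; McrBC cuts
# only methylated DNA, so it leaves the complementary (unmethylated)
# allele. Concordance between the two digests validates the call. With
# trio genotypes the methylated allele is traced to a parent; in trisomic
# samples the bulk percent-methylation alone separates maternal from
# paternal origin of the extra chromosome when the methylated allele is
# maternal (2 of 3 alleles methylated vs 1 of 3).

#' Detected alleles above an instrument noise floor
#'
#' An allele counts as detected in a SNuPE electropherogram when its
#' signal is at least `min_rel` of the strongest peak.
#'
#' @param alleles Character vector of allele labels.
#' @param signals Non-negative signal intensities, parallel to `alleles`.
#' @param min_rel Minimum relative signal (default 0.1).
#' @return Character vector of detected allele labels.
#' @export
detected_alleles <- function(alleles, signals, min_rel = 0.1) {
  .check_finite_positive(signals, "signals", allow_zero = TRUE)
  stopifnot(length(alleles) == length(signals))
  if (all(signals == 0)) return(character(0))
  unique(alleles[signals >= min_rel * max(signals)])
}

#' Call the methylated allele from dual-enzyme digest genotypes
#'
#' @param untreated Character vector: both alleles detected without
#'   digestion (must be heterozygous, exactly 2 labels).
#' @param hhai Character vector: alleles surviving HhaI
#'   (methylation-sensitive) digestion.
#' @param mcrbc Optional character vector: alleles surviving McrBC
#'   (methylation-dependent) digestion; used for cross-enzyme validation.
#' @return List with `methylated_allele` (an allele label, `"both"`,
#'   `"none"` or `"ambiguous"`), `methylated_parent` (`"unassigned"`; see
#'   [assign_parent()]) and `cross_enzyme_consistent` (NA without McrBC
#'   data).
#' @examples
#' call_allele_methylation(c("C", "A"), hhai = "C", mcrbc = "A")
#' @export
call_allele_methylation <- function(untreated, hhai, mcrbc = NULL) {
  untreated <- unique(untreated)
  if (length(untreated) != 2L) {
    stop("SNP uninformative: untreated genotype must show 2 alleles",
      call. = FALSE
    )
  }
  hhai <- unique(hhai)
  if (!all(hhai %in% untreated)) {
    stop("digest alleles must be a subset of the untreated genotype",
      call. = FALSE
    )
  }
  meth <- if (length(hhai) == 2L) {
    "both"
  } else if (length(hhai) == 0L) {
    "none"
  } else {
    hhai
  }
  consistent <- NA
  if (!is.null(mcrbc)) {
    mcrbc <- unique(mcrbc)
    if (!all(mcrbc %in% untreated)) {
      stop("digest alleles must be a subset of the untreated genotype",
        call. = FALSE
      )
    }
    if (meth %in% untreated) {
      # complementary enzyme must leave exactly the other allele
      consistent <- identical(sort(mcrbc), sort(setdiff(untreated, meth)))
      if (!consistent) meth <- "ambiguous"
    } else {
      # both/none under HhaI: McrBC should show the mirror image
      consistent <- identical(sort(mcrbc), sort(setdiff(untreated, hhai)))
    }
  }
  list(
    methylated_allele = meth,
    methylated_parent = "unassigned",
    cross_enzyme_consistent = consistent
  )
}

#' Assign the parental origin of a methylated allele
#'
#' @param asm Result of [call_allele_methylation()] with a single
#'   methylated allele.
#' @param mother,father,child Character vectors of alleles (genotypes).
#' @return `asm` with `methylated_parent` set to `"maternal"`,
#'   `"paternal"` or `"unassigned"` (when both parents carry the allele).
#' @export
assign_parent <- function(asm, mother, father, child) {
  if (length(unique(child)) < 2L) {
    stop("child must be heterozygous for parental assignment", call. = FALSE)
  }
  allele <- asm$methylated_allele
  if (!allele %in% child) {
    stop("methylated allele must be one of the child's alleles", call. = FALSE)
  }
  in_m <- allele %in% mother
  in_f <- allele %in% father
  if (!in_m && !in_f) {
    stop("methylated allele absent from both parents", call. = FALSE)
  }
  asm$methylated_parent <- if (in_m && in_f) {
    "unassigned"
  } else if (in_m) "maternal" else "paternal"
  asm
}

#' Classify trisomy origin from bulk percent methylation
#'
#' At a maternally methylated DMR a trisomic sample carries either two
#' methylated maternal alleles of three (maternal-origin trisomy,
#' expectation 200/3 ~ 66.7%) or one of three (paternal origin, 100/3 ~
#' 33.3%); a disomic sample sits at 50%. Default decision thresholds are
#' the midpoints between the disomic and trisomic expectations (58.3 /
#' 41.7), so the indeterminate band covers the disomic value.
#'
#' @param percent_meth Percentage(s) in `[0, 100]` from a known trisomic
#'   sample.
#' @param thresholds Named vector `c(pt = ..., mt = ...)`: PT21 at or
#'   below `pt`, MT21 at or above `mt`.
#' @return Character vector over `c("MT21", "PT21", "indeterminate")`.
#' @examples
#' epigenetic_origin(c(66.7, 33.3, 50)) # MT21, PT21, indeterminate
#' @export
epigenetic_origin <- function(percent_meth,
                              thresholds = c(pt = 125 / 3, mt = 175 / 3)) {
  if (!is.numeric(percent_meth) || any(!is.finite(percent_meth)) ||
      any(percent_meth < 0) || any(percent_meth > 100)) {
    stop("'percent_meth' must be in [0, 100]", call. = FALSE)
  }
  stopifnot(thresholds["pt"] < thresholds["mt"])
  ifelse(percent_meth >= thresholds[["mt"]], "MT21",
    ifelse(percent_meth <= thresholds[["pt"]], "PT21", "indeterminate")
  )
}
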