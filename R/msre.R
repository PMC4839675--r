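# MSRE-PCR methylation quantification.
#
# A triplex assay amplifies (1) the query CpG island, (2) a fully
# digestion-susceptible positive-control region, and (3) an
# enzyme-refractory normalization reference, from both undigested and
# HhaI-digested genomic DNA. Methylated (enzyme-resistant) template at the
# query survives digestion; the fraction surviving, normalized by the
# undigested amplification imbalance, estimates the percent methylation.

#' Amplification-imbalance correction factor
#'
#' The undigested run measures how unevenly the query amplimer (area `A`)
#' and the normalization reference amplimer (area `B`) amplify:
#' `f_AB = [(A * 100 / (A + B)) - 50] * 0.02`, equivalently
#' `2 * A / (A + B) - 1`. It is 0 for a balanced assay, positive when the
#' query over-amplifies, and antisymmetric under swapping `A` and `B`.
#'
#' @param A Area under the peak of the query amplimer, undigested DNA (> 0).
#' @param B Area under the peak of the reference amplimer, undigested DNA
#'   (> 0).
#' @return Correction factor strictly inside (-1, 1). Vectorized.
#' @examples
#' correction_factor(600, 400) # 0.2
#' @export
correction_factor <- function(A, B) {
  .check_finite_positive(A, "A")
  .check_finite_positive(B, "B")
  ((A * 100 / (A + B)) - 50) * 0.02
}

#' Percent methylation from an MSRE-PCR peak-area quartet
#'
#' Computes `%Meth = 100 * C * (1 - f_AB) / (D * (1 + f_AB))` where `C` and
#' `D` are the query and reference areas from the digested run and `f_AB`
#' is [correction_factor()] from the undigested run. Because
#' `(1 - f_AB) / (1 + f_AB) = B / A`, this equals
#' `100 * (C / D) * (B / A)`: the digested query:reference ratio normalized
#' by the undigested one, so it is invariant to each amplimer's
#' amplification efficiency. Values outside `[0, 100]` (measurement noise)
#' are clamped and flagged; clamping beyond `slack` points raises a
#' warning.
#'
#' @param A,B Undigested query and reference areas (> 0).
#' @param C Digested query area (>= 0).
#' @param D Digested reference area (> 0).
#' @param slack Clamping beyond this many percentage points warns
#'   (default 10).
#' @param thresholds Passed to [classify_state()].
#' @return A data.frame with columns `f_ab`, `percent_meth`, `clamped`,
#'   `state`. Vectorized over quartets.
#' @examples
#' methylation_ratio(600, 400, 90, 90) # ~66.67, hemimethylated
#' @export
methylation_ratio <- function(A, B, C, D, slack = 10,
                              thresholds = c(hypo = 20, hyper = 80)) {
  .check_finite_positive(A, "A")
  .check_finite_positive(B, "B")
  .check_finite_positive(C, "C", allow_zero = TRUE)
  .check_finite_positive(D, "D")
  f_ab <- correction_factor(A, B)
  raw <- 100 * (C * (1 - f_ab)) / (D * (1 + f_ab))
  clamped <- raw < 0 | raw > 100
  over <- pmax(raw - 100, -raw, 0)
  if (any(clamped & over > slack)) {
    warning(sprintf(
      "%d quartet(s) clamped by more than %g percentage points",
      sum(clamped & over > slack), slack
    ), call. = FALSE)
  }
  pm <- pmin(pmax(raw, 0), 100)
  data.frame(
    f_ab = f_ab,
    percent_meth = pm,
    clamped = clamped,
    state = classify_state(pm, thresholds = thresholds),
    stringsAsFactors = FALSE
  )
}

#' Classify a percent-methylation value
#'
#' Three-state classification of a CpG island:
#' hypomethylated at or below `thresholds["hypo"]`, hypermethylated at or
#' above `thresholds["hyper"]`, hemimethylated in between. Defaults (20/80)
#' place the androgenetic-mole reference (~0%) in the hypomethylated
#' state, disomic blood (~47%) in the hemimethylated state and hESCs
#' (~82%) in the hypermethylated state.
#'
#' @param percent_meth Percentage(s) in `[0, 100]`.
#' @param thresholds Named vector with elements `hypo` and `hyper`.
#' @return Character vector over
#'   `c("hypomethylated", "hemimethylated", "hypermethylated")`.
#' @export
classify_state <- function(percent_meth, thresholds = c(hypo = 20, hyper = 80)) {
  if (!is.numeric(percent_meth) || any(!is.finite(percent_meth)) ||
      any(percent_meth < 0) || any(percent_meth > 100)) {
    stop("'percent_meth' must be in [0, 100]", call. = FALSE)
  }
  stopifnot(thresholds["hypo"] < thresholds["hyper"])
  ifelse(percent_meth <= thresholds[["hypo"]], "hypomethylated",
    ifelse(percent_meth >= thresholds[["hyper"]], "hypermethylated",
      "hemimethylated"
    )
  )
}

#' Digestion-efficiency quality control
#'
#' The positive-control amplimer covers a fully digestion-susceptible
#' region, so after complete digestion it should vanish. The residual
#' fraction is its digested:reference ratio normalized by the undigested
#' one; the run passes when the residual is at or below `threshold`.
#'
#' @param pos_undigested,neg_undigested Positive-control and reference
#'   areas, undigested DNA (> 0).
#' @param pos_digested Positive-control area, digested DNA (>= 0).
#' @param neg_digested Reference area, digested DNA (> 0).
#' @param threshold Maximum residual fraction to pass (default 0.05).
#' @return data.frame with columns `residual_fraction`, `passed`.
#' @examples
#' digestion_qc(1000, 1000, 40, 1000) # residual 0.04, passed
#' @export
digestion_qc <- function(pos_undigested, neg_undigested, pos_digested,
                         neg_digested, threshold = 0.05) {
  .check_finite_positive(pos_undigested, "pos_undigested")
  .check_finite_positive(neg_undigested, "neg_undigested")
  .check_finite_positive(pos_digested, "pos_digested", allow_zero = TRUE)
  .check_finite_positive(neg_digested, "neg_digested")
  residual <- (pos_digested / neg_digested) / (pos_undigested / neg_undigested)
  data.frame(residual_fraction = residual, passed = residual <= threshold)
}

#' Quantify methylation for a table of MSRE-PCR quartets
#'
#' Table-level driver over [methylation_ratio()] (and [digestion_qc()] when
#' the positive-control columns are present).
#'
#' @param quartets data.frame with columns `sample_id`, `target`, `A`, `B`,
#'   `C`, `D`, and optionally `pos_undigested`, `pos_digested` for QC
#'   (reference areas `B`/`D` are reused as the QC denominators).
#' @param qc_threshold Passed to [digestion_qc()].
#' @param ... Passed to [methylation_ratio()].
#' @return data.frame with `sample_id`, `target`, `f_ab`, `percent_meth`,
#'   `clamped`, `state`, `qc_passed` (NA when no QC columns).
#' @export
quantify_methylation <- function(quartets, qc_threshold = 0.05, ...) {
  need <- c("sample_id", "target", "A", "B", "C", "D")
  if (!all(need %in% names(quartets))) {
    stop("quartet table needs columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  res <- methylation_ratio(quartets$A, quartets$B, quartets$C, quartets$D, ...)
  qc_passed <- rep(NA, nrow(quartets))
  if (all(c("pos_undigested", "pos_digested") %in% names(quartets))) {
    qc <- digestion_qc(quartets$pos_undigested, quartets$B,
      quartets$pos_digested, quartets$D,
      threshold = qc_threshold
    )
    qc_passed <- qc$passed
  }
  cbind(
    quartets[, c("sample_id", "target")],
    res,
    qc_passed = qc_passed
  )
}
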