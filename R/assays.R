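# Fixed amino-acid class memberships (one-letter codes). Classes overlap:
# Phe and Tyr are both hydrophobic and aromatic.
HAA_CLASS <- c("A", "V", "I", "L", "Y", "F", "P", "M", "C")
NCAA_CLASS <- c("D", "E")
AAA_CLASS <- c("F", "Y")

#' Amino-acid class composition profile
#'
#' Aggregates per-residue quantities (e.g. nmol/mg from an amino-acid
#' analyzer) into hydrophobic (HAA: Ala, Val, Ile, Leu, Tyr, Phe, Pro, Met,
#' Cys), negatively charged (NCAA: Asp, Glu) and aromatic (AAA: Phe, Tyr)
#' class totals and their percentages of the grand total. The classes
#' overlap at Phe/Tyr; within a class no residue is counted twice. Residues
#' absent from the input count as zero.
#'
#' @param quantities Named numeric vector (names are one- or three-letter
#'   residue codes) or a two-column data frame (residue, amount).
#' @return An `aa_profile`: `quantities` (named by one-letter code),
#'   `class_sums` and `fractions` (percent) for HAA/NCAA/AAA, and `total`.
#' @export
#' @examples
#' composition_profile(c(Ala = 10, Asp = 5, Phe = 2))
composition_profile <- function(quantities) {
  if (is.data.frame(quantities)) {
    q <- as.numeric(quantities[[2]])
    names(q) <- as.character(quantities[[1]])
    quantities <- q
  }
  if (length(quantities) == 0L) stop("empty amino-acid profile")
  if (is.null(names(quantities)) || any(!nzchar(names(quantities)))) {
    stop("quantities must be named by residue")
  }
  if (any(!is.finite(quantities)) || any(quantities < 0)) {
    stop("amino-acid amounts must be finite and non-negative")
  }
  res <- canonical_residue(names(quantities))
  if (anyDuplicated(res)) stop("duplicate residue in profile")
  names(quantities) <- res
  total <- sum(quantities)
  class_sum <- function(members) sum(quantities[intersect(members, res)])
  sums <- c(HAA = class_sum(HAA_CLASS), NCAA = class_sum(NCAA_CLASS),
            AAA = class_sum(AAA_CLASS))
  fracs <- if (total > 0) 100 * sums / total else sums * NA_real_
  structure(list(quantities = quantities, class_sums = sums,
                 fractions = fracs, total = total),
            class = "aa_profile")
}

#' @export
print.aa_profile <- function(x, ...) {
  cat(sprintf("Amino-acid profile: total %.2f\n", x$total))
  for (cl in names(x$class_sums)) {
    cat(sprintf("  %-4s %8.2f  (%.2f%%)\n", cl, x$class_sums[[cl]],
                x$fractions[[cl]]))
  }
  invisible(x)
}

#' ABTS radical scavenging percentage
#'
#' `[1 - (As - Ac)/Ab] * 100`, where As is the sample absorbance (sample +
#' radical), Ac the sample colour control (sample + buffer) and Ab the blank
#' (radical alone). The source formula is sometimes typeset as
#' `1 - [(As - Ac)/Ab] * 100`, which cannot yield a percentage; the bracket
#' placement used here gives 0% when the radical absorbance is untouched and
#' 100% when it is fully quenched.
#'
#' @param a_s,a_c,a_b Sample, control and blank absorbances.
#' @return Scavenging activity in percent.
#' @export
abts_scavenging <- function(a_s, a_c, a_b) {
  stopifnot(is.finite(a_s), is.finite(a_c), is.finite(a_b))
  if (a_b == 0) stop("blank absorbance is zero")
  (1 - (a_s - a_c) / a_b) * 100
}

#' Cell viability percentage
#'
#' `(As - Ab) / (Ac - Ab) * 100` from CCK-8 style absorbances: As treated
#' cells, Ac untreated control cells, Ab cell-free blank.
#'
#' @param a_s,a_c,a_b Sample, control and blank absorbances.
#' @return Viability in percent.
#' @export
cell_viability <- function(a_s, a_c, a_b) {
  stopifnot(is.finite(a_s), is.finite(a_c), is.finite(a_b))
  if (a_c == a_b) stop("control equals blank: viability undefined")
  (a_s - a_b) / (a_c - a_b) * 100
}

#' Cellular antioxidant activity (CAA) unit from fluorescence kinetics
#'
#' `CAA = 100 - 100 * AUC(sample) / AUC(control)`, areas under the
#' fluorescence-time curves by the trapezoidal rule over the shared grid.
#'
#' @param sample_curve,control_curve Fluorescence readings on `times`.
#' @param times Increasing time grid (min), length >= 2.
#' @return CAA unit in percent.
#' @export
caa_unit <- function(sample_curve, control_curve, times) {
  times <- as.numeric(times)
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE)) {
    stop("times must be an increasing grid of >= 2 points")
  }
  if (length(sample_curve) != length(times) ||
      length(control_curve) != length(times)) {
    stop("curves and time grid differ in length")
  }
  sa <- pracma::trapz(times, as.numeric(sample_curve))
  ca <- pracma::trapz(times, as.numeric(control_curve))
  if (ca <= 0) stop("control curve has non-positive area")
  100 - 100 * sa / ca
}

#' Median-effect EC50 from a dose-CAA series
#'
#' Linearizes the dose-effect relation as `log10(CAA / (100 - CAA))` against
#' `log10(dose)` and reads EC50 off the fitted least-squares line at the
#' zero crossing (CAA = 50): `EC50 = 10^(-intercept / slope)`. Doses whose
#' CAA lies outside (0, 100) are excluded (the transform is undefined there)
#' and recorded in the result.
#'
#' @param doses Dose levels (mg/mL), all positive.
#' @param caa CAA units (percent) matching `doses`.
#' @return A `dose_response`: `doses`, `caa`, fitted `slope` and `intercept`,
#'   `ec50` (mg/mL), and `excluded` (indices dropped from the fit).
#' @export
estimate_ec50 <- function(doses, caa) {
  doses <- as.numeric(doses); caa <- as.numeric(caa)
  if (length(doses) != length(caa)) stop("doses and caa differ in length")
  if (any(doses <= 0)) stop("doses must be positive")
  usable <- which(caa > 0 & caa < 100)
  if (length(usable) < 2L) {
    stop("need at least 2 doses with CAA strictly between 0 and 100")
  }
  x <- log10(doses[usable])
  z <- log10(caa[usable] / (100 - caa[usable]))
  fit <- stats::lm(z ~ x)
  b <- unname(stats::coef(fit)[1]); m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m == 0) stop("zero slope: EC50 undefined")
  structure(list(doses = doses, caa = caa, slope = m, intercept = b,
                 ec50 = 10^(-b / m), excluded = setdiff(seq_along(doses), usable)),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Median-effect fit: slope %.3f, EC50 %.4g mg/mL (%d/%d doses used)\n",
              x$slope, x$ec50, length(x$doses) - length(x$excluded),
              length(x$doses)))
  invisible(x)
}

#' Relative gene expression by the delta-delta-Ct method
#'
#' `2^-((Ct_target,treated - Ct_ref,treated) - (Ct_target,control - Ct_ref,control))`.
#'
#' @param ct_target_treated,ct_ref_treated Ct of target and reference gene in
#'   the treated sample.
#' @param ct_target_control,ct_ref_control Ct of target and reference gene in
#'   the control sample.
#' @return Fold change relative to control.
#' @export
relative_expression <- function(ct_target_treated, ct_ref_treated,
                                ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) stop("all Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
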