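#' Simulate a peptide-activity dataset with a known descriptor-linear signal
#'
#' Draws peptide sequences uniformly over the 20-letter alphabet with lengths
#' uniform in `length_range`, encodes them under `spec`/`scale`, and sets
#' `activity = X beta + eps` with `eps ~ N(0, noise_sd * sd(X beta))`, i.e.
#' `noise_sd` is the noise level as a fraction of the signal standard
#' deviation. The generator mirrors the structure of a hydrolysate ORAC
#' database: short-to-medium peptides and a real-valued activity.
#'
#' @param n Number of peptides.
#' @param length_range Integer vector `c(min, max)` of peptide lengths.
#' @param spec,scale Encoding specification and descriptor scale.
#' @param true_beta Coefficient vector in encoded-feature space; by default
#'   drawn once as standard normal under `seed`.
#' @param noise_sd Gaussian noise SD as a fraction of signal SD (>= 0).
#' @param seed Integer seed; the dataset is a pure function of it.
#' @return List: `records` (data frame sequence/activity), `true_beta`,
#'   `signal_sd`, `noise_sd_abs` (the absolute noise SD used), `X`.
#' @export
gen_peptide_dataset <- function(n = 60L, length_range = c(2L, 26L),
                                spec = encoding_spec(), scale = load_scale(),
                                true_beta = NULL, noise_sd = 0.1, seed) {
  stopifnot(n >= 1L, length_range[1] >= 1L,
            length_range[2] >= length_range[1], noise_sd >= 0)
  p <- (spec$k_n + spec$k_c) * scale$dims
  with_seed(seed, {
    if (is.null(true_beta)) true_beta <- stats::rnorm(p)
    if (length(true_beta) != p) stop(sprintf("true_beta must have length %d", p))
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    }, character(1))
    X <- encode_set(seqs, spec, scale)
    signal <- as.numeric(X %*% true_beta)
    sig_sd <- stats::sd(signal)
    eps <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd * sig_sd) else numeric(n)
    list(records = data.frame(sequence = seqs, activity = signal + eps,
                              stringsAsFactors = FALSE),
         true_beta = true_beta, signal_sd = sig_sd,
         noise_sd_abs = noise_sd * sig_sd, X = X)
  })
}

#' Simulate a fluorescence experiment obeying an exact median-effect law
#'
#' Builds a control fluorescence decay on the 0-60 min grid read every
#' 10 min, and for each dose D a sample curve scaled so that the resulting
#' CAA unit satisfies `log10(CAA/(100-CAA)) = slope * (log10 D - log10 ec50)`
#' exactly: the sample curve is `control * (1 - CAA(D)/100)`, which fixes the
#' AUC ratio analytically whatever the control's shape. Optional
#' multiplicative lognormal noise (`sdlog = noise_frac`) is applied pointwise
#' to the sample curves.
#'
#' @param doses Dose levels (mg/mL), all positive.
#' @param ec50 Ground-truth EC50 (mg/mL), > 0.
#' @param slope Median-effect slope, non-zero.
#' @param f0 Control fluorescence at time zero.
#' @param decay_rate Exponential decay rate of the control (per min).
#' @param noise_frac Multiplicative noise level (0 = noiseless).
#' @param seed Integer seed.
#' @return List: `times`, `control_curve`, `sample_curves` (matrix, one
#'   column per dose, dose as column name), `doses`, `ec50` (ground truth),
#'   `slope`.
#' @export
gen_fluorescence_experiment <- function(doses = c(0.01, 0.02, 0.04, 0.08, 0.16),
                                        ec50 = 0.04, slope = 1.5,
                                        f0 = 1000, decay_rate = 0.03,
                                        noise_frac = 0, seed = 1L) {
  stopifnot(all(doses > 0), ec50 > 0, slope != 0, f0 > 0, noise_frac >= 0)
  times <- seq(0, 60, by = 10)
  control <- f0 * exp(-decay_rate * times)
  r <- (doses / ec50)^slope        # CAA/(100-CAA) under the median-effect law
  caa <- 100 * r / (1 + r)
  with_seed(seed, {
    curves <- vapply(seq_along(doses), function(j) {
      base <- control * (1 - caa[j] / 100)
      if (noise_frac > 0) base <- base * stats::rlnorm(length(base), 0, noise_frac)
      base
    }, numeric(length(times)))
    colnames(curves) <- format(doses, trim = TRUE)
    list(times = times, control_curve = control, sample_curves = curves,
         doses = doses, ec50 = ec50, slope = slope)
  })
}

#' CAA units and EC50 from a (possibly simulated) fluorescence experiment
#'
#' Convenience wrapper: computes the CAA unit of every dose curve against the
#' control with [caa_unit()] and fits the median-effect line with
#' [estimate_ec50()].
#'
#' @param experiment A list as returned by [gen_fluorescence_experiment()]
#'   (fields `times`, `control_curve`, `sample_curves`, `doses`).
#' @return A `dose_response` (see [estimate_ec50()]).
#' @export
dose_response_from_curves <- function(experiment) {
  caa <- apply(experiment$sample_curves, 2, caa_unit,
               control_curve = experiment$control_curve,
               times = experiment$times)
  estimate_ec50(experiment$doses, caa)
}
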