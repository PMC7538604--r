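#' OSN population parameters
#'
#' A glomerulus pools a population of sibling olfactory sensory neurons that
#' all express the same receptor but differ in effective EC50 (half-maximal
#' concentration), e.g. through a range of spare receptor capacities. Pooling
#' sigmoids with staggered EC50s yields a population dose-response with
#' reduced effective cooperativity and an extended dynamic range, compared to
#' the ~1.5 log-unit range of a single receptor with Hill coefficient 1.
#'
#' @param n_sibling Number of sibling OSNs per receptor type.
#' @param hill_n Hill coefficient (cooperativity), >= 1.
#' @param ec50_center Geometric center of the EC50 distribution (conc. units).
#' @param ec50_spread_decades Total log10 span of EC50 heterogeneity. 0 gives
#'   a degenerate population identical to a single unit.
#' @param random_ec50 If `TRUE`, EC50 exponents are drawn log-uniformly at
#'   random (seeded); default is deterministic even spacing across the span.
#' @param seed Seed for the random EC50 variant.
#' @return An object of class `osn_params`.
#' @export
osn_params <- function(n_sibling = 30L, hill_n = 1, ec50_center = 1,
                       ec50_spread_decades = 4, random_ec50 = FALSE,
                       seed = 0L) {
  stopifnot(n_sibling >= 1, hill_n >= 1, ec50_center > 0,
            ec50_spread_decades >= 0)
  structure(
    list(n_sibling = as.integer(n_sibling), hill_n = hill_n,
         ec50_center = ec50_center,
         ec50_spread_decades = ec50_spread_decades,
         random_ec50 = isTRUE(random_ec50), seed = as.integer(seed)),
    class = "osn_params"
  )
}

# EC50 values of the sibling population (concentration units)
population_ec50s <- function(params) {
  half <- params$ec50_spread_decades / 2
  n <- params$n_sibling
  expo <- if (n == 1L) {
    0
  } else if (params$random_ec50) {
    with_substream(params$seed, "ec50", 0L, stats::runif(n, -half, half))
  } else {
    seq(-half, half, length.out = n)
  }
  params$ec50_center * 10^expo
}

#' Single-receptor Hill activation
#'
#' Ligand-receptor binding with cooperativity `hill_n` gives activation
#' `drive * c^n / (c^n + EC50^n)`: half-maximal at `c = EC50`, bounded by the
#' ligand's receptor drive, and monotone in concentration. With `hill_n = 1`
#' the 10-90% dynamic range spans log10(81) ~ 1.9 orders of magnitude of
#' concentration, the Boltzmann limit that population heterogeneity relaxes.
#'
#' @param drive Per-receptor ligand drive in `[0, 1]`.
#' @param concentration Positive concentration (arbitrary units).
#' @param ec50 Positive half-maximal concentration.
#' @param hill_n Hill coefficient >= 1.
#' @return Activation in `[0, drive]`.
#' @export
#' @examples
#' hill_activation(1, concentration = 2, ec50 = 2)  # 0.5
hill_activation <- function(drive, concentration, ec50, hill_n = 1) {
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("'concentration' must be positive")
  }
  if (any(!is.finite(ec50)) || any(ec50 <= 0)) stop("'ec50' must be positive")
  stopifnot(hill_n >= 1)
  cn <- concentration^hill_n
  drive * cn / (cn + ec50^hill_n)
}

#' Population dose-response of sibling OSNs
#'
#' Mean activation over `n_sibling` Hill units whose EC50s are log-uniformly
#' spaced over `ec50_spread_decades` decades centered on `ec50_center`
#' (convergent axons onto a glomerulus average presynaptically). With zero
#' spread this reduces exactly to [hill_activation()].
#'
#' @inheritParams hill_activation
#' @param params An [osn_params()] object.
#' @return Activation in `[0, drive]`, monotone nondecreasing in
#'   `concentration`.
#' @export
sample_population <- function(drive, concentration, params = osn_params()) {
  ec50s <- population_ec50s(params)
  cn <- concentration^params$hill_n
  drive * mean(cn / (cn + ec50s^params$hill_n))
}

#' Glomerular activation pattern from an effective receptor drive
#'
#' Applies the sibling-population dose-response independently per receptor
#' type. Because concentration enters every channel through the same
#' population binding curve, the pattern is the affinity vector scaled by a
#' common concentration-dependent gain; downstream relational normalization
#' removes that gain, which is the root of the pipeline's concentration
#' tolerance.
#'
#' @param affinity Effective drive vector (length N, entries in `[0, 1]`).
#' @param concentration Positive scalar concentration.
#' @param params An [osn_params()] object.
#' @return Numeric glomerular pattern, length N, entries in `[0, 1]`.
#' @export
glomerular_input <- function(affinity, concentration, params = osn_params()) {
  if (inherits(affinity, "odor_signature")) affinity <- affinity$affinity
  if (length(affinity) == 0L) stop("'affinity' must be a nonempty vector")
  ec50s <- population_ec50s(params)
  cn <- concentration^params$hill_n
  gain <- mean(cn / (cn + ec50s^params$hill_n))
  affinity * gain
}

#' Dose-response curve of the sibling population
#'
#' Convenience tabulation for inspection or CSV export.
#'
#' @param params An [osn_params()] object.
#' @param drive Receptor drive used for the curve.
#' @param log10_range Length-2 log10 concentration range.
#' @param n_points Grid resolution.
#' @return data.frame with columns `concentration`, `activation`.
#' @export
dose_response <- function(params = osn_params(), drive = 1,
                          log10_range = c(-6, 6), n_points = 601L) {
  conc <- 10^seq(log10_range[1L], log10_range[2L], length.out = n_points)
  act <- vapply(conc, function(c) sample_population(drive, c, params), 1.0)
  data.frame(concentration = conc, activation = act)
}

#' 10-90% dynamic range of a dose-response curve, in log10 units
#'
#' Measured by monotone interpolation of the curve between 10% and 90% of its
#' asymptotic maximum (the drive). Used to verify that EC50 heterogeneity
#' extends the population's input range beyond the single-receptor
#' log10(81) ~ 1.91 decades.
#'
#' @inheritParams dose_response
#' @return Width of the 10-90% activation interval in log10 concentration
#'   units.
#' @export
dynamic_range_log10 <- function(params = osn_params(), drive = 1,
                                log10_range = c(-8, 8), n_points = 4001L) {
  dr <- dose_response(params, drive, log10_range, n_points)
  x <- log10(dr$concentration)
  y <- dr$activation / drive
  # curve is strictly increasing; invert by interpolation
  c10 <- stats::approx(y, x, xout = 0.1, ties = "ordered")$y
  c90 <- stats::approx(y, x, xout = 0.9, ties = "ordered")$y
  c90 - c10
}
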