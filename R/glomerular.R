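#' Non-topographical contrast enhancement parameters
#'
#' Each glomerular column combines direct excitation of its mitral/tufted
#' cells (MTCs) with activation-dependent feedforward inhibition. The
#' inhibition term saturates, so weak-to-moderate afferent input is dominated
#' by inhibition (MTC pushed below baseline) while strong input escapes it
#' (MTC fires). The contrast-enhancement operator used here is
#' `gain * x - stringency * A * x^m / (x^m + k^m)`.
#'
#' @param inhibition_amplitude Amplitude `A` of the saturating inhibition,
#'   in (0, 1].
#' @param inhibition_halfmax Input level `k` at which inhibition is
#'   half-maximal.
#' @param inhibition_steepness Hill steepness `m` of the inhibition, >= 1.
#' @param excitation_gain Linear excitatory gain.
#' @param stringency Multiplier on the inhibition amplitude; the
#'   neuromodulatory (cholinergic) knob regulating how stringent contrast
#'   enhancement is. 0 disables inhibition entirely.
#' @return An object of class `ntce_params`.
#' @export
ntce_params <- function(inhibition_amplitude = 0.5, inhibition_halfmax = 0.2,
                        inhibition_steepness = 2, excitation_gain = 1,
                        stringency = 1) {
  stopifnot(inhibition_amplitude > 0, inhibition_amplitude <= 1,
            inhibition_halfmax > 0, inhibition_steepness >= 1,
            excitation_gain > 0, stringency >= 0)
  structure(
    list(inhibition_amplitude = inhibition_amplitude,
         inhibition_halfmax = inhibition_halfmax,
         inhibition_steepness = inhibition_steepness,
         excitation_gain = excitation_gain,
         stringency = stringency),
    class = "ntce_params"
  )
}

#' Relational normalization across glomerular columns
#'
#' Rescales the pattern multiplicatively so its mean equals `target_mean`,
#' modeling the feedback circuit of the deep glomerular layer that normalizes
#' each column with respect to total activity sampled across columns. The
#' output is invariant under any uniform positive scaling of the input, which
#' is what renders downstream computation concentration tolerant. Values
#' pushed above 1 are clipped (hard) or soft-saturated.
#'
#' @param pattern Numeric vector, entries in `[0, 1]`, at least one positive.
#' @param target_mean Positive target for the post-normalization mean.
#' @param clip `"hard"` (clip at 1, warning when values are clipped) or
#'   `"soft"` (when any value overflows, the whole pattern is rescaled by its
#'   maximum so ratios between columns are preserved instead of truncated).
#' @param warn Emit a warning when hard clipping occurs.
#' @return Normalized pattern. An all-zero input is returned unchanged with
#'   attribute `blank_scene = TRUE` (no normalization is possible).
#' @export
#' @examples
#' normalize_columns(c(0.1, 0.2, 0.3, 0.4), target_mean = 0.25)
normalize_columns <- function(pattern, target_mean = 0.25,
                              clip = c("hard", "soft"), warn = TRUE) {
  clip <- match.arg(clip)
  stopifnot(is.numeric(pattern), target_mean > 0)
  m <- mean(pattern)
  if (m == 0) {
    attr(pattern, "blank_scene") <- TRUE
    return(pattern)
  }
  out <- pattern * (target_mean / m)
  if (any(out > 1)) {
    if (clip == "hard") {
      if (warn) warning("normalize_columns: ", sum(out > 1),
                        " value(s) clipped to 1")
      out <- pmin(1, out)
    } else {
      out <- out / max(out)
    }
  }
  out
}

#' Activation-dependent contrast enhancement (NTCE)
#'
#' Applies, per column, linear excitation minus saturating feedforward
#' inhibition: `gain * x - stringency * A * x^m / (x^m + k^m)`. With the
#' defaults the output is positive for normalized inputs above ~0.4
#' (excited columns), negative on roughly (0.1, 0.4) (below-baseline
#' inhibition of moderately driven columns), and negligible for the weakest
#' inputs — the excited / suppressed / silent partition that implements
#' surround inhibition in receptor-space rather than anatomical space.
#' `x = 0` maps to 0 and `stringency = 0` reduces to pure excitation.
#'
#' @param normalized Numeric vector of normalized column activations in
#'   `[0, 1]`.
#' @param params An [ntce_params()] object.
#' @return Signed per-column MTC drive vector.
#' @export
#' @examples
#' ntce_transform(c(0, 0.15, 0.8))  # c(0, -0.03, ~0.329)
ntce_transform <- function(normalized, params = ntce_params()) {
  stopifnot(is.numeric(normalized))
  x <- normalized
  m <- params$inhibition_steepness
  k <- params$inhibition_halfmax
  xm <- x^m
  inh <- params$stringency * params$inhibition_amplitude * xm / (xm + k^m)
  inh[x == 0] <- 0
  params$excitation_gain * x - inh
}

#' Probe-column response profile along an odor similarity series
#'
#' Runs each odor of a series (ordered from most to least similar to the
#' probe column's preferred odor) through the glomerular stages
#' (OSN sampling, relational normalization, NTCE) and returns the signed
#' drive of the probe column for each. A correctly tuned column responds with
#' excitation to its preferred odor, below-baseline inhibition to near
#' neighbors (its "surround"), and essentially no response to dissimilar
#' odors — surround inhibition in high-dimensional R-space.
#'
#' @param probe_column Column (receptor) index probed.
#' @param odor_series List of [make_signature()] objects or affinity vectors,
#'   length >= 3, ordered by decreasing similarity to the probe's preferred
#'   odor.
#' @param concentration Presentation concentration.
#' @param osn An [osn_params()] object.
#' @param ntce An [ntce_params()] object.
#' @param target_mean Normalization target mean.
#' @return Numeric vector of signed probe responses, one per odor.
#' @export
surround_profile <- function(probe_column, odor_series, concentration = 1,
                             osn = osn_params(), ntce = ntce_params(),
                             target_mean = 0.25) {
  if (length(odor_series) < 3L) {
    stop("'odor_series' must span at least 3 odors from high to low similarity")
  }
  vapply(odor_series, function(s) {
    aff <- if (inherits(s, "odor_signature")) s$affinity else as.numeric(s)
    g <- glomerular_input(aff, concentration, osn)
    nrm <- normalize_columns(g, target_mean, warn = FALSE)
    drv <- ntce_transform(nrm, ntce)
    drv[probe_column]
  }, 1.0)
}
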