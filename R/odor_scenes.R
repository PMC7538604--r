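#' Synthetic odor signatures and scene perturbations
#'
#' An odor source is modeled as a point in receptor space ("R-space"): the
#' unit N-cube whose axes are the activation drives it delivers to each of the
#' N odorant receptor types. Odors are sparse — they do not activate all
#' receptor types — so a signature has a controlled fraction of nonzero
#' entries, each drawn uniformly from (0, 1].
#'
#' @param n_receptors Number of receptor types N (>= 2).
#' @param sparsity Fraction of receptor types activated, in (0, 1]. Exactly
#'   `round(sparsity * n_receptors)` entries are nonzero.
#' @param seed Integer seed; the same seed reproduces the signature exactly.
#' @param id Label for the odor source.
#' @return An object of class `odor_signature`: list with `id`, `affinity`
#'   (length-N numeric in `[0,1]`), and `sparsity`.
#' @export
#' @examples
#' sig <- make_signature(72, sparsity = 0.5, seed = 1)
#' sum(sig$affinity > 0)  # 36
make_signature <- function(n_receptors, sparsity, seed, id = "odor") {
  stopifnot(n_receptors >= 2, length(sparsity) == 1L)
  if (!is.finite(sparsity) || sparsity <= 0 || sparsity > 1) {
    stop("'sparsity' must lie in (0, 1]: a signature must activate at least one receptor")
  }
  n_active <- max(1L, as.integer(round(sparsity * n_receptors)))
  aff <- with_substream(seed, "signature", 0L, {
    idx <- sample.int(n_receptors, n_active)
    a <- numeric(n_receptors)
    # uniform on (0, 1]: flip a U[0,1) draw
    a[idx] <- 1 - stats::runif(n_active)
    a
  })
  structure(
    list(id = as.character(id), affinity = aff, sparsity = n_active / n_receptors),
    class = "odor_signature"
  )
}

#' @export
print.odor_signature <- function(x, ...) {
  cat(sprintf(
    "<odor_signature '%s'>  N = %d receptors, %d active (sparsity %.2f)\n",
    x$id, length(x$affinity), sum(x$affinity > 0), x$sparsity
  ))
  invisible(x)
}

#' Bernoulli sensor occlusion
#'
#' Replaces a fixed fraction of channels, chosen uniformly without
#' replacement, with independent uniform draws on `[0, 1]`. This models
#' competition for receptors by unknown background odorants, which may
#' strongly activate, weakly occupy, or block any given receptor
#' unpredictably. Unoccluded channels are returned bit-identical.
#'
#' @param pattern Numeric vector of channel activations in `[0, 1]`.
#' @param fraction Fraction of channels occluded, in `[0, 1]`.
#'   `round(fraction * length(pattern))` channels are replaced.
#' @param seed Integer seed for the occlusion draw.
#' @param index Substream index for repeated independent draws under one seed.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' p <- rep(0.5, 72)
#' q <- apply_bernoulli_occlusion(p, 0.5, seed = 1)
#' sum(q != p)  # 36
apply_bernoulli_occlusion <- function(pattern, fraction, seed, index = 0L) {
  stopifnot(is.numeric(pattern), length(pattern) >= 1L)
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop("'fraction' must lie in [0, 1]")
  }
  n <- length(pattern)
  n_occ <- as.integer(round(fraction * n))
  if (n_occ == 0L) return(pattern)
  with_substream(seed, "occlusion", index, {
    idx <- sample.int(n, n_occ)
    pattern[idx] <- stats::runif(n_occ)
    pattern
  })
}

#' Multiplicative plume fluctuation noise
#'
#' Odor plumes impose broadly Gaussian fluctuations on the activity of all
#' receptors. This is emulated as clipped multiplicative Gaussian noise: each
#' channel is scaled by `max(0, 1 + g)` with `g ~ Normal(0, sigma)`, then
#' clipped back to `[0, 1]`. `sigma` is configurable so the variance can be
#' matched to any recorded plume. Zeros are preserved exactly.
#'
#' @param pattern Numeric vector of channel activations in `[0, 1]`.
#' @param sigma Nonnegative standard deviation of the relative fluctuation.
#' @param seed Integer seed.
#' @param index Substream index for repeated draws.
#' @return Numeric vector of the same length, in `[0, 1]`.
#' @export
apply_plume_noise <- function(pattern, sigma, seed, index = 0L) {
  stopifnot(is.numeric(pattern))
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(pattern)
  with_substream(seed, "plume", index, {
    g <- stats::rnorm(length(pattern), 0, sigma)
    pmin(1, pmax(0, pattern * pmax(0, 1 + g)))
  })
}

#' Combine odor sources into one effective receptor drive
#'
#' Ligands from different sources compete for the same receptors. Two mixture
#' rules are provided:
#' \describe{
#'   \item{`"sum-saturate"`}{per-receptor drive `min(1, sum_i affinity_i * w_i)`
#'     with `w_i` the (relative) concentrations — additive agonism with a
#'     saturating receptor.}
#'   \item{`"competitive"`}{a single shared binding site with global
#'     dissociation constant `K`: drive
#'     `sum_i affinity_i * c_i / (K + sum_i c_i)`. A single odor at `c >> K`
#'     saturates to its own affinity.}
#' }
#'
#' @param signatures List of [make_signature()] objects (or plain affinity
#'   vectors) of equal length.
#' @param concentrations Positive numeric vector, one entry per signature.
#' @param rule `"sum-saturate"` or `"competitive"`.
#' @param K Shared binding constant for the competitive rule.
#' @return Numeric effective affinity vector in `[0, 1]`.
#' @export
#' @examples
#' a <- make_signature(4, 0.5, seed = 1, id = "a")
#' b <- make_signature(4, 0.5, seed = 2, id = "b")
#' mix_scenes(list(a, b), c(1, 1), rule = "competitive")
mix_scenes <- function(signatures, concentrations,
                       rule = c("sum-saturate", "competitive"), K = 1.0) {
  rule <- match.arg(rule)
  if (!is.list(signatures) || length(signatures) < 1L) {
    stop("'signatures' must be a nonempty list")
  }
  affs <- lapply(signatures, function(s) {
    if (inherits(s, "odor_signature")) s$affinity else as.numeric(s)
  })
  n <- length(affs[[1L]])
  if (any(vapply(affs, length, 1L) != n)) stop("signatures have mismatched lengths")
  if (length(concentrations) != length(affs)) {
    stop("'signatures' and 'concentrations' must have the same length")
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be positive")
  }
  A <- do.call(rbind, affs)
  if (rule == "sum-saturate") {
    pmin(1, as.numeric(concentrations %*% A))
  } else {
    as.numeric(concentrations %*% A) / (K + sum(concentrations))
  }
}

#' Write / read odor scene batches as CSV
#'
#' The scene dialect is a plain CSV with channel columns
#' `channel_000 .. channel_{N-1}` followed by metadata columns `odor_id`,
#' `concentration`, `occlusion_fraction`, `seed`. One row per presentation.
#'
#' @param scenes Numeric matrix (rows = presentations, columns = channels).
#' @param path Output file path.
#' @param odor_id,concentration,occlusion_fraction,seed Metadata, recycled to
#'   the number of rows.
#' @return `path`, invisibly (for `write_scenes`); a list with `channels`
#'   (matrix) and `meta` (data.frame) for `read_scenes`.
#' @export
write_scenes <- function(scenes, path, odor_id = "odor", concentration = 1,
                         occlusion_fraction = 0, seed = NA_integer_) {
  scenes <- as.matrix(scenes)
  n <- ncol(scenes)
  df <- as.data.frame(scenes)
  names(df) <- sprintf("channel_%03d", seq_len(n) - 1L)
  df$odor_id <- rep_len(odor_id, nrow(scenes))
  df$concentration <- rep_len(concentration, nrow(scenes))
  df$occlusion_fraction <- rep_len(occlusion_fraction, nrow(scenes))
  df$seed <- rep_len(seed, nrow(scenes))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenes
#' @export
read_scenes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ch_cols <- grep("^channel_[0-9]+$", names(df), value = TRUE)
  if (length(ch_cols) == 0L) stop("no channel_* columns found in ", path)
  ch <- as.matrix(df[, ch_cols, drop = FALSE])
  storage.mode(ch) <- "double"
  meta <- df[, setdiff(names(df), ch_cols), drop = FALSE]
  list(channels = ch, meta = meta)
}
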