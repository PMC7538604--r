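#' Run one odor presentation through the glomerular pipeline
#'
#' A presentation is a single sniff snapshot: ligand drive is sampled by the
#' OSN populations ([glomerular_input()]), optionally degraded by Bernoulli
#' sensor occlusion and plume noise, normalized across columns
#' ([normalize_columns()]), contrast enhanced ([ntce_transform()]), expanded
#' to MTC duplicates (with excitability offsets when `mtc_per_column > 1`),
#' and encoded as gamma phase ([encode_phase()]).
#'
#' @param signature An [make_signature()] object or affinity vector.
#' @param config A [bulb_config()] object.
#' @param occlusion Fraction of sensor channels occluded for this
#'   presentation.
#' @param plume_sigma Plume noise SD for this presentation.
#' @param concentration Presentation concentration; defaults to the
#'   configured scene concentration.
#' @param seed Seed for the occlusion/noise draws (defaults to the config
#'   seed).
#' @param index Substream index distinguishing repeated draws.
#' @param return_stages If `TRUE`, attach all intermediate stage vectors as
#'   attribute `"stages"` (for debugging / stage dumps).
#' @return A `phase_pattern` (integer vector, `NA` = silent).
#' @export
present_odor <- function(signature, config = bulb_config(), occlusion = 0,
                         plume_sigma = 0, concentration = NULL,
                         seed = config$seed, index = 0L,
                         return_stages = FALSE) {
  aff <- if (inherits(signature, "odor_signature")) signature$affinity else
    as.numeric(signature)
  if (is.null(concentration)) concentration <- config$scene$concentration
  osn <- config_osn(config)
  # degradation acts on the sensor scale: occluding channels replaces their
  # activity with random levels drawn from the same [0,1] range the clean
  # channels live on, before the shared concentration gain is applied
  occluded <- apply_bernoulli_occlusion(aff, occlusion, seed, index)
  noisy <- apply_plume_noise(occluded, plume_sigma, seed, index)
  glom <- glomerular_input(noisy, concentration, osn)
  nrm <- normalize_columns(glom, config$glomerular$target_mean,
                           clip = config$glomerular$clip, warn = FALSE)
  if (identical(config$glomerular$drive_gain, "relative")) {
    # peak-referenced gain control: contrast enhancement judges weak /
    # moderate / strong afferent input relative to the most strongly
    # activated column of the ensemble, so the excitation / suppression
    # partition depends on the activation profile, not its absolute scale
    mx <- max(nrm)
    if (mx > 0) nrm <- nrm / mx
  }
  # MTC duplicates sample their column's afferent activation with
  # heterogeneous intrinsic excitability: each duplicate sees the normalized
  # activation shifted by its own offset, so the ensemble reads the contrast-
  # enhancement nonlinearity at several effective thresholds
  d <- config$epl$mtc_per_column
  x <- if (d > 1L) {
    offs <- seq(-config$epl$excitability_spread / 2,
                config$epl$excitability_spread / 2, length.out = d)
    pmin(1, pmax(0, rep(nrm, each = d) + rep(offs, times = length(nrm))))
  } else as.numeric(nrm)
  drv <- ntce_transform(x, config_ntce(config))
  if (identical(config$glomerular$drive_gain, "relative")) {
    # divisive gain control: gamma phase is assigned by relative drive, so
    # the phase code depends on the drive profile, not its absolute scale
    mx <- max(drv)
    if (mx > 0) drv <- drv / mx
  }
  out <- encode_phase(drv, config_gamma(config))
  if (return_stages) {
    attr(out, "stages") <- list(glomerular = glom, occluded = occluded,
                                noisy = noisy, normalized = nrm,
                                mtc_drive = drv)
  }
  out
}

# network constructor wired from a config
config_network <- function(config, n_columns) {
  ew <- config$epl$early_window  # 0 = automatic (bins - 1)
  epl_network(
    n_columns = n_columns,
    mtc_per_column = config$epl$mtc_per_column,
    gc_to_mtc_ratio = config$epl$gc_to_mtc_ratio,
    coincidence_range = c(config$epl$coincidence_min,
                          config$epl$coincidence_max),
    early_window = if (is.null(ew) || is.na(ew[1L]) || ew[1L] <= 0L) NULL else ew,
    excitability_spread = config$epl$excitability_spread,
    lag_tolerance = config$epl$lag_tolerance,
    gamma = config_gamma(config),
    seed = config$seed
  )
}

#' Fit an olfactory bulb model by sequential one-shot learning
#'
#' The central fitting function. Each odor signature is presented once,
#' cleanly (no occlusion, no plume noise), run through the glomerular
#' pipeline, and stored in the EPL attractor network by one-shot spike-timing
#' plasticity ([train_one_shot()]). Training is strictly sequential and
#' online: committed granule cells are frozen, so learning odor k never
#' alters the memory of odors 1..k-1. Before each presentation the naive
#' granule-cell pool is replenished to its configured size by adult
#' neurogenesis, mirroring the constitutive turnover that enables lifelong
#' learning.
#'
#' @param signatures List of [make_signature()] objects (or affinity
#'   vectors), or a numeric matrix with one odor per row.
#' @param labels Character class labels, one per odor; defaults to signature
#'   ids or `odor_01..`.
#' @param config A [bulb_config()] object.
#' @return An object of class `bulb_fit`: list with the trained `network`,
#'   the `config`, the training `signatures`, `labels`, and the clean
#'   encoded `patterns`.
#' @seealso [predict.bulb_fit()], [run_identification_experiment()]
#' @export
#' @examples
#' sigs <- lapply(1:3, function(i)
#'   make_signature(36, 0.5, seed = i, id = paste0("odor_", i)))
#' fit <- bulb_fit(sigs, config = bulb_config(scene = list(n_receptors = 36)))
#' fit
bulb_fit <- function(signatures, labels = NULL, config = bulb_config()) {
  if (is.matrix(signatures)) {
    signatures <- lapply(seq_len(nrow(signatures)),
                         function(i) signatures[i, ])
  }
  if (!is.list(signatures) || length(signatures) == 0L) {
    stop("'signatures' must be a nonempty list or matrix of odors")
  }
  n <- length(affinity_of(signatures[[1L]]))
  if (n != config$scene$n_receptors) {
    stop("signature length ", n, " != configured n_receptors ",
         config$scene$n_receptors)
  }
  if (is.null(labels)) {
    labels <- vapply(seq_along(signatures), function(i) {
      s <- signatures[[i]]
      if (inherits(s, "odor_signature") && s$id != "odor") s$id
      else sprintf("odor_%02d", i)
    }, "")
  }
  if (anyDuplicated(labels)) stop("duplicate class labels")
  net <- config_network(config, n)
  pool_target <- nrow(net$gc)
  patterns <- vector("list", length(signatures))
  for (i in seq_along(signatures)) {
    n_naive <- sum(net$gc$state == "naive")
    if (n_naive < pool_target) {
      net <- neurogenesis_replenish(net, pool_target - n_naive,
                                    seed = config$seed)
    }
    p <- present_odor(signatures[[i]], config)
    net <- train_one_shot(net, p, labels[i])
    patterns[[i]] <- p
  }
  structure(
    list(network = net, config = config, signatures = signatures,
         labels = labels, patterns = patterns),
    class = "bulb_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

affinity_of <- function(s) {
  if (inherits(s, "odor_signature")) s$affinity else as.numeric(s)
}

#' @export
print.bulb_fit <- function(x, ...) {
  cat(sprintf("<bulb_fit>  %d odor class(es) learned one-shot on %d channels\n",
              length(x$labels), x$config$scene$n_receptors))
  print(x$network)
  invisible(x)
}

#' @export
summary.bulb_fit <- function(object, ...) {
  net <- object$network
  spikes <- vapply(object$patterns, function(p) sum(!is.na(p)), 1L)
  out <- list(
    n_classes = length(object$labels),
    labels = object$labels,
    n_columns = net$n_columns,
    mtc_per_column = net$mtc_per_column,
    n_gc = nrow(net$gc),
    n_committed = sum(net$gc$state == "committed"),
    spikes_per_signature = stats::setNames(spikes, object$labels)
  )
  class(out) <- "summary.bulb_fit"
  out
}

#' @export
print.summary.bulb_fit <- function(x, ...) {
  cat(sprintf("Olfactory bulb model: %d classes, %d columns x %d MTC\n",
              x$n_classes, x$n_columns, x$mtc_per_column))
  cat(sprintf("Granule cells: %d total, %d committed\n", x$n_gc, x$n_committed))
  cat("Spiking MTCs per stored signature:\n")
  print(x$spikes_per_signature)
  invisible(x)
}

#' Identify odors with a fitted bulb model
#'
#' Presents each odor under the requested degradation, runs the attractor
#' denoising for the configured number of gamma cycles, and classifies the
#' final pattern against the stored signatures.
#'
#' @param object A [bulb_fit()] object.
#' @param newdata Odors to present: a list of signatures, a numeric matrix
#'   (odor per row), or `NULL` for the training odors.
#' @param occlusion Bernoulli occlusion fraction applied to each
#'   presentation.
#' @param plume_sigma Plume noise SD.
#' @param concentration Presentation concentration (default: training
#'   concentration).
#' @param n_draws Independent degraded presentations per odor.
#' @param seed Seed for the degradation draws (default: config seed).
#' @param true_labels Optional labels to score correctness against; defaults
#'   to the training labels when `newdata` is `NULL`.
#' @param ... Unused.
#' @return data.frame with one row per presentation: `odor`, `draw`,
#'   `label`, `similarity`, `margin`, and `correct` when truth is known.
#' @export
predict.bulb_fit <- function(object, newdata = NULL, occlusion = 0,
                             plume_sigma = 0, concentration = NULL,
                             n_draws = 1L, seed = NULL, true_labels = NULL,
                             ...) {
  if (is.null(newdata)) {
    newdata <- object$signatures
    if (is.null(true_labels)) true_labels <- object$labels
  } else if (is.matrix(newdata)) {
    newdata <- lapply(seq_len(nrow(newdata)), function(i) newdata[i, ])
  }
  if (is.null(seed)) seed <- object$config$seed
  min_sim <- object$config$evaluation$min_similarity
  rows <- vector("list", length(newdata) * n_draws)
  r <- 0L
  for (i in seq_along(newdata)) {
    for (dr in seq_len(n_draws)) {
      idx <- (i - 1L) * n_draws + dr
      p <- present_odor(newdata[[i]], object$config, occlusion = occlusion,
                        plume_sigma = plume_sigma,
                        concentration = concentration,
                        seed = seed, index = idx)
      traj <- denoise(object$network, p)
      res <- classify(object$network, traj, min_similarity = min_sim)
      r <- r + 1L
      rows[[r]] <- data.frame(
        odor = i, draw = dr, label = res$label,
        similarity = res$similarity, margin = res$margin,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(true_labels)) {
    out$truth <- true_labels[out$odor]
    out$correct <- out$label == out$truth
  }
  out
}

#' Simulate degraded presentations from a fitted model
#'
#' Draws occluded / noisy glomerular patterns for each training odor, the
#' same presentations [predict.bulb_fit()] would see before encoding.
#'
#' @param object A [bulb_fit()] object.
#' @param nsim Draws per odor.
#' @param seed Seed for the draws.
#' @param occlusion,plume_sigma Degradation parameters.
#' @param ... Unused.
#' @return Numeric matrix (`length(labels) * nsim` rows) of glomerular
#'   patterns, with columns `channel_*` and attributes `odor` (index) and
#'   `draw`.
#' @export
simulate.bulb_fit <- function(object, nsim = 1L, seed = NULL, occlusion = 0.5,
                              plume_sigma = 0, ...) {
  if (is.null(seed)) seed <- object$config$seed
  cfg <- object$config
  osn <- config_osn(cfg)
  n <- cfg$scene$n_receptors
  out <- matrix(NA_real_, length(object$signatures) * nsim, n,
                dimnames = list(NULL, sprintf("channel_%03d", seq_len(n) - 1L)))
  odor <- integer(nrow(out)); draw <- integer(nrow(out))
  r <- 0L
  for (i in seq_along(object$signatures)) {
    aff <- affinity_of(object$signatures[[i]])
    for (dr in seq_len(nsim)) {
      idx <- (i - 1L) * nsim + dr
      s <- apply_bernoulli_occlusion(aff, occlusion, seed, idx)
      s <- apply_plume_noise(s, plume_sigma, seed, idx)
      g <- glomerular_input(s, cfg$scene$concentration, osn)
      r <- r + 1L
      out[r, ] <- g
      odor[r] <- i; draw[r] <- dr
    }
  }
  attr(out, "odor") <- odor
  attr(out, "draw") <- draw
  out
}

#' Plot stored class signatures as a phase raster
#'
#' Each row is a learned odor class, each column an MTC; cell shade encodes
#' the stored gamma phase bin (dark = early = strongly driven), white =
#' silent.
#'
#' @param x A [bulb_fit()] object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.bulb_fit <- function(x, ...) {
  sigs <- x$network$class_signatures
  bins <- x$network$gamma$bins_per_cycle
  M <- do.call(rbind, sigs)
  Z <- t(M)[, rev(seq_len(nrow(M))), drop = FALSE]
  graphics::image(
    x = seq_len(nrow(Z)), y = seq_len(ncol(Z)), z = Z,
    zlim = c(0, bins - 1), col = grDevices::gray.colors(bins, 0.1, 0.9),
    xlab = "MTC", ylab = "", axes = FALSE,
    main = "Stored odor signatures (gamma phase)", ...
  )
  graphics::axis(1)
  graphics::axis(2, at = seq_len(ncol(Z)), labels = rev(names(sigs)),
                 las = 2, cex.axis = 0.8)
  graphics::box()
  invisible(x)
}
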