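#' Desk-scale odor identification experiment
#'
#' Generates `n_odors` synthetic signatures, trains them sequentially with a
#' single presentation each ([bulb_fit()]), then tests every odor under
#' Bernoulli occlusion with `n_draws` independent draws. An odor counts as
#' reliably identified when at least the criterion fraction of its draws are
#' classified correctly.
#'
#' @param n_odors Number of odor classes (>= 2).
#' @param n_receptors Number of sensor channels N.
#' @param occlusion Occlusion fraction applied at test.
#' @param n_draws Independent occlusion draws per odor.
#' @param config A [bulb_config()] object; `scene$n_receptors` is overridden
#'   by `n_receptors`.
#' @param seed Global seed (overrides the config seed).
#' @param plume_sigma Plume noise SD at test.
#' @param fit Optionally, an existing [bulb_fit()] to reuse instead of
#'   generating and training.
#' @return Object of class `identification_result`: list with `accuracy`
#'   (overall fraction of correct draws), `per_odor` (data.frame with
#'   per-odor accuracy and identification flag), `n_identified`, `fit`, and
#'   the evaluation parameters.
#' @export
run_identification_experiment <- function(n_odors = 10L, n_receptors = 72L,
                                          occlusion = 0.5, n_draws = 20L,
                                          config = bulb_config(),
                                          seed = config$seed,
                                          plume_sigma = 0, fit = NULL) {
  stopifnot(n_odors >= 2)
  config$seed <- as.integer(seed)
  config$scene$n_receptors <- as.integer(n_receptors)
  if (is.null(fit)) {
    sigs <- lapply(seq_len(n_odors), function(i) {
      make_signature(n_receptors, config$scene$sparsity,
                     seed = substream_seed(seed, "signature_batch", i),
                     id = sprintf("odor_%02d", i))
    })
    fit <- bulb_fit(sigs, config = config)
  } else {
    if (fit$config$scene$n_receptors != n_receptors) {
      stop("supplied fit has N = ", fit$config$scene$n_receptors,
           " receptors, expected ", n_receptors)
    }
  }
  pred <- predict(fit, occlusion = occlusion, plume_sigma = plume_sigma,
                  n_draws = n_draws, seed = substream_seed(seed, "test", 0L))
  criterion <- config$evaluation$criterion
  acc <- vapply(seq_along(fit$labels),
                function(i) mean(pred$correct[pred$odor == i]), 1.0)
  per_odor <- data.frame(
    odor = fit$labels,
    accuracy = unname(acc),
    identified = unname(acc) >= criterion,
    stringsAsFactors = FALSE
  )
  structure(
    list(accuracy = mean(pred$correct),
         per_odor = per_odor,
         n_identified = sum(per_odor$identified),
         occlusion = occlusion, n_draws = n_draws, criterion = criterion,
         seed = seed, fit = fit, predictions = pred),
    class = "identification_result"
  )
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf(
    "<identification_result>  occlusion %.0f%%: %d/%d odors identified (overall accuracy %.3f)\n",
    100 * x$occlusion, x$n_identified, nrow(x$per_odor), x$accuracy))
  invisible(x)
}

#' Occlusion tolerance sweep
#'
#' Runs the identification experiment at each occlusion fraction of a grid
#' (reusing one trained network) and reports the largest fraction at which
#' overall identification accuracy stays at or above the criterion.
#'
#' @param grid Strictly increasing occlusion fractions in `[0, 1]`.
#' @inheritParams run_identification_experiment
#' @param criterion Accuracy criterion defining "tolerated".
#' @return Object of class `sweep_result`: data.frame-like list with the
#'   grid, per-fraction overall and per-odor accuracy, and
#'   `tolerated_fraction` (`NA` if no gridpoint reaches criterion).
#' @export
run_occlusion_sweep <- function(grid = seq(0.1, 0.8, by = 0.1),
                                n_odors = 10L, n_receptors = 72L,
                                n_draws = 20L, config = bulb_config(),
                                seed = config$seed, criterion = NULL,
                                fit = NULL) {
  if (length(grid) == 0L || any(grid < 0 | grid > 1)) {
    stop("'grid' must be nonempty with values in [0, 1]")
  }
  if (is.unsorted(grid, strictly = TRUE)) stop("'grid' must be strictly increasing")
  if (is.null(criterion)) criterion <- config$evaluation$criterion
  results <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    results[[i]] <- run_identification_experiment(
      n_odors = n_odors, n_receptors = n_receptors, occlusion = grid[i],
      n_draws = n_draws, config = config, seed = seed, fit = fit
    )
    if (is.null(fit)) fit <- results[[i]]$fit  # train once, reuse
  }
  overall <- vapply(results, function(r) r$accuracy, 1.0)
  ok <- overall >= criterion
  tolerated <- if (any(ok)) max(grid[ok]) else NA_real_
  per_odor <- do.call(rbind, lapply(seq_along(grid), function(i) {
    cbind(occlusion = grid[i], results[[i]]$per_odor)
  }))
  structure(
    list(grid = grid, accuracy = overall, per_odor = per_odor,
         tolerated_fraction = tolerated, criterion = criterion,
         seed = seed, fit = fit),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  print(data.frame(occlusion = x$grid, accuracy = x$accuracy))
  cat(sprintf("largest tolerated fraction (accuracy >= %.2f): %s\n",
              x$criterion,
              ifelse(is.na(x$tolerated_fraction), "none",
                     format(x$tolerated_fraction))))
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  graphics::plot(x$grid, x$accuracy, type = "b", pch = 19, ylim = c(0, 1),
                 xlab = "Bernoulli occlusion fraction",
                 ylab = "Identification accuracy", ...)
  graphics::abline(h = x$criterion, lty = 2)
  if (!is.na(x$tolerated_fraction)) {
    graphics::abline(v = x$tolerated_fraction, lty = 3)
  }
  invisible(x)
}

#' Forgetting curve under sequential training
#'
#' Trains odors in the given order and, after every training step, re-tests
#' the probe odor (which must be trained first) on an identical set of
#' occluded draws. Because committed granule cells are structurally frozen,
#' the attractor's probe accuracy is expected to stay flat — the online-
#' learning guarantee. For contrast, a naive single-template learner that
#' overwrites its running mean template with every newly trained odor is
#' scored on the same schedule and degrades.
#'
#' @param training_order Character vector of labels, probe first.
#' @param probe The probe label (must equal `training_order[1]`).
#' @param n_receptors Channels N.
#' @param occlusion,n_draws Test degradation and draw count.
#' @param config A [bulb_config()] object.
#' @param seed Global seed.
#' @return Object of class `forgetting_curve`: data.frame with one row per
#'   training step: `step`, `trained`, `probe_accuracy` (EPL attractor) and
#'   `template_accuracy` (overwriting baseline), plus attributes.
#' @export
forgetting_curve <- function(training_order, probe = training_order[1L],
                             n_receptors = 72L, occlusion = 0.5,
                             n_draws = 20L, config = bulb_config(),
                             seed = config$seed) {
  if (!identical(probe, training_order[1L])) {
    stop("'probe' must be the first label in 'training_order'")
  }
  config$seed <- as.integer(seed)
  config$scene$n_receptors <- as.integer(n_receptors)
  k <- length(training_order)
  sigs <- lapply(seq_len(k), function(i) {
    make_signature(n_receptors, config$scene$sparsity,
                   seed = substream_seed(seed, "signature_batch", i),
                   id = training_order[i])
  })
  # fixed probe test set: identical occlusion draws re-used at every step
  test_seed <- substream_seed(seed, "probe_test", 0L)
  min_sim <- config$evaluation$min_similarity
  score_probe <- function(fit) {
    pred <- predict(fit, newdata = sigs[1L], occlusion = occlusion,
                    n_draws = n_draws, seed = test_seed,
                    true_labels = probe)
    mean(pred$correct)
  }
  # overwriting baseline: one template = running mean of all trained patterns;
  # probe scored correct when the occluded probe is closer to the template
  # than the template's self-dissimilarity criterion allows. It conflates
  # classes by construction, so probe accuracy decays as odors accumulate.
  template <- NULL
  glom_of <- function(s) glomerular_input(affinity_of(s),
                                          config$scene$concentration,
                                          config_osn(config))
  score_template <- function(trained_gloms) {
    tmpl <- Reduce(`+`, trained_gloms) / length(trained_gloms)
    correct <- vapply(seq_len(n_draws), function(dr) {
      s <- apply_bernoulli_occlusion(affinity_of(sigs[[1L]]), occlusion,
                                     test_seed, dr)
      g <- glomerular_input(s, config$scene$concentration,
                            config_osn(config))
      d_probe <- sqrt(sum((g - trained_gloms[[1L]])^2))
      d_tmpl <- sqrt(sum((g - tmpl)^2))
      d_tmpl <= d_probe  # template must still represent the probe at least
    }, NA)              # as well as the probe's own clean pattern does
    mean(correct)
  }
  steps <- vector("list", k)
  fit <- NULL
  gloms <- list()
  for (i in seq_len(k)) {
    fit <- if (is.null(fit)) {
      bulb_fit(sigs[1L], labels = training_order[1L], config = config)
    } else {
      net <- fit$network
      n_naive <- sum(net$gc$state == "naive")
      pool <- net$gc_to_mtc_ratio * net$n_mtc
      if (n_naive < pool) net <- neurogenesis_replenish(net, pool - n_naive,
                                                        seed = config$seed)
      p <- present_odor(sigs[[i]], config)
      net <- train_one_shot(net, p, training_order[i])
      fit$network <- net
      fit$labels <- c(fit$labels, training_order[i])
      fit$signatures <- c(fit$signatures, sigs[i])
      fit$patterns <- c(fit$patterns, list(p))
      fit
    }
    gloms[[i]] <- glom_of(sigs[[i]])
    steps[[i]] <- data.frame(
      step = i, trained = training_order[i],
      probe_accuracy = score_probe(fit),
      template_accuracy = score_template(gloms),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, steps)
  attr(out, "probe") <- probe
  attr(out, "fit") <- fit
  class(out) <- c("forgetting_curve", "data.frame")
  out
}

#' @export
plot.forgetting_curve <- function(x, ...) {
  graphics::plot(x$step, x$probe_accuracy, type = "b", pch = 19,
                 ylim = c(0, 1), xlab = "Odors trained",
                 ylab = "Probe accuracy", ...)
  graphics::lines(x$step, x$template_accuracy, type = "b", pch = 1, lty = 2)
  graphics::legend("bottomleft", c("EPL attractor", "overwriting template"),
                   pch = c(19, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Nearest-neighbor baseline on raw glomerular patterns
#'
#' 1-nearest-neighbor (Euclidean) classification of test patterns against
#' training patterns — the sanity baseline the attractor network is compared
#' with on identical splits and seeds.
#'
#' @param train_x Numeric matrix of training patterns (row per example).
#' @param train_y Labels for `train_x`.
#' @param test_x Numeric matrix of test patterns.
#' @param test_y Optional true labels; when given, accuracy is returned.
#' @return If `test_y` is `NULL`, the predicted labels; otherwise a list
#'   with `predicted` and `accuracy`.
#' @export
nn_baseline <- function(train_x, train_y, test_x, test_y = NULL) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  stopifnot(ncol(train_x) == ncol(test_x),
            nrow(train_x) == length(train_y))
  pred <- vapply(seq_len(nrow(test_x)), function(i) {
    d2 <- rowSums(sweep(train_x, 2, test_x[i, ])^2)
    train_y[which.min(d2)]
  }, train_y[1L])
  if (is.null(test_y)) return(pred)
  list(predicted = pred, accuracy = mean(pred == test_y))
}
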