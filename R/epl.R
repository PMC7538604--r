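#' Gamma-cycle discretization parameters
#'
#' The external plexiform layer (EPL) computes with spike timing on the gamma
#' timescale. Each presentation is abstracted as a fixed number of discrete
#' gamma cycles; within a cycle a mitral/tufted cell (MTC) either spikes in
#' one of `bins_per_cycle` phase bins (earlier = more strongly driven) or is
#' silent. Only MTCs driven above `spike_threshold` participate in the
#' coherent gamma dynamics at all.
#'
#' @param bins_per_cycle Number of phase bins per gamma cycle (>= 2).
#' @param cycles_per_presentation Gamma cycles simulated per sniff (>= 1).
#' @param spike_threshold Minimum MTC drive theta in (0, 1) for
#'   participation; NTCE-inhibited (negative) drives are always silent.
#' @return An object of class `gamma_params`.
#' @export
gamma_params <- function(bins_per_cycle = 8L, cycles_per_presentation = 5L,
                         spike_threshold = 0.1) {
  stopifnot(bins_per_cycle >= 2, cycles_per_presentation >= 1,
            spike_threshold > 0, spike_threshold < 1)
  structure(
    list(bins_per_cycle = as.integer(bins_per_cycle),
         cycles_per_presentation = as.integer(cycles_per_presentation),
         spike_threshold = spike_threshold),
    class = "gamma_params"
  )
}

#' Encode MTC drive as gamma phase
#'
#' Strongly driven MTCs escape the periodic inhibition earliest in each gamma
#' cycle, so drive maps monotonically to phase lead: bin
#' `floor((1 - drive) / (1 - theta) * bins)`, clamped to
#' `[0, bins - 1]`. Drives at or below `theta` (including all negative,
#' NTCE-suppressed drives) do not participate and are encoded `NA` (silent).
#'
#' @param mtc_drive Signed numeric drive vector (one entry per MTC).
#' @param gamma A [gamma_params()] object.
#' @return Integer phase-bin vector; `NA` = silent. Class `phase_pattern`.
#' @export
#' @examples
#' encode_phase(c(1.0, 0.55, 0.05, -0.3), gamma_params())
encode_phase <- function(mtc_drive, gamma = gamma_params()) {
  stopifnot(all(is.finite(mtc_drive)))
  theta <- gamma$spike_threshold
  bins <- gamma$bins_per_cycle
  # epsilon guards against floating-point underflow at exact bin boundaries
  bin <- floor((1 - mtc_drive) / (1 - theta) * bins + 1e-9)
  bin <- pmax(0, pmin(bins - 1L, bin))
  bin[mtc_drive <= theta] <- NA
  structure(as.integer(bin), class = "phase_pattern")
}

# draw heterogeneous GC parameters for n cells
draw_gc_pool <- function(n, columns, k_range, window_range, seed, index = 0L) {
  with_substream(seed, "gc_pool", index, {
    ks <- seq.int(k_range[1L], k_range[2L])
    k <- if (length(ks) == 1L) rep.int(ks, n) else sample(ks, n, replace = TRUE)
    ws <- seq.int(window_range[1L], window_range[2L])
    w <- if (length(ws) == 1L) rep.int(ws, n) else sample(ws, n, replace = TRUE)
    data.frame(
      column = rep_len(columns, n),
      k = as.integer(k),
      window = as.integer(w),
      state = rep.int("naive", n),
      class = rep.int(NA_character_, n),
      w_pot = rep.int(NA_real_, n),
      stringsAsFactors = FALSE
    )
  })
}

#' Construct an EPL attractor network
#'
#' The network holds, per glomerular column, `mtc_per_column` principal
#' neurons (duplicated MTCs with heterogeneous excitability offsets when
#' > 1) and a pool of granule cells (GCs). MTC excitation of GCs is
#' topologically unrestricted (lateral dendrites propagate spikes broadly),
#' whereas each GC can inhibit only the MTCs of its assigned column(s) — the
#' column-centric, non-reciprocal topology of the EPL. GCs are born naive
#' with heterogeneous coincidence thresholds and are permanently committed to
#' an odor class when recruited during learning; the pool is replenished by
#' adult neurogenesis ([neurogenesis_replenish()]).
#'
#' @param n_columns Number of glomerular columns N (= receptor types).
#' @param mtc_per_column MTC duplicates per column (default 1).
#' @param gc_to_mtc_ratio Naive GC pool size as a multiple of the MTC count
#'   (default 25, the approximate anatomical ratio).
#' @param coincidence_range Integer range (inclusive) from which GC
#'   coincidence thresholds are drawn uniformly; heterogeneity makes some GCs
#'   highly selective and others broadly tuned.
#' @param early_window Number of leading phase bins that count as
#'   "coincident early spikes" for GC activation; default `bins - 1`, i.e.
#'   every bin except the last (weakest participants are excluded).
#'   May be a length-2 range for heterogeneous windows.
#' @param excitability_spread Total spread of additive drive offsets across
#'   MTC duplicates within a column (used only when `mtc_per_column > 1`).
#' @param lag_tolerance Number of phase bins a spike may lag behind its
#'   stored bin and still be treated as consistent with a class, both by the
#'   recall dynamics (veto) and by the similarity readout. Inhibition can
#'   only delay spikes, so interference lags surviving member spikes; spikes
#'   earlier than the stored bin are themselves delayed back onto it cycle by
#'   cycle, while spikes lagging beyond the tolerance are treated as spurious.
#' @param gamma A [gamma_params()] object.
#' @param seed Seed for the heterogeneity draws.
#' @return An object of class `epl_network`.
#' @export
epl_network <- function(n_columns, mtc_per_column = 1L, gc_to_mtc_ratio = 25,
                        coincidence_range = c(3L, 6L), early_window = NULL,
                        excitability_spread = 0.1, lag_tolerance = 2L,
                        gamma = gamma_params(), seed = 0L) {
  stopifnot(n_columns >= 1, mtc_per_column >= 1, gc_to_mtc_ratio >= 1,
            length(coincidence_range) == 2L,
            coincidence_range[1L] >= 2L,
            coincidence_range[2L] >= coincidence_range[1L])
  bins <- gamma$bins_per_cycle
  if (is.null(early_window)) early_window <- bins - 1L
  if (length(early_window) == 1L) early_window <- rep(early_window, 2L)
  stopifnot(early_window[1L] >= 1L, early_window[2L] <= bins)
  d <- as.integer(mtc_per_column)
  n_mtc <- as.integer(n_columns) * d
  n_gc <- as.integer(round(gc_to_mtc_ratio * n_mtc))
  gc <- draw_gc_pool(n_gc, seq_len(n_columns), coincidence_range,
                     as.integer(early_window), seed, index = 0L)
  offsets <- if (d == 1L) 0 else {
    seq(-excitability_spread / 2, excitability_spread / 2, length.out = d)
  }
  structure(
    list(
      n_columns = as.integer(n_columns),
      mtc_per_column = d,
      n_mtc = n_mtc,
      col_of_mtc = rep(seq_len(n_columns), each = d),
      excitability_offsets = offsets,
      gc_to_mtc_ratio = gc_to_mtc_ratio,
      coincidence_range = as.integer(coincidence_range),
      early_window = as.integer(early_window),
      lag_tolerance = as.integer(lag_tolerance),
      gamma = gamma,
      seed = as.integer(seed),
      replenish_count = 0L,
      gc = gc,
      w_exc = matrix(0, n_gc, n_mtc),
      w_inh = matrix(0, n_gc, n_mtc),
      class_signatures = list(),
      version = "1.0.0"
    ),
    class = "epl_network"
  )
}

#' @export
print.epl_network <- function(x, ...) {
  cat(sprintf(
    paste0("<epl_network>  %d columns x %d MTC/column; %d GCs ",
           "(%d committed, %d naive); %d learned class(es)\n"),
    x$n_columns, x$mtc_per_column, nrow(x$gc),
    sum(x$gc$state == "committed"), sum(x$gc$state == "naive"),
    length(x$class_signatures)
  ))
  if (length(x$class_signatures)) {
    cat("  classes:", paste(names(x$class_signatures), collapse = ", "), "\n")
  }
  invisible(x)
}

#' One-shot odor learning
#'
#' Stores one clean phase pattern as a new odor class in a single
#' presentation, by the fixed-point consequence of asymmetric spike-timing-
#' dependent plasticity: (a) every naive GC whose early window captures at
#' least its coincidence threshold of spiking MTCs is recruited and
#' permanently committed to the class; (b) excitatory synapses from MTCs
#' that spiked within the window are potentiated to `w_pot` and all others
#' depressed to 0; (c) inhibitory synapses from each recruited GC onto the
#' MTCs of its column are enabled, so that during recall the GC delays
#' target-column spikes inconsistent with the learned pattern while sparing
#' consistent ones; (d) the clean pattern is stored as the class signature.
#' Weights of previously committed GCs are never touched — learning is
#' strictly online and earlier memories are structurally frozen.
#'
#' @param state An [epl_network()] object.
#' @param clean_pattern Phase pattern from [encode_phase()] (integer vector,
#'   `NA` = silent), length `n_mtc`.
#' @param label Class label (must not already be trained).
#' @param force If the label is already trained with an identical signature,
#'   return the state unchanged instead of erroring (retraining recruits no
#'   additional GCs); retraining with a different pattern is always an error.
#' @param w_pot Potentiated excitatory weight value.
#' @return The updated `epl_network`.
#' @export
train_one_shot <- function(state, clean_pattern, label, force = FALSE,
                           w_pot = 1) {
  stopifnot(inherits(state, "epl_network"))
  p <- as.integer(clean_pattern)
  if (length(p) != state$n_mtc) {
    stop("pattern length ", length(p), " != network MTC count ", state$n_mtc)
  }
  if (label %in% names(state$class_signatures)) {
    if (force && identical(state$class_signatures[[label]], p)) {
      return(state)  # already stored; nothing to recruit
    }
    stop("class '", label, "' is already trained; committed memories are immutable")
  }
  naive <- which(state$gc$state == "naive")
  if (length(naive) == 0L) {
    stop(structure(
      class = c("epl_pool_exhausted", "error", "condition"),
      list(message = "naive granule-cell pool exhausted; call neurogenesis_replenish()",
           call = sys.call())
    ))
  }
  spike <- !is.na(p)
  # early-spike count seen through each naive GC's window
  n_early <- vapply(state$gc$window[naive],
                    function(w) sum(spike & p < w), 1L)
  recruited <- naive[n_early >= state$gc$k[naive]]
  if (length(recruited) == 0L) {
    stop(structure(
      class = c("epl_no_recruits", "epl_pool_exhausted", "error", "condition"),
      list(message = paste0(
        "no naive granule cell reached coincidence on this pattern; ",
        "replenish the pool or lower coincidence thresholds"),
        call = sys.call())
    ))
  }
  for (g in recruited) {
    members <- spike & p < state$gc$window[g]
    state$w_exc[g, ] <- 0
    state$w_exc[g, members] <- w_pot
    targets <- state$col_of_mtc == state$gc$column[g]
    state$w_inh[g, ] <- 0
    state$w_inh[g, targets] <- 1
  }
  state$gc$state[recruited] <- "committed"
  state$gc$class[recruited] <- label
  state$gc$w_pot[recruited] <- w_pot
  state$class_signatures[[label]] <- p
  state
}

#' Replenish the naive granule-cell pool (adult neurogenesis)
#'
#' Recruitment permanently differentiates GCs, so lifelong learning requires
#' constitutive replacement: `n_new` naive GCs are appended with coincidence
#' thresholds and windows drawn from the network's configured heterogeneity
#' distributions. Committed GCs and their weights are untouched.
#'
#' @param state An [epl_network()] object.
#' @param n_new Number of naive GCs to append (>= 0).
#' @param seed Seed for the heterogeneity draws.
#' @return The updated `epl_network` with exactly `n_new` more GCs.
#' @export
neurogenesis_replenish <- function(state, n_new, seed = state$seed) {
  stopifnot(inherits(state, "epl_network"), n_new >= 0)
  n_new <- as.integer(n_new)
  if (n_new == 0L) return(state)
  state$replenish_count <- state$replenish_count + 1L
  newgc <- draw_gc_pool(n_new, seq_len(state$n_columns),
                        state$coincidence_range, state$early_window,
                        seed, index = state$replenish_count)
  state$gc <- rbind(state$gc, newgc)
  state$w_exc <- rbind(state$w_exc, matrix(0, n_new, state$n_mtc))
  state$w_inh <- rbind(state$w_inh, matrix(0, n_new, state$n_mtc))
  state
}

# committed-GC firing vector for the current pattern. STDP potentiated each
# MTC->GC synapse at the phase the MTC spiked during learning, so a GC's
# receptive field is configural in time: a potentiated input only counts as
# coincident evidence when it spikes within lag_tolerance bins of its stored
# phase (earlier spikes count too - recurrent inhibition will delay them back
# onto the stored bin).
gc_fired <- function(state, p) {
  fired <- logical(nrow(state$gc))
  committed <- state$gc$state == "committed"
  if (!any(committed)) return(fired)
  tol <- state$lag_tolerance
  for (lb in names(state$class_signatures)) {
    idx <- which(committed & state$gc$class == lb)
    if (length(idx) == 0L) next
    s <- state$class_signatures[[lb]]
    cons <- as.numeric(!is.na(p) & !is.na(s) & abs(p - s) <= tol)
    cnt <- as.numeric(((state$w_exc[idx, , drop = FALSE] > 0) + 0) %*% cons)
    fired[idx] <- cnt >= state$gc$k[idx]
  }
  fired
}

# evidence each learned class has in the current pattern: the fraction of its
# signature spikes reproduced within the lag tolerance (either side; early
# spikes will be delayed back onto the stored bin). Normalizing by signature
# size keeps sparse and dense odor representations on an equal footing.
class_evidence <- function(state, p) {
  tol <- state$lag_tolerance
  vapply(state$class_signatures, function(s) {
    n_sig <- sum(!is.na(s))
    if (n_sig == 0L) return(0)
    sum(!is.na(p) & !is.na(s) & abs(p - s) <= tol) / n_sig
  }, 1.0)
}

#' Iterative attractor denoising over gamma cycles
#'
#' On each gamma cycle, (1) committed GCs fire if at least their coincidence
#' threshold of potentiated MTC inputs spike within their early window;
#' (2) each firing GC delays, by one phase bin, those spikes of its target
#' column's MTCs that are inconsistent with its class signature
#' (inhibition-imposed phase lag), silencing spikes pushed past the last
#' bin, while vetoing any delay of spikes that match its signature;
#' (3) repeat. Spurious spikes are thus progressively pushed later and
#' extinguished while learned-pattern spikes are protected, so the activity
#' pattern descends toward the stored fixed point of the best-matching class.
#'
#' @param state A trained [epl_network()].
#' @param noisy_pattern Phase pattern (integer vector, `NA` = silent).
#' @param gamma Optional [gamma_params()] override (cycle count is taken
#'   from it).
#' @return List of phase patterns, one per cycle (the trajectory).
#' @export
denoise <- function(state, noisy_pattern, gamma = state$gamma) {
  stopifnot(inherits(state, "epl_network"))
  if (length(state$class_signatures) == 0L) {
    stop("network has no trained classes; nothing to denoise toward")
  }
  p <- as.integer(noisy_pattern)
  if (length(p) != state$n_mtc) {
    stop("pattern length ", length(p), " != network MTC count ", state$n_mtc)
  }
  bins <- gamma$bins_per_cycle
  labels <- names(state$class_signatures)
  S <- do.call(rbind, state$class_signatures)  # n_classes x n_mtc
  cls_idx <- match(state$gc$class, labels)
  trajectory <- vector("list", gamma$cycles_per_presentation)
  tol <- state$lag_tolerance
  for (cyc in seq_len(gamma$cycles_per_presentation)) {
    fired <- gc_fired(state, p)
    fg <- which(fired)
    if (length(fg)) {
      # a spike is consistent with a class when it sits at the stored bin or
      # lags it by at most lag_tolerance bins (recurrent inhibition can only
      # delay); spikes earlier than the stored bin are delayed back onto it.
      # A firing GC delays inconsistent spikes in its column and vetoes any
      # delay of consistent ones; protection wins over delay, so a learned
      # assembly shields its own member spikes from cross-class inhibition.
      fired_cc <- matrix(FALSE, length(labels), state$n_columns)
      fired_cc[cbind(cls_idx[fg], state$gc$column[fg])] <- TRUE
      covered <- fired_cc[, state$col_of_mtc, drop = FALSE]  # class x mtc
      P <- matrix(p, nrow(S), ncol(S), byrow = TRUE)
      match_sig <- !is.na(S) & P >= S & P <= S + tol
      match_sig[is.na(match_sig)] <- FALSE
      veto <- colSums(covered & match_sig) > 0
      delay <- colSums(covered & !match_sig) > 0
      shift <- !is.na(p) & delay & !veto
      p[shift] <- p[shift] + 1L
      p[!is.na(p) & p > bins - 1L] <- NA
    }
    trajectory[[cyc]] <- structure(p, class = "phase_pattern")
  }
  trajectory
}

#' Classify a denoised trajectory
#'
#' The readout statistic is per-class similarity: the fraction of MTCs whose
#' final-cycle state (phase bin or silent) is consistent with the stored
#' class signature — silent where it is silent, or spiking at the stored bin
#' (up to the network's lag tolerance later, since recurrent inhibition can
#' only delay spikes). The best class is returned if its similarity reaches
#' `min_similarity`, else `"UNKNOWN"`. Ties are broken toward the
#' lexicographically lowest label.
#'
#' @param state A trained [epl_network()].
#' @param trajectory Nonempty list of phase patterns (from [denoise()]), or a
#'   single phase pattern.
#' @param min_similarity Acceptance threshold in `[0, 1]`.
#' @return List of class `epl_classification` with `label`, `similarity`,
#'   `margin` (top1 - top2 similarity; 0 when a single class is trained),
#'   and `per_class` (named similarity vector).
#' @export
classify <- function(state, trajectory, min_similarity = 0.5) {
  stopifnot(inherits(state, "epl_network"))
  if (is.list(trajectory)) {
    if (length(trajectory) == 0L) stop("'trajectory' must be nonempty")
    final <- as.integer(trajectory[[length(trajectory)]])
  } else {
    final <- as.integer(trajectory)
  }
  labels <- sort(names(state$class_signatures))
  tol <- state$lag_tolerance
  sims <- vapply(labels, function(lb) {
    sig <- state$class_signatures[[lb]]
    mean((is.na(final) & is.na(sig)) |
           (!is.na(final) & !is.na(sig) &
              final >= sig & final <= sig + tol))
  }, 1.0)
  best <- which.max(sims)  # first max = lexicographically lowest label
  margin <- if (length(sims) > 1L) {
    sims[best] - max(sims[-best])
  } else 0
  structure(
    list(label = if (sims[best] >= min_similarity) labels[best] else "UNKNOWN",
         similarity = unname(sims[best]),
         margin = unname(margin),
         per_class = sims),
    class = "epl_classification"
  )
}

#' @export
print.epl_classification <- function(x, ...) {
  cat(sprintf("<classification>  label = %s (similarity %.3f, margin %.3f)\n",
              x$label, x$similarity, x$margin))
  invisible(x)
}

#' Hamming distance between phase patterns
#'
#' Number of MTCs whose state (phase bin or silent) differs between two
#' patterns; the convergence metric of the attractor dynamics.
#'
#' @param a,b Phase patterns of equal length.
#' @return Integer count of differing positions.
#' @export
phase_hamming <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  stopifnot(length(a) == length(b))
  sum(!((is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)))
}
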