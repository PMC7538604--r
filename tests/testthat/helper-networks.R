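# Shared fixtures: tiny trained networks and an independent brute-force
# implementation of the recall update rule (naive loops over GCs and MTCs),
# used as the oracle for attractor-equivalence tests.

toy_gamma <- function(cycles = 4L) gamma_params(bins_per_cycle = 4L,
                                                cycles_per_presentation = cycles,
                                                spike_threshold = 0.1)

# 4-column, 4-bin toy net trained on two hand-written phase patterns
make_toy_net <- function(lag_tolerance = 1L, seed = 7L) {
  net <- epl_network(
    n_columns = 4L, gc_to_mtc_ratio = 5, coincidence_range = c(2L, 3L),
    lag_tolerance = lag_tolerance, gamma = toy_gamma(), seed = seed
  )
  net <- train_one_shot(net, c(0L, 1L, 2L, NA), "A")
  net <- neurogenesis_replenish(net, 20L, seed = seed + 1L)
  net <- train_one_shot(net, c(NA, 2L, 0L, 1L), "B")
  net
}

# independent oracle: same update rule, coded as explicit per-GC / per-MTC
# loops reading only the network's weight matrices and signatures
brute_force_denoise <- function(net, p, cycles = net$gamma$cycles_per_presentation) {
  bins <- net$gamma$bins_per_cycle
  tol <- net$lag_tolerance
  p <- as.integer(p)
  out <- vector("list", cycles)
  for (cyc in seq_len(cycles)) {
    fired <- rep(FALSE, nrow(net$gc))
    for (g in seq_len(nrow(net$gc))) {
      if (net$gc$state[g] != "committed") next
      s <- net$class_signatures[[net$gc$class[g]]]
      cnt <- 0L
      for (m in seq_len(net$n_mtc)) {
        if (net$w_exc[g, m] > 0 && !is.na(p[m]) && !is.na(s[m]) &&
            abs(p[m] - s[m]) <= tol) {
          cnt <- cnt + 1L
        }
      }
      if (cnt >= net$gc$k[g]) fired[g] <- TRUE
    }
    newp <- p
    for (m in seq_len(net$n_mtc)) {
      if (is.na(p[m])) next
      veto <- FALSE
      delay <- FALSE
      for (g in which(fired)) {
        if (net$w_inh[g, m] <= 0) next
        s <- net$class_signatures[[net$gc$class[g]]]
        consistent <- !is.na(s[m]) && p[m] >= s[m] && p[m] <= s[m] + tol
        if (consistent) veto <- TRUE else delay <- TRUE
      }
      if (delay && !veto) {
        newp[m] <- p[m] + 1L
        if (newp[m] > bins - 1L) newp[m] <- NA_integer_
      }
    }
    p <- newp
    out[[cyc]] <- p
  }
  out
}

# all phase patterns of length n over {0..bins-1, NA}
enumerate_patterns <- function(n, bins) {
  states <- c(NA_integer_, seq.int(0L, bins - 1L))
  grid <- do.call(expand.grid, rep(list(states), n))
  lapply(seq_len(nrow(grid)), function(i) as.integer(unlist(grid[i, ])))
}

# standard 10-odor batch used across evaluation tests
ten_signatures <- function(n_receptors = 72L, seed = 42L) {
  lapply(1:10, function(i) {
    make_signature(n_receptors, 0.5,
                   seed = substream_seed(seed, "signature_batch", i),
                   id = sprintf("odor_%02d", i))
  })
}
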