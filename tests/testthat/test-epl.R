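test_that("phase encoding maps drive to bins monotonically with silence below threshold", {
  g <- gamma_params(bins_per_cycle = 8, spike_threshold = 0.1)
  enc <- encode_phase(c(1.0, 0.55, 0.05, -0.3, 0.1), g)
  expect_identical(as.integer(enc), c(0L, 4L, NA, NA, NA))
  # stronger drive never spikes later
  drives <- seq(0.11, 1, by = 0.01)
  bins <- as.integer(encode_phase(drives, g))
  expect_true(all(diff(bins) <= 0))
  expect_true(all(bins >= 0 & bins <= 7))
  # just above threshold lands in the last bin
  expect_identical(as.integer(encode_phase(0.100001, g)), 7L)
})

test_that("one-shot training recruits exactly the coincidence-reaching naive GCs and freezes them", {
  # 4-column toy, 4 bins, pattern with 3 early spikes; pool has k = 3 and
  # heterogeneous windows 1..4: exactly the GCs whose window spans all three
  # spikes (window > 2, i.e. 3 or 4) commit
  net <- epl_network(4, gc_to_mtc_ratio = 4, coincidence_range = c(3L, 3L),
                     early_window = c(1L, 4L), gamma = toy_gamma(), seed = 2)
  pat <- c(0L, 1L, 2L, NA)
  trained <- train_one_shot(net, pat, "A")
  committed <- trained$gc$state == "committed"
  expect_identical(committed, net$gc$window >= 3L)
  expect_true(all(trained$gc$class[committed] == "A"))
  expect_identical(trained$class_signatures$A, pat)
  # potentiated synapses exactly from the window-captured spiking MTCs
  for (g in which(committed)) {
    members <- which(!is.na(pat) & pat < trained$gc$window[g])
    expect_identical(which(trained$w_exc[g, ] > 0), members)
  }
  # duplicate label is an error; force with the same pattern is a no-op
  expect_error(train_one_shot(trained, pat, "A"), "immutable")
  expect_identical(train_one_shot(trained, pat, "A", force = TRUE), trained)
})

test_that("training a second odor leaves the first class bitwise untouched", {
  net <- make_toy_net()
  before <- train_one_shot(
    epl_network(4, gc_to_mtc_ratio = 5, coincidence_range = c(2L, 3L),
                lag_tolerance = 1L, gamma = toy_gamma(), seed = 7),
    c(0L, 1L, 2L, NA), "A")
  gA <- which(before$gc$state == "committed")
  expect_identical(net$class_signatures$A, before$class_signatures$A)
  expect_identical(net$w_exc[gA, ], before$w_exc[gA, ])
  expect_identical(net$w_inh[gA, ], before$w_inh[gA, ])
  expect_identical(net$gc[gA, ], before$gc[gA, ])
})

test_that("inhibitory weights respect the columnar topology after every training step", {
  net <- make_toy_net()
  for (g in which(net$gc$state == "committed")) {
    targets <- which(net$w_inh[g, ] > 0)
    expect_identical(unique(net$col_of_mtc[targets]), net$gc$column[g])
  }
  # naive GCs have no weights at all
  naive <- net$gc$state == "naive"
  expect_true(all(net$w_exc[naive, ] == 0))
  expect_true(all(net$w_inh[naive, ] == 0))
})

test_that("an exhausted or unreachable naive pool raises a typed condition", {
  net <- epl_network(4, gc_to_mtc_ratio = 2, coincidence_range = c(3L, 3L),
                     gamma = toy_gamma(), seed = 1)
  # pattern with too few early spikes: nothing can reach coincidence
  expect_error(train_one_shot(net, c(0L, NA, NA, NA), "A"),
               class = "epl_pool_exhausted")
  trained <- train_one_shot(net, c(0L, 1L, 2L, NA), "A")
  expect_error(train_one_shot(trained, c(1L, 0L, NA, 2L), "B"),
               class = "epl_pool_exhausted")
})

test_that("neurogenesis appends naive heterogeneous GCs without touching memories", {
  net <- make_toy_net()
  expect_identical(neurogenesis_replenish(net, 0), net)
  big <- neurogenesis_replenish(net, 100, seed = 9)
  expect_equal(nrow(big$gc), nrow(net$gc) + 100)
  expect_equal(sum(big$gc$state == "naive"), sum(net$gc$state == "naive") + 100)
  expect_identical(big$class_signatures, net$class_signatures)
  expect_identical(big$w_exc[seq_len(nrow(net$gc)), ], net$w_exc)
  # heterogeneity: thresholds span at least 2 distinct values over 100 draws
  newk <- utils::tail(big$gc$k, 100)
  expect_gte(length(unique(newk)), 2)
  expect_true(all(newk >= 2))
})

test_that("stored signatures are fixed points and silence is absorbing", {
  net <- make_toy_net()
  for (lb in names(net$class_signatures)) {
    traj <- denoise(net, net$class_signatures[[lb]])
    expect_identical(as.integer(traj[[1]]), net$class_signatures[[lb]])
    expect_identical(as.integer(traj[[length(traj)]]),
                     net$class_signatures[[lb]])
  }
  all_silent <- rep(NA_integer_, 4)
  traj <- denoise(net, all_silent)
  for (p in traj) expect_identical(as.integer(p), all_silent)
  expect_error(denoise(epl_network(4, gamma = toy_gamma()), all_silent),
               "no trained classes")
})

test_that("a spurious extra spike is delayed each cycle and silenced", {
  # hand-traced: one trained odor A = (0,1,2,silent); inject a spike at bin 0
  # in the silent column. A's GCs fire (all three members at their stored
  # bins); the intruder mismatches the signature so it is delayed one bin per
  # cycle, 0 -> 1 -> 2 -> 3 -> silent, while member spikes are vetoed in place.
  net <- epl_network(4, gc_to_mtc_ratio = 5, coincidence_range = c(2L, 3L),
                     lag_tolerance = 1L, gamma = toy_gamma(), seed = 7)
  net <- train_one_shot(net, c(0L, 1L, 2L, NA), "A")
  traj <- denoise(net, c(0L, 1L, 2L, 0L))
  expect_identical(as.integer(traj[[1]]), c(0L, 1L, 2L, 1L))
  expect_identical(as.integer(traj[[2]]), c(0L, 1L, 2L, 2L))
  expect_identical(as.integer(traj[[3]]), c(0L, 1L, 2L, 3L))
  expect_identical(as.integer(traj[[4]]), c(0L, 1L, 2L, NA))
})

test_that("classification returns per-class match fractions, margins, and UNKNOWN", {
  # tiny 2-class, 8-MTC readout check: final pattern matches A on 7/8 MTCs
  # (one A-spike missing) and B on 2/8; mismatches are spike-vs-silent so the
  # lag window cannot blur them
  net <- epl_network(8, gc_to_mtc_ratio = 4, coincidence_range = c(2L, 2L),
                     gamma = gamma_params(8, 5, 0.1), seed = 3)
  sigA <- c(0L, 1L, 2L, 3L, 4L, NA, NA, NA)
  sigB <- c(5L, 6L, NA, 3L, 0L, 5L, NA, 0L)
  net <- train_one_shot(net, sigA, "A")
  net <- neurogenesis_replenish(net, 32, seed = 4)
  net <- train_one_shot(net, sigB, "B")
  # hand count: final matches A at positions 1-4 plus silents 6-8 (7/8, one
  # A spike missing); it matches B only at position 4 and the silent 7 (2/8)
  final <- c(0L, 1L, 2L, 3L, NA, NA, NA, NA)
  res <- classify(net, list(final))
  expect_identical(res$label, "A")
  expect_equal(res$similarity, 7 / 8)
  expect_equal(unname(res$per_class["B"]), 2 / 8)
  expect_equal(res$margin, 7 / 8 - 2 / 8)
  # all-silent pattern vs non-silent signatures fails the acceptance bar
  silent <- rep(NA_integer_, 8)
  expect_identical(classify(net, list(silent), min_similarity = 0.5)$label,
                   "UNKNOWN")
  # single-class network has zero margin by definition
  one <- train_one_shot(
    epl_network(8, gc_to_mtc_ratio = 4, coincidence_range = c(2L, 2L),
                gamma = gamma_params(8, 5, 0.1), seed = 3), sigA, "A")
  expect_equal(classify(one, list(sigA))$margin, 0)
})

test_that("phase hamming distance counts differing states including silence", {
  expect_equal(phase_hamming(c(0L, 1L, NA), c(0L, 1L, NA)), 0)
  expect_equal(phase_hamming(c(0L, 1L, NA), c(0L, 2L, 3L)), 2)
  expect_equal(phase_hamming(c(NA, NA), c(0L, NA)), 1)
})
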