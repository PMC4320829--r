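test_that("generator is deterministic and honours degenerate parameters", {
  p <- train_params(burst_rate = 8, background_rate = 0.2)
  a <- generate_train(p, 300, seed = 5)
  b <- generate_train(p, 300, seed = 5)
  expect_identical(a$times, b$times)
  expect_true(all(diff(a$times) > 0))
  expect_true(all(a$times >= 0 & a$times <= 300))

  # no sources -> empty train
  silent <- generate_train(train_params(background_rate = 0, burst_rate = 0),
                           300, seed = 1)
  expect_equal(n_spikes(silent), 0)

  expect_error(train_params(burst_rate = -1), ">= 0")
  expect_error(network_params(participation_p = 1.5), "participation_p")
  expect_error(network_params(shared_fraction = -0.1), "shared_fraction")
})

test_that("whole recordings are reproducible and stable under electrode count", {
  np <- network_params(n_electrodes = 6, duration = 60, seed = 9)
  r1 <- generate_recording(train_params(), np)
  r2 <- generate_recording(train_params(), np)
  expect_identical(lapply(r1$trains, `[[`, "times"),
                   lapply(r2$trains, `[[`, "times"))
  # fixed per-electrode seed splitting: growing the array leaves the
  # private component of earlier electrodes alone (checked with no sharing)
  np0 <- network_params(n_electrodes = 4, duration = 60,
                        shared_fraction = 0, seed = 9)
  np1 <- network_params(n_electrodes = 8, duration = 60,
                        shared_fraction = 0, seed = 9)
  a <- generate_recording(train_params(), np0)
  b <- generate_recording(train_params(), np1)
  for (i in 1:4)
    expect_identical(a$trains[[i]]$times, b$trains[[i]]$times)
})

test_that("detected burst rate recovers the generator setting (20 seeds)", {
  p <- train_params(burst_rate = 10, background_rate = 0.1,
                    spikes_per_burst = 10, within_burst_rate = 60)
  rates <- vapply(1:20, function(s) {
    st <- generate_train(p, 900, seed = s)
    burst_statistics(st, detect_bursts(st, burst_params()))$burst_rate
  }, numeric(1))
  expect_lt(abs(mean(rates) - 10) / 10, 0.2)
})

test_that("ibi_cv knob moves the measured CV of IBI monotonically", {
  cv_of <- function(cv, s) {
    p <- train_params(burst_rate = 10, ibi_cv = cv, background_rate = 0)
    st <- generate_train(p, 900, seed = s)
    burst_statistics(st, detect_bursts(st, burst_params()))$cv_ibi
  }
  for (s in 1:5) expect_lt(cv_of(0.1, s), cv_of(1.0, s))
})

test_that("shared_fraction controls pairwise correlation as designed", {
  mean_sttc <- function(sf, pp, jit, s) {
    tp <- train_params(burst_rate = 10, background_rate = 0.1,
                       spikes_per_burst = 12, within_burst_rate = 100,
                       jitter_sd = jit)
    np <- network_params(n_electrodes = 8, duration = 300,
                         shared_fraction = sf, participation_p = pp,
                         seed = s)
    mean_correlation(pairwise_correlations(generate_recording(tp, np)))
  }
  # independence: mean STTC near 0
  indep <- vapply(1:5, function(s) mean_sttc(0, 1, 0.005, s), numeric(1))
  expect_lt(abs(mean(indep)), 0.05)
  # full sharing with 1 ms jitter: strongly tiled
  shared <- vapply(1:5, function(s) mean_sttc(1, 1, 0.001, s), numeric(1))
  expect_true(all(shared > 0.5))
  expect_gt(mean(shared), mean(indep))
})

test_that("fully participating shared bursts yield network spikes", {
  tp <- train_params(burst_rate = 10, spikes_per_burst = 12,
                     within_burst_rate = 100, jitter_sd = 0.0005)
  np <- network_params(n_electrodes = 59, duration = 120,
                       shared_fraction = 1, participation_p = 1, seed = 2)
  rec <- generate_recording(tp, np)
  ns <- detect_network_spikes(count_active(rec, 0.003), threshold = 10)
  expect_gt(network_spike_summary(ns, duration(rec))$ns_rate, 0)
})

test_that("presets encode the documented region contrasts", {
  for (div in c(7, 14, 21, 28)) {
    hpc <- preset_profile("HPC", div)
    ctx <- preset_profile("CTX", div)
    expect_lt(hpc$train$ibi_cv, ctx$train$ibi_cv)
    expect_gt(hpc$network$shared_fraction, ctx$network$shared_fraction)
    expect_gt(hpc$network$theta_fraction, ctx$network$theta_fraction)
  }
  # mature hippocampal theta prevalence parameter sits in the 50-75% range
  expect_gte(preset_profile("HPC", 14)$network$theta_fraction, 0.5)
  expect_lte(preset_profile("HPC", 14)$network$theta_fraction, 0.75)
  # deterministic registry
  expect_identical(preset_profile("CTX", 7), preset_profile("CTX", 7))
  # development strengthens bursting up to DIV 14, then plateaus
  expect_lt(preset_profile("CTX", 7)$train$burst_rate,
            preset_profile("CTX", 14)$train$burst_rate)
  expect_equal(preset_profile("CTX", 21)$train$burst_rate,
               preset_profile("CTX", 14)$train$burst_rate)
  expect_error(preset_profile("HPC", 3), "age_div")
  expect_error(preset_profile("TH", 14))
})
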