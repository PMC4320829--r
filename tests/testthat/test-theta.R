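test_that("log-ISI density is a proper, well-placed density", {
  # near-constant 0.15 s ISIs -> unimodal with mode at log10(0.15)
  st <- spike_train(cumsum(rep(0.15, 40)), t_stop = 10)
  d <- log_isi_density(st)
  expect_s3_class(d, "isi_density")
  mode_at <- d$grid[which.max(d$density)]
  expect_equal(mode_at, log10(0.15), tolerance = 0.01)
  expect_true(all(d$density >= 0))
  expect_true(all(diff(d$grid) > 0))

  # normalisation: integrates to 1 (trapezoid) on random trains
  set.seed(31)
  for (r in 1:10) {
    st <- random_train(150, t_stop = 60)
    dn <- log_isi_density(st, min_isi = 10)
    if (is.null(dn)) next
    area <- sum(diff(dn$grid) * (dn$density[-1] + dn$density[-512]) / 2)
    expect_equal(area, 1, tolerance = 1e-3)
  }

  # bimodal mixture: local maxima near both components
  set.seed(32)
  iv <- sample(c(rep(0.15, 60) * exp(rnorm(60, 0, 0.05)),
                 rep(1.5, 60) * exp(rnorm(60, 0, 0.05))))
  st2 <- spike_train(cumsum(iv), t_stop = 120)
  d2 <- log_isi_density(st2)
  y <- d2$density
  peaks <- which(y[2:511] > y[1:510] & y[2:511] > y[3:512]) + 1
  px <- d2$grid[peaks]
  expect_true(any(abs(px - log10(0.15)) < 0.15))
  expect_true(any(abs(px - log10(1.5)) < 0.15))

  # too few ISIs -> undefined
  expect_null(log_isi_density(spike_train(1:5, t_stop = 10)))
})

test_that("theta calls depend on a peak inside 0.1-0.25 s", {
  set.seed(33)
  # concentrated 0.15 s ISIs -> theta
  iv <- 0.15 * exp(rnorm(80, 0, 0.1))
  expect_true(detect_theta(spike_train(cumsum(iv), t_stop = 60)))

  # regular 1 Hz firing: single mode at 1 s -> not theta
  expect_false(detect_theta(spike_train(1:50 + rnorm(50, 0, 1e-4),
                                        t_stop = 60)))

  # modes at 0.02 s and 1 s only -> not theta
  iv2 <- sample(c(0.02 * exp(rnorm(80, 0, 0.1)), exp(rnorm(80, 0, 0.1))))
  expect_false(detect_theta(spike_train(cumsum(iv2), t_stop = 200)))

  # undefined density -> NA
  expect_true(is.na(detect_theta(spike_train(c(1, 2), t_stop = 10))))
})

test_that("detection is invariant to time shift and appended silence", {
  set.seed(34)
  iv <- 0.15 * exp(rnorm(100, 0, 0.1))
  t <- cumsum(iv)
  a <- spike_train(t, t_stop = 60)
  b <- spike_train(t + 100, t_start = 100, t_stop = 160)
  c_ <- spike_train(t, t_stop = 600)   # extra silent time
  expect_identical(detect_theta(a), detect_theta(b))
  expect_identical(detect_theta(a), detect_theta(c_))
})

test_that("array fraction counts undefined electrodes in the denominator", {
  set.seed(35)
  theta_tr <- function() spike_train(cumsum(0.15 * exp(rnorm(60, 0, 0.1))),
                                     t_stop = 60)
  tonic_tr <- function() spike_train(sort(runif(60, 0, 60)), t_stop = 60)
  sparse_tr <- function() spike_train(c(10, 30), t_stop = 60)
  rec <- mea_recording(c(replicate(3, theta_tr(), simplify = FALSE),
                         replicate(5, tonic_tr(), simplify = FALSE),
                         replicate(2, sparse_tr(), simplify = FALSE)),
                       region = "HPC", age_div = 14)
  expect_equal(theta_fraction(rec), 3 / 10)

  rec_all <- mea_recording(replicate(4, theta_tr(), simplify = FALSE),
                           region = "HPC", age_div = 14)
  expect_equal(theta_fraction(rec_all), 1)

  rec_none <- mea_recording(replicate(3, sparse_tr(), simplify = FALSE),
                            region = "HPC", age_div = 14)
  expect_warning(f0 <- theta_fraction(rec_none), "enough ISIs")
  expect_equal(f0, 0)
})

test_that("planted theta electrodes are recovered on synthetic recordings", {
  # 30 of 59 electrodes theta, strong modulation; mean over seeds within 0.05
  fr <- vapply(1:5, function(s) {
    tp <- train_params(burst_rate = 8, ibi_cv = 0.4, spikes_per_burst = 12,
                       within_burst_rate = 100, background_rate = 0.1)
    np <- network_params(n_electrodes = 59, duration = 600,
                         shared_fraction = 0, theta_fraction = 30 / 59,
                         seed = s)
    theta_fraction(generate_recording(tp, np))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 30 / 59), 0.05)
})
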