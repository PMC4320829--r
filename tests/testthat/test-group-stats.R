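test_that("Mann-Whitney worked examples", {
  r <- mann_whitney(1:4, 5:8)
  expect_equal(r$p, 2 / choose(8, 4), tolerance = 1e-12)  # 0.02857
  expect_equal(r$U, 0)
  expect_equal(r$method, "exact")

  expect_equal(mann_whitney(c(1), c(2))$p, 1)     # n too small to reach sig.
  # identical multisets: U sits exactly at its null mean, p = 1
  expect_equal(mann_whitney(c(1, 3, 5), c(1, 3, 5))$p, 1)
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("exact p matches full enumeration for combined n <= 10", {
  set.seed(41)
  for (r in 1:40) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    x <- round(rnorm(m), 3); y <- round(rnorm(n, sample(c(0, 1), 1)), 3)
    if (any(duplicated(c(x, y)))) next    # oracle defined for tie-free data
    expect_equal(mann_whitney(x, y)$p, oracle_mw_p(x, y), tolerance = 1e-10)
  }
})

test_that("approximate branch engages for ties/large n and is calibrated", {
  r <- mann_whitney(c(1, 2, 2, 3), c(2, 4, 5, 6))
  expect_equal(r$method, "approximate")   # ties force the approximation
  expect_true(r$p >= 0 && r$p <= 1)
  big <- mann_whitney(rnorm(15), rnorm(15))
  expect_equal(big$method, "approximate")
  # agreement with stats::wilcox.test's corrected normal approximation
  set.seed(42)
  x <- rnorm(25); y <- rnorm(30, 0.5)
  ours <- mann_whitney(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  expect_equal(ours$U, unname(ref$statistic))
})

test_that("BH adjustment matches hand-computed cases and p.adjust", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(c(0.005, 0.05)), c(0.01, 0.05))
  expect_equal(fdr_adjust(0.3), 0.3)                 # single p unchanged
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(43)
  for (r in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(fdr_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # NA passthrough keeps positions
  p <- c(0.01, NA, 0.5)
  a <- fdr_adjust(p)
  expect_true(is.na(a[2]))
  expect_equal(a[c(1, 3)], stats::p.adjust(p[c(1, 3)], "BH"))

  # monotone in raw p order
  p2 <- runif(20)
  a2 <- fdr_adjust(p2)
  expect_true(all(diff(a2[order(p2)]) >= -1e-12))
  expect_true(all(a2 >= p2 - 1e-12))
})

fake_features <- function(n_per, ages, effect = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (a in ages) for (reg in c("CTX", "HPC")) {
    shift <- if (reg == "HPC") effect else 0
    for (j in seq_len(n_per)) {
      fv <- as.list(rnorm(11))
      names(fv) <- feature_names()
      fv$cv_ibi <- fv$cv_ibi - shift     # planted difference in cv_ibi only
      rows[[length(rows) + 1]] <- data.frame(
        fv, region = reg, age_div = a,
        array_id = paste0(reg, a, "-", j), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("comparison table finds a planted cv_ibi effect and books counts", {
  tab <- comparison_table(fake_features(10, c(7, 14), effect = 3, seed = 2))
  expect_equal(nrow(tab), 22)            # 11 features x 2 ages
  cv <- tab[tab$feature == "cv_ibi", ]
  expect_true(all(cv$significance == "**"))
  expect_true(all(tab$p_adjusted >= tab$p_raw, na.rm = TRUE))
  expect_true(all(tab$n_ctx == 10 & tab$n_hpc == 10))

  # undefined values are dropped pairwise and reflected in the counts
  ff <- fake_features(6, 7, effect = 3, seed = 3)
  ff$theta_fraction[ff$region == "CTX"][1:2] <- NA
  tab2 <- comparison_table(ff)
  expect_equal(tab2$n_ctx[tab2$feature == "theta_fraction"], 4)

  # a missing group yields an undefined test, not an error
  ff3 <- fake_features(6, 7, seed = 4)
  ff3 <- ff3[ff3$region == "CTX" | ff3$age_div != 7, ]
  tab3 <- comparison_table(ff3)
  expect_true(all(is.na(tab3$p_raw)))
})

test_that("null data rarely produces stars (FDR control)", {
  n_sig <- 0; n_cell <- 0
  for (s in 1:6) {
    tab <- comparison_table(fake_features(8, c(7, 14), effect = 0, seed = s))
    n_sig <- n_sig + sum(tab$p_adjusted < 0.05, na.rm = TRUE)
    n_cell <- n_cell + sum(!is.na(tab$p_adjusted))
  }
  expect_lte(n_sig / n_cell, 0.05)
})
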