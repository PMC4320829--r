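# small planted dataset: k informative features out of p
planted_data <- function(n_per = 15, p = 11, informative = "f1", gap = 3,
                         seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  y <- rep(c("CTX", "HPC"), each = n_per)
  for (f in informative) x[y == "HPC", f] <- x[y == "HPC", f] + gap
  list(x = x, y = y)
}

test_that("PCA projections obey eigen-structure invariants", {
  set.seed(51)
  x <- matrix(rnorm(40 * 11), 40, 11, dimnames = list(NULL, paste0("f", 1:11)))
  pc <- pca_project(x)
  expect_equal(sum(pc$variance_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(pc$variance_fractions) <= 1e-12))  # non-increasing
  expect_true(all(pc$variance_fractions >= 0))
  # independent oracle: singular values of the standardised matrix
  z <- scale(x)
  sv <- svd(z)$d
  expect_equal(pc$variance_fractions, sv^2 / sum(sv^2), tolerance = 1e-9)

  # variance in exactly one feature -> PC1 explains everything
  x1 <- matrix(5, 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  x1[, 2] <- rnorm(30)
  expect_warning(pc1 <- pca_project(x1), "zero-variance")
  expect_equal(pc1$variance_fractions[1], 1)
  expect_setequal(pc1$dropped, c("a", "c"))

  # duplicated recordings project to identical points
  xd <- rbind(x, x[1, ])
  pcd <- pca_project(xd)
  expect_equal(pcd$projections[41, ], pcd$projections[1, ], tolerance = 1e-9)
})

test_that("a perfectly separating feature gives 100% held-out accuracy", {
  d <- planted_data(informative = "f1", gap = 10, seed = 52)
  expect_equal(train_eval(d$x, d$y, "forest", split_seed = 1,
                          ntree = 100)$accuracy, 100)
  expect_equal(train_eval(d$x, d$y, "svm", split_seed = 1)$accuracy, 100)
  # over repeats a rare tree-vote upset on a tiny test set is possible
  r <- evaluate_classifier(d$x, d$y, "forest", n_repeats = 20, seed = 3,
                           ntree = 100)
  expect_gte(r$mean_accuracy, 95)
})

test_that("the only informative feature receives importance 1", {
  d <- planted_data(informative = "f3", gap = 6, seed = 53)
  r <- evaluate_classifier(d$x, d$y, "forest", n_repeats = 30, seed = 5,
                           ntree = 200)
  expect_equal(max(r$importance), 1)          # normalised to the top
  expect_equal(names(which.max(r$importance)), "f3")
  expect_true(all(r$importance >= 0))
  expect_gt(r$importance["f3"], 3 * max(r$importance[names(r$importance) != "f3"]))
})

test_that("evaluation is deterministic given the seed", {
  d <- planted_data(gap = 1, seed = 54)
  a <- train_eval(d$x, d$y, "forest", split_seed = 7, ntree = 50)
  b <- train_eval(d$x, d$y, "forest", split_seed = 7, ntree = 50)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$importance, b$importance)
  r1 <- evaluate_classifier(d$x, d$y, "svm", n_repeats = 5, seed = 9)
  r2 <- evaluate_classifier(d$x, d$y, "svm", n_repeats = 5, seed = 9)
  expect_identical(r1$accuracies, r2$accuracies)
})

test_that("null labels give chance-level accuracy", {
  set.seed(55)
  x <- matrix(rnorm(30 * 11), 30, 11, dimnames = list(NULL, paste0("f", 1:11)))
  y <- rep(c("CTX", "HPC"), each = 15)       # labels independent of x
  rf <- evaluate_classifier(x, y, "forest", n_repeats = 60, seed = 11,
                            ntree = 100)
  expect_lt(abs(rf$mean_accuracy - 50), 15)
  sv <- evaluate_classifier(x, y, "svm", n_repeats = 60, seed = 11)
  expect_lt(abs(sv$mean_accuracy - 50), 15)
})

test_that("importance ordering is invariant to column permutation", {
  d <- planted_data(informative = c("f2", "f7"), gap = 4, seed = 56)
  r <- evaluate_classifier(d$x, d$y, "forest", n_repeats = 20, seed = 13,
                           ntree = 200)
  perm <- sample(ncol(d$x))
  rp <- evaluate_classifier(d$x[, perm], d$y, "forest", n_repeats = 20,
                            seed = 13, ntree = 200)
  # the two planted features share the top ranks in either column order
  expect_setequal(names(sort(r$importance, decreasing = TRUE))[1:2],
                  names(sort(rp$importance, decreasing = TRUE))[1:2])
  expect_setequal(names(sort(r$importance, decreasing = TRUE))[1:2],
                  c("f2", "f7"))
})

test_that("incremental performance reduces to the full model at k = max", {
  d <- planted_data(informative = c("f1", "f2"), gap = 3, seed = 57)
  ranking <- paste0("f", 1:11)
  inc <- incremental_performance(d$x, d$y, ranking, "forest",
                                 n_repeats = 10, seed = 15, ntree = 100)
  expect_equal(nrow(inc), 11)
  full <- evaluate_classifier(d$x, d$y, "forest", n_repeats = 10, seed = 15,
                              ntree = 100)
  expect_equal(inc$mean_accuracy[11], full$mean_accuracy)
  # a pure-noise single feature stays near chance
  noise_first <- c("f5", setdiff(ranking, "f5"))
  inc2 <- incremental_performance(d$x, d$y, noise_first, "forest",
                                  n_repeats = 30, seed = 17, ntree = 100)
  expect_lt(abs(inc2$mean_accuracy[1] - 50), 20)
  expect_gt(inc2$mean_accuracy[11], inc2$mean_accuracy[1])
  expect_error(incremental_performance(d$x, d$y, ranking[-1], "forest"),
               "cover")
})

test_that("undefined feature values are imputed from the training fold", {
  d <- planted_data(informative = "f1", gap = 8, seed = 58)
  d$x[c(3, 20), "f2"] <- NA
  d$x[5, "f1"] <- NA
  r <- train_eval(d$x, d$y, "forest", split_seed = 21, ntree = 100)
  expect_equal(r$accuracy, 100)   # NA handling must not break separability
  s <- train_eval(d$x, d$y, "svm", split_seed = 21)
  expect_true(is.finite(s$accuracy))
})
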