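test_that("subtractive clustering matches a brute-force density computation", {
  set.seed(41)
  # two tight groups far apart relative to the influence range
  X <- rbind(matrix(runif(20, 0.08, 0.12), 10, 2),
             matrix(runif(20, 0.88, 0.92), 10, 2))
  cfg <- anfis_config(influence_range = 0.2)
  centers <- subtractive_cluster(X, cfg)
  expect_equal(nrow(centers), 2)
  in_group <- function(c) all(c > 0.05 & c < 0.15) || all(c > 0.85 & c < 0.95)
  expect_true(in_group(centers[1, ]) && in_group(centers[2, ]))
  expect_false(all(abs(centers[1, ] - centers[2, ]) < 0.5))
  # the first selected center is the brute-force density argmax
  D <- brute_density(X, 0.2)
  expect_equal(unname(centers[1, ]), unname(X[which.max(D), ]))
})

test_that("clustering is invariant to duplicating the dataset", {
  set.seed(43)
  X <- matrix(runif(40), 20, 2)
  cfg <- anfis_config(influence_range = 0.3)
  c1 <- subtractive_cluster(X, cfg)
  c2 <- subtractive_cluster(rbind(X, X), cfg)
  expect_equal(unclass(c1), unclass(c2), ignore_attr = TRUE)
})

test_that("a single point clusters to itself and seeds a one-rule FIS", {
  X <- matrix(c(0.4, 0.6), 1, 2)
  centers <- subtractive_cluster(X, anfis_config())
  expect_equal(unclass(centers), X, ignore_attr = TRUE)
  fis <- init_fis(centers, X, y = 3)
  expect_equal(nrow(fis$centers), 1)
  expect_equal(infer_crisp(fis, c(0.4, 0.6)), 3, tolerance = 1e-6)
})

test_that("one rule per center, independent of the input dimension", {
  set.seed(44)
  m <- 5
  centers <- matrix(runif(9 * m), 9, m)
  X <- matrix(runif(60 * m), 60, m)
  y <- rowSums(X)
  fis <- init_fis(centers, X, y)
  expect_equal(nrow(fis$centers), 9)   # 9 clusters -> 9 rules, not n^m
  expect_equal(ncol(fis$centers), m)
})

test_that("training returns the FIS unchanged at 0 epochs and fits constants fast", {
  set.seed(45)
  X <- matrix(runif(40), 20, 2)
  y <- rep(4, 20)
  fis0 <- init_fis(subtractive_cluster(X, anfis_config()), X, y)
  out <- train_anfis(fis0, X, y, epochs = 0)
  expect_identical(out$fis, fis0)
  out5 <- train_anfis(fis0, X, y, epochs = 5)
  expect_lt(out5$report$final_rmse, 1e-6)
})

test_that("training RMSE improves on a separable six-class set", {
  fix <- separable_features(n_per_class = 10)
  fis <- fit_anfis(fix$X, fix$y, anfis_config(epochs = 20))
  rep <- attr(fis, "report")
  expect_lt(rep$final_rmse, 0.3)
  expect_lte(rep$final_rmse, rep$rmse[1])
  expect_true(all(is.finite(rep$rmse)))
})

test_that("defuzzification is a bounded weighted average of the consequents", {
  fis <- structure(list(
    centers = matrix(c(0.2, 0.8), 2, 1), sigma = matrix(0.15, 2, 1),
    coef = c(1, 5), consequent = "constant", norm = NULL,
    config = anfis_config()), class = "fis")
  # at a center with the other rule ~4 sigma away: essentially that rule's
  # consequent (the far rule still contributes ~exp(-8) of the gap)
  expect_equal(infer_crisp(fis, 0.2), 1, tolerance = 5e-3)
  # symmetric midpoint: the mean of the two consequents
  expect_equal(infer_crisp(fis, 0.5), 3, tolerance = 1e-9)
  # bounded by the consequent range wherever any rule fires
  for (x in seq(0, 1, by = 0.05)) {
    v <- infer_crisp(fis, x)
    expect_gte(v, 1)
    expect_lte(v, 5)
  }
  # far outside every membership: explicit out-of-range signal
  expect_error(infer_crisp(fis, 50), class = "rehabrecog_out_of_range")
})

test_that("crisp outputs decode to labels by round-half-up with clamping", {
  expect_equal(crisp_to_label(0.9), 1L)
  expect_equal(crisp_to_label(1.75), 2L)
  expect_equal(crisp_to_label(c(0.5, 1.4, 1.45, 2.1)), c(1L, 1L, 1L, 2L))
  expect_equal(crisp_to_label(-3), 1L)
  expect_equal(crisp_to_label(9.2), 6L)
  expect_error(crisp_to_label(NaN), "non-finite")
})

test_that("ANFIS recovers a known 3-rule Sugeno generator within 2x the noise", {
  set.seed(7)
  gen <- structure(list(
    centers = matrix(c(0.2, 0.2, 0.5, 0.8, 0.9, 0.3), 3, 2, byrow = TRUE),
    sigma = matrix(0.25, 3, 2), coef = c(1, 3, 5),
    consequent = "constant", norm = NULL, config = anfis_config()),
    class = "fis")
  X <- matrix(runif(400), 200, 2)
  colnames(X) <- c("f1", "f2")
  y_clean <- predict_anfis(gen, X)
  noise_sd <- 0.05
  y <- y_clean + rnorm(200, 0, noise_sd)
  fit <- fit_anfis(X, y, anfis_config(influence_range = 0.5))
  pred <- predict_anfis(fit, X)
  expect_lt(sqrt(mean((pred - y_clean)^2)), 2 * noise_sd)
})
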