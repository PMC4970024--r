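test_that("pearson handles exact linear relationships and errors", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(1, 10)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("pearson matches the direct covariance formula and t-transform", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 5)
  got <- pearson(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  tstat <- r_hand * sqrt(2 / (1 - r_hand^2))
  expect_equal(got$p_value, 2 * pt(-abs(tstat), df = 2),
               tolerance = 1e-12)
})

test_that("pearson is invariant under positive affine maps, flips sign under negation", {
  set.seed(1)
  x <- rnorm(30)
  y <- x + rnorm(30, sd = 0.5)
  r0 <- pearson(x, y)$r
  expect_equal(pearson(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson(x, 0.1 * y - 2)$r, r0, tolerance = 1e-12)
  expect_equal(pearson(-x, y)$r, -r0, tolerance = 1e-12)
})

test_that("ols_fit recovers exact lines and degenerate responses", {
  x <- seq(0, 1, length.out = 20)
  fit <- ols_fit(x, 3 * x - 0.5)
  expect_equal(fit$slope, 3, tolerance = 1e-12)
  expect_equal(fit$intercept, -0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  flat <- ols_fit(x, rep(2, 20))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
})

test_that("ols_fit equals the normal-equations oracle", {
  set.seed(7)
  x <- runif(40)
  y <- 1.3 - 0.8 * x + rnorm(40, sd = 0.3)
  fit <- ols_fit(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  expect_equal(fit$r_squared, fit$r^2, tolerance = 1e-12)
})

test_that("cda separates well-separated groups perfectly", {
  set.seed(3)
  f <- cbind(c(rnorm(15, 0.05, 0.01), rnorm(15, 0.18, 0.01)))
  g <- factor(rep(c("a", "b"), each = 15))
  cm <- cda_confusion(f, g, "leave_one_out")
  expect_equal(unname(diag(cm)), c(100, 100))
  expect_error(cda_fit(f[1:16, , drop = FALSE],
                       factor(c(rep("a", 15), "b"))),
               "fewer than 2 samples")
})

test_that("cda axes match a generalized-eigenproblem oracle and MASS::lda", {
  skip_if_not_installed("MASS")
  set.seed(9)
  n <- 30
  f <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)),
             cbind(rnorm(n, 2), rnorm(n, 1)),
             cbind(rnorm(n, 1), rnorm(n, 3)))
  g <- factor(rep(c("a", "b", "c"), each = n))
  fit <- cda_fit(f, g)
  # brute-force oracle: eigenvectors of W^-1 B
  lev <- levels(g)
  means <- t(sapply(lev, function(l) colMeans(f[g == l, ])))
  W <- Reduce(`+`, lapply(lev, function(l)
    crossprod(scale(f[g == l, ], center = TRUE, scale = FALSE)))) /
    (3 * n - 3)
  grand <- colMeans(f)
  B <- crossprod(sweep(means, 2, grand) * sqrt(n)) / 2
  ev <- eigen(solve(W) %*% B)
  for (k in 1:2) {
    a1 <- fit$canonical_coefficients[, k]
    a2 <- Re(ev$vectors[, k])
    cosang <- abs(sum(a1 * a2)) / sqrt(sum(a1^2) * sum(a2^2))
    expect_equal(cosang, 1, tolerance = 1e-8)
  }
  # cross-check against MASS::lda scaling direction
  ld <- MASS::lda(f, g)
  cos_lda <- abs(sum(fit$canonical_coefficients[, 1] * ld$scaling[, 1])) /
    sqrt(sum(fit$canonical_coefficients[, 1]^2) * sum(ld$scaling[, 1]^2))
  expect_equal(cos_lda, 1, tolerance = 1e-6)
  # and classification agreement with lda under equal priors
  ld_eq <- MASS::lda(f, g, prior = rep(1 / 3, 3))
  expect_gt(mean(predict(fit, f) == predict(ld_eq, f)$class), 0.97)
})

test_that("cda classification is invariant to common affine maps of features", {
  set.seed(11)
  f <- rbind(cbind(rnorm(20, 0), rnorm(20, 0)),
             cbind(rnorm(20, 3), rnorm(20, 1)))
  g <- factor(rep(c("a", "b"), each = 20))
  p0 <- predict(cda_fit(f, g), f)
  A <- matrix(c(2, 0.5, -1, 3), 2, 2)
  f2 <- f %*% A + matrix(c(5, -7), 40, 2, byrow = TRUE)
  p1 <- predict(cda_fit(f2, g), f2)
  expect_identical(p0, p1)
})

test_that("identical group distributions classify at chance level", {
  set.seed(13)
  f <- cbind(rnorm(60), rnorm(60))
  g <- factor(rep(c("a", "b", "c"), each = 20))
  cm <- cda_confusion(f, g, "leave_one_out")
  acc <- sum(diag(cm) * attr(cm, "counts")) / (100 * sum(attr(cm, "counts")))
  band <- 2.576 * sqrt(1 / 3 * 2 / 3 / 60)
  expect_gt(acc, 1 / 3 - band)
  expect_lt(acc, 1 / 3 + band)
})

test_that("confusion matrix rows always sum to 100", {
  set.seed(15)
  for (i in 1:5) {
    f <- cbind(rnorm(45), rnorm(45))
    g <- factor(sample(c("monocots", "dicots", "mixture"), 45, TRUE,
                       prob = c(0.4, 0.3, 0.3)),
                levels = c("monocots", "dicots", "mixture"))
    if (any(table(g) < 2)) next
    for (scheme in c("resubstitution", "leave_one_out")) {
      cm <- cda_confusion(f, g, scheme)
      expect_equal(unname(rowSums(cm)), rep(100, 3), tolerance = 0.1)
      expect_true(all(cm >= 0))
    }
  }
})

test_that("ridge regularization handles perfectly collinear features", {
  hf <- simulate_height_features(seed = 4)  # p90 = 0.9 * max exactly
  fit <- cda_fit(hf[, c("max_height", "p90_height")], hf$weed_class)
  expect_true(fit$ridge_used)
  cm <- cda_confusion(hf[, c("max_height", "p90_height")], hf$weed_class)
  expect_equal(unname(rowSums(cm)), rep(100, 3), tolerance = 0.1)
})

make_matched_dataset <- function(n = 24, noise = 0) {
  set.seed(100)
  ids <- sprintf("S%02d", seq_len(n))
  maize_v <- c(rep(0, n / 3), runif(2 * n / 3, 2e-4, 8e-4))
  weed_v <- runif(n, 0, 1e-4)
  weed_v[seq(1, n, by = 6)] <- 0
  wm <- ifelse(weed_v > 0, runif(n, 0.05, 0.2), NA)
  volumes <- data.frame(sample_id = ids,
                        maize_volume_m3 = maize_v,
                        weed_volume_m3 = weed_v,
                        total_volume_m3 = maize_v + weed_v,
                        weed_max_height_m = wm,
                        weed_p90_height_m = 0.9 * wm)
  truth <- data.frame(sample_id = ids,
                      maize_biomass_g = 6e4 * maize_v * (1 + noise *
                                                           rnorm(n)),
                      weed_biomass_g = 9e4 * weed_v,
                      weed_density = ifelse(weed_v > 0,
                                            pmax(1, round(weed_v * 1e5)),
                                            0),
                      weed_class = ifelse(weed_v == 0, "none",
                                          sample(c("monocots", "dicots",
                                                   "mixture"), n, TRUE)),
                      maize_count = ifelse(maize_v > 0, 3L, 0L))
  list(volumes = volumes, truth = truth)
}

test_that("analyze_dataset reports r = 1 for exactly proportional biomass", {
  d <- make_matched_dataset()
  rep <- analyze_dataset(d$volumes, d$truth)
  rel <- rep$relationships
  expect_equal(rel$r[rel$relationship == "weed_volume~weed_biomass"], 1,
               tolerance = 1e-12)
  expect_equal(rel$r[rel$relationship == "maize_volume~maize_biomass"], 1,
               tolerance = 1e-12)
  expect_equal(nrow(rel), 6)
})

test_that("a constant maize stand flags the count relationship degenerate", {
  d <- make_matched_dataset()
  rep <- analyze_dataset(d$volumes, d$truth)
  rel <- rep$relationships
  expect_equal(rel$flag[rel$relationship == "maize_count~maize_volume"],
               "degenerate")
})

test_that("analyze_dataset rejects mismatched sample ids", {
  d <- make_matched_dataset()
  d$truth$sample_id[1] <- "NOPE"
  expect_error(analyze_dataset(d$volumes, d$truth), "do not match")
})
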