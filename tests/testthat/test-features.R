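test_that("log transform maps listed scores by log(1+x)", {
  df <- data.frame(exfscore = c(0, exp(1) - 1), motscore = c(exp(1) - 1, 3),
                   tfcscore = c(13, 7), swrt1 = c(90, 40))
  tr <- log_transform(df)
  expect_equal(tr$exfscore, c(0, 1))
  expect_equal(tr$motscore[1], 1)
  expect_equal(tr$tfcscore, c(13, 7))   # not in the transformed set
  expect_equal(tr$swrt1, c(90, 40))
  expect_error(log_transform(data.frame(exfscore = -1)), "negative")
})

test_that("age brackets partition and assign with nearest fallback", {
  br <- make_age_brackets(c(23, 57), width = 10)
  expect_equal(br, seq(20, 60, 10))
  g <- assign_age_brackets(c(5, 23, 39.99, 40, 95), br)
  expect_equal(as.character(g),
               c("[20,30)", "[20,30)", "[30,40)", "[40,50)", "[50,60)"))
})

test_that("grouped PCA matches prcomp within each group up to sign", {
  set.seed(10)
  X <- matrix(rnorm(200 * 12), 200, 12,
              dimnames = list(NULL, paste0("v", 1:12)))
  X[, 2] <- X[, 1] * 0.8 + rnorm(200, sd = 0.3)
  g <- factor(rep(c("a", "b"), each = 100))
  pcm <- fit_group_pca(X, g, n_pcs = 2)
  for (gg in c("a", "b")) {
    pr <- prcomp(X[g == gg, ], center = TRUE, scale. = TRUE)
    for (k in 1:2) {
      got <- pcm$groups[[gg]]$loadings[, k]
      ref <- pr$rotation[, k]
      expect_lt(min(max(abs(got - ref)), max(abs(got + ref))), 1e-8)
    }
    expect_equal(pcm$groups[[gg]]$explained_variance,
                 pr$sdev^2 / sum(pr$sdev^2), tolerance = 1e-10)
  }
})

test_that("two perfectly correlated variables put 100% on PC1", {
  x <- rnorm(50)
  X <- cbind(a = x, b = 2 * x + 3)
  pcm <- fit_group_pca(X, rep("g", 50), n_pcs = 1)
  expect_equal(pcm$groups$g$explained_variance[1], 1, tolerance = 1e-12)
})

test_that("PCA validation names the offending group and variable", {
  X <- cbind(a = rnorm(30), b = rep(1, 30))
  expect_error(fit_group_pca(X, rep("g1", 30), 1), "g1")
  expect_error(fit_group_pca(X, rep("g1", 30), 1), "`b`")
  expect_error(fit_group_pca(cbind(a = rnorm(2), b = rnorm(2)),
                             rep("g", 2), 1), "too few")
})

test_that("explained variance is non-increasing and signs align", {
  co <- generate_cohort(cohort_params(300, seed = 12))
  X <- log_transform(co$visits)[, default_score_model()$vars]
  g <- assign_age_brackets(co$visits$age_at_visit,
                           make_age_brackets(co$visits$age_at_visit, 10))
  g <- hdprog:::merge_small_groups(g, 14)
  pcm <- fit_group_pca(X, g, n_pcs = 2)
  lev <- names(pcm$groups)
  for (i in seq_along(lev)) {
    expect_true(all(diff(pcm$groups[[lev[i]]]$explained_variance) <= 1e-12))
    expect_equal(sum(pcm$groups[[lev[i]]]$loadings[, 1]^2), 1,
                 tolerance = 1e-10)
    if (i > 1) {
      for (k in 1:2)
        expect_gte(sum(pcm$groups[[lev[i]]]$loadings[, k] *
                         pcm$groups[[lev[i - 1]]]$loadings[, k]), 0)
    }
  }
})

test_that("orientation pins the severity direction of PC1", {
  co <- generate_cohort(cohort_params(300, seed = 13))
  X <- log_transform(co$visits)[, default_score_model()$vars]
  g <- hdprog:::merge_small_groups(
    assign_age_brackets(co$visits$age_at_visit,
                        make_age_brackets(co$visits$age_at_visit, 10)), 14)
  dec <- c("swrt1", "sit1", "sdmt1", "scnt1", "verfct5", "tfcscore",
           "indepscl")
  pcm <- fit_group_pca(X, g, 2, orient_negative = dec)
  expect_lt(sum(pcm$groups[[1]]$loadings[dec, 1]), 0)
  # sicker true states score higher on PC1
  sc <- project(X, pcm, g)
  m <- tapply(sc[, 1], co$truth$true_state, mean)
  expect_true(all(diff(m) > 0))
})

test_that("projection is centred, consistent and validated", {
  set.seed(14)
  X <- matrix(rnorm(80 * 3), 80, 3, dimnames = list(NULL, c("a", "b", "c")))
  g <- factor(rep(c("g1", "g2"), each = 40))
  pcm <- fit_group_pca(X, g, n_pcs = 2)
  sc <- project(X, pcm, g)
  # group-mean visit projects to the origin
  mean_visit <- pcm$groups$g1$center
  expect_equal(as.numeric(project(t(as.matrix(mean_visit)), pcm, "g1")),
               c(0, 0), tolerance = 1e-10)
  expect_equal(colMeans(sc[g == "g2", ]), c(PC1 = 0, PC2 = 0),
               tolerance = 1e-10)
  # hand-computed score for one row
  z <- (X[5, ] - pcm$groups$g1$center) / pcm$groups$g1$scale
  expect_equal(unname(sc[5, 1]), sum(z * pcm$groups$g1$loadings[, 1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(project(X, pcm, rep("nope", 80)), "unknown")
})

test_that("pooled centring preserves within-group decorrelation", {
  set.seed(15)
  X <- matrix(rnorm(300 * 4), 300, 4, dimnames = list(NULL, letters[1:4]))
  X[1:150, ] <- X[1:150, ] + 3          # two separated groups
  g <- factor(rep(c("s1", "s2"), each = 150))
  pcm <- fit_group_pca(X, g, 2, center = "pooled")
  sc <- project(X, pcm, g)
  for (gg in c("s1", "s2"))
    expect_lt(abs(cor(sc[g == gg, 1], sc[g == gg, 2])), 1e-10)
  # between-group separation survives
  expect_gt(abs(mean(sc[g == "s1", 1]) - mean(sc[g == "s2", 1])), 0.5)
})

test_that("state correlation check behaves on edge cases", {
  x <- rnorm(100)
  expect_equal(state_correlation_check(cbind(x, x),
                                       rep(1, 100))$max_abs_r, 1)
  set.seed(16)
  sc <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(state_correlation_check(sc, rep(1, 10000))$max_abs_r, 0.05)
  expect_warning(state_correlation_check(cbind(rnorm(5), rnorm(5)),
                                         c(1, 1, 1, 2, 2)),
                 "fewer than 3")
})

test_that("the iterative fit converges below the correlation threshold", {
  co <- generate_cohort(cohort_params(600, seed = 21))
  pf <- iterative_fit(co, n_states = 5,
                      upper_bound = calibrate_upper_bound(co)$upper_bound,
                      maxit = 200)
  expect_true(pf$converged)
  expect_lt(pf$max_abs_r, 0.2)
  expect_true(pf$iterations >= 1)
  soj <- mean_sojourn_times(pf$fit$model)
  expect_true(all(soj > 2) && all(soj < 60))
})
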