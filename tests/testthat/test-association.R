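test_that("propensity model recovers the null and survives separation", {
  set.seed(31)
  n <- 200
  age <- rnorm(n, 60, 10)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  grp <- rep(c("relative", "control"), each = n / 2)
  # identical covariate distributions: scores hover at the group prevalence
  ps <- estimate_propensity(age, sex, grp)
  expect_equal(mean(ps$scores), 0.5, tolerance = 0.02)
  expect_lt(sd(ps$scores), 0.1)
  # group determined by sex: separation, Firth fallback, finite coefficients
  grp2 <- ifelse(sex == "male", "relative", "control")
  ps2 <- estimate_propensity(age, sex, grp2)
  expect_identical(ps2$method, "firth")
  expect_true(all(is.finite(ps2$coefficients)))
  # older controls: relatives get higher scores at younger ages
  age3 <- c(rnorm(100, 50, 8), rnorm(100, 70, 8))
  ps3 <- estimate_propensity(age3, sex, grp)
  expect_gt(mean(ps3$scores[1:100]), mean(ps3$scores[101:200]))
})

test_that("optimal matching attains the exhaustive-assignment optimum", {
  m <- optimal_match(c(0.2, 0.8, 0.25, 0.75), c("relative", "relative",
                                                "control", "control"))
  expect_equal(m$total_distance, 0.10)
  expect_equal(nrow(m$pairs), 2)
  # identical multisets: zero distance
  m0 <- optimal_match(c(0.1, 0.4, 0.1, 0.4),
                      rep(c("relative", "control"), each = 2))
  expect_equal(m0$total_distance, 0)
  # greedy-adversarial and random instances vs brute force
  set.seed(33)
  for (i in 1:25) {
    nr <- sample(2:4, 1); nc <- sample(nr:6, 1)
    rs <- runif(nr); cs <- runif(nc)
    m <- optimal_match(c(rs, cs), rep(c("relative", "control"), c(nr, nc)))
    expect_equal(m$total_distance, brute_force_match(rs, cs),
                 tolerance = 1e-12)
    expect_lte(m$total_distance, greedy_match_distance(rs, cs) + 1e-12)
    # each control used at most once
    expect_false(anyDuplicated(m$pairs$control) > 0)
  }
  # exact sex stratification: pairs never cross sex
  sexes <- rep(c("male", "female"), 10)
  sc <- runif(20)
  gl <- rep(c("relative", "control"), each = 10)
  ms <- optimal_match(sc, gl, sex = sexes, exact_on_sex = TRUE)
  expect_true(all(sexes[ms$pairs$relative] == sexes[ms$pairs$control]))
})

test_that("PS-adjusted linear model reduces to difference of means when PS is flat", {
  set.seed(35)
  y <- rnorm(80)
  grp <- rep(c("relative", "control"), each = 40)
  r <- suppressWarnings(ps_adjusted_linear(y, grp, rep(0.5, 80)))
  expect_equal(r$estimate, mean(y[1:40]) - mean(y[41:80]), tolerance = 1e-12)
  # identical outcomes: estimate 0, p ~ 1
  r0 <- suppressWarnings(ps_adjusted_linear(rep(c(y[1:40]), 2), grp, rep(0.5, 80)))
  expect_equal(r0$estimate, 0, tolerance = 1e-12)
  # CI is estimate +/- 1.96 SE and p matches the Wald statistic
  ps <- runif(80)
  r2 <- ps_adjusted_linear(y, grp, ps)
  expect_equal(r2$ci_upper - r2$estimate, qnorm(0.975) * r2$se)
  expect_equal(r2$p, 2 * pnorm(-abs(r2$estimate / r2$se)))
})

test_that("PS adjustment recovers a programmed group shift under confounding", {
  set.seed(36)
  reps <- 40
  est_adj <- est_raw <- numeric(reps)
  for (i in 1:reps) {
    n <- 300
    age <- c(rnorm(n / 2, 55, 10), rnorm(n / 2, 68, 10)) # relatives younger
    grp <- rep(c("relative", "control"), each = n / 2)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    # age drives the outcome, group adds +16
    y <- 2 * age + 16 * (grp == "relative") + rnorm(n, 0, 20)
    ps <- estimate_propensity(age, sex, grp)
    est_adj[i] <- ps_adjusted_linear(y, grp, ps$scores)$estimate
    est_raw[i] <- mean(y[grp == "relative"]) - mean(y[grp == "control"])
  }
  expect_lt(abs(mean(est_adj) - 16), abs(mean(est_raw) - 16))
  expect_lt(abs(mean(est_adj) - 16), 3 * sd(est_adj) / sqrt(reps) + 2)
})

test_that("multivariable model reports ORs and drops constant flags", {
  set.seed(37)
  n <- 4000
  e_igm <- rbinom(n, 1, 0.2)
  aflc <- rbinom(n, 1, 0.1)
  age <- rnorm(n, 60, 12)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  eta <- -1 + log(5) * e_igm + log(6) * aflc
  grp <- ifelse(rbinom(n, 1, plogis(eta)) == 1, "relative", "control")
  res <- multivariable_model(grp, e_igm, aflc, age, sex)
  expect_setequal(res$term, c("e_igm", "aflc", "age", "male"))
  expect_equal(res$or[res$term == "e_igm"], 5, tolerance = 0.25)
  expect_equal(res$or[res$term == "aflc"], 6, tolerance = 0.25)
  expect_warning(
    res2 <- multivariable_model(grp, e_igm, rep(FALSE, n), age, sex),
    "constant")
  expect_false("aflc" %in% res2$term)
})

test_that("age trend recovers constructed slopes and flags undefined folds", {
  age <- seq(20, 90, length.out = 60)
  grp <- rep(c("relative", "control"), each = 60)
  # relatives exactly 0.01/year, controls exactly flat
  y <- c(0.01 * age, rep(0.8, 60))
  expect_warning(tr <- age_trend(c(y), c(age, age), grp), "fold-ratio undefined")
  expect_equal(tr$slopes$slope_per_10y[1], 0.10, tolerance = 1e-10)
  expect_equal(tr$slopes$slope_per_10y[2], 0, tolerance = 1e-10)
  expect_true(is.na(tr$fold_ratio))
  expect_error(age_trend(y, rep(50, 120), grp), "zero age variance")
  # noisy recovery with programmed slopes, fold ratio near 0.010/0.0038
  set.seed(38)
  reps <- 30
  folds <- slopes <- numeric(reps)
  for (i in 1:reps) {
    a1 <- runif(120, 25, 95); a2 <- runif(160, 25, 95)
    y1 <- 0.35 + 0.010 * a1 + rnorm(120, 0, 0.2)
    y2 <- 0.72 + 0.0038 * a2 + rnorm(160, 0, 0.2)
    tr <- age_trend(c(y1, y2), c(a1, a2),
                    rep(c("relative", "control"), c(120, 160)))
    slopes[i] <- tr$slopes$slope_per_10y[1]
    folds[i] <- tr$fold_ratio
  }
  expect_lt(abs(mean(slopes) - 0.10), 3 * sd(slopes) / sqrt(reps))
  expect_lt(abs(median(folds) - 0.010 / 0.0038), 1.0)
})
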