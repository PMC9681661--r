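# gestational models: day regression, window comparison, robust trend fits,
# differential expression, ANOVA dispatch, Taylor ratio test

test_that("day regression is exact on noiseless linear composition", {
  day <- rep(c(10.5, 12.5, 14.5, 16.5, 18.5), each = 3)
  x <- cbind(MP = 0.8 - 0.02 * day, Neutrophil = 0.2 + 0.02 * day)
  fit <- fit_day_regression(x, day, k = 3, seed = 1)
  expect_equal(fit$r2_train, 1, tolerance = 1e-9)
  expect_true(all(fit$cv_r2 > 0.999, na.rm = TRUE))
  expect_error(fit_day_regression(x[1:2, ], day[1:2]), "at least 3")
  wide <- matrix(rnorm(5 * 10), nrow = 5)
  expect_error(fit_day_regression(wide, day[1:5]), "ridge")
  expect_silent(fit_day_regression(wide, day[1:5], ridge = TRUE, k = 2))
})

test_that("windows filter the samples they claim to", {
  day <- c(10.5, 12.5, 13.5, 14.5, 16.5, 18.5)
  x <- cbind(f = seq_along(day))
  early <- fit_day_regression(x, day, window = "early", k = 2)
  late <- fit_day_regression(x, day, window = "late", k = 2)
  expect_equal(early$n, 3); expect_equal(late$n, 3)
})

test_that("permuted day labels give non-positive cross-validated R2 on average", {
  set.seed(61)
  means <- replicate(20, {
    day <- rep(seq(10.5, 18.5, 1), each = 3)
    x <- matrix(rnorm(length(day) * 4), ncol = 4)
    fit <- fit_day_regression(x, sample(day), k = 5, seed = sample.int(1e6, 1))
    mean(fit$cv_r2, na.rm = TRUE)
  })
  expect_lte(mean(means), 0)
})

test_that("window comparison reports the fold ratio and textbook t", {
  same <- compare_windows(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(same$ratio, 1); expect_equal(same$p_value, 1)
  r <- compare_windows(c(0.8, 0.8), c(0.4, 0.4))
  expect_equal(r$ratio, 2)
  a <- c(0.9, 0.7, 0.85, 0.8); b <- c(0.4, 0.5, 0.35, 0.3)
  res <- compare_windows(a, b)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  expect_equal(res$t, (mean(a) - mean(b)) / sqrt(sp2 * 0.5), tolerance = 1e-9)
  expect_error(compare_windows(0.5, c(0.4, 0.3)), "at least 2")
})

test_that("robust covariance equals the brute-force sandwich on a fixed design", {
  set.seed(62)
  n <- 20
  dat <- data.frame(day = seq(10.5, 18.5, length.out = n),
                    compartment = rep(c("PB", "EV"), 10))
  dat$y <- 1 + 0.1 * dat$day + rnorm(n, sd = abs(dat$day - 14) / 10 + 0.05)
  fit <- robust_trend_fit(dat, "y")
  # independent oracle: explicit matrix products
  X <- cbind(1, dat$day - mean(dat$day), as.integer(dat$compartment == "EV"))
  beta <- solve(t(X) %*% X) %*% t(X) %*% dat$y
  e <- dat$y - X %*% beta
  D <- diag(as.vector(e)^2)
  V <- solve(t(X) %*% X) %*% t(X) %*% D %*% X %*% solve(t(X) %*% X)
  expect_lt(max(abs(unname(fit$vcov) - V)), 1e-10)
  expect_equal(unname(fit$tidy$estimate), as.vector(beta), tolerance = 1e-10)
  # cross-check against the established sandwich estimator
  m <- lm(y ~ I(day - mean(day)) + relevel(factor(compartment), "PB"),
          data = dat)
  expect_lt(max(abs(unname(fit$vcov) - unname(sandwich::vcovHC(m, "HC0")))),
            1e-10)
  # PB is the reference level
  expect_true(any(grepl("compartmentEV", fit$tidy$term)))
})

test_that("equal-magnitude residuals collapse the sandwich to sigma2 (X'X)^-1", {
  # y constructed so residuals are exactly +/- c on a balanced design
  x <- rep(c(-1, 1), each = 4)
  e <- rep(c(0.3, -0.3), 4)
  dat <- data.frame(day = x + 14.5, y = 2 + 0.5 * x + e)
  fit <- robust_trend_fit(dat, "y", compartment = NULL)
  X <- cbind(1, x)
  expect_lt(max(abs(unname(fit$vcov) - 0.09 * solve(crossprod(X)))), 1e-10)
})

test_that("robust SEs converge to classical SEs under homoskedasticity", {
  set.seed(63)
  n <- 10000
  dat <- data.frame(day = runif(n, 10.5, 18.5))
  dat$y <- 0.2 + 0.03 * dat$day + rnorm(n, sd = 0.1)
  fit <- robust_trend_fit(dat, "y", compartment = NULL)
  m <- lm(y ~ I(day - mean(day)), data = dat)
  ratio <- fit$tidy$se_robust / sqrt(diag(vcov(m)))
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("quadratic trends are recovered with the right sign", {
  pops <- default_populations(fetal = FALSE)
  nm <- vapply(pops, `[[`, character(1), "name")
  pops[[match("Neutrophil", nm)]]$abundance$TIS <-
    stats::setNames(c(0.30, 0, -0.008), c("intercept", "slope", "quad"))
  hits <- vapply(1:5, function(i) {
    d <- study_design(compartments = "TIS", mice_per_day = 3,
                      events_per_sample = 1500, dead_frac = 0, rbc_frac = 0,
                      seed = 100 + i)
    s <- generate_study(d, pops)
    fr <- s$truth$fractions
    md <- s$metadata
    fr$day <- md$day[match(fr$sample_id, md$sample_id)]
    fr <- fr[!is.na(fr$day) & fr$population == "Neutrophil", ]
    fit <- robust_trend_fit(fr, "fraction", compartment = NULL,
                            quadratic = TRUE)
    row <- fit$tidy[fit$tidy$term == "day2", ]
    row$estimate < 0 && row$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("differential expression flags the shifted marker only", {
  set.seed(64)
  mice <- paste0("m", 1:10)
  group <- rep(c("early", "late"), each = 5)
  markers <- paste0("mk", 1:10)
  med <- expand.grid(mouse = mice, marker = markers)
  med$group <- group[match(med$mouse, mice)]
  med$value <- rnorm(nrow(med), 2, 0.3)
  shift <- med$marker == "mk1" & med$group == "early"
  med$value[shift] <- med$value[shift] + 1.5
  res <- differential_expression(med, "early", "late")
  expect_true(res$significant[res$marker == "mk1"])
  expect_gt(res$mean_diff[res$marker == "mk1"], 1)
  expect_equal(res$p_adjusted, pmin(res$p_value * 10, 1))
  same <- med; same$value <- 2
  res0 <- differential_expression(same, "early", "late")
  expect_false(any(res0$significant))
  # markers with too few mice are skipped with a warning
  few <- med[!(med$marker == "mk2" & med$mouse %in% mice[2:10]), ]
  expect_warning(differential_expression(few, "early", "late"), "skipped")
})

test_that("ANOVA dispatch: classic on the toy groups, Welch when variances differ", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  res <- anova_dispatch(vals, grp)
  expect_equal(res$method, "classic")
  expect_equal(res$statistic, 3.0, tolerance = 1e-12)
  expect_equal(res$posthoc_method, "tukey-hsd")
  # three identical groups: F = 0, p = 1
  same <- anova_dispatch(rep(c(1, 2, 3), 3), grp)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  # blatant variance inequality routes to Welch + Games-Howell
  set.seed(65)
  v2 <- c(rnorm(20, 0, 0.1), rnorm(20, 0, 3), rnorm(20, 0, 0.1))
  g2 <- rep(c("a", "b", "c"), each = 20)
  r2 <- anova_dispatch(v2, g2)
  expect_equal(r2$method, "welch")
  expect_equal(r2$posthoc_method, "games-howell")
  expect_true(all(r2$posthoc$p_adjusted >= 0 & r2$posthoc$p_adjusted <= 1))
  # zero-variance group goes to the Welch branch
  v3 <- c(rep(1, 3), rnorm(3), rnorm(3))
  r3 <- anova_dispatch(v3, rep(c("a", "b", "c"), each = 3))
  expect_equal(r3$method, "welch")
  expect_error(anova_dispatch(rnorm(4), rep(c("a", "b"), 2)), "3 groups")
})

test_that("Games-Howell agrees with Welch pairwise t on two of three groups", {
  set.seed(66)
  v <- c(rnorm(15, 0), rnorm(15, 1, 2), rnorm(15, 0.5, 0.5))
  g <- rep(c("a", "b", "c"), each = 15)
  gh <- games_howell(v, g)
  wt <- t.test(v[g == "b"], v[g == "a"])
  row <- gh[gh$comparison == "b-a", ]
  expect_equal(abs(row$t), abs(unname(wt$statistic)), tolerance = 1e-9)
  expect_equal(row$df, unname(wt$parameter), tolerance = 1e-9)
})

test_that("Taylor ratio variance tracks the Monte-Carlo truth at low CV", {
  set.seed(67)
  x <- rnorm(2e5, 10, 1); y <- rnorm(2e5, 5, 0.5)
  rt <- ratio_test(x, y)
  expect_equal(rt$ratio, 2, tolerance = 0.01)
  mc <- var(rnorm(2e5, 10, 1) / rnorm(2e5, 5, 0.5))
  expect_lt(abs(rt$variance - mc) / mc, 0.05)
  # identical arms give ratio 1; common rescaling leaves the variance as is
  z <- rnorm(50, 10, 1)
  expect_equal(ratio_test(z, z)$ratio, 1)
  r1 <- ratio_test(x[1:100], y[1:100])
  r2 <- ratio_test(3 * x[1:100], 3 * y[1:100])
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  expect_equal(r1$variance, r2$variance, tolerance = 1e-12)
  expect_error(ratio_test(1, c(1, 2)), "n >= 2")
  expect_message(ratio_test(c(1, 2, 3), c(0, 1, 2)), "pseudo-count")
})

test_that("ratio comparison reproduces the descriptive-statistics t test", {
  r1 <- structure(list(ratio = 2, variance = 0.04, sd = 0.2, n = 5),
                  class = "ratio_test")
  r2 <- structure(list(ratio = 1.5, variance = 0.09, sd = 0.3, n = 4),
                  class = "ratio_test")
  res <- ratio_compare(r1, r2)
  sp2 <- (4 * 0.04 + 3 * 0.09) / 7
  t_hand <- 0.5 / sqrt(sp2 * (1 / 5 + 1 / 4))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 7)
  eq <- ratio_compare(r1, r1)
  expect_equal(eq$diff, 0)
})
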