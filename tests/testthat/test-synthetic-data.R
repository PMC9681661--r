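# synthetic study generator: determinism, ground-truth consistency,
# multinomial convergence, cross-over / perturbation / batch / leakage
# injections

test_that("identical seeds give identical studies; labels match the mixture", {
  s1 <- generate_study(tiny_design(seed = 7))
  s2 <- generate_study(tiny_design(seed = 7))
  expect_identical(as.data.frame(s1$events), as.data.frame(s2$events))
  expect_identical(s1$truth$events, s2$truth$events)
  s3 <- generate_study(tiny_design(seed = 8))
  expect_false(identical(as.data.frame(s1$events), as.data.frame(s3$events)))
  # per-sample realized fractions sum to 1
  fr <- s1$truth$fractions
  sums <- tapply(fr$fraction, fr$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("a single-population design labels every event with that population", {
  pops <- fixed_populations(c(OnlyPop = 1))
  d <- study_design(days = 12.5, mice_per_day = 1, compartments = "TIS",
                    events_per_sample = 100, dead_frac = 0, rbc_frac = 0,
                    seed = 2)
  s <- generate_study(d, pops)
  tt <- s$truth$events[!grepl("anchor", s$truth$events$sample_id), ]
  expect_equal(nrow(tt), 100)
  expect_true(all(tt$population == "OnlyPop"))
})

test_that("realized fractions converge to the configured mixture (3 multinomial SE)", {
  fracs <- c(A = 0.5, B = 0.3, C = 0.2)
  pops <- fixed_populations(fracs)
  d <- study_design(days = 12.5, mice_per_day = 1, compartments = "TIS",
                    events_per_sample = 50000, dead_frac = 0, rbc_frac = 0,
                    mouse_sd = 0, seed = 11)
  s <- generate_study(d, pops)
  fr <- s$truth$fractions
  fr <- fr[!grepl("anchor", fr$sample_id), ]
  for (p in names(fracs)) {
    se <- sqrt(fracs[p] * (1 - fracs[p]) / 50000)
    expect_lt(abs(fr$fraction[fr$population == p] - fracs[p]), 3 * se)
  }
})

test_that("degenerate single-day design rejects recoverable slopes", {
  d <- study_design(days = 12.5, mice_per_day = 1, events_per_sample = 100)
  expect_error(generate_study(d, default_populations()), "degenerate day range")
})

test_that("cross-over injection crosses analytically at day_star", {
  pops <- inject_crossover(default_populations(), "MP", "Neutrophil",
                           day_star = 14.0, compartment = "EV")
  nm <- vapply(pops, `[[`, character(1), "name")
  a <- pops[[match("MP", nm)]]; b <- pops[[match("Neutrophil", nm)]]
  expect_equal(abundance_at(a, 14.0, "EV"), abundance_at(b, 14.0, "EV"))
  expect_gt(abundance_at(a, 10.5, "EV"), abundance_at(b, 10.5, "EV"))
  expect_lt(abundance_at(a, 18.5, "EV"), abundance_at(b, 18.5, "EV"))
  expect_error(inject_crossover(default_populations(), "MP", "Neutrophil",
                                day_star = 25), "outside")
  expect_error(inject_crossover(default_populations(), "MP", "NoSuch",
                                day_star = 14), "existing")
})

test_that("re-estimated crossing day from realized fractions lands near day_star", {
  pops <- inject_crossover(default_populations(fetal = FALSE), "MP",
                           "Neutrophil", day_star = 14.0, compartment = "EV")
  d <- study_design(compartments = "EV", mice_per_day = 2,
                    events_per_sample = 5000, mouse_sd = 0.05,
                    dead_frac = 0, rbc_frac = 0, seed = 3)
  s <- generate_study(d, pops)
  fr <- s$truth$fractions
  fr$day <- s$metadata$day[match(fr$sample_id, s$metadata$sample_id)]
  fr <- fr[!is.na(fr$day), ]
  fit <- function(pop) stats::lm(fraction ~ day, data = fr[fr$population == pop, ])
  ca <- coef(fit("MP")); cb <- coef(fit("Neutrophil"))
  cross <- (ca[1] - cb[1]) / (cb[2] - ca[2])
  expect_lt(abs(cross - 14.0), 0.5)
})

test_that("perturbation multipliers renormalize as expected", {
  pops <- fixed_populations(c(A = 0.5, B = 0.5))
  # identity multiplier leaves expectations untouched
  p1 <- inject_perturbation(pops, list(A = 1.0))
  f_sal <- mficyto:::expected_fractions(p1, 12.5, "TIS", "SAL", c(1, 1))
  f_pic <- mficyto:::expected_fractions(p1, 12.5, "TIS", "PIC", c(1, 1))
  expect_equal(f_sal, f_pic)
  # 0.5x on one of two equal populations gives (1/3, 2/3)
  p2 <- inject_perturbation(pops, list(A = 0.5))
  f2 <- mficyto:::expected_fractions(p2, 12.5, "TIS", "PIC", c(1, 1))
  expect_equal(unname(f2), c(1 / 3, 2 / 3))
  expect_error(inject_perturbation(pops, list(A = -1)), "positive")
  expect_error(inject_perturbation(pops, list(Nope = 0.5)), "unknown")
})

test_that("batch distortion is monotone, skipped at identity, and measurable", {
  d <- tiny_design(batches = 2, seed = 4)
  s <- generate_study(d)
  same <- add_batch_effect(s$events, list(list(scale = 1, shift = 0),
                                          list(scale = 1, shift = 0)))
  expect_equal(as.data.frame(same), as.data.frame(s$events))
  dist <- add_batch_effect(s$events, list(NULL, list(scale = 1.2, shift = 0.3)))
  df0 <- as.data.frame(s$events); df1 <- as.data.frame(dist)
  b2 <- df0$batch == 2
  expect_identical(order(df0$Ly6C[b2]), order(df1$Ly6C[b2]))
  expect_equal(df0$Ly6C[!b2], df1$Ly6C[!b2])
  # the two batches' anchors (common material) are separated by the distortion
  a1 <- asinh(df1$CD68[df1$sample_id == "anchor_b1"] / 5)
  a2 <- asinh(df1$CD68[df1$sample_id == "anchor_b2"] / 5)
  expect_gt(suppressWarnings(stats::ks.test(a1, a2)$statistic), 0.2)
  expect_error(add_batch_effect(s$events, list(list(scale = -1, shift = 0))),
               "monotone")
})

test_that("leakage control sample carries the configured leaked fraction", {
  d <- study_design(days = 12.5, mice_per_day = 1, events_per_sample = 10000,
                    seed = 5)
  none <- simulate_leakage_mouse(d, 0)
  all_ <- simulate_leakage_mouse(d, 1)
  some <- simulate_leakage_mouse(d, 0.2)
  frac_above <- function(x) {
    ev <- arcsinh_transform(x$events)
    mean(as.data.frame(ev)$iCD45 >= 3.5)
  }
  expect_lt(frac_above(none), 0.01)
  expect_gt(frac_above(all_), 0.99)
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(frac_above(some) - 0.2), 3 * se)
  expect_error(simulate_leakage_mouse(d, 1.5), "fraction_leaked")
})
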