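# compositional statistics: fraction tables, Bray-Curtis, group comparison,
# Fisher discriminant, z-scores and cross-over detection, condition ratios

test_that("cell fractions count correctly and keep zero-count types", {
  ann <- data.frame(sample_id = "s1",
                    cell_type = c(rep("MP", 6), rep("Neutrophil", 4)))
  cf <- cell_fractions(ann, grouping = "sample_id",
                       types = c("MP", "Neutrophil", "B"))
  expect_equal(cf$fraction[cf$cell_type == "MP"], 0.6)
  expect_equal(cf$fraction[cf$cell_type == "Neutrophil"], 0.4)
  expect_equal(cf$count[cf$cell_type == "B"], 0L)
  expect_equal(sum(cf$fraction), 1, tolerance = 1e-9)
  # a group with an empty denominator is dropped with a warning
  ann2 <- data.frame(sample_id = c("s1", "s1", "s2"),
                     cell_type = c("MP", "MP", "Other"))
  expect_warning(cf2 <- cell_fractions(ann2, grouping = "sample_id",
                                       types = "MP"),
                 "empty denominator")
  expect_false("s2" %in% cf2$sample_id)
})

test_that("Bray-Curtis matches the formula, its bounds, and vegan", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(6, 2), c(2, 2)), 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(-1, 1), c(1, 1)), "nonnegative")
  brute <- function(u, v) {
    num <- 0; du <- 0; dv <- 0
    for (i in seq_along(u)) {
      num <- num + min(u[i], v[i]); du <- du + u[i]; dv <- dv + v[i]
    }
    1 - 2 * num / (du + dv)
  }
  set.seed(51)
  for (i in 1:200) {
    u <- rpois(8, 20); v <- rpois(8, 20)
    if (sum(u) + sum(v) == 0) next
    bc <- bray_curtis(u, v)
    expect_equal(bc, brute(u, v), tolerance = 1e-12)
    expect_equal(bc, bray_curtis(v, u))
    expect_gte(bc, 0); expect_lte(bc, 1)
    expect_equal(bc, unname(as.numeric(
      vegan::vegdist(rbind(u, v), method = "bray"))), tolerance = 1e-12)
  }
})

test_that("dissimilarity comparison reports fold change and a pooled t", {
  same <- dissimilarity_compare(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2))
  expect_equal(same$fold_change, 1)
  expect_equal(same$p_value, 1)
  fc <- dissimilarity_compare(c(0.2, 0.2, 0.2), c(0.4, 0.4, 0.4))
  expect_equal(fc$fold_change, 2)
  set.seed(52)
  a <- rnorm(8, 0.3, 0.05); b <- rnorm(10, 0.45, 0.05)
  res <- dissimilarity_compare(a, b)
  sp2 <- ((7) * var(a) + (9) * var(b)) / 16
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 8 + 1 / 10))
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 16), tolerance = 1e-9)
  expect_error(dissimilarity_compare(0.1, c(0.2, 0.3)), "at least 2")
})

test_that("Fisher discriminant matches the closed form and is label-symmetric", {
  set.seed(53)
  n <- 40
  x <- cbind(f1 = c(rnorm(n, 0, 1), rnorm(n, 1.5, 1)),
             f2 = c(rnorm(n, 0, 1), rnorm(n, 0, 1)))
  y <- rep(c("a", "b"), each = n)
  m <- lda_fit(x, y)
  # two-class direction is proportional to Sw^-1 (mu1 - mu0)
  Sw <- crossprod(sweep(x[y == "a", ], 2, colMeans(x[y == "a", ]))) +
    crossprod(sweep(x[y == "b", ], 2, colMeans(x[y == "b", ])))
  dir <- solve(Sw, colMeans(x[y == "b", ]) - colMeans(x[y == "a", ]))
  dir <- dir / sqrt(sum(dir^2))
  expect_equal(abs(sum(dir * m$scalings[, 1])), 1, tolerance = 1e-6)
  # permuting class labels leaves the subspace unchanged (up to sign)
  m2 <- lda_fit(x, ifelse(y == "a", "b", "a"))
  expect_equal(abs(sum(m2$scalings[, 1] * m$scalings[, 1])), 1,
               tolerance = 1e-9)
  # agreement with the reference implementation's discriminant direction
  ref <- MASS::lda(x, grouping = y)
  ref_dir <- ref$scaling[, 1] / sqrt(sum(ref$scaling[, 1]^2))
  expect_equal(abs(sum(ref_dir * m$scalings[, 1])), 1, tolerance = 1e-6)
  expect_error(lda_fit(x, rep("a", 2 * n)), "2 classes")
  expect_error(lda_fit(x[1:3, ], c("a", "b", "b")), "at least 2 samples")
})

test_that("projection of held-out samples lands near their class means", {
  fx <- make_fixtures("default-gestation", seed = 54, events_per_sample = 600)
  fr <- fx$truth$fractions
  md <- fx$metadata
  fr <- fr[!grepl("anchor", fr$sample_id), ]
  fr$compartment <- md$compartment[match(fr$sample_id, md$sample_id)]
  fm <- fraction_matrix(cbind(fr, cell_type = fr$population),
                        grouping = c("sample_id", "compartment"))
  m <- lda_fit(fm$matrix, fm$meta$compartment)
  proj <- m$projections
  sil <- cluster::silhouette(as.integer(factor(fm$meta$compartment)),
                             dist(proj))
  expect_gt(mean(sil[, "sil_width"]), 0)
  held <- lda_project(m, fm$matrix[1:3, , drop = FALSE])
  expect_equal(held, proj[1:3, , drop = FALSE])
})

test_that("z-scores standardize day means with the sample sd", {
  fr <- data.frame(day = rep(c(1, 2, 3), each = 2), compartment = "EV",
                   cell_type = "MP", fraction = rep(c(1, 2, 3), each = 2))
  z <- zscore_by_day(fr, "EV", "MP")
  expect_equal(z$z, c(-1, 0, 1))
  expect_equal(sum(z$z), 0, tolerance = 1e-9)
  expect_equal(sd(z$z), 1, tolerance = 1e-9)
  const <- data.frame(day = 1:3, compartment = "EV", cell_type = "MP",
                      fraction = 0.5)
  expect_error(zscore_by_day(const, "EV", "MP"), "zero variance")
})

test_that("cross-over detection finds sign changes and point crossings", {
  res <- detect_crossover(c(1, -1), c(-1, 1), days = c(13.5, 14.5))
  expect_equal(nrow(res), 1)
  expect_equal(c(res$day_lo, res$day_hi), c(13.5, 14.5))
  expect_equal(res$estimate, 14.0)
  none <- detect_crossover(c(1, 2), c(-1, 0), days = c(1, 2))
  expect_equal(nrow(none), 0)
  degen <- detect_crossover(c(1, 2, 3), c(1, 2, 3), days = 1:3)
  expect_equal(degen$type, rep("point", 3))
  expect_equal(degen$estimate, 1:3)
  asym <- detect_crossover(c(3, -1), c(0, 0), days = c(0, 1))
  expect_equal(asym$estimate, 0.75)
})

test_that("log2 condition ratios behave at identity and known shifts", {
  tr <- data.frame(sample_id = paste0("t", 1:4), cell_type = "MP",
                   fraction = c(0.2, 0.2, 0.2, 0.2))
  ct <- data.frame(sample_id = paste0("c", 1:4), cell_type = "MP",
                   fraction = c(0.1, 0.1, 0.1, 0.1))
  r <- log2_condition_ratio(tr, ct)
  expect_equal(r$log2_ratio, 1)
  same <- log2_condition_ratio(ct, ct)
  expect_equal(same$log2_ratio, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
})
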