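# Temporal inference: embryonic-day regression from composition with
# early/late windows, heteroskedasticity-robust trend regression (the
# singleton-cluster, independence-working-correlation GEE collapses to the
# HC0 sandwich), differential marker expression with Bonferroni correction,
# variance-aware ANOVA dispatch, and the Taylor-series ratio test.

EARLY_LATE_BOUNDARY <- 14  # early = E10.5-13.5, late = E14.5-18.5

#' Predict embryonic day from cell-type fractions
#'
#' Ordinary least squares of embryonic day on the fraction features, with
#' training R^2 and seeded k-fold cross-validated R^2 (per-fold
#' out-of-sample R^2 against the fold's own mean).
#'
#' @param x samples x cell-types fraction matrix.
#' @param day embryonic day per sample.
#' @param window "all", "early" (day < 14) or "late" (day > 14).
#' @param k number of CV folds (default 5).
#' @param seed fold-assignment seed.
#' @param ridge allow p >= n fits by ridge penalization.
#' @param lambda ridge penalty when `ridge = TRUE`.
#' @return list(coefficients, r2_train, cv_r2 (per-fold vector), window, n).
#' @export
fit_day_regression <- function(x, day, window = c("all", "early", "late"),
                               k = 5, seed = 1, ridge = FALSE, lambda = 1e-3) {
  window <- match.arg(window)
  x <- as.matrix(x)
  keep <- switch(window,
                 all = rep(TRUE, length(day)),
                 early = day < EARLY_LATE_BOUNDARY,
                 late = day > EARLY_LATE_BOUNDARY)
  x <- x[keep, , drop = FALSE]; day <- day[keep]
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples in the window")
  if (ncol(x) >= n && !ridge)
    stop("more features than samples; enable ridge = TRUE")
  fit_beta <- function(xt, yt) {
    X <- cbind(1, xt)
    if (ridge) {
      pen <- diag(c(0, rep(lambda, ncol(xt))))
      solve(crossprod(X) + pen, crossprod(X, yt))
    } else {
      # pivoted least squares: aliased columns (compositions sum to one, so
      # one fraction is always redundant) get coefficient zero
      b <- qr.coef(qr(X), yt)
      b[is.na(b)] <- 0
      b
    }
  }
  beta <- fit_beta(x, day)
  pred <- cbind(1, x) %*% beta
  r2_train <- 1 - sum((day - pred)^2) / sum((day - mean(day))^2)
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  cv <- vapply(seq_len(k), function(f) {
    tr <- folds != f; te <- !tr
    if (sum(te) == 0 || sum(tr) <= ncol(x)) return(NA_real_)
    b <- fit_beta(x[tr, , drop = FALSE], day[tr])
    ph <- cbind(1, x[te, , drop = FALSE]) %*% b
    sst <- sum((day[te] - mean(day[te]))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((day[te] - ph)^2) / sst
  }, numeric(1))
  list(coefficients = stats::setNames(as.vector(beta),
                                      c("(Intercept)", colnames(x))),
       r2_train = r2_train, cv_r2 = cv, window = window, n = n, k = k)
}

#' Compare predictability between two gestational windows
#'
#' Ratio of mean R^2 (window A over window B) and a pooled-variance
#' two-sample t test across the per-fold scores.
#'
#' @param scoresA,scoresB per-fold R^2 vectors, or [fit_day_regression()]
#'   results (their `cv_r2` is used).
#' @return list(ratio, mean_a, mean_b, t, df, p_value).
#' @export
compare_windows <- function(scoresA, scoresB) {
  if (is.list(scoresA)) scoresA <- scoresA$cv_r2
  if (is.list(scoresB)) scoresB <- scoresB$cv_r2
  scoresA <- scoresA[!is.na(scoresA)]; scoresB <- scoresB[!is.na(scoresB)]
  if (length(scoresA) < 2 || length(scoresB) < 2)
    stop("need at least 2 fold scores per window")
  cmp <- dissimilarity_compare(scoresA, scoresB)
  list(ratio = mean(scoresA) / mean(scoresB),
       mean_a = mean(scoresA), mean_b = mean(scoresB),
       t = cmp$t, df = cmp$df, p_value = cmp$p_value)
}

hc_sandwich <- function(X, e, type = c("HC0", "HC1")) {
  type <- match.arg(type)
  bread <- solve(crossprod(X))
  meat <- crossprod(X * e^2, X)  # X' diag(e^2) X
  V <- bread %*% meat %*% bread
  if (type == "HC1") V <- V * nrow(X) / (nrow(X) - ncol(X))
  V
}

#' Heteroskedasticity-robust trend regression
#'
#' OLS point estimates with the HC sandwich covariance
#' (X'X)^-1 X' diag(e^2) X (X'X)^-1 and Wald z p-values -- algebraically
#' the GEE with singleton clusters and an independence working correlation.
#' Compartment is coded with PB as the reference level so coefficients
#' compare each compartment against PB; day is mean-centered before squaring
#' to reduce collinearity of the optional quadratic term.
#'
#' @param data data.frame holding the response and covariates.
#' @param response response column name (a fraction or a median intensity).
#' @param day day column name, or NULL for compartment-only models.
#' @param compartment compartment column name, or NULL.
#' @param quadratic include a centered day-squared term.
#' @param interactions include day x compartment interactions.
#' @param hc "HC0" (default, the GEE-equivalent estimator) or "HC1".
#' @return list(tidy data.frame(term, estimate, se_robust, z, p_value),
#'   vcov, model (the lm fit)).
#' @export
robust_trend_fit <- function(data, response, day = "day",
                             compartment = "compartment",
                             quadratic = FALSE, interactions = FALSE,
                             hc = "HC0") {
  df <- as.data.frame(data)
  terms <- character()
  if (!is.null(day)) {
    df$.day_c <- df[[day]] - mean(df[[day]])
    terms <- c(terms, "day")
    df$day <- df$.day_c
    if (quadratic) {
      df$day2 <- df$.day_c^2
      terms <- c(terms, "day2")
    }
  }
  if (!is.null(compartment)) {
    df$compartment <- stats::relevel(factor(df[[compartment]]), ref = "PB")
    terms <- c(terms, "compartment")
    if (interactions && !is.null(day)) terms <- c(terms, "day:compartment")
  }
  if (length(terms) == 0) stop("no covariates requested")
  f <- stats::reformulate(terms, response = response)
  fit <- stats::lm(f, data = df)
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2) stop("need at least p + 2 observations")
  V <- hc_sandwich(X, stats::resid(fit), hc)
  se <- sqrt(diag(V))
  est <- stats::coef(fit)
  z <- est / se
  tidy <- data.frame(term = names(est), estimate = unname(est),
                     se_robust = unname(se), z = unname(z),
                     p_value = 2 * stats::pnorm(-abs(unname(z))),
                     stringsAsFactors = FALSE)
  list(tidy = tidy, vcov = V, model = fit, hc = hc)
}

#' Differential marker expression between two groups
#'
#' Per-marker pooled-variance two-sample t test on per-mouse median
#' intensities, Bonferroni-adjusted across markers; the significant set is
#' adjusted p <= 0.05. Markers with fewer than 2 mice in either group are
#' skipped with a warning.
#'
#' @param medians long data.frame: `mouse`, `group`, `marker`, `value`
#'   (per-mouse per-marker median intensity).
#' @param groupA,groupB the two levels of `group` to compare.
#' @return volcano data.frame(marker, mean_diff, t, p_value, p_adjusted,
#'   significant); mean_diff = mean(A) - mean(B).
#' @export
differential_expression <- function(medians, groupA, groupB) {
  markers <- unique(medians$marker)
  rows <- list(); skipped <- character()
  for (m in markers) {
    a <- medians$value[medians$marker == m & medians$group == groupA]
    b <- medians$value[medians$marker == m & medians$group == groupB]
    if (length(a) < 2 || length(b) < 2) {
      skipped <- c(skipped, m); next
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      t <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
      p <- if (t == 0) 1 else 0
    } else {
      ht <- stats::t.test(a, b, var.equal = TRUE)
      t <- unname(ht$statistic); p <- ht$p.value
    }
    rows[[length(rows) + 1]] <- data.frame(marker = m,
                                           mean_diff = mean(a) - mean(b),
                                           t = t, p_value = p)
  }
  if (length(skipped) > 0)
    warning("skipped markers with < 2 mice per group: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  out$significant <- out$p_adjusted <= 0.05
  out
}

#' Variance-aware one-way ANOVA dispatch with post hocs
#'
#' A Levene test (Brown-Forsythe, median-centered) decides between classic
#' ANOVA (equal variances; Tukey-HSD post hoc) and Welch ANOVA (unequal
#' variances, Welch-Satterthwaite df; Games-Howell post hoc). A group with
#' zero variance routes directly to the Welch branch.
#'
#' @param values numeric response.
#' @param groups group labels (>= 3 groups, each n >= 2).
#' @param alpha_levene variance-homogeneity cutoff (default 0.05).
#' @return list(method, levene_p, statistic, df, p_value, posthoc,
#'   posthoc_method).
#' @export
anova_dispatch <- function(values, groups, alpha_levene = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 3) stop("need at least 3 groups")
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  vars <- tapply(values, groups, stats::var)
  zero_var <- any(vars == 0)
  levene_p <- if (zero_var) NA_real_ else
    car::leveneTest(values, groups)[1, "Pr(>F)"]
  welch <- zero_var || (is.finite(levene_p) && levene_p < alpha_levene)
  if (all(vars == 0)) {
    # fully degenerate input: identical-variance, possibly identical-mean
    means <- tapply(values, groups, mean)
    eq <- length(unique(means)) == 1
    return(list(method = "welch", levene_p = levene_p,
                statistic = if (eq) 0 else Inf, df = c(nlevels(groups) - 1, NA),
                p_value = if (eq) 1 else 0, posthoc = NULL,
                posthoc_method = "games-howell"))
  }
  if (welch) {
    ht <- stats::oneway.test(values ~ groups, var.equal = FALSE)
    posthoc <- games_howell(values, groups)
    list(method = "welch", levene_p = levene_p,
         statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, posthoc = posthoc,
         posthoc_method = "games-howell")
  } else {
    fit <- stats::aov(values ~ groups)
    s <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    posthoc <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adjusted = tk[, "p adj"], row.names = NULL)
    list(method = "classic", levene_p = levene_p,
         statistic = s[1, "F value"], df = s[["Df"]],
         p_value = s[1, "Pr(>F)"], posthoc = posthoc,
         posthoc_method = "tukey-hsd")
  }
}

#' Games-Howell post hoc test
#'
#' Pairwise comparisons for unequal variances: Welch t statistics referred
#' to the studentized-range distribution with Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @return data.frame(comparison, diff, se, t, df, p_adjusted).
#' @export
games_howell <- function(values, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  k <- length(lev)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  n <- tapply(values, groups, length)
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se2 <- v[i] / n[i] + v[j] / n[j]
    se <- sqrt(se2)
    t <- (m[i] - m[j]) / se
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(abs(t) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    out[[length(out) + 1]] <- data.frame(
      comparison = paste(lev[j], lev[i], sep = "-"),
      diff = unname(m[j] - m[i]), se = unname(se), t = unname(t),
      df = unname(df), p_adjusted = unname(p))
  }
  do.call(rbind, out)
}

#' Taylor-series ratio of means with delta-method variance
#'
#' Ratio of arm means (treated over control) with its variance from the
#' Taylor expansion V(X/Y) = E(X^2) E(1/Y^2) - [E(X) E(1/Y)]^2 evaluated at
#' the sample moments; sd = sqrt(V). Control zeros are lifted by a declared
#' pseudo-count.
#'
#' @param counts_treated,counts_control per-mouse counts (n >= 2 each).
#' @param pseudo pseudo-count replacing control zeros (default 0.5, the
#'   conventional continuity correction; its use is messaged).
#' @return a `ratio_test` list: ratio, variance, sd, n.
#' @export
ratio_test <- function(counts_treated, counts_control, pseudo = 0.5) {
  x <- counts_treated; y <- counts_control
  if (length(x) < 2 || length(y) < 2) stop("both arms need n >= 2")
  if (any(y == 0)) {
    message("control zeros lifted by pseudo-count ", pseudo)
    y[y == 0] <- pseudo
  }
  if (mean(y) <= 0) stop("control mean must be positive")
  v <- mean(x^2) * mean(1 / y^2) - (mean(x) * mean(1 / y))^2
  v <- max(v, 0)
  structure(list(ratio = mean(x) / mean(y), variance = v, sd = sqrt(v),
                 n = min(length(x), length(y))),
            class = "ratio_test")
}

#' Compare two ratios by a t test from descriptive statistics
#'
#' Pooled-variance two-sample t computed from each ratio's point estimate,
#' Taylor-series sd and n (e.g., the day-12.5 vs day-14.5 treated/control
#' count ratios).
#'
#' @param r1,r2 `ratio_test` results.
#' @return list(t, df, p_value, diff).
#' @export
ratio_compare <- function(r1, r2) {
  n1 <- r1$n; n2 <- r2$n
  sp2 <- ((n1 - 1) * r1$variance + (n2 - 1) * r2$variance) / (n1 + n2 - 2)
  d <- r1$ratio - r2$ratio
  t <- if (sp2 == 0) {
    if (d == 0) 0 else Inf * sign(d)
  } else d / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df), diff = d)
}
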