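# Compositional statistics: cell-fraction tables, Bray-Curtis beta
# diversity, Fisher linear discriminant projection (control-train /
# perturbed-project mode), Z-score cross-over detection, and condition
# log-ratios.

#' Cell-fraction table
#'
#' Counts and fractions of cell types within groups (e.g., sample x
#' compartment), with the denominator declared. Types absent from a group
#' appear with count 0 and fraction 0; groups with an empty denominator are
#' dropped with a warning.
#'
#' @param annotations data.frame with one row per cell carrying the grouping
#'   columns and the cell-type column.
#' @param grouping character vector of grouping column names.
#' @param type_col cell-type column name.
#' @param types cell types to tabulate (default: all observed).
#' @param denominator free-text denominator declaration recorded on the
#'   result (e.g., "all immune cells in compartment").
#' @return long data.frame: grouping columns, cell_type, count, fraction;
#'   the denominator declaration in `attr(, "denominator")`.
#' @export
cell_fractions <- function(annotations, grouping, type_col = "cell_type",
                           types = NULL,
                           denominator = "all immune cells in group") {
  stopifnot(all(c(grouping, type_col) %in% names(annotations)))
  if (is.null(types)) types <- sort(unique(annotations[[type_col]]))
  key <- interaction(annotations[grouping], drop = TRUE, sep = "\r")
  tab <- table(key, factor(annotations[[type_col]], levels = types))
  totals <- rowSums(tab)
  if (any(totals == 0)) {
    warning("dropping ", sum(totals == 0), " group(s) with empty denominator")
    tab <- tab[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  keys <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  out <- data.frame(keys[rep(seq_len(nrow(tab)), ncol(tab)), , drop = FALSE],
                    stringsAsFactors = FALSE)
  names(out) <- grouping
  out$cell_type <- rep(colnames(tab), each = nrow(tab))
  out$count <- as.integer(as.vector(tab))
  out$fraction <- as.vector(tab / totals)
  for (g in grouping) {
    if (is.numeric(annotations[[g]])) out[[g]] <- as.numeric(out[[g]])
  }
  attr(out, "denominator") <- denominator
  out
}

#' Widen a cell-fraction table to a samples x types matrix
#'
#' @param fractions output of [cell_fractions()].
#' @param grouping the grouping columns identifying a row.
#' @param value "fraction" or "count".
#' @return list(matrix, meta): the numeric matrix and a data.frame of the
#'   grouping values per row.
#' @export
fraction_matrix <- function(fractions, grouping, value = c("fraction", "count")) {
  value <- match.arg(value)
  key <- interaction(fractions[grouping], drop = TRUE, sep = "\r")
  types <- sort(unique(fractions$cell_type))
  rows <- levels(key)
  mat <- matrix(0, nrow = length(rows), ncol = length(types),
                dimnames = list(rows, types))
  mat[cbind(match(key, rows), match(fractions$cell_type, types))] <-
    fractions[[value]]
  meta <- unique(fractions[grouping])
  meta <- meta[match(rows, interaction(meta[grouping], drop = TRUE, sep = "\r")), ,
               drop = FALSE]
  rownames(meta) <- NULL
  list(matrix = mat, meta = meta)
}

#' Bray-Curtis dissimilarity
#'
#' BC(u, v) = 1 - 2 * sum(min(u_i, v_i)) / (sum(u) + sum(v)), the
#' ecology-derived compositional distance with cell types in place of
#' species. Bounded in [0, 1]; 0 iff u = v, 1 for disjoint supports.
#'
#' @param u,v nonnegative count (or fraction) vectors on the same cell-type
#'   columns; not both all-zero.
#' @return scalar dissimilarity in [0, 1].
#' @export
bray_curtis <- function(u, v) {
  stopifnot(length(u) == length(v))
  if (any(u < 0) || any(v < 0)) stop("inputs must be nonnegative")
  tot <- sum(u) + sum(v)
  if (tot == 0) stop("both vectors are all-zero")
  1 - 2 * sum(pmin(u, v)) / tot
}

#' Pairwise Bray-Curtis between two compartments
#'
#' Computes Bray-Curtis values between the composition vectors of two
#' compartments, either pairing samples within mouse (matched design,
#' default) or across all cross-compartment pairs.
#'
#' @param mat samples x types numeric matrix (counts or fractions).
#' @param meta row metadata with `compartment` and `mouse` columns.
#' @param comp_a,comp_b the two compartments to compare.
#' @param pairing "mouse" or "all".
#' @return data.frame(pair_a, pair_b, dissimilarity).
#' @export
compartment_dissimilarity <- function(mat, meta, comp_a, comp_b,
                                      pairing = c("mouse", "all")) {
  pairing <- match.arg(pairing)
  ia <- which(meta$compartment == comp_a)
  ib <- which(meta$compartment == comp_b)
  if (pairing == "mouse") {
    common <- intersect(meta$mouse[ia], meta$mouse[ib])
    ia <- ia[match(common, meta$mouse[ia])]
    ib <- ib[match(common, meta$mouse[ib])]
    pairs <- cbind(ia, ib)
  } else {
    pairs <- as.matrix(expand.grid(ia, ib))
  }
  if (nrow(pairs) == 0) stop("no sample pairs between compartments")
  data.frame(pair_a = rownames(mat)[pairs[, 1]],
             pair_b = rownames(mat)[pairs[, 2]],
             dissimilarity = apply(pairs, 1, function(p)
               bray_curtis(mat[p[1], ], mat[p[2], ])))
}

#' Compare two groups of dissimilarity values
#'
#' Fold-change of the group means (group B over group A) and a pooled-
#' variance two-sample t test.
#'
#' @param groupA,groupB numeric vectors of pairwise dissimilarities (n >= 2
#'   each).
#' @return list(mean_a, mean_b, fold_change, t, df, p_value, n_a, n_b).
#' @export
dissimilarity_compare <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 values")
  ma <- mean(groupA); mb <- mean(groupB)
  n1 <- length(groupA); n2 <- length(groupB)
  sp2 <- ((n1 - 1) * stats::var(groupA) + (n2 - 1) * stats::var(groupB)) /
    (n1 + n2 - 2)
  if (sp2 == 0) {
    t <- if (ma == mb) 0 else Inf * sign(ma - mb)
  } else {
    t <- (ma - mb) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  list(mean_a = ma, mean_b = mb, fold_change = mb / ma,
       t = t, df = df, p_value = p, n_a = n1, n_b = n2)
}

#' Fisher linear discriminant fit on cell fractions
#'
#' Solves the generalized eigenproblem of between-class scatter against
#' pooled within-class scatter. The within-class scatter is ridge-
#' regularized by eps = 1e-8 * trace(Sw) / p so that few-sample,
#' many-fraction designs stay solvable. At most (classes - 1) axes are
#' returned; axis signs are fixed (largest-magnitude coefficient positive)
#' for determinism.
#'
#' @param x samples x features numeric matrix (cell fractions).
#' @param y class labels (>= 2 classes, each with >= 2 samples;
#'   n >= classes + 1).
#' @return an `mfi_lda` model: scalings (features x axes), center, class
#'   means (original and projected), training projections.
#' @export
lda_fit <- function(x, y) {
  x <- as.matrix(x); y <- factor(y)
  k <- nlevels(y); n <- nrow(x); p <- ncol(x)
  if (k < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  if (n < k + 1) stop("need at least classes + 1 samples")
  xbar <- colMeans(x)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (lev in levels(y)) {
    xi <- x[y == lev, , drop = FALSE]
    mi <- colMeans(xi)
    Sw <- Sw + crossprod(sweep(xi, 2, mi))
    Sb <- Sb + nrow(xi) * tcrossprod(mi - xbar)
  }
  eps <- 1e-8 * sum(diag(Sw)) / p
  if (eps == 0) eps <- 1e-12
  Sw_r <- Sw + diag(eps, p)
  eig <- eigen(solve(Sw_r, Sb))
  naxes <- min(k - 1, p)
  W <- Re(eig$vectors[, seq_len(naxes), drop = FALSE])
  # unit-norm columns, deterministic sign
  for (j in seq_len(ncol(W))) {
    W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  rownames(W) <- colnames(x)
  colnames(W) <- paste0("LD", seq_len(ncol(W)))
  proj <- sweep(x, 2, xbar) %*% W
  cm <- do.call(rbind, lapply(levels(y), function(lev)
    colMeans(proj[y == lev, , drop = FALSE])))
  rownames(cm) <- levels(y)
  structure(list(scalings = W, center = xbar, classes = levels(y),
                 class_means = cm, projections = proj, labels = y,
                 eigenvalues = Re(eig$values[seq_len(naxes)])),
            class = "mfi_lda")
}

#' @rdname lda_fit
#' @param model an `mfi_lda` model.
#' @param new_x held-out samples x features matrix (e.g., perturbed-arm
#'   fractions projected into the control-trained space).
#' @export
lda_project <- function(model, new_x) {
  new_x <- as.matrix(new_x)
  sweep(new_x[, rownames(model$scalings), drop = FALSE], 2, model$center) %*%
    model$scalings
}

#' Z-score a cell type's abundance across embryonic days
#'
#' Per-day mean fractions are standardized across days using the sample
#' (n - 1) standard deviation: z_d = (m_d - mean(m)) / sd(m).
#'
#' @param fractions long cell-fraction table with `day`, `compartment`,
#'   `cell_type`, `fraction` columns.
#' @param compartment compartment to score within.
#' @param cell_type cell type to score.
#' @return data.frame(day, mean_fraction, z), ordered by day.
#' @export
zscore_by_day <- function(fractions, compartment, cell_type) {
  sub <- fractions[fractions$compartment == compartment &
                     fractions$cell_type == cell_type, , drop = FALSE]
  if (nrow(sub) == 0) stop("no data for that compartment / cell type")
  m <- tapply(sub$fraction, sub$day, mean)
  days <- as.numeric(names(m))
  if (length(days) < 2) stop("need at least 2 days")
  s <- stats::sd(m)
  if (s == 0) stop("zero variance across days: z-score undefined")
  ord <- order(days)
  data.frame(day = days[ord], mean_fraction = as.vector(m)[ord],
             z = as.vector((m - mean(m)) / s)[ord])
}

#' Detect cross-over points between two z-score series
#'
#' Returns each consecutive day pair where sign(zA - zB) changes, with a
#' linearly interpolated crossing-day estimate; an exact-zero difference is
#' reported as a point crossing at that day. No crossing yields a
#' zero-row result (not an error).
#'
#' @param zA,zB numeric z-series on the same day grid.
#' @param days the day grid.
#' @return data.frame(day_lo, day_hi, estimate, type) with type "interval"
#'   or "point".
#' @export
detect_crossover <- function(zA, zB, days) {
  stopifnot(length(zA) == length(zB), length(zA) == length(days))
  d <- zA - zB
  out <- list()
  for (i in seq_along(days)) {
    if (d[i] == 0) {
      out[[length(out) + 1]] <- data.frame(day_lo = days[i], day_hi = days[i],
                                           estimate = days[i], type = "point")
    }
  }
  for (i in seq_len(length(days) - 1)) {
    if (d[i] != 0 && d[i + 1] != 0 && sign(d[i]) != sign(d[i + 1])) {
      est <- days[i] + (days[i + 1] - days[i]) * abs(d[i]) / (abs(d[i]) + abs(d[i + 1]))
      out[[length(out) + 1]] <- data.frame(day_lo = days[i], day_hi = days[i + 1],
                                           estimate = est, type = "interval")
    }
  }
  if (length(out) == 0)
    return(data.frame(day_lo = numeric(), day_hi = numeric(),
                      estimate = numeric(), type = character()))
  res <- do.call(rbind, out)
  res[order(res$day_lo), , drop = FALSE]
}

#' Per-cell-type log2 condition ratio (treated / control)
#'
#' log2 of the ratio of mean fractions, treated over control, per cell type,
#' with an uncorrected two-sample t test flag at p < 0.05. Zero mean control
#' fractions are lifted by a declared pseudo-fraction.
#'
#' @param fractions_treated,fractions_control long fraction tables
#'   (`sample_id`, `cell_type`, `fraction`) already restricted to one
#'   compartment.
#' @param pseudo pseudo-fraction added when a mean is zero; default half the
#'   smallest nonzero fraction observed.
#' @return data.frame(cell_type, mean_treated, mean_control, log2_ratio,
#'   p_value, significant).
#' @export
log2_condition_ratio <- function(fractions_treated, fractions_control,
                                 pseudo = NULL) {
  types <- sort(intersect(unique(fractions_treated$cell_type),
                          unique(fractions_control$cell_type)))
  if (is.null(pseudo)) {
    nz <- c(fractions_treated$fraction, fractions_control$fraction)
    nz <- nz[nz > 0]
    pseudo <- if (length(nz) > 0) min(nz) / 2 else 1e-6
  }
  rows <- lapply(types, function(ct) {
    a <- fractions_treated$fraction[fractions_treated$cell_type == ct]
    b <- fractions_control$fraction[fractions_control$cell_type == ct]
    ma <- mean(a); mb <- mean(b)
    ratio <- log2(max(ma, pseudo) / max(mb, pseudo))
    p <- if (length(a) >= 2 && length(b) >= 2 &&
             (stats::var(a) > 0 || stats::var(b) > 0)) {
      stats::t.test(a, b, var.equal = TRUE)$p.value
    } else if (ma == mb) 1 else NA_real_
    data.frame(cell_type = ct, mean_treated = ma, mean_control = mb,
               log2_ratio = ratio, p_value = p,
               significant = !is.na(p) & p < 0.05)
  })
  do.call(rbind, rows)
}
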