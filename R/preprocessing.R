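# Preprocessing: event reading, arcsinh transform, anchor-based quantile
# normalization across batches, capped subsampling.

#' Read event files into one event table
#'
#' Accepts FCS 3.x files and the gzip-compressed delimited dialect written by
#' [write_events_delim()]. Channels are aligned by name across files (the
#' first file fixes the order); events are concatenated with per-event
#' provenance joined from `metadata`.
#'
#' @param paths file paths, named by sample id.
#' @param metadata data.frame with one row per sample id (columns
#'   `sample_id`, `mouse`, `day`, `organ`, `batch`, `treatment`, optionally
#'   `anchor`).
#' @param rename_map optional named character vector mapping file channel
#'   names to panel names.
#' @param panel optional `panel_spec`; channels not in the panel are kept
#'   but flagged in `attr(, "unknown_channels")`.
#' @return a raw-state event table.
#' @export
read_events <- function(paths, metadata, rename_map = NULL, panel = NULL) {
  stopifnot(length(paths) >= 1, !is.null(names(paths)))
  missing_meta <- setdiff(names(paths), metadata$sample_id)
  if (length(missing_meta) > 0)
    stop("metadata row missing for sample(s): ", paste(missing_meta, collapse = ", "))
  read_one <- function(path) {
    con <- file(path, "rb"); magic <- readBin(con, "raw", 4); close(con)
    if (identical(rawToChar(magic), "FCS3")) read_fcs(path)
    else {
      df <- read_events_delim(path)
      as.matrix(df[, vapply(df, is.numeric, logical(1)), drop = FALSE])
    }
  }
  mats <- lapply(paths, read_one)
  mats <- lapply(mats, function(m) {
    if (!is.null(rename_map)) {
      hit <- colnames(m) %in% names(rename_map)
      colnames(m)[hit] <- rename_map[colnames(m)[hit]]
    }
    m
  })
  ref <- colnames(mats[[1]])
  for (i in seq_along(mats)) {
    if (!setequal(colnames(mats[[i]]), ref))
      stop("channel-name mismatch in ", paths[i],
           " (supply rename_map to reconcile)")
    mats[[i]] <- mats[[i]][, ref, drop = FALSE]
  }
  prov_cols <- intersect(c("sample_id", "mouse", "day", "organ", "batch",
                           "treatment", "anchor"), names(metadata))
  blocks <- lapply(seq_along(mats), function(i) {
    sid <- names(paths)[i]
    md <- metadata[match(sid, metadata$sample_id), prov_cols, drop = FALSE]
    cbind(md[rep(1, nrow(mats[[i]])), , drop = FALSE],
          as.data.frame(mats[[i]], check.names = FALSE))
  })
  df <- do.call(rbind, blocks)
  rownames(df) <- NULL
  out <- event_table(df, markers = ref, transformed = FALSE)
  if (!is.null(panel))
    attr(out, "unknown_channels") <- setdiff(ref, panel$channel)
  out
}

#' Arcsinh transform
#'
#' Replaces every raw intensity x by asinh(x / cofactor). A second transform
#' of already-transformed data is rejected.
#'
#' @param events raw-state event table.
#' @param cofactor arcsinh cofactor (default 5).
#' @return the transformed event table.
#' @export
arcsinh_transform <- function(events, cofactor = 5) {
  if (is_transformed(events))
    stop("events are already arcsinh-transformed")
  mk <- marker_names(events)
  df <- as.data.frame(events)
  df[mk] <- as.data.frame(asinh(as.matrix(df[mk]) / cofactor))
  event_table(df, mk, transformed = TRUE, cofactor = cofactor)
}

#' @rdname arcsinh_transform
#' @export
inverse_arcsinh <- function(events) {
  if (!is_transformed(events)) stop("events are not transformed")
  cf <- attr(events, "cofactor", exact = TRUE)
  mk <- marker_names(events)
  df <- as.data.frame(events)
  df[mk] <- as.data.frame(cf * sinh(as.matrix(df[mk])))
  event_table(df, mk, transformed = FALSE, cofactor = cf)
}

# monotone piecewise-linear interpolation through (xs, ys) knots; beyond the
# observed range the terminal segment's slope is extended so that the map
# stays strictly increasing (no extrapolation blow-up, no rank collapse)
interp_monotone <- function(x, xs, ys) {
  keep <- !duplicated(xs)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) == 1) return(x - xs + ys)
  y <- stats::approx(xs, ys, xout = x, rule = 2, ties = "ordered")$y
  m <- length(xs)
  sl_lo <- (ys[2] - ys[1]) / (xs[2] - xs[1])
  sl_hi <- (ys[m] - ys[m - 1]) / (xs[m] - xs[m - 1])
  if (!is.finite(sl_lo) || sl_lo <= 0) sl_lo <- 1
  if (!is.finite(sl_hi) || sl_hi <= 0) sl_hi <- 1
  lo <- x < xs[1]; hi <- x > xs[m]
  y[lo] <- ys[1] + (x[lo] - xs[1]) * sl_lo
  y[hi] <- ys[m] + (x[hi] - xs[m]) * sl_hi
  y
}

#' Anchor-based quantile normalization across batches
#'
#' Every batch carries one anchor sample of common material. For each batch
#' and marker, the monotone map sending the batch anchor's empirical
#' quantiles onto the reference batch anchor's quantiles (linear
#' interpolation between `n_quantiles` knots) is built and applied to all
#' events of that batch. The reference batch is passed through unchanged.
#' Operates on arcsinh-transformed values.
#'
#' @param events transformed event table with `batch` and `anchor` columns
#'   (or supply `anchor_sample_ids`).
#' @param anchor_sample_ids character vector of anchor sample ids, one per
#'   batch; defaults to samples flagged `anchor == TRUE`.
#' @param n_quantiles number of quantile knots (default 101).
#' @param reference_batch batch whose anchor defines the target distribution
#'   (default: lowest batch number).
#' @return list(events = normalized event table, map = long data.frame of
#'   knots: batch, marker, prob, source, reference).
#' @export
quantile_normalize <- function(events, anchor_sample_ids = NULL,
                               n_quantiles = 101, reference_batch = NULL) {
  stopifnot(is_transformed(events))
  df <- as.data.frame(events)
  mk <- marker_names(events)
  if (is.null(anchor_sample_ids)) {
    if (!"anchor" %in% names(df)) stop("no anchor flag and no anchor_sample_ids")
    anchor_sample_ids <- unique(df$sample_id[df$anchor])
  }
  batches <- sort(unique(df$batch))
  if (is.null(reference_batch)) reference_batch <- batches[1]
  anchor_batch <- vapply(anchor_sample_ids, function(s)
    df$batch[match(s, df$sample_id)], df$batch[1])
  for (b in batches) {
    ids <- anchor_sample_ids[anchor_batch == b]
    if (length(ids) != 1)
      stop("batch ", b, " must contain exactly one anchor sample")
  }
  probs <- seq(0, 1, length.out = n_quantiles)
  ref_anchor <- df[df$sample_id == anchor_sample_ids[anchor_batch == reference_batch], ,
                   drop = FALSE]
  if (nrow(ref_anchor) < n_quantiles)
    stop("reference anchor has fewer events than n_quantiles")
  maps <- list()
  for (b in batches) {
    if (b == reference_batch) next
    src_anchor <- df[df$sample_id == anchor_sample_ids[anchor_batch == b], , drop = FALSE]
    if (nrow(src_anchor) < n_quantiles)
      stop("anchor for batch ", b, " has fewer events than n_quantiles")
    rows <- df$batch == b
    for (m in mk) {
      qs <- stats::quantile(src_anchor[[m]], probs, names = FALSE, type = 7)
      qr <- stats::quantile(ref_anchor[[m]], probs, names = FALSE, type = 7)
      df[rows, m] <- interp_monotone(df[rows, m], qs, qr)
      maps[[length(maps) + 1]] <- data.frame(batch = b, marker = m, prob = probs,
                                             source = qs, reference = qr)
    }
  }
  map <- if (length(maps) > 0) do.call(rbind, maps)
         else data.frame(batch = integer(), marker = character(),
                         prob = numeric(), source = numeric(), reference = numeric())
  list(events = restore_event_table(df, events), map = map)
}

#' Subsample events per group with a cap
#'
#' Within each group (e.g., mouse x organ), retains min(cap, n) events
#' drawn uniformly without replacement ("up to cap" semantics), deterministic
#' under the seed.
#'
#' @param events event table.
#' @param per_group_cap maximum events retained per group (>= 1).
#' @param group_keys provenance column names defining the groups.
#' @param seed integer seed.
#' @return the subsampled event table (original row order preserved).
#' @export
subsample_events <- function(events, per_group_cap,
                             group_keys = c("mouse", "organ"), seed = 1) {
  stopifnot(per_group_cap >= 1)
  df <- as.data.frame(events)
  key <- interaction(df[group_keys], drop = TRUE)
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(df)), key), function(idx) {
      if (length(idx) <= per_group_cap) idx
      else sample(idx, per_group_cap)
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  restore_event_table(df[keep, , drop = FALSE], events)
}
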