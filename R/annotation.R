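# Clustering and annotation: graph-based community detection on a
# k-nearest-neighbor graph over a marker panel, cluster median profiles with
# min-max scaled display values, rule-driven metaclustering (merge / split /
# exclude), and canonical Ly-6C monocyte classes.

#' Clustering specification
#'
#' @param markers marker panel used to build the kNN graph.
#' @param k neighbor count (default 20, >= 2).
#' @param resolution community-detection resolution parameter.
#' @param backend backend identifier; "leiden" (default) and "louvain" are
#'   provided via igraph.
#' @param seed integer seed making the backend deterministic.
#' @return a `clustering_spec` list.
#' @export
clustering_spec <- function(markers, k = 20, resolution = 1,
                            backend = c("leiden", "louvain"), seed = 1) {
  backend <- match.arg(backend)
  if (k < 2) stop("neighbor count must be >= 2")
  structure(list(markers = markers, k = k, resolution = resolution,
                 backend = backend, seed = seed),
            class = "clustering_spec")
}

# exact kNN by chunked Euclidean distances (no kNN library dependency);
# returns an n x k index matrix
knn_index <- function(x, k, chunk = 512L) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  out <- matrix(0L, nrow = n, ncol = k)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    for (r in seq_along(idx)) {
      d2[r, idx[r]] <- Inf
      out[idx[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  out
}

#' Cluster events on a marker panel
#'
#' Builds a k-nearest-neighbor graph of the events in the panel's marker
#' space and partitions it by community detection (Leiden by default).
#' Deterministic under the spec's seed.
#'
#' @param events transformed event table.
#' @param spec a `clustering_spec`.
#' @return integer cluster labels, one per event.
#' @export
cluster_events <- function(events, spec) {
  stopifnot(inherits(spec, "clustering_spec"), is_transformed(events))
  missing <- setdiff(spec$markers, marker_names(events))
  if (length(missing) > 0)
    stop("panel markers absent: ", paste(missing, collapse = ", "))
  x <- as.matrix(as.data.frame(events)[, spec$markers, drop = FALSE])
  n <- nrow(x)
  if (n <= spec$k) stop("fewer events than the neighbor count")
  nn <- knn_index(x, spec$k)
  edges <- cbind(rep(seq_len(n), each = spec$k), as.vector(t(nn)))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  with_seed(spec$seed, {
    cl <- if (spec$backend == "leiden") {
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = spec$resolution, n_iterations = 5)
    } else {
      igraph::cluster_louvain(g, resolution = spec$resolution)
    }
    as.integer(igraph::membership(cl))
  })
}

#' Cluster median profiles with scaled display values
#'
#' Medians are computed per cluster and marker on the transformed scale; the
#' display matrix min-max scales each marker across clusters:
#' (value - min) / (max - min). A marker constant across clusters has zero
#' range; its scaled values are defined as 0 and the marker is listed in the
#' `degenerate` field.
#'
#' @param events transformed event table.
#' @param labels per-event cluster labels.
#' @param markers markers to profile (default: clustering panel order not
#'   known here, so all markers).
#' @param scaling "minmax" (default) or "none".
#' @return list(medians, scaled, counts, degenerate), matrices are
#'   clusters x markers.
#' @export
compute_cluster_profiles <- function(events, labels,
                                     markers = marker_names(events),
                                     scaling = c("minmax", "none")) {
  scaling <- match.arg(scaling)
  stopifnot(length(labels) == nrow(events))
  x <- as.data.frame(events)[, markers, drop = FALSE]
  labs <- sort(unique(labels))
  med <- t(vapply(labs, function(l)
    vapply(x[labels == l, , drop = FALSE], stats::median, numeric(1)),
    numeric(length(markers))))
  dimnames(med) <- list(as.character(labs), markers)
  counts <- as.integer(table(factor(labels, levels = labs)))
  if (any(counts == 0)) stop("empty cluster")
  degenerate <- character()
  scaled <- med
  if (scaling == "minmax") {
    for (m in markers) {
      rng <- range(med[, m])
      if (diff(rng) == 0) {
        scaled[, m] <- 0
        degenerate <- c(degenerate, m)
      } else {
        scaled[, m] <- (med[, m] - rng[1]) / diff(rng)
      }
    }
  }
  list(medians = med, scaled = scaled,
       counts = stats::setNames(counts, as.character(labs)),
       degenerate = degenerate)
}

#' Min-max scale a vector
#'
#' (value - min) / (max - min); a zero-range input returns all zeros with a
#' `degenerate` attribute set.
#' @param x numeric vector.
#' @export
minmax_scale <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(structure(rep(0, length(x)), degenerate = TRUE))
  (x - rng[1]) / diff(rng)
}

#' Metacluster fine clusters into lineage labels
#'
#' Exclusion rules are applied first: clusters whose scaled medians are all
#' above `exclude_high` ("broad expression of all markers", doublet-like) or
#' all below `exclude_low` (all-negative) are dropped. Remaining cluster
#' median profiles are merged by agglomerative (average-linkage)
#' hierarchical clustering with Euclidean or correlation distance, cut at
#' `cut_height`; manual rules then override in order.
#'
#' @param profiles output of [compute_cluster_profiles()].
#' @param metric "euclidean" or "correlation".
#' @param cut_height tree cut height.
#' @param manual_rules list of rules, each
#'   `list(type = "merge", clusters = c(...), label = "...")` or
#'   `list(type = "exclude", clusters = c(...), reason = "...")`.
#' @param exclude_high,exclude_low scaled-median quantile bounds for the
#'   automatic doublet-like / all-negative exclusions.
#' @return a `metacluster_map`: data.frame(cluster, metacluster, excluded,
#'   reason) with the replayable rule records in `attr(, "rules")`.
#' @export
metacluster <- function(profiles, metric = c("euclidean", "correlation"),
                        cut_height = 3, manual_rules = list(),
                        exclude_high = 0.9, exclude_low = 0.1) {
  metric <- match.arg(metric)
  med <- profiles$medians; sc <- profiles$scaled
  if (nrow(med) == 0) stop("no cluster profiles")
  cl_ids <- rownames(med)
  rules <- list()
  excluded <- rep(FALSE, nrow(med)); reason <- rep(NA_character_, nrow(med))
  hi <- apply(sc, 1, function(r) all(r > exclude_high))
  lo <- apply(sc, 1, function(r) all(r < exclude_low))
  excluded[hi] <- TRUE; reason[hi] <- "broad-positive (doublet-like)"
  excluded[lo] <- TRUE; reason[lo] <- "all-negative"
  for (i in which(hi | lo))
    rules[[length(rules) + 1]] <- list(type = "exclude", clusters = cl_ids[i],
                                       reason = reason[i])
  keep <- !excluded
  lab <- rep(NA_character_, nrow(med))
  if (sum(keep) == 1) {
    lab[keep] <- "M1"
  } else if (sum(keep) > 1) {
    d <- if (metric == "euclidean") stats::dist(med[keep, , drop = FALSE])
         else stats::as.dist(1 - stats::cor(t(med[keep, , drop = FALSE])))
    hc <- stats::hclust(d, method = "average")
    grp <- stats::cutree(hc, h = cut_height)
    lab[keep] <- paste0("M", grp)
    rules[[length(rules) + 1]] <- list(type = "merge_tree", metric = metric,
                                       cut_height = cut_height,
                                       assignment = stats::setNames(lab[keep], cl_ids[keep]))
  }
  # manual overrides, in order; a cluster named in two merge rules with
  # different target labels is a conflict
  assign_tab <- list()
  for (r in Filter(function(r) r$type == "merge", manual_rules)) {
    for (cl in as.character(r$clusters)) {
      if (!is.null(assign_tab[[cl]]) && !identical(assign_tab[[cl]], r$label))
        stop("conflicting manual rules: cluster ", cl, " merged into two labels")
      assign_tab[[cl]] <- r$label
    }
  }
  seen <- stats::setNames(lab, cl_ids)
  for (r in manual_rules) {
    if (r$type == "merge") {
      seen[as.character(r$clusters)] <- r$label
    } else if (r$type == "exclude") {
      i <- match(as.character(r$clusters), cl_ids)
      excluded[i] <- TRUE
      reason[i] <- if (!is.null(r$reason)) r$reason else "manual"
      seen[as.character(r$clusters)] <- NA_character_
    }
    rules[[length(rules) + 1]] <- r
  }
  map <- data.frame(cluster = cl_ids, metacluster = unname(seen),
                    excluded = excluded, reason = reason,
                    stringsAsFactors = FALSE)
  structure(map, rules = rules, class = c("metacluster_map", class(map)))
}

#' Apply a metacluster map to per-event cluster labels
#'
#' Replaying a saved map's assignments onto the same clustering reproduces
#' identical metacluster labels; excluded clusters map to NA.
#'
#' @param map a `metacluster_map`.
#' @param labels per-event cluster labels.
#' @return character vector of metacluster labels (NA = excluded).
#' @export
apply_metacluster <- function(map, labels) {
  map$metacluster[match(as.character(labels), map$cluster)]
}

#' Serialize / read a metacluster map as a human-readable rules table
#'
#' @param map a `metacluster_map`.
#' @param path output TSV path.
#' @export
write_metacluster_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_metacluster_map
#' @export
read_metacluster_map <- function(path) {
  map <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(cluster = "character"))
  structure(map, class = c("metacluster_map", class(map)))
}

#' Split one cluster at a marker threshold
#'
#' Events of `cluster` with `marker` at or above `cutoff` go to the positive
#' branch, the rest to the negative branch (the FceRI = 1 basophil /
#' eosinophil split is the canonical use).
#'
#' @param events transformed event table.
#' @param labels per-event cluster/metacluster labels.
#' @param cluster label to split.
#' @param marker marker name.
#' @param cutoff arcsinh threshold (default 1, boundary inclusive on the
#'   positive branch).
#' @param pos_label,neg_label names for the two branches.
#' @return updated label vector.
#' @export
split_by_threshold <- function(events, labels, cluster, marker, cutoff = 1,
                               pos_label = paste0(cluster, "+"),
                               neg_label = paste0(cluster, "-")) {
  stopifnot(is_transformed(events), length(labels) == nrow(events))
  x <- as.data.frame(events)[[marker]]
  labels <- as.character(labels)
  in_cl <- labels == as.character(cluster)
  labels[in_cl] <- ifelse(x[in_cl] >= cutoff, pos_label, neg_label)
  labels
}

#' Canonical Ly-6C monocyte classes
#'
#' arcsinh Ly-6C at or above 4.5 is classical; at or above 3 but below 4.5 is
#' intermediate; below 3 is non-classical. Boundaries inclusive exactly as
#' stated.
#'
#' @param ly6c_values arcsinh-transformed Ly-6C values (per-event or
#'   per-cluster medians).
#' @return character vector of classes.
#' @export
classify_monocytes_canonical <- function(ly6c_values) {
  ifelse(ly6c_values >= 4.5, "classical",
         ifelse(ly6c_values >= 3, "intermediate", "non-classical"))
}
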