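# clustering backend, cluster profiles, metaclustering rules, threshold
# splits, canonical monocyte classes

test_that("well-separated blobs cluster cleanly; one blob stays one cluster", {
  set.seed(41)
  n <- 300
  chans <- c("A", "B")
  blob <- function(center, n) data.frame(A = rnorm(n, center[1], 0.3),
                                         B = rnorm(n, center[2], 0.3))
  df <- rbind(blob(c(0, 0), n), blob(c(10, 10), n))
  df <- cbind(data.frame(sample_id = "s", mouse = "m", day = 1, organ = "PB",
                         batch = 1, treatment = "SAL"), df)
  ev <- event_table(df, chans, transformed = TRUE)
  # the blobs are disconnected components of the kNN graph, so a low
  # resolution keeps each intact while they can never merge
  lab <- cluster_events(ev, clustering_spec(chans, k = 15, resolution = 0.01,
                                            seed = 2))
  expect_equal(length(unique(lab)), 2)
  truth <- rep(1:2, each = n)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1)
  # determinism under the seed
  lab2 <- cluster_events(ev, clustering_spec(chans, k = 15, resolution = 0.01,
                                             seed = 2))
  expect_identical(lab, lab2)
  one <- event_table(cbind(df[seq_len(n), 1:6], blob(c(0, 0), n)), chans,
                     transformed = TRUE)
  lab1 <- cluster_events(one, clustering_spec(chans, k = 15, resolution = 0.01,
                                              seed = 2))
  expect_equal(length(unique(lab1)), 1)
  expect_error(cluster_events(one, clustering_spec(chans, k = 500, seed = 1)),
               "fewer events")
})

test_that("cluster profiles: medians, min-max scaling, degenerate markers", {
  df <- data.frame(sample_id = "s", mouse = "m", day = 1, organ = "PB",
                   batch = 1, treatment = "SAL",
                   M1 = c(1, 2, 9, 2, 4, 6), M2 = rep(7, 6))
  ev <- event_table(df, c("M1", "M2"), transformed = TRUE)
  lab <- rep(c("a", "b"), each = 3)
  prof <- compute_cluster_profiles(ev, lab, c("M1", "M2"))
  expect_equal(prof$medians["a", "M1"], 2)
  expect_equal(prof$medians["b", "M1"], 4)
  expect_equal(prof$degenerate, "M2")
  expect_true(all(prof$scaled[, "M2"] == 0))
  expect_equal(unname(minmax_scale(c(2, 4, 6))), c(0, 0.5, 1))
  expect_true(attr(minmax_scale(c(3, 3)), "degenerate"))
})

test_that("metaclustering merges identical profiles and replays exactly", {
  med <- rbind(c1 = c(A = 5, B = 0.5, C = 0.4),
               c2 = c(A = 5, B = 0.5, C = 0.4),
               c3 = c(A = 0.4, B = 5, C = 0.5))
  prof <- list(medians = med,
               scaled = apply(med, 2, function(x) (x - min(x)) / diff(range(x))),
               counts = c(c1 = 10, c2 = 10, c3 = 10), degenerate = character())
  map <- metacluster(prof, cut_height = 0.5)
  expect_equal(map$metacluster[map$cluster == "c1"],
               map$metacluster[map$cluster == "c2"])
  expect_false(map$metacluster[map$cluster == "c3"] ==
                 map$metacluster[map$cluster == "c1"])
  labels <- c("c1", "c2", "c3", "c1")
  replay <- apply_metacluster(map, labels)
  path <- tempfile(fileext = ".tsv")
  write_metacluster_map(map, path)
  map2 <- read_metacluster_map(path)
  expect_equal(apply_metacluster(map2, labels), replay)
  # conflicting manual merges are rejected
  expect_error(metacluster(prof, cut_height = 0.5, manual_rules = list(
    list(type = "merge", clusters = "c1", label = "X"),
    list(type = "merge", clusters = "c1", label = "Y"))), "conflicting")
})

test_that("broad-positive and all-negative clusters are excluded by rule", {
  med <- rbind(good = c(A = 5, B = 0.4), doublet = c(A = 6, B = 6),
               neg = c(A = 0.1, B = 0.1))
  scaled <- rbind(good = c(A = 0.83, B = 0.05), doublet = c(A = 1, B = 1),
                  neg = c(A = 0, B = 0))
  prof <- list(medians = med, scaled = scaled,
               counts = c(good = 5, doublet = 5, neg = 5),
               degenerate = character())
  map <- metacluster(prof, cut_height = 0.5)
  expect_true(map$excluded[map$cluster == "doublet"])
  expect_match(map$reason[map$cluster == "doublet"], "broad-positive")
  expect_true(map$excluded[map$cluster == "neg"])
  expect_false(map$excluded[map$cluster == "good"])
  expect_true(is.na(apply_metacluster(map, "doublet")))
})

test_that("over-clustering is repaired to one label per ground-truth population", {
  fx <- clustering_fixture(seed = 44, events_per_sample = 600, cap = 150)
  spec <- clustering_spec(lineage_markers(), k = 20, resolution = 3, seed = 3)
  lab <- cluster_events(fx$events, spec)
  expect_gt(length(unique(lab)), length(unique(fx$truth)))
  prof <- compute_cluster_profiles(fx$events, lab, lineage_markers())
  map <- metacluster(prof)
  meta <- apply_metacluster(map, lab)
  keep <- !is.na(meta)
  expect_gte(mclust::adjustedRandIndex(meta[keep], fx$truth[keep]), 0.99)
  expect_equal(length(unique(meta[keep])), length(unique(fx$truth)))
})

test_that("threshold split is boundary-inclusive (FceRI basophil rule)", {
  df <- data.frame(sample_id = "s", mouse = "m", day = 1, organ = "PB",
                   batch = 1, treatment = "SAL",
                   FceRI = c(1.0, 0.0, 2.5, 0.99))
  ev <- event_table(df, "FceRI", transformed = TRUE)
  lab <- split_by_threshold(ev, rep("BasoEos", 4), "BasoEos", "FceRI",
                            cutoff = 1, pos_label = "Basophil",
                            neg_label = "Eosinophil")
  expect_equal(lab, c("Basophil", "Eosinophil", "Basophil", "Eosinophil"))
  # recovered split fraction on a mixed synthetic cluster (3 binomial SE)
  set.seed(45)
  n <- 5000; pos_frac <- 0.3
  pos <- runif(n) < pos_frac
  mix <- data.frame(sample_id = "s", mouse = "m", day = 1, organ = "PB",
                    batch = 1, treatment = "SAL",
                    FceRI = ifelse(pos, rnorm(n, 4.5, 0.5), rnorm(n, 0.3, 0.25)))
  evm <- event_table(mix, "FceRI", transformed = TRUE)
  labm <- split_by_threshold(evm, rep("c", n), "c", "FceRI", cutoff = 1)
  expect_lt(abs(mean(labm == "c+") - pos_frac), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("canonical Ly-6C monocyte classes match the quoted cutoffs", {
  expect_equal(classify_monocytes_canonical(c(4.9, 4.5, 3.0, 2.99, 0)),
               c("classical", "classical", "intermediate", "non-classical",
                 "non-classical"))
})

test_that("composition tables are invariant to cluster-id relabeling", {
  fx <- clustering_fixture(seed = 46, events_per_sample = 400, cap = 100)
  ann <- as.data.frame(fx$events)[c("sample_id", "mouse")]
  ann$cell_type <- fx$truth
  cf1 <- cell_fractions(ann, grouping = "sample_id")
  perm <- sample(unique(fx$truth))
  names(perm) <- unique(fx$truth)
  ann2 <- ann; ann2$cell_type <- unname(perm[ann$cell_type])
  cf2 <- cell_fractions(ann2, grouping = "sample_id")
  cf2$cell_type <- names(perm)[match(cf2$cell_type, perm)]
  cf2 <- cf2[order(cf2$sample_id, cf2$cell_type), ]
  cf1 <- cf1[order(cf1$sample_id, cf1$cell_type), ]
  rownames(cf1) <- rownames(cf2) <- NULL
  expect_equal(cf1, cf2, ignore_attr = TRUE)
})
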