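# Configuration-driven orchestration of the stages in processing order
# (simulate -> transform/normalize -> gate -> cluster -> quantify -> model),
# with a run manifest, plus canned fixture scenarios for tests and examples.

#' Pipeline configuration
#'
#' @param design a `study_design` for the synthetic input.
#' @param populations population list (default [default_populations()]).
#' @param gate a `gate_config`.
#' @param cluster_markers marker panel for the main clustering round.
#' @param cluster_resolution community-detection resolution.
#' @param subsample_cap per mouse x organ cap before clustering.
#' @param stages character subset of c("gate", "cluster", "quantify",
#'   "model"); later stages require the earlier ones.
#' @param out_dir output directory for the delimited tables (created).
#' @param seed seed propagated to every stochastic stage.
#' @return validated `pipeline_config`.
#' @export
pipeline_config <- function(design = study_design(),
                            populations = default_populations(),
                            gate = gate_config(),
                            cluster_markers = NULL,
                            cluster_resolution = 0.4,
                            subsample_cap = 500,
                            stages = c("gate", "cluster", "quantify", "model"),
                            out_dir = tempfile("mfi_run_"),
                            seed = 1) {
  order <- c("gate", "cluster", "quantify", "model")
  stages <- intersect(order, stages)
  need <- match(stages, order)
  if (length(need) > 0 && !identical(need, seq_len(max(need))))
    stop("stage dependency violated: ", paste(order[setdiff(seq_len(max(need)), need)],
                                              collapse = ", "), " must be enabled")
  if (is.null(cluster_markers))
    cluster_markers <- default_panel()$channel[default_panel()$role == "lineage"]
  structure(list(design = design, populations = populations, gate = gate,
                 cluster_markers = cluster_markers,
                 cluster_resolution = cluster_resolution,
                 subsample_cap = subsample_cap, stages = stages,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

stage_row <- function(stage, rows_in, rows_out, note = "") {
  data.frame(stage = stage, rows_in = rows_in, rows_out = rows_out,
             note = note, stringsAsFactors = FALSE)
}

#' Run the end-to-end pipeline on a synthetic study
#'
#' Executes the enabled stages in processing order, writing every table to
#' `out_dir` and recording a manifest (config hash, per-stage row counts).
#' Re-running with an identical config reproduces identical outputs.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, list(manifest, tables = named list of the in-memory
#'   results, out_dir).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  tables <- list()

  study <- generate_study(config$design, config$populations)
  manifest[[1]] <- stage_row("simulate", 0, nrow(study$events))
  ev <- arcsinh_transform(study$events)
  if (config$design$batches > 1) {
    qn <- quantile_normalize(ev)
    ev <- qn$events
    utils::write.table(qn$map, file.path(config$out_dir, "quantile_map.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest[[length(manifest) + 1]] <- stage_row("normalize", nrow(ev), nrow(ev))
  }
  tables$metadata <- study$metadata

  ann <- NULL
  if ("gate" %in% config$stages) {
    ann <- annotate_events(ev, config$gate)
    ann$truth_population <- study$truth$events$population
    manifest[[length(manifest) + 1]] <-
      stage_row("gate", nrow(ev), sum(ann$viable), note = "viable events")
    utils::write.table(ann, file.path(config$out_dir, "annotations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  labels <- NULL; keep_idx <- NULL
  if ("cluster" %in% config$stages) {
    keep_idx <- which(ann$viable & ann$origin == "maternal" &
                        ann$compartment %in% c("PB", "EV", "TIS"))
    sub <- restore_event_table(as.data.frame(ev)[keep_idx, , drop = FALSE], ev)
    sub <- subsample_events(sub, config$subsample_cap,
                            group_keys = c("mouse", "organ"), seed = config$seed)
    spec <- clustering_spec(config$cluster_markers, k = 20,
                            resolution = config$cluster_resolution,
                            seed = config$seed)
    labels <- cluster_events(sub, spec)
    prof <- compute_cluster_profiles(sub, labels, config$cluster_markers)
    map <- metacluster(prof)
    meta_labels <- apply_metacluster(map, labels)
    tables$clustered <- cbind(as.data.frame(sub),
                              cluster = labels, metacluster = meta_labels)
    write_metacluster_map(map, file.path(config$out_dir, "metacluster_map.tsv"))
    manifest[[length(manifest) + 1]] <-
      stage_row("cluster", nrow(sub), length(unique(labels)), note = "clusters")
    # annotate clustered events with their ground-truth-free metacluster id;
    # downstream composition uses the per-event gate annotation + cluster id
    sub_ann <- annotate_events(sub, config$gate)
    tables$clustered$compartment <- sub_ann$compartment
  }

  comp <- NULL
  if ("quantify" %in% config$stages) {
    viable_ann <- ann[ann$viable & ann$origin == "maternal" &
                        ann$compartment %in% c("PB", "EV", "TIS"), , drop = FALSE]
    viable_ann$cell_type <- viable_ann$truth_population
    comp <- cell_fractions(viable_ann,
                           grouping = c("sample_id", "mouse", "day",
                                        "treatment", "compartment"),
                           denominator = "all immune cells in compartment")
    tables$composition <- comp
    utils::write.table(comp, file.path(config$out_dir, "composition.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest[[length(manifest) + 1]] <-
      stage_row("quantify", nrow(viable_ann), nrow(comp))
  }

  if ("model" %in% config$stages) {
    fm <- fraction_matrix(comp, c("sample_id", "mouse", "day", "treatment",
                                  "compartment"))
    # beta diversity between compartments, paired within mouse
    bc <- rbind(
      cbind(pair = "EV-PB",
            compartment_dissimilarity(fm$matrix, fm$meta, "EV", "PB")),
      cbind(pair = "EV-TIS",
            compartment_dissimilarity(fm$matrix, fm$meta, "EV", "TIS")))
    tables$dissimilarity <- bc
    utils::write.table(bc, file.path(config$out_dir, "dissimilarity.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    # discriminant projection of compartments from composition
    lda <- lda_fit(fm$matrix, fm$meta$compartment)
    coefs <- data.frame(feature = rownames(lda$scalings), lda$scalings,
                        row.names = NULL)
    tables$lda <- lda
    utils::write.table(coefs, file.path(config$out_dir, "lda_coefficients.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    # robust gestational trends per cell type
    trends <- list()
    for (ct in colnames(fm$matrix)) {
      dat <- cbind(fm$meta, fraction = fm$matrix[, ct])
      fit <- robust_trend_fit(dat, "fraction")
      trends[[ct]] <- cbind(cell_type = ct, fit$tidy)
    }
    trends <- do.call(rbind, trends)
    rownames(trends) <- NULL
    tables$trends <- trends
    utils::write.table(trends, file.path(config$out_dir, "trend_fits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    # day regression within the endovascular compartment
    ev_rows <- fm$meta$compartment == "EV"
    dayreg <- fit_day_regression(fm$matrix[ev_rows, , drop = FALSE],
                                 fm$meta$day[ev_rows], seed = config$seed,
                                 ridge = ncol(fm$matrix) >= sum(ev_rows))
    tables$day_regression <- dayreg
    manifest[[length(manifest) + 1]] <- stage_row("model", nrow(fm$matrix),
                                                  nrow(trends))
  }

  manifest <- do.call(rbind, manifest)
  manifest <- cbind(config_hash = config_hash(config), manifest)
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest, tables = tables, out_dir = config$out_dir))
}

#' Build a canned fixture scenario
#'
#' Small, seeded synthetic datasets with ground truth for the test suite and
#' examples.
#'
#' @param scenario one of "default-gestation", "crossover-at-14",
#'   "perturbation", "leakage-mouse", "batch-distortion".
#' @param seed integer seed.
#' @param events_per_sample per-sample event count override.
#' @return list with at least `events`, `metadata`, `truth` (contents vary
#'   by scenario).
#' @export
make_fixtures <- function(scenario = c("default-gestation", "crossover-at-14",
                                       "perturbation", "leakage-mouse",
                                       "batch-distortion"),
                          seed = 1, events_per_sample = 1000) {
  scenario <- match.arg(scenario)
  switch(scenario,
    "default-gestation" = {
      d <- study_design(events_per_sample = events_per_sample, seed = seed)
      generate_study(d)
    },
    "crossover-at-14" = {
      pops <- inject_crossover(default_populations(), "MP", "Neutrophil",
                               day_star = 14.0, compartment = "EV")
      d <- study_design(events_per_sample = events_per_sample, seed = seed)
      generate_study(d, pops)
    },
    "perturbation" = {
      pops <- inject_perturbation(default_populations(),
                                  list(MP = c(EV = 0.5, TIS = 0.5)))
      d <- study_design(days = c(12.5, 14.5), mice_per_day = 4,
                        treatment_arms = c("SAL", "PIC"),
                        events_per_sample = events_per_sample, seed = seed)
      generate_study(d, pops)
    },
    "leakage-mouse" = {
      d <- study_design(days = c(12.5, 13.5), mice_per_day = 2,
                        events_per_sample = events_per_sample, seed = seed)
      study <- generate_study(d)
      leak <- simulate_leakage_mouse(d, fraction_leaked = 0.2)
      study$leakage <- leak
      study$truth$leaky_mouse <- leak$metadata$mouse[1]
      study
    },
    "batch-distortion" = {
      d <- study_design(days = c(12.5, 14.5), mice_per_day = 2, batches = 2,
                        events_per_sample = events_per_sample, seed = seed)
      study <- generate_study(d)
      bp <- list(NULL, list(scale = 1.2, shift = 0.3))
      study$events <- add_batch_effect(study$events, bp)
      study$truth$batch_params <- bp
      study
    })
}
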