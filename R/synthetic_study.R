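# Synthetic CyTOF study generation.
#
# Each (day, mouse, compartment) sample draws population counts from a
# multinomial over the clipped, renormalized abundance models (with
# per-mouse log-scale random intercepts), then draws per-event marker values
# from the population archetype: Gaussian on the arcsinh(./cofactor) scale,
# inverse-transformed to raw counts and floored at zero. Gating-utility
# channels are set from ground truth so the rule-based gates are exactly
# recoverable up to the configured channel noise.

#' Study design
#'
#' @param days strictly increasing embryonic days (default E10.5-18.5).
#' @param mice_per_day mice per day per treatment arm.
#' @param compartments subset of c("PB", "EV", "TIS").
#' @param events_per_sample events drawn per (day, mouse, compartment) sample.
#' @param treatment_arms "SAL" alone, or c("SAL", "PIC") for a perturbation
#'   study (PIC = poly(I:C) viral mimic).
#' @param batches number of staining/acquisition batches; mice are assigned
#'   round-robin and every batch receives one splenocyte anchor sample of
#'   common material.
#' @param anchor_events events per anchor sample.
#' @param mouse_sd sd of the per-mouse log-scale random intercept on
#'   population fractions.
#' @param dead_frac,rbc_frac fractions of cisplatin-positive (dead) events
#'   and Ter119-positive erythrocyte contaminants per sample.
#' @param ev_icd45_mean,tis_icd45_mean,icd45_sd arcsinh-scale injected-CD45
#'   channel locations for endovascular/blood vs. tissue events.
#' @param seed integer RNG seed; identical seeds give identical studies.
#' @return a validated `study_design` list.
#' @export
study_design <- function(days = seq(10.5, 18.5, by = 1),
                         mice_per_day = 3,
                         compartments = c("PB", "EV", "TIS"),
                         events_per_sample = 2000,
                         treatment_arms = "SAL",
                         batches = 1,
                         anchor_events = 2000,
                         mouse_sd = 0.15,
                         dead_frac = 0.02,
                         rbc_frac = 0.02,
                         ev_icd45_mean = 6.0,
                         tis_icd45_mean = 0.5,
                         icd45_sd = 0.5,
                         seed = 1) {
  if (is.unsorted(days, strictly = TRUE)) stop("days must be strictly increasing")
  if (events_per_sample <= 0) stop("events_per_sample must be positive")
  if (!all(compartments %in% c("PB", "EV", "TIS"))) stop("unknown compartment")
  if (!all(treatment_arms %in% c("SAL", "PIC"))) stop("treatment arms are SAL / PIC")
  if (batches < 1) stop("need at least one batch")
  stopifnot(dead_frac >= 0, dead_frac < 1, rbc_frac >= 0, rbc_frac < 1)
  structure(list(days = days, mice_per_day = mice_per_day,
                 compartments = compartments,
                 events_per_sample = events_per_sample,
                 treatment_arms = treatment_arms, batches = batches,
                 anchor_events = anchor_events, mouse_sd = mouse_sd,
                 dead_frac = dead_frac, rbc_frac = rbc_frac,
                 ev_icd45_mean = ev_icd45_mean, tis_icd45_mean = tis_icd45_mean,
                 icd45_sd = icd45_sd, seed = seed),
            class = "study_design")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

draw_archetype <- function(pop, n, channels, cofactor = 5) {
  mu <- archetype_means(pop, channels)
  sd <- archetype_sds(pop, channels)
  z <- matrix(stats::rnorm(n * length(channels)), nrow = n) %*% diag(sd, length(sd))
  z <- sweep(z, 2, mu, "+")
  colnames(z) <- channels
  z
}

utility_overrides <- function(z, truth, design) {
  n <- nrow(z)
  z[, "DNA"] <- stats::rnorm(n, 5.5, 0.3)
  z[, "Viability"] <- ifelse(truth$dead, stats::rnorm(n, 4.5, 0.5), stats::rnorm(n, 0.5, 0.4))
  z[, "Ter119"] <- ifelse(truth$rbc, stats::rnorm(n, 5.0, 0.5), stats::rnorm(n, 0.4, 0.3))
  z[, "CD45.2"] <- ifelse(truth$rbc, stats::rnorm(n, 0.4, 0.3), stats::rnorm(n, 5.5, 0.4))
  z[, "CD45.1"] <- ifelse(!truth$rbc & truth$origin == "fetal",
                          stats::rnorm(n, 5.0, 0.5), stats::rnorm(n, 0.4, 0.3))
  ev_like <- truth$compartment %in% c("PB", "EV")
  z[, "iCD45"] <- ifelse(ev_like,
                         stats::rnorm(n, design$ev_icd45_mean, design$icd45_sd),
                         stats::rnorm(n, design$tis_icd45_mean, design$icd45_sd))
  z
}

expected_fractions <- function(populations, day, compartment, arm, mouse_eff) {
  f <- vapply(seq_along(populations), function(i) {
    pop <- populations[[i]]
    a <- abundance_at(pop, day, compartment)
    if (arm == "PIC") a <- a * pic_multiplier_for(pop, compartment)
    a * mouse_eff[i]
  }, numeric(1))
  names(f) <- pop_names(populations)
  if (all(f <= 0))
    stop("configuration error: no population has positive expected fraction at day ",
         day, " in ", compartment)
  f / sum(f)
}

#' Generate a synthetic multi-sample CyTOF study
#'
#' @param design a `study_design`.
#' @param populations list of `population_spec` (default
#'   [default_populations()]).
#' @param panel a `panel_spec` (default [default_panel()]).
#' @param cofactor arcsinh cofactor of the generative scale.
#' @return list with `events` (raw-scale event table), `metadata`
#'   (per-sample design table) and `truth` (per-event labels, the realized
#'   per-sample fraction table over viable immune events, and any configured
#'   cross-over / perturbation ground truth).
#' @export
generate_study <- function(design, populations = default_populations(),
                           panel = default_panel(), cofactor = 5) {
  stopifnot(inherits(design, "study_design"))
  channels <- panel$channel
  if (length(design$days) == 1) {
    slopes <- unlist(lapply(populations, function(p)
      vapply(p$abundance, function(a) abs(a[["slope"]]) + abs(a[["quad"]]), numeric(1))))
    if (any(slopes > 0))
      stop("degenerate day range: a single day cannot identify nonzero day trends")
  }
  with_seed(design$seed, {
    blocks <- list(); meta <- list(); truths <- list()
    bi <- 0L
    mouse_counter <- 0L
    for (arm in design$treatment_arms) {
      for (day in design$days) {
        for (m in seq_len(design$mice_per_day)) {
          mouse_counter <- mouse_counter + 1L
          mouse <- sprintf("m%03d", mouse_counter)
          batch <- ((mouse_counter - 1L) %% design$batches) + 1L
          mouse_eff <- exp(stats::rnorm(length(populations), 0, design$mouse_sd))
          for (comp in design$compartments) {
            f <- expected_fractions(populations, day, comp, arm, mouse_eff)
            n <- design$events_per_sample
            n_rbc <- stats::rbinom(1, n, design$rbc_frac)
            n_imm <- n - n_rbc
            counts <- as.vector(stats::rmultinom(1, n_imm, f))
            sample_id <- sprintf("%s_E%.1f_%s_%s", mouse, day, comp, arm)
            organ <- if (comp == "PB") "PB" else "placenta"
            pop_idx <- rep(seq_along(populations), counts)
            dead <- stats::runif(n_imm) < design$dead_frac
            truth <- data.frame(
              sample_id = sample_id,
              population = c(pop_names(populations)[pop_idx], rep("RBC", n_rbc)),
              origin = c(vapply(populations[pop_idx], `[[`, character(1), "origin"),
                         rep("other", n_rbc)),
              compartment = comp,
              batch = batch, treatment = arm,
              dead = c(dead, rep(FALSE, n_rbc)),
              rbc = c(rep(FALSE, n_imm), rep(TRUE, n_rbc)),
              stringsAsFactors = FALSE)
            truth$viable <- !truth$dead & !truth$rbc
            z <- matrix(0, nrow = n, ncol = length(channels),
                        dimnames = list(NULL, channels))
            for (i in unique(pop_idx)) {
              rows <- which(c(pop_idx, rep(NA, n_rbc)) == i)
              z[rows, ] <- draw_archetype(populations[[i]], length(rows), channels)
            }
            if (n_rbc > 0) {
              rbc_rows <- n_imm + seq_len(n_rbc)
              z[rbc_rows, ] <- matrix(stats::rnorm(n_rbc * length(channels), 0.3, 0.3),
                                      nrow = n_rbc)
            }
            z <- utility_overrides(z, truth, design)
            raw <- pmax(cofactor * sinh(z), 0)
            bi <- bi + 1L
            blocks[[bi]] <- data.frame(
              sample_id = sample_id, mouse = mouse, day = day, organ = organ,
              batch = batch, treatment = arm, anchor = FALSE,
              raw, check.names = FALSE, stringsAsFactors = FALSE)
            truths[[bi]] <- truth
            meta[[bi]] <- data.frame(sample_id = sample_id, mouse = mouse,
                                     day = day, organ = organ,
                                     compartment = comp, batch = batch,
                                     treatment = arm, anchor = FALSE,
                                     stringsAsFactors = FALSE)
          }
        }
      }
    }
    # one splenocyte anchor of common material per batch
    spleen_f <- c(B = 0.55, CD4T = 0.15, CD8T = 0.10, NK = 0.05,
                  Neutrophil = 0.08, MP = 0.04, Eosinophil = 0.02, Basophil = 0.01)
    spleen_f <- spleen_f[intersect(names(spleen_f), pop_names(populations))]
    if (length(spleen_f) > 0) {
      spleen_f <- spleen_f / sum(spleen_f)
      for (b in seq_len(design$batches)) {
        n <- design$anchor_events
        idx <- match(names(spleen_f), pop_names(populations))
        counts <- as.vector(stats::rmultinom(1, n, spleen_f))
        pop_idx <- rep(idx, counts)
        sample_id <- sprintf("anchor_b%d", b)
        truth <- data.frame(sample_id = sample_id,
                            population = pop_names(populations)[pop_idx],
                            origin = "maternal", compartment = "n/a",
                            batch = b, treatment = "SAL",
                            dead = FALSE, rbc = FALSE, viable = TRUE,
                            stringsAsFactors = FALSE)
            truth$compartment <- "TIS"  # spleen not injected: low iCD45
        z <- matrix(0, nrow = n, ncol = length(channels),
                    dimnames = list(NULL, channels))
        for (i in unique(pop_idx)) {
          rows <- which(pop_idx == i)
          z[rows, ] <- draw_archetype(populations[[i]], length(rows), channels)
        }
        z <- utility_overrides(z, truth, design)
        truth$compartment <- "n/a"
        raw <- pmax(cofactor * sinh(z), 0)
        bi <- bi + 1L
        blocks[[bi]] <- data.frame(sample_id = sample_id, mouse = sample_id,
                                   day = NA_real_, organ = "spleen",
                                   batch = b, treatment = "SAL", anchor = TRUE,
                                   raw, check.names = FALSE, stringsAsFactors = FALSE)
        truths[[bi]] <- truth
        meta[[bi]] <- data.frame(sample_id = sample_id, mouse = sample_id,
                                 day = NA_real_, organ = "spleen",
                                 compartment = "n/a", batch = b,
                                 treatment = "SAL", anchor = TRUE,
                                 stringsAsFactors = FALSE)
      }
    }
    events <- do.call(rbind, blocks)
    truth <- do.call(rbind, truths)
    metadata <- do.call(rbind, meta)
    rownames(events) <- rownames(truth) <- rownames(metadata) <- NULL
    ev <- event_table(events, markers = channels, transformed = FALSE,
                      cofactor = cofactor)
    frac <- realized_fractions(truth)
    list(events = ev, metadata = metadata,
         truth = list(events = truth, fractions = frac,
                      crossover = attr(populations, "crossover"),
                      arm_effects = attr(populations, "arm_effects")))
  })
}

# realized per-sample fractions over viable immune events
realized_fractions <- function(truth) {
  keep <- truth$viable & truth$population != "RBC"
  t2 <- truth[keep, , drop = FALSE]
  tab <- table(t2$sample_id, t2$population)
  frac <- prop.table(tab, margin = 1)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("sample_id", "population", "count")
  out$fraction <- as.data.frame(frac)$Freq
  out
}

#' Apply a per-batch monotone intensity distortion
#'
#' Distortions are affine on the arcsinh scale: y' = scale * y + shift with
#' scale > 0 (strictly monotone). Anchor samples are distorted with their
#' batch, exactly like every other sample in it.
#'
#' @param events raw-scale event table with a `batch` column.
#' @param batch_params list indexed by batch number, each
#'   `list(scale =, shift =)` (scalars, or per-marker named vectors).
#' @param cofactor arcsinh cofactor on which the distortion operates.
#' @return the distorted event table.
#' @export
add_batch_effect <- function(events, batch_params, cofactor = 5) {
  stopifnot(!is_transformed(events))
  mk <- marker_names(events)
  df <- as.data.frame(events)
  for (b in seq_along(batch_params)) {
    bp <- batch_params[[b]]
    if (is.null(bp)) next
    if (any(bp$scale <= 0)) stop("non-monotone distortion: scale must be > 0")
    if (isTRUE(all(bp$scale == 1)) && isTRUE(all(bp$shift == 0))) next
    rows <- df$batch == b
    if (!any(rows)) next
    scale <- if (length(bp$scale) == 1) rep(bp$scale, length(mk)) else bp$scale[mk]
    shift <- if (length(bp$shift) == 1) rep(bp$shift, length(mk)) else bp$shift[mk]
    x <- as.matrix(df[rows, mk, drop = FALSE])
    y <- asinh(x / cofactor)
    y <- sweep(sweep(y, 2, scale, "*"), 2, shift, "+")
    df[rows, mk] <- pmax(cofactor * sinh(y), 0)
  }
  restore_event_table(df, events)
}

#' Simulate a lymph-node leakage-control sample
#'
#' Emits one lymph-node sample in which `fraction_leaked` of the events carry
#' injected-CD45 at the endovascular level (the injected antibody reached the
#' node), the remainder at the protected-tissue level.
#'
#' @param design a `study_design` (events_per_sample and channel noise reused).
#' @param fraction_leaked in [0, 1].
#' @param populations,panel as in [generate_study()].
#' @param mouse mouse id for the control sample.
#' @return list(events, metadata, truth) for the single LN sample.
#' @export
simulate_leakage_mouse <- function(design, fraction_leaked,
                                   populations = default_populations(fetal = FALSE),
                                   panel = default_panel(), mouse = "leaky01") {
  if (fraction_leaked < 0 || fraction_leaked > 1)
    stop("fraction_leaked must be in [0, 1]")
  channels <- panel$channel
  with_seed(design$seed + 7901L, {
    n <- design$events_per_sample
    f <- expected_fractions(populations, design$days[1], "PB", "SAL",
                            rep(1, length(populations)))
    counts <- as.vector(stats::rmultinom(1, n, f))
    pop_idx <- rep(seq_along(populations), counts)
    sample_id <- paste0(mouse, "_LN")
    leaked <- stats::runif(n) < fraction_leaked
    truth <- data.frame(sample_id = sample_id,
                        population = pop_names(populations)[pop_idx],
                        origin = "maternal",
                        compartment = ifelse(leaked, "PB", "TIS"),
                        batch = 1L, treatment = "SAL",
                        dead = FALSE, rbc = FALSE, viable = TRUE,
                        leaked = leaked, stringsAsFactors = FALSE)
    z <- matrix(0, nrow = n, ncol = length(channels),
                dimnames = list(NULL, channels))
    for (i in unique(pop_idx)) {
      rows <- which(pop_idx == i)
      z[rows, ] <- draw_archetype(populations[[i]], length(rows), channels)
    }
    z <- utility_overrides(z, truth, design)
    truth$compartment <- "n/a"
    raw <- pmax(5 * sinh(z), 0)
    events <- event_table(
      data.frame(sample_id = sample_id, mouse = mouse, day = design$days[1],
                 organ = "LN", batch = 1L, treatment = "SAL", anchor = FALSE,
                 raw, check.names = FALSE, stringsAsFactors = FALSE),
      markers = channels, transformed = FALSE, cofactor = 5)
    metadata <- data.frame(sample_id = sample_id, mouse = mouse,
                           day = design$days[1], organ = "LN",
                           compartment = "n/a", batch = 1L, treatment = "SAL",
                           anchor = FALSE, stringsAsFactors = FALSE)
    list(events = events, metadata = metadata, truth = truth)
  })
}
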