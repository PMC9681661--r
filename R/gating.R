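# Rule-based gating: DNA+/live/Ter119- viability, congenic origin
# assignment, endovascular vs. tissue compartment at the injected-antibody
# threshold, and antibody-leakage QC. All gates are pure functions of
# arcsinh-scale intensities plus the configuration.

#' Gating configuration
#'
#' All thresholds are on the arcsinh(./5) scale. Any of the viability-gate
#' thresholds may be the string "auto", in which case the valley of a
#' two-component Gaussian mixture fitted to the channel is used (falling
#' back to the numeric default with a warning if the channel looks
#' unimodal).
#'
#' @param dna,viability,ter119,cd45_1,cd45_2,icd45 channel names.
#' @param dna_min DNA-intercalator threshold (events above are DNA+).
#' @param viability_max cisplatin threshold (events below are live).
#' @param ter119_max erythrocyte-exclusion threshold.
#' @param cd45_min positivity threshold shared by CD45.1 / CD45.2.
#' @param ev_threshold injected-CD45 endovascular cutoff; events at or above
#'   it in placental samples are endovascular (default 3.5).
#' @param leakage_threshold maximal tolerated fraction of lymph-node events
#'   above `ev_threshold` before a mouse is flagged (default 0.05).
#' @return a `gate_config` list.
#' @export
gate_config <- function(dna = "DNA", viability = "Viability", ter119 = "Ter119",
                        cd45_1 = "CD45.1", cd45_2 = "CD45.2", icd45 = "iCD45",
                        dna_min = 2, viability_max = 2, ter119_max = 2,
                        cd45_min = 2, ev_threshold = 3.5,
                        leakage_threshold = 0.05) {
  if (!is.numeric(ev_threshold) || ev_threshold <= 0)
    stop("ev_threshold must be a positive number")
  structure(list(dna = dna, viability = viability, ter119 = ter119,
                 cd45_1 = cd45_1, cd45_2 = cd45_2, icd45 = icd45,
                 dna_min = dna_min, viability_max = viability_max,
                 ter119_max = ter119_max, cd45_min = cd45_min,
                 ev_threshold = ev_threshold,
                 leakage_threshold = leakage_threshold),
            class = "gate_config")
}

#' Valley of a two-component Gaussian mixture
#'
#' Fits a two-component unequal-variance mixture and returns the density
#' minimum between the component means. Used by the "auto" threshold mode.
#'
#' @param x numeric channel values.
#' @param default fallback threshold when the fit fails or the components
#'   are not separated.
#' @return a scalar threshold.
#' @export
fit_gate_valley <- function(x, default) {
  fit <- tryCatch({
    # Mclust() resolves helper functions in the caller's scope, which fails
    # when mclust is imported but not attached; evaluate inside an
    # environment parented by the mclust namespace instead
    env <- new.env(parent = asNamespace("mclust"))
    assign("x_", x, envir = env)
    eval(quote(Mclust(x_, G = 2, modelNames = "V", verbose = FALSE)), env)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixture fit failed; using default threshold ", default)
    return(default)
  }
  mu <- fit$parameters$mean
  sd <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sd) == 1) sd <- rep(sd, 2)
  if (abs(diff(mu)) < 2 * mean(sd)) {
    warning("channel looks unimodal; using default threshold ", default)
    return(default)
  }
  dens <- function(t) {
    p <- fit$parameters$pro
    p[1] * stats::dnorm(t, mu[1], sd[1]) + p[2] * stats::dnorm(t, mu[2], sd[2])
  }
  stats::optimize(dens, interval = sort(mu))$minimum
}

resolve_threshold <- function(thr, x, default) {
  if (identical(thr, "auto")) fit_gate_valley(x, default) else thr
}

#' Viability gate
#'
#' viable = DNA above threshold AND cisplatin below threshold AND Ter119
#' below threshold (erythrocytes excluded).
#'
#' @param events transformed event table.
#' @param config a `gate_config`.
#' @return data.frame with per-event logical columns `dna_pos`, `live`,
#'   `not_rbc`, `viable`.
#' @export
gate_viable <- function(events, config = gate_config()) {
  stopifnot(is_transformed(events))
  df <- as.data.frame(events)
  dna_thr <- resolve_threshold(config$dna_min, df[[config$dna]], 2)
  via_thr <- resolve_threshold(config$viability_max, df[[config$viability]], 2)
  ter_thr <- resolve_threshold(config$ter119_max, df[[config$ter119]], 2)
  dna_pos <- df[[config$dna]] > dna_thr
  live <- df[[config$viability]] < via_thr
  not_rbc <- df[[config$ter119]] < ter_thr
  data.frame(dna_pos = dna_pos, live = live, not_rbc = not_rbc,
             viable = dna_pos & live & not_rbc)
}

#' Congenic origin assignment
#'
#' maternal = CD45.2 above threshold and CD45.1 below (single positive);
#' fetal = CD45.2 and CD45.1 both above (double positive); other = remainder.
#'
#' @param events transformed event table.
#' @param config a `gate_config`.
#' @return character vector of origins per event.
#' @export
assign_origin <- function(events, config = gate_config()) {
  stopifnot(is_transformed(events))
  df <- as.data.frame(events)
  p2 <- df[[config$cd45_2]] > config$cd45_min
  p1 <- df[[config$cd45_1]] > config$cd45_min
  ifelse(p2 & !p1, "maternal", ifelse(p2 & p1, "fetal", "other"))
}

#' Endovascular vs. tissue compartment assignment
#'
#' For maternal events from placental samples: injected-CD45 arcsinh
#' intensity at or above the threshold (boundary inclusive, default 3.5)
#' means endovascular (EV); below means tissue-resident (TIS). Maternal PB
#' events are labeled PB regardless. Fetal and other events, and events from
#' non-placental, non-PB organs, get "n/a" -- the injected-antibody rule
#' applies only to maternal cells.
#'
#' @param events transformed event table with an `organ` column.
#' @param origin per-event origin from [assign_origin()].
#' @param config a `gate_config`.
#' @return character vector: "PB", "EV", "TIS" or "n/a".
#' @export
assign_compartment <- function(events, origin, config = gate_config()) {
  if (!is_transformed(events))
    stop("assign_compartment requires arcsinh-transformed events")
  df <- as.data.frame(events)
  stopifnot(length(origin) == nrow(df))
  comp <- rep("n/a", nrow(df))
  maternal <- origin == "maternal"
  comp[maternal & df$organ == "PB"] <- "PB"
  plc <- maternal & df$organ == "placenta"
  comp[plc] <- ifelse(df[[config$icd45]][plc] >= config$ev_threshold, "EV", "TIS")
  comp
}

#' Full per-event annotation
#'
#' Runs the viability, origin and compartment gates in order. Origin is
#' reported only for viable events ("n/a" otherwise), compartment only for
#' viable maternal events.
#'
#' @inheritParams assign_compartment
#' @return data.frame: viable, origin, compartment (one row per event).
#' @export
annotate_events <- function(events, config = gate_config()) {
  v <- gate_viable(events, config)
  origin <- assign_origin(events, config)
  origin[!v$viable] <- "n/a"
  comp <- assign_compartment(events, origin, config)
  cbind(as.data.frame(events)[c("sample_id", "mouse", "day", "organ",
                                "batch", "treatment")],
        data.frame(viable = v$viable, origin = origin, compartment = comp,
                   stringsAsFactors = FALSE))
}

#' Antibody-leakage QC on a lymph-node control sample
#'
#' The injected antibody must not reach the lymph node; a mouse whose LN
#' immune events score at or above the EV threshold more often than the
#' leakage threshold is failed and should be excluded from all downstream
#' tables.
#'
#' @param ln_events transformed event table of the mouse's LN sample (may be
#'   pre-filtered to viable events); `NULL` or zero rows returns
#'   pass-with-warning.
#' @param config a `gate_config`.
#' @return list(status = "pass"/"fail", fraction_above = observed fraction).
#' @export
qc_leakage <- function(ln_events, config = gate_config()) {
  if (is.null(ln_events) || nrow(ln_events) == 0) {
    warning("no lymph-node control sample; leakage QC passes by default")
    return(list(status = "pass", fraction_above = NA_real_))
  }
  stopifnot(is_transformed(ln_events))
  x <- as.data.frame(ln_events)[[config$icd45]]
  frac <- mean(x >= config$ev_threshold)
  list(status = if (frac > config$leakage_threshold) "fail" else "pass",
       fraction_above = frac)
}
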