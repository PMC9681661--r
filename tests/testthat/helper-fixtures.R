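# shared small fixtures built in code

tiny_design <- function(..., seed = 1) {
  study_design(days = c(12.5, 14.5), mice_per_day = 2,
               events_per_sample = 500, seed = seed, ...)
}

# a hand-built transformed event table for boundary/rule tests
rule_events <- function(values) {
  chans <- default_panel()$channel
  df <- as.data.frame(matrix(0.3, nrow = nrow(values), ncol = length(chans),
                             dimnames = list(NULL, chans)))
  for (ch in names(values)) df[[ch]] <- values[[ch]]
  df <- cbind(data.frame(sample_id = "s1", mouse = "m1", day = 12.5,
                         organ = if ("organ" %in% names(values)) values$organ
                                 else "placenta",
                         batch = 1L, treatment = "SAL",
                         stringsAsFactors = FALSE),
              df[setdiff(names(df), "organ")])
  event_table(df, markers = chans, transformed = TRUE, cofactor = 5)
}

# fixed fraction populations with flat abundance (for multinomial oracles)
fixed_populations <- function(fracs, compartment = "TIS") {
  lapply(seq_along(fracs), function(i) {
    ab <- list(c(fracs[i], 0, 0))
    names(ab) <- compartment
    population_spec(names(fracs)[i], "maternal",
                    positive = stats::setNames(4.5, default_panel()$channel[i]),
                    abundance = ab)
  })
}

# truth-labelled maternal events, transformed, for clustering tests
clustering_fixture <- function(seed = 5, events_per_sample = 800,
                               populations = default_populations(fetal = FALSE),
                               cap = 200) {
  d <- study_design(days = c(12.5, 14.5), mice_per_day = 3,
                    events_per_sample = events_per_sample, seed = seed,
                    dead_frac = 0, rbc_frac = 0)
  s <- generate_study(d, populations)
  ev <- arcsinh_transform(s$events)
  tt <- s$truth$events
  idx <- which(tt$origin %in% c("maternal", "fetal") & !s$metadata$anchor[
    match(tt$sample_id, s$metadata$sample_id)])
  df <- as.data.frame(ev)[idx, , drop = FALSE]
  sub <- event_table(df, marker_names(ev), transformed = TRUE, cofactor = 5)
  sub <- subsample_events(sub, cap, group_keys = c("mouse", "organ"), seed = seed)
  keep <- match(rownames(as.data.frame(sub)), rownames(as.data.frame(ev)))
  list(events = sub, truth = tt$population[keep])
}

lineage_markers <- function() {
  p <- default_panel()
  p$channel[p$role == "lineage"]
}
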