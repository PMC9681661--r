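# Panel and population specifications for the synthetic study generator.
#
# Marker archetypes live on the arcsinh(./5) scale; generation draws
# Gaussian values there and inverse-transforms to raw counts. Abundance
# models are per-compartment polynomials in embryonic day, parameterized
# around a fixed reference day (mid-gestation of the E10.5-18.5 window):
#   fraction(day) = intercept + slope * (day - 14.5) + quad * (day - 14.5)^2
# clipped at zero and renormalized within each sample.

DAY_REF <- 14.5
GATING_UTILITY <- c("DNA", "Viability", "CD45.1", "CD45.2", "iCD45", "Ter119")

#' Panel specification
#'
#' @param markers data.frame with columns `channel` and `role`
#'   (one of "lineage", "function", "utility"). The gating-utility channels
#'   DNA, Viability, CD45.1, CD45.2 and iCD45 (the injected antibody) must
#'   be present.
#' @return the validated panel data.frame, class `panel_spec`.
#' @export
panel_spec <- function(markers) {
  stopifnot(is.data.frame(markers), all(c("channel", "role") %in% names(markers)))
  if (anyDuplicated(markers$channel))
    stop("channel names must be unique")
  if (!all(markers$role %in% c("lineage", "function", "utility")))
    stop("roles must be lineage / function / utility")
  need <- setdiff(setdiff(GATING_UTILITY, "Ter119"), markers$channel)
  if (length(need) > 0)
    stop("gating-utility channels missing from panel: ", paste(need, collapse = ", "))
  structure(markers, class = c("panel_spec", class(markers)))
}

#' Default ~30-channel CyTOF-like panel
#'
#' Lineage channels mirror a murine immune phenotyping panel (Ly-6G, CD11c,
#' TCRb, F4/80, CD3, IgD, IgM, CD19, CD8, CD11b, Ly-6C, FceRI, Siglec-F,
#' CD68, CD49b, CD4, MHC-II); function channels carry checkpoint/activation
#' markers (PD-L1, CD62L, CD80, CD40, CD64, CD86, CD44, B220, cKit) and the
#' proliferation label IdU; utility channels drive gating (DNA intercalator,
#' cisplatin viability, congenic CD45.1/CD45.2, the injected anti-CD45, and
#' the erythrocyte marker Ter119).
#' @return a `panel_spec`.
#' @export
default_panel <- function() {
  lineage <- c("Ly6G", "CD11c", "TCRb", "F4_80", "CD3", "IgD", "IgM", "CD19",
               "CD8", "CD11b", "Ly6C", "FceRI", "SiglecF", "CD68", "CD49b",
               "CD4", "MHCII")
  fun <- c("PD_L1", "CD62L", "CD80", "CD40", "CD64", "CD86", "IdU", "CD44",
           "B220", "cKit")
  panel_spec(data.frame(
    channel = c(lineage, fun, GATING_UTILITY),
    role = c(rep("lineage", length(lineage)),
             rep("function", length(fun)),
             rep("utility", length(GATING_UTILITY)))))
}

#' Population specification
#'
#' @param name cell-type label.
#' @param origin "maternal" or "fetal".
#' @param positive named numeric vector of arcsinh-scale means for markers
#'   this population expresses; unlisted markers default to `baseline_mean`.
#' @param sds named numeric vector of arcsinh-scale sds overriding
#'   `baseline_sd` per marker.
#' @param abundance named list (PB / EV / TIS) of numeric vectors
#'   `c(intercept, slope, quad)` (quad optional) in fraction units around
#'   the reference day 14.5.
#' @param baseline_mean,baseline_sd defaults for unlisted markers.
#' @return a `population_spec` list.
#' @export
population_spec <- function(name, origin = c("maternal", "fetal"),
                            positive = numeric(), sds = numeric(),
                            abundance,
                            baseline_mean = 0.4, baseline_sd = 0.35) {
  origin <- match.arg(origin)
  stopifnot(is.list(abundance), length(abundance) > 0)
  if (any(vapply(sds, function(s) s <= 0, logical(1))))
    stop("archetype sds must be positive")
  if (baseline_sd <= 0) stop("baseline_sd must be positive")
  structure(list(name = name, origin = origin, positive = positive, sds = sds,
                 abundance = lapply(abundance, function(a) {
                   a <- c(a, rep(0, max(0, 3 - length(a))))[1:3]
                   stats::setNames(a, c("intercept", "slope", "quad"))
                 }),
                 pic_multiplier = NULL,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd),
            class = "population_spec")
}

#' Expected (pre-normalization) fraction of a population
#'
#' Evaluates the abundance polynomial at `day` for `compartment`, clipped
#' at zero. Populations with no model for the compartment contribute zero.
#' @param pop a `population_spec`.
#' @param day embryonic day (the .5 convention).
#' @param compartment "PB", "EV" or "TIS".
#' @export
abundance_at <- function(pop, day, compartment) {
  a <- pop$abundance[[compartment]]
  if (is.null(a)) return(rep(0, length(day)))
  u <- day - DAY_REF
  pmax(0, a[["intercept"]] + a[["slope"]] * u + a[["quad"]] * u^2)
}

pop_names <- function(populations) vapply(populations, `[[`, character(1), "name")

archetype_means <- function(pop, channels) {
  m <- rep(pop$baseline_mean, length(channels))
  names(m) <- channels
  hit <- intersect(names(pop$positive), channels)
  m[hit] <- pop$positive[hit]
  m
}

archetype_sds <- function(pop, channels) {
  s <- rep(pop$baseline_sd, length(channels))
  names(s) <- channels
  hit <- intersect(names(pop$sds), channels)
  s[hit] <- pop$sds[hit]
  s
}

#' Default population set
#'
#' Eight maternal lineages (B, CD4 T, CD8 T, NK, neutrophil, mononuclear
#' phagocyte, eosinophil, basophil) with compartment abundances echoing the
#' biology: MPs dominate the endovascular space, neutrophils are
#' tissue-biased, T and B cells dominate peripheral blood. Two fetal
#' populations (MP, neutrophil) appear only at the interface and ramp from
#' roughly 0.1% to 0.8% of immune cells across E10.5-18.5.
#'
#' @param fetal include the fetal populations (default TRUE).
#' @return list of `population_spec`.
#' @export
default_populations <- function(fetal = TRUE) {
  hi <- 4.5
  pops <- list(
    population_spec("B", "maternal",
                    positive = c(CD19 = hi, IgD = hi, IgM = 4, MHCII = 4, B220 = hi),
                    abundance = list(PB = c(0.25, 0), EV = c(0.05, 0), TIS = c(0.06, 0))),
    population_spec("CD4T", "maternal",
                    positive = c(CD3 = hi, TCRb = hi, CD4 = hi),
                    abundance = list(PB = c(0.18, 0), EV = c(0.04, 0), TIS = c(0.05, 0))),
    population_spec("CD8T", "maternal",
                    positive = c(CD3 = hi, TCRb = hi, CD8 = hi),
                    abundance = list(PB = c(0.12, 0), EV = c(0.03, 0), TIS = c(0.04, 0))),
    population_spec("NK", "maternal",
                    positive = c(CD49b = hi),
                    abundance = list(PB = c(0.06, 0), EV = c(0.05, 0), TIS = c(0.05, 0))),
    population_spec("Neutrophil", "maternal",
                    positive = c(Ly6G = hi, CD11b = hi, CD44 = 2.5, Ly6C = 2.5,
                                 CD62L = 2.5),
                    abundance = list(PB = c(0.20, 0.004),
                                     EV = c(0.25, 0.02),
                                     TIS = c(0.30, -0.01))),
    population_spec("MP", "maternal",
                    positive = c(CD11b = hi, CD64 = hi, F4_80 = 4, CD68 = 4,
                                 Ly6C = 4, MHCII = 3, CD86 = 2.5, PD_L1 = 2),
                    sds = c(Ly6C = 1.2, PD_L1 = 1.2),
                    abundance = list(PB = c(0.12, 0),
                                     EV = c(0.45, -0.02),
                                     TIS = c(0.35, 0))),
    population_spec("Eosinophil", "maternal",
                    positive = c(SiglecF = hi, CD11b = 4),
                    abundance = list(PB = c(0.04, 0), EV = c(0.06, 0), TIS = c(0.08, 0))),
    population_spec("Basophil", "maternal",
                    positive = c(FceRI = hi, CD49b = 2),
                    abundance = list(PB = c(0.03, 0), EV = c(0.04, 0), TIS = c(0.04, 0))))
  if (fetal) {
    ramp <- c(0.0045, 0.00085)   # ~0.001 at E10.5 to ~0.008 at E18.5
    pops <- c(pops, list(
      population_spec("FetalMP", "fetal",
                      positive = c(CD11b = hi, CD64 = hi, F4_80 = 4, CD68 = 4,
                                   Ly6C = 3.5, MHCII = 3),
                      abundance = list(EV = ramp * 0.6, TIS = ramp * 0.4)),
      population_spec("FetalNeutrophil", "fetal",
                      positive = c(Ly6G = hi, CD11b = hi),
                      abundance = list(EV = ramp * 0.25, TIS = ramp * 0.15))))
  }
  pops
}

#' Strong-early gestational dynamics scenario
#'
#' A population set in which the two dominant myeloid lineages (MP and
#' neutrophil) change steeply across early gestation in the endovascular
#' compartment and plateau after mid-gestation (the abundance derivative
#' reaches zero at E18.5), while all other lineages stay flat. Under this
#' scenario embryonic day is far more predictable from MP/neutrophil
#' fractions in the early window (E10.5-13.5) than in the late window
#' (E14.5-18.5).
#'
#' @return list of `population_spec`.
#' @export
strong_early_populations <- function() {
  pops <- default_populations(fetal = FALSE)
  nm <- pop_names(pops)
  # derivative b + 2*c*(day - 14.5) vanishes at E18.5: b = -8c
  pops[[match("MP", nm)]]$abundance$EV <-
    stats::setNames(c(0.40, -0.03, 0.00375), c("intercept", "slope", "quad"))
  pops[[match("Neutrophil", nm)]]$abundance$EV <-
    stats::setNames(c(0.25, 0.03, -0.00375), c("intercept", "slope", "quad"))
  pops
}

#' Inject an abundance cross-over between two populations
#'
#' Replaces both populations' abundance models in one compartment with
#' straight lines of opposite slope that intersect exactly at `day_star`:
#' `cell_a` decreases with day, `cell_b` increases. The shared level is the
#' mean of their current expected fractions at `day_star`, and the slope is
#' chosen so both lines stay positive over `days`.
#'
#' @param populations list of `population_spec`.
#' @param cell_a,cell_b population names.
#' @param day_star crossing day; must lie within `range(days)`.
#' @param compartment compartment in which to force the cross-over.
#' @param days the study's embryonic-day grid.
#' @return the modified population list, with the configured crossing day
#'   recorded in `attr(, "crossover")`.
#' @export
inject_crossover <- function(populations, cell_a, cell_b, day_star,
                             compartment = "EV", days = seq(10.5, 18.5, by = 1)) {
  nm <- pop_names(populations)
  ia <- match(cell_a, nm); ib <- match(cell_b, nm)
  if (is.na(ia) || is.na(ib))
    stop("cell_a / cell_b must name existing populations")
  if (day_star < min(days) || day_star > max(days))
    stop("day_star outside the study day range")
  base <- mean(c(abundance_at(populations[[ia]], day_star, compartment),
                 abundance_at(populations[[ib]], day_star, compartment)))
  if (base <= 0) base <- 0.15
  s <- 0.9 * base / max(abs(days - day_star))
  # f(day) = base +/- s * (day - day_star), re-expressed around DAY_REF
  populations[[ia]]$abundance[[compartment]] <-
    stats::setNames(c(base - s * (DAY_REF - day_star), -s, 0),
                    c("intercept", "slope", "quad"))
  populations[[ib]]$abundance[[compartment]] <-
    stats::setNames(c(base + s * (DAY_REF - day_star), s, 0),
                    c("intercept", "slope", "quad"))
  attr(populations, "crossover") <- list(day = day_star, compartment = compartment,
                                         cell_a = cell_a, cell_b = cell_b)
  populations
}

#' Register perturbation-arm abundance multipliers
#'
#' Scales the named populations' abundance models in the treated (PIC) arm
#' before per-sample renormalization; the control (SAL) arm is untouched.
#'
#' @param populations list of `population_spec`.
#' @param arm_effects named list: population name -> either a single positive
#'   multiplier (all compartments) or a named vector of per-compartment
#'   multipliers.
#' @return the modified population list; multipliers recorded per population
#'   and in `attr(, "arm_effects")` as ground truth.
#' @export
inject_perturbation <- function(populations, arm_effects) {
  nm <- pop_names(populations)
  for (pop in names(arm_effects)) {
    i <- match(pop, nm)
    if (is.na(i)) stop("unknown population in arm_effects: ", pop)
    eff <- arm_effects[[pop]]
    if (any(eff <= 0)) stop("perturbation multipliers must be positive")
    populations[[i]]$pic_multiplier <- eff
  }
  attr(populations, "arm_effects") <- arm_effects
  populations
}

pic_multiplier_for <- function(pop, compartment) {
  eff <- pop$pic_multiplier
  if (is.null(eff)) return(1)
  if (length(eff) == 1 && is.null(names(eff))) return(unname(eff))
  if (!is.null(names(eff)) && compartment %in% names(eff)) return(unname(eff[[compartment]]))
  if (!is.null(names(eff))) return(1)
  unname(eff[[1]])
}
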