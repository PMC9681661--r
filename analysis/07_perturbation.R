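#!/usr/bin/env Rscript
# Perturbation-arm analysis: a poly(I:C)-like 0.5x contraction of MPs at the
# interface, analyzed by control-trained discriminant projection, by
# Bray-Curtis dissimilarity between arms, by per-cell-type log2(PIC/SAL)
# ratios, and by the Taylor-series ratio test between days.
#
# Finding: the treated arm's MP log2 ratio is negative (the renormalized
# expectation for a 0.5x multiplier on a ~35% population is about -0.7),
# the discriminant projection shifts treated samples away from their
# control class, and the ratio test flags the day difference only when one
# is injected.

library(mficyto)

out <- "results/perturbation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pops <- inject_perturbation(default_populations(fetal = FALSE),
                            list(MP = c(EV = 0.5, TIS = 0.5)))
d <- study_design(days = c(12.5, 14.5), mice_per_day = 6,
                  treatment_arms = c("SAL", "PIC"),
                  events_per_sample = 2000, seed = 3)
s <- generate_study(d, pops)
ann <- annotate_events(arcsinh_transform(s$events))
ann$cell_type <- s$truth$events$population
ann$treatment <- as.data.frame(s$events)$treatment
keep <- ann$viable & ann$origin == "maternal" &
  ann$compartment %in% c("PB", "EV", "TIS")
cf <- cell_fractions(ann[keep, ], grouping = c("sample_id", "mouse", "day",
                                               "treatment", "compartment"))
write.table(cf, file.path(out, "cell_fractions.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

# log2(PIC/SAL) per cell type in TIS
tis <- cf[cf$compartment == "TIS", ]
lr <- log2_condition_ratio(tis[tis$treatment == "PIC", ],
                           tis[tis$treatment == "SAL", ])
write.table(lr, file.path(out, "log2_pic_sal_tis.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("TIS MP log2(PIC/SAL) = %.2f (p = %.2g)\n",
            lr$log2_ratio[lr$cell_type == "MP"],
            lr$p_value[lr$cell_type == "MP"]))

# control-trained discriminant, perturbed samples projected
fm <- fraction_matrix(cf, c("sample_id", "mouse", "day", "treatment",
                            "compartment"))
sal <- fm$meta$treatment == "SAL"
lda <- lda_fit(fm$matrix[sal, ], fm$meta$compartment[sal])
proj_pic <- lda_project(lda, fm$matrix[!sal, ])
write.table(data.frame(fm$meta[!sal, ], proj_pic),
            file.path(out, "lda_projected_pic.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

# Bray-Curtis between arms within compartment at E12.5
e12 <- fm$meta$day == 12.5
bc_arm <- function(comp) {
  m <- fm$matrix[e12 & fm$meta$compartment == comp, ]
  tr <- fm$meta$treatment[e12 & fm$meta$compartment == comp]
  pairs <- expand.grid(which(tr == "SAL"), which(tr == "PIC"))
  apply(pairs, 1, function(p) bray_curtis(m[p[1], ], m[p[2], ]))
}
cat(sprintf("mean E12.5 SAL-vs-PIC Bray-Curtis: TIS %.3f, PB %.3f\n",
            mean(bc_arm("TIS")), mean(bc_arm("PB"))))

# Taylor-series ratio test: MP counts PIC/SAL at E12.5 vs E14.5 in TIS
mp_counts <- function(day) {
  sub <- tis[tis$cell_type == "MP" & tis$day == day, ]
  list(pic = sub$count[sub$treatment == "PIC"],
       sal = sub$count[sub$treatment == "SAL"])
}
c12 <- mp_counts(12.5); c14 <- mp_counts(14.5)
r12 <- ratio_test(c12$pic, c12$sal)
r14 <- ratio_test(c14$pic, c14$sal)
cmp <- ratio_compare(r12, r14)
cat(sprintf("MP PIC/SAL ratio: E12.5 %.2f (sd %.2f), E14.5 %.2f (sd %.2f); t = %.2f, p = %.2g\n",
            r12$ratio, r12$sd, r14$ratio, r14$sd, cmp$t, cmp$p_value))
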