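#!/usr/bin/env Rscript
# Wet-lab validation statistics on the simulated assay tables: 2^-ddCt
# relative expression, dual-luciferase activity, glucose production and
# the neonatal blood-glucose trajectory.

source("analysis/00_config.R")

ct <- utils::read.delim(data_path("assay_ct.tsv"))
luc <- utils::read.delim(data_path("assay_luciferase.tsv"))
glu <- utils::read.delim(data_path("assay_glucose.tsv"))
blood <- utils::read.delim(data_path("assay_blood_glucose.tsv"))

rel <- ddct(ct, calibrator = "prenatal")
summ <- do.call(rbind, lapply(split(rel, rel$target), function(d) {
  post <- d$rel_expr[d$group == "postnatal"]
  cmp <- group_compare(d$rel_expr, d$group)
  data.frame(target = d$target[1], fold_postnatal = round(mean(post), 3),
             p_value = signif(cmp$p_value, 3), flag = cmp$flag)
}))
write_tsv(summ, res_path("qpcr_relative_expression.tsv"))
message("  qRT-PCR fold changes (postnatal vs prenatal):")
for (i in seq_len(nrow(summ))) {
  message(sprintf("    %-10s %.2fx %s", summ$target[i],
                  summ$fold_postnatal[i], summ$flag[i]))
}

act <- luciferase_relative_activity(luc)
luc_sum <- do.call(rbind, lapply(split(act, act$construct), function(d) {
  cmp <- group_compare(d$activity, d$treatment)
  data.frame(construct = d$construct[1],
             mimic_activity = round(mean(d$activity[d$treatment == "mimic"]), 3),
             p_value = signif(cmp$p_value, 3), flag = cmp$flag)
}))
write_tsv(luc_sum, res_path("luciferase_activity.tsv"))
message("  luciferase: Wt mimic activity ",
        luc_sum$mimic_activity[luc_sum$construct == "Wt"], " (",
        luc_sum$flag[luc_sum$construct == "Wt"], "), Mut ",
        luc_sum$mimic_activity[luc_sum$construct == "Mut"], " (",
        luc_sum$flag[luc_sum$construct == "Mut"], ")")

g <- glucose_output(glu$glucose, glu$protein, glu$group)
ga <- group_compare(g$wells$normalized, g$wells$group)
gs <- g$summary
gs$mean <- round(gs$mean, 3); gs$sd <- round(gs$sd, 3)
write_tsv(gs, res_path("glucose_production.tsv"))
message(sprintf("  glucose production ANOVA: F = %.2f, p = %.3g %s",
                ga$statistic, ga$p_value, ga$flag))

curve <- aggregate(glucose_mmol_l ~ time_h, blood, mean)
curve$glucose_mmol_l <- round(curve$glucose_mmol_l, 2)
write_tsv(curve, res_path("blood_glucose_curve.tsv"))
nadir <- curve[which.min(curve$glucose_mmol_l), ]
message(sprintf("  blood glucose: %.2f mmol/L at birth, nadir %.2f at %d h, %.2f at 6 h",
                curve$glucose_mmol_l[curve$time_h == 0],
                nadir$glucose_mmol_l, nadir$time_h,
                curve$glucose_mmol_l[curve$time_h == 6]))
message("Done.")
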