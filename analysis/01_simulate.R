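#!/usr/bin/env Rscript
# Generate the synthetic study materials used by the downstream analyses:
# a two-channel confocal stack of the scale epidermis with known ground
# truth, a photoconversion pulse-chase series, a developmental density
# cohort, a two-genotype cohort, and traced scale outlines with cell
# positions. Everything is seeded, so reruns reproduce the same files.

library(mcskin)

seed <- 4
out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("-- skin stack: 50 Merkel cells, 90% innervated, 2 channels")
sp <- sim_stack_spec(field_um = c(120, 120, 24), n_cells = 50, p_inn = 0.9,
                     seed = seed)
sim <- generate_skin_stack(sp)
write_stack(sim$stack, file.path(out, "stack"))
write.csv(sim$truth, file.path(out, "truth_cells.csv"), row.names = FALSE)
message(sprintf("   %d cells placed, %d innervated",
                nrow(sim$truth), sum(sim$truth$innervated)))

message("-- photoconversion series: 60 converted cells, 15%/week loss")
ser <- generate_photoconversion_series(
  turnover_sim_spec(n0 = 60, p_loss = 0.15, lambda_add = 9, seed = seed + 10))
write.csv(ser$counts, file.path(out, "series_counts.csv"), row.names = FALSE)
for (k in seq_along(ser$snapshots)) {
  write.csv(ser$snapshots[[k]],
            file.path(out, sprintf("series_t%02d.csv", ser$counts$t_days[k])),
            row.names = FALSE)
}
print(ser$counts, row.names = FALSE)

message("-- developmental cohort: n = 52 fish, breakpoint 8.27 mm SL")
dev <- generate_cohort(cohort_sim_spec(seed = seed + 20))
write.csv(dev, file.path(out, "cohort_dev.csv"), row.names = FALSE)

message("-- two-genotype cohort: 17 fish/genotype, interaction with SL")
gen <- generate_cohort(cohort_sim_spec(
  genotypes = c("sibling", "mutant"), n_per_genotype = 17,
  sl_range_mm = c(7, 19), genotype_effect = 2.1, interaction_effect = -0.3,
  sigma = 2.5, seed = seed + 21))
write.csv(gen, file.path(out, "cohort_genotype.csv"), row.names = FALSE)

message("-- scale fields: 49 scales/genotype, posterior margins annotated")
sib <- generate_scale_field(n_scales = 49, points_per_scale = 25,
                            radius_um = 150, jitter_um = 10, seed = seed + 30)
mut <- generate_scale_field(n_scales = 43, points_per_scale = 25,
                            radius_um = 150, lobe_depth = 0.35,
                            jitter_um = 60, seed = seed + 31)
write.csv(sib$outlines, file.path(out, "scales_sibling_outlines.csv"), row.names = FALSE)
write.csv(sib$points, file.path(out, "scales_sibling_points.csv"), row.names = FALSE)
write.csv(mut$outlines, file.path(out, "scales_mutant_outlines.csv"), row.names = FALSE)
write.csv(mut$points, file.path(out, "scales_mutant_points.csv"), row.names = FALSE)

message("done: fixtures under ", out)
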