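#!/usr/bin/env Rscript
# Stage 1: generate the synthetic measurement campaign.
#
# Emulates the feedforward sender-receiver design: the 6 aTc x 7 IPTG
# inducer grid measured in triplicate at nominal density 0.1 OD600, plus
# the pLac calibration series used to fit lines of equivalence. Writes the
# noisy and noise-free grids and the calibration tables under results/.

library(promoterlogic)

dir.create("results", showWarnings = FALSE)
seed <- 20260920L

p0 <- default_plf_params()
grid_noisy <- generate_plf_grid(p0, noise = noise_model(cv = 0.15, seed = seed))
grid_clean <- generate_plf_grid(p0, noise = noise_model(cv = 0, seed = seed))
write_plf_grid(grid_noisy, "results/plf_grid_cv15.tsv", force = TRUE)
write_plf_grid(grid_clean, "results/plf_grid_cv0.tsv", force = TRUE)

# calibration series: reporter vs LuxR channel (scale lambda_Z / lambda_R)
# and reporter vs LuxI channel (scale lambda_Z / lambda_I)
cal_R <- generate_equivalence_table(true_scale = 1000 / 500,
                                    backgrounds = c(30, 15),
                                    noise = noise_model(0.1, seed + 1))
cal_I <- generate_equivalence_table(true_scale = 1000 / 3000,
                                    backgrounds = c(25, 15),
                                    noise = noise_model(0.1, seed + 2))
utils::write.table(cal_R, "results/equivalence_luxR.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cal_I, "results/equivalence_luxI.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

span <- log10(max(grid_clean$output_cfp) / min(grid_clean$output_cfp))
message(sprintf(
  "Generated %d grid records over %d inducer combinations; noise-free output spans %.2f decades (AND-type surface).",
  nrow(grid_noisy), nrow(unique(grid_noisy[, c("aTc_ng_ml", "IPTG_uM")])),
  span))
message("Calibration series written for both feedback channels.")
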