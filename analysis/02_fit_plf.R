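#!/usr/bin/env Rscript
# Stage 2: estimate promoter-logic parameters from the measured grid.
#
# Fits the parameterized PLF to the noisy grid by weighted nonlinear least
# squares on log outputs (AHL-LuxR Hill coefficient m held fixed), sweeps
# the fixed m to show why it cannot be fit freely, and runs the
# Monte-Carlo goodness-of-fit. Writes the fit report and m-sweep table.

library(promoterlogic)

dir.create("results", showWarnings = FALSE)
grid <- read_plf_grid("results/plf_grid_cv15.tsv")
p0 <- default_plf_params()

fit <- fit_plf(grid, m_fixed = 2)
print(fit)
write_param_file(plf_params_from_fit(fit, density = 0.1),
                 "results/fitted_plf_params.tsv", force = TRUE)

sw <- sweep_m(grid, m_values = c(1, 1.5, 2, 2.5, 3, 4))
utils::write.table(sw, "results/m_sweep.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message(sprintf(
  "m sweep: chi-square falls monotonically with m (%.3g at m=1 to %.3g at m=4) -- m is held fixed at 2; fitted n varies only %.2f across the sweep.",
  sw$chi_square[1], sw$chi_square[nrow(sw)], diff(range(sw$hill_n))))

mcq <- goodness_of_fit_mc(grid, fit, trials = 400, seed = 42)
message(sprintf(
  "Monte-Carlo goodness of fit: Q = %.2f over %d trials (%d refit failures; cv estimated %.3f): %s",
  mcq$Q, mcq$trials, mcq$n_failed, mcq$cv_estimated,
  if (mcq$Q >= 0.05) "deviations are within measurement error."
  else "the model is rejected at the 5% level."))

truth <- c(basal_fraction = p0$basal_fraction,
           c_tilde = p0$ahl_density_const * p0$density / p0$ahl_luxr_halfsat,
           luxr_dna_halfsat = p0$luxr_dna_halfsat, hill_n = p0$hill_n)
est <- unlist(fit$params[names(truth)])
report <- data.frame(parameter = names(truth), truth = truth, estimate = est,
                     se = fit$se[names(truth)],
                     rel_error = (est - truth) / truth)
utils::write.table(report, "results/fit_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("Recovered generating parameters within %.1f%% (worst case).",
                100 * max(abs(report$rel_error))))
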