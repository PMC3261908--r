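#!/usr/bin/env Rscript
# Stage 3: model-independent feedback prediction.
#
# Fits lines of equivalence from the calibration tables, slices the
# measured grid into input-output characteristics, enumerates their
# intersections with the lines (with 1000-trial Monte-Carlo noise
# propagation), and compares the predicted stable levels with
# ON/OFF-history terminal responses simulated from the generating model.
# The grid is measured at 0.1 OD600 while the autonomous loops run at a
# terminal density of 0.05 OD600; for the LuxI loop the IOC input axis is
# stretched by the density ratio (the exact rescaling the promoter logic
# obeys, since AHL enters only through density x LuxI).

library(promoterlogic)

dir.create("results", showWarnings = FALSE)
grid <- read_plf_grid("results/plf_grid_cv15.tsv")
p0 <- default_plf_params()
lv <- default_inducer_levels()
rho_grid <- 0.1
rho_T <- 0.05

line_R <- fit_equivalence_line(utils::read.table("results/equivalence_luxR.tsv",
                                                 header = TRUE, sep = "\t"))
line_I <- fit_equivalence_line(utils::read.table("results/equivalence_luxI.tsv",
                                                 header = TRUE, sep = "\t"))
message(sprintf("Lines of equivalence: LuxR channel s = %.3f (truth 2.000), LuxI channel s = %.4f (truth 0.3333).",
                line_R$scale, line_I$scale))

predict_loop <- function(axis, line, n_idx, input_scale = 1) {
  do.call(rbind, lapply(seq_len(n_idx), function(k) {
    mc <- mc_predict(grid, line, axis, k, trials = 1000, seed = 100 + k,
                     input_scale = input_scale)
    det <- mc$deterministic
    stable <- det$level[det$stability == "stable"]
    data.frame(axis = axis, regulator_index = k,
               n_stable = length(stable),
               level_low = min(stable), level_high = max(stable),
               multistable_fraction = mc$multistable_fraction)
  }))
}
pred_R <- predict_loop("luxR", line_R, length(lv$aTc_ng_ml))
pred_I <- predict_loop("luxI", line_I, length(lv$IPTG_uM),
                       input_scale = rho_grid / rho_T)
pred <- rbind(pred_R, pred_I)
utils::write.table(pred, "results/model_independent_predictions.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
multi <- pred_I$multistable_fraction > 0.5
message(sprintf(
  "LuxR-feedback slices: %d/%d predicted monostable. LuxI-feedback slices predicted multistable (hysteretic) at IPTG = %s uM, with multistable trial fractions %s.",
  sum(pred_R$n_stable == 1), nrow(pred_R),
  paste(lv$IPTG_uM[multi], collapse = ", "),
  paste(sprintf("%.0f%%", 100 * pred_I$multistable_fraction[multi]),
        collapse = ", ")))

# simulated terminal-response measurement for comparison (ON/OFF histories)
q <- default_induction_params()
reg_levels <- hill_induction(lv$IPTG_uM, q$IPTG)
topos <- default_topologies()
fb <- generate_feedback_dataset(topos$luxI_feedback, p0,
                                regulator_levels = reg_levels,
                                density_terminal = rho_T,
                                noise = noise_model(0.15, 7))
utils::write.table(fb, "results/terminal_responses_luxI.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
agg <- stats::aggregate(terminal ~ regulator + history, data = fb,
                        FUN = function(v) exp(mean(log(v))))
wide <- stats::reshape(agg, idvar = "regulator", timevar = "history",
                       direction = "wide")
hyst <- wide$terminal.ON / wide$terminal.OFF > 10
frac_txt <- paste(sprintf("%g uM: %.0f%%", lv$IPTG_uM[pred_I$multistable_fraction > 0],
                          100 * pred_I$multistable_fraction[pred_I$multistable_fraction > 0]),
                  collapse = "; ")
message(sprintf(
  "Simulated LuxI-feedback terminal responses are hysteretic at IPTG = %s uM. The model-independent route recovers this window partially (multistable trial fractions -- %s): noise on a 6-node characteristic blurs fold locations, as expected near a bifurcation.",
  paste(lv$IPTG_uM[hyst], collapse = ", "), frac_txt))
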