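#!/usr/bin/env Rscript
# Delay-recovery experiment: simulate p52 time courses at known
# translational delays, corrupt them with 5% multiplicative noise, and
# recover both delays by least-squares grid search on the 15-min lattice.

suppressPackageStartupMessages(library(nfkbcoupler))
dir.create("results", showWarnings = FALSE)

params <- default_params()
truth <- c(240, 180)
grid <- seq(120, 300, by = 15)

cat("precomputing noise-free p52 series over the candidate lattice...\n")
pre <- precompute_p52_grid(params, grid = grid, dt_out_min = 5)

res <- do.call(rbind, lapply(1:20, function(seed) {
  obs <- gen_noisy_trajectory(params, truth, noise_sd_fraction = 0.05,
                              seed = seed, dt_out_min = 5)
  got <- recover_delays(obs, params, grid = grid, precomputed = pre,
                        dt_out_min = 5)
  data.frame(seed = seed, tau_traf1_min = got[["tau_traf1_min"]],
             tau_nfkb2_min = got[["tau_nfkb2_min"]],
             err_traf1 = got[["tau_traf1_min"]] - truth[1],
             err_nfkb2 = got[["tau_nfkb2_min"]] - truth[2])
}))
utils::write.csv(res, "results/delay_recovery.csv", row.names = FALSE)

cat(sprintf("truth (%g, %g), 20 seeds at 5%% noise\n", truth[1], truth[2]))
cat(sprintf("worst-case absolute error: TRAF1 %g min, NF-kB2 %g min\n",
            max(abs(res$err_traf1)), max(abs(res$err_nfkb2))))
cat(sprintf("exact recoveries: %d / 20\n",
            sum(res$err_traf1 == 0 & res$err_nfkb2 == 0)))
cat("per-seed table written to results/delay_recovery.csv\n")
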