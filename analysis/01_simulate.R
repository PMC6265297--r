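#!/usr/bin/env Rscript
# Stage 1: generate the synthetic voltage-clamp recordings every later
# stage analyzes.
#
# Four conducting constructs (amide control and ester variant at two S4
# sites, Boltzmann truths taken from the printed fit-parameter table) are
# recorded with a standard activation protocol plus P/8 companion
# subpulses, and one nonconducting (W434F-like) three-state channel is
# recorded with a gating-current protocol.  Sweep families are written as
# TSV + JSON sidecar under scratch/sweeps/ (bulky raw data); a small
# manifest goes to results/.

suppressMessages(library(vsgating))

seed <- 20260923L
out_raw <- "scratch/sweeps"
dir.create(out_raw, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

params <- gating_parameter_table()
constructs <- c("V363Val", "V363Vah", "V369Val", "V369Vah")

protocol <- voltage_protocol(V_hold = -80,
                             step_voltages = seq(-80, 100, by = 5),
                             step_duration = 30, V_tail = -80,
                             tail_duration = 30, pre_duration = 5,
                             sample_rate = 10)
sub_protocol <- p_over_n_subpulses(protocol, n = 8, V_sub_hold = -110)

manifest <- list()
for (i in seq_along(constructs)) {
  nm <- constructs[i]
  row <- params[params$construct == nm, ]
  scheme <- wt_like_scheme(z = row$z, Vd = row$Vd)
  cell <- study_cell(noise_sd = 0.03, seed = seed + i)
  test <- simulate_sweeps(scheme, protocol, cell)
  sub_cell <- cell; sub_cell$seed <- cell$seed + 1000003L
  sub <- simulate_sweeps(scheme, sub_protocol, sub_cell)
  write_sweep_set(test, file.path(out_raw, paste0(nm, "_test")))
  write_sweep_set(sub, file.path(out_raw, paste0(nm, "_p8")))
  manifest[[length(manifest) + 1L]] <-
    data.frame(construct = nm, kind = row$kind, z_true = row$z,
               Vd_true = row$Vd, gv_method = row$gv_method,
               seed = cell$seed)
  message(sprintf("simulated %-8s  (z = %.1f, Vd = %+.1f mV, %s G-V)",
                  nm, row$z, row$Vd, row$gv_method))
}

# nonconducting gating-current family: resting -> intermediate ->
# activated chain, 2 mV-resolved Q-V would be overkill; 5 mV as standard
gsweeps <- simulate_sweeps(charge_scheme(), gating_protocol(by = 5),
                           study_cell(noise_sd = 0, seed = seed + 99L))
write_sweep_set(gsweeps, file.path(out_raw, "w434f_like_gating"))
message("simulated w434f_like_gating (3-state chain, 51 steps, 200 kHz)")

manifest <- do.call(rbind, manifest)
utils::write.csv(manifest, "results/01_sweep_manifest.csv",
                 row.names = FALSE)
message("wrote results/01_sweep_manifest.csv and ", out_raw, "/*.tsv")
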