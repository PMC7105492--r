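#!/usr/bin/env Rscript
# Generate one example of every synthetic input modality with ground truth
# attached, and write them under results/simulated/. These files are the
# same objects the downstream analysis stages consume; regenerating with
# the same seeds reproduces them bit-identically.

suppressPackageStartupMessages(library(astrocr))
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# Dye-filled astrocyte (control occupancy, 5%-of-peak noise)
img <- gen_astrocyte_image(imaging_params(leaflet_vf = 0.032, noise_sd = 10,
                                          seed = 101))
write_labeled_image(img, file.path(out, "astrocyte_control.tiff"))
cat("astrocyte image:", dim(img$planes[[1]])[1], "x", dim(img$planes[[1]])[2],
    "px, true VF", img$ground_truth$vf, "\n")

# Dye-coupled network (control length constant)
net <- gen_coupled_network(coupling_params(n_cells = 13, noise_sd = 0.05,
                                           seed = 102))
write_coupled_network(net, file.path(out, "coupled_network_control.csv"))
cat("coupled network:", nrow(net) - 1, "coupled cells, true C_lambda",
    attr(net, "ground_truth")$length_constant_um, "um\n")

# Connexin-like puncta frames, both channel presets
for (ch in c("cx30_proximal", "cx43")) {
  fr <- gen_puncta_frame(puncta_preset(ch, seed = 103))
  write_labeled_image(fr, file.path(out, paste0("puncta_", ch, ".tiff")))
  cat(sprintf("%s frame: %d true clusters of %.2f um\n", ch,
              fr$ground_truth$n_true, fr$ground_truth$diameter_um))
}

# Stimulus-evoked astrocytic sweeps (all drug conditions)
ss <- gen_astro_sweeps(sweep_params(noise_sd = 5, seed = 104))
write_sweep_set(ss, file.path(out, "astro_sweeps.csv"))
cat("sweeps:", length(ss$traces), "condition traces x",
    ncol(ss$traces[[1]]), "sweeps\n")

# fEPSP amplitude series (CR potentiation)
ltp <- gen_ltp_series(ltp_series_params(potentiation_factor = 1.68,
                                        amplitude_noise_cv = 0.05,
                                        seed = 105))
utils::write.csv(ltp, file.path(out, "ltp_series_cr.csv"), row.names = FALSE)
cat("LTP series:", nrow(ltp), "samples,",
    "true late plateau", attr(ltp, "ground_truth")$late_mean_pct, "%\n")

# Voltage-step response for input resistance
st <- gen_step_response(r_mohm = 30, noise_sd_frac = 0.02, seed = 106)
utils::write.csv(data.frame(time = st$time, current_pA = st$current_pA),
                 file.path(out, "step_response.csv"), row.names = FALSE)
cat("step response: true R_i", st$ground_truth$r_mohm, "MOhm\n")
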