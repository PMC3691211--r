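#!/usr/bin/env Rscript
# Generate the synthetic study data used by the downstream analysis
# drivers: aster vs dispersed filament images (with ground truth), a
# two-channel acetylation image, labelled comet tracks, dynamic-instability
# tracks, and immunogold EM filament annotations. Everything is written
# under results/data/ with a reproducibility metadata block.

suppressMessages(library(mtquant))
seed <- 20260101
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("simulating aster / dispersed image pairs ...")
for (layout in c("aster", "dispersed")) {
  spec <- image_spec(192, 192, psf_sigma_px = 1.5, background_level = 0.05,
                     noise_model = "gaussian", noise_param = 0.01,
                     seed = seed)
  g <- make_filament_image(spec, 40, c(2, 6), layout = layout)
  img <- g$image
  img$pixels <- pmin(img$pixels / max(img$pixels), 1)
  write_image(img, file.path(out, sprintf("cell_%s.tif", layout)))
}
write_roi(circle_geometry(c(95.5, 95.5), 90),
          file.path(out, "cell_roi.csv"))

message("simulating a two-channel washout image (30 MTs, 12 acetylated) ...")
spec2 <- image_spec(320, 320, psf_sigma_px = 1.5, seed = seed + 1)
g2 <- make_filament_image(spec2, 30, c(2, 4), acetyl_fraction = 0.4,
                          min_separation_px = 8)
img2 <- g2$image
sc <- max(img2$pixels, img2$channel2)
img2$pixels <- img2$pixels / sc
img2$channel2 <- img2$channel2 / sc
write_image(img2, file.path(out, "washout_two_channel.tif"))
writeLines(as.character(sum(!g2$truth$is_acetylated)),
           file.path(out, "washout_true_de_novo.txt"))

message("simulating labelled EB1 comets ...")
geo <- circle_geometry(c(199.5, 199.5), 190)
cm <- simulate_comets(10, 10, c(199.5, 199.5), geo,
                      exclusion_radius_um = 6, seed = seed + 2)
write_tracks(cm$tracks, file.path(out, "comets.csv"), labels = cm$origin)

message("simulating dynamic-instability tip tracks (500 x 10 min) ...")
tracks <- vector("list", 500)
for (i in seq_len(500)) {
  p <- dynamics_params(k_catastrophe_per_min = 2, k_rescue_per_min = 2,
                       n_frames = 201, seed = seed + 10 + i)
  tracks[[i]] <- simulate_di_track(p, track_id = i)
}
write_tracks(tracks, file.path(out, "di_tracks.csv"))

message("simulating immunogold EM filaments (inverse-length decoration) ...")
em <- make_em_filaments(200,
                        length_dist = list(dist = "uniform", min = 0.5, max = 6),
                        density_fn = function(L) 6 / L, seed = seed + 3)
write_em_annotations(em, file.path(out, "em_polylines.csv"),
                     file.path(out, "em_particles.csv"))

run_metadata(list(stage = "simulate", n_comets = 20, n_di_tracks = 500,
                  n_em_filaments = 200, k_catastrophe = 2, k_rescue = 2),
             seed = seed, path = file.path(out, "metadata.yaml"))
message("done; data under ", out)
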