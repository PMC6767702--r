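# Shared fixtures, built in code.

# Small default scene for structural tests.
small_scene <- function(seed = 1, ...) {
  generate_scene(scene_config(n_ihc = 10, cells_per_ohc_row = 10,
                              seed = seed, ...))
}

# Classification chain on a scene.
scene_partition <- function(scene) {
  plane <- build_plane(fit_axis(scene$ribbons), fit_axis(scene$ihc_nuclei),
                       scene$landmark_point)
  classify_ribbons(scene$ribbons, plane)
}

# Independent all-pairs nearest-neighbor oracle (plain double loop; kept
# deliberately separate from the package's accelerated implementation).
nn_oracle <- function(s, t) {
  vapply(seq_len(nrow(s)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(t))) {
      d2 <- (t[j, 1] - s[i, 1])^2 + (t[j, 2] - s[i, 2])^2 +
        (t[j, 3] - s[i, 3])^2
      if (d2 < best) best <- d2
    }
    sqrt(best)
  }, numeric(1))
}

# Well-separated blob field for detector tests: jittered grid positions with
# log-normal volumes, guaranteed minimum separation >> PSF.
blob_field <- function(n_side = c(5, 5, 4), spacing = 6, seed = 4,
                       vol_meanlog = log(0.4), vol_sdlog = 0.5) {
  set.seed(seed)
  g <- as.matrix(expand.grid(x = (seq_len(n_side[1]) - 1) * spacing,
                             y = (seq_len(n_side[2]) - 1) * spacing,
                             z = (seq_len(n_side[3]) - 1) * spacing * 0.8))
  g <- g + matrix(runif(length(g), -0.8, 0.8), nrow(g), 3)
  puncta_set(g, "fixture", "CTBP2",
             volumes = rlnorm(nrow(g), vol_meanlog, vol_sdlog))
}
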