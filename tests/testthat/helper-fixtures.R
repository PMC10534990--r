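# shared fixtures: small rendered wells and matching helpers

with_seed_test <- function(seed, code) withr::with_seed(seed, code)

small_pop <- function(n = 50, cv = 0) bead_population(n, 94.8, cv)

small_img <- function(noise_sd = 0, ...) {
  image_spec(width = 300, height = 300, noise_sd = noise_sd, ...)
}

# match every truth bead to its nearest valid detection; returns per-bead
# centre distance, radius error and detection indices
match_truth <- function(det, truth) {
  v <- det[det$valid, ]
  t(vapply(seq_len(nrow(truth)), function(i) {
    d2 <- (v$x - truth$x_px[i])^2 + (v$y - truth$y_px[i])^2
    j <- which.min(d2)
    c(dist = sqrt(d2[j]),
      radius_err = abs(v$radius[j] - truth$radius_px[i]) / truth$radius_px[i],
      j = j)
  }, numeric(3)))
}
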