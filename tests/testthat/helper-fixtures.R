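## Shared fixtures: small deterministic recordings and cohorts. Everything
## is generated in code; nothing is read from disk.

quiet_spec <- function(duration = 15, ...) {
  synth_spec(duration = duration, hr_bpm = 60, hr_sd_bpm = 0, noise_sd = 0,
             wander_amp = 0, amp_jitter_sd = 0, ...)
}

## narrow CNN used where training speed matters more than capacity
small_cnn <- function(...) {
  cnn_spec(filters = c(8L, 8L, 8L), fc_units = c(32L, 32L), ...)
}

## deterministic toy feature matrices with a linearly separable class signal
toy_features <- function(n_per_class = 30, p = 750, shift = 1, seed = 1) {
  set.seed(seed)
  x_cad <- matrix(runif(n_per_class * p), n_per_class)
  x_non <- matrix(runif(n_per_class * p), n_per_class)
  x_cad[, 1:25] <- x_cad[, 1:25] + shift
  list(x = rbind(x_cad, x_non),
       y = rep(c("CAD", "nonCAD"), each = n_per_class))
}
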