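# shared fixture builders; everything is generated in code at test time

quiet_bipolar <- function(seed, ...) {
  simulate_bipolar_cell(bipolar_manifest(seed, ...,
                                         noise = noise_model("none")))
}

quiet_monopolar <- function(seed, ...) {
  simulate_monopolar_cell(monopolar_manifest(seed, ...,
                                             noise = noise_model("none")))
}

true_fwhm <- function(sigma_um) 2 * sqrt(2 * log(2)) * sigma_um

# brute-force grid-search Gaussian fit, the independent oracle for the
# Levenberg-Marquardt path: minimizes SSE of A*exp(-(x-mu)^2/(2 s^2)) + c
# over a dense parameter grid
grid_gaussian_sigma <- function(x, y) {
  best <- c(sse = Inf, sigma = NA)
  span <- diff(range(x))
  for (mu in seq(min(x), max(x), length.out = 41))
    for (s in seq(span / 40, span / 2, length.out = 60))
      for (A in seq(0.2, 1.2, length.out = 11))
        for (cc in seq(-0.2, 0.3, length.out = 11)) {
          sse <- sum((y - (A * exp(-(x - mu)^2 / (2 * s^2)) + cc))^2)
          if (sse < best["sse"]) best <- c(sse = sse, sigma = s)
        }
  unname(best["sigma"])
}
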