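# shared fixtures: everything is generated in code at test time

wl40 <- seq(400, 750, length.out = 40)

# a smooth, band-interior phantom-like transmission spectrum
smooth_spectrum <- function(wl = wl40) {
  0.3 + 0.5 * exp(-((wl - 550) / 60)^2) + 0.2 * exp(-((wl - 450) / 40)^2)
}

# small random image stack in [0, 1]
rand_images <- function(n, h = 16, w = 16, c = 3, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(runif(h * w * c), c(h, w, c)))
}

default_cfg <- optical_config()
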