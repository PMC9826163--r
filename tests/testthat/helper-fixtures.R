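# shared fixtures: small deterministic traces and reference parameters

avp_tone_params <- function() preset("AVP-tone-proximal")

decade_concs <- function(from = -12, to = -5) 10^seq(from, to, by = 1)

# a single isolated kernel on a flat baseline, noise-free
single_kernel_trace <- function(shape = contraction_shape(2, 5, 10, 60, 20),
                                duration = 120, fs = 10, onset = 40) {
  t <- (seq_len(duration * fs) - 1) / fs
  force <- shape$baseline_tone + contraction_kernel(t - onset, shape)
  force_trace(t, force, fs = fs)
}

# half-up decimal rounding as printed values are reported (guards the
# floating-point representation of exact half boundaries such as 51/20)
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5 + abs(x) * 1e-9) / s
}

# strip classes recursively so serialized/reconstructed objects compare by value
unclass_compare <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_compare) else x
}
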