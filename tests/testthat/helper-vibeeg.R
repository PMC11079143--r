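# Shared fixture builders; everything is generated in code at test time.

rand_rec <- function(n = 1000, channels = c("F3", "F4"), fs = 250,
                     seed = NULL, sd = 10) {
  if (!is.null(seed)) set.seed(seed)
  recording(matrix(rnorm(n * length(channels), sd = sd), ncol = length(channels)),
            fs, channels)
}

sine_wave <- function(freq, duration, fs, amp = 1, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t + phase)
}

# causal FIR convolution with zero-padded history (matches the adaptive
# filter's window convention)
fir_apply <- function(x, h) {
  y <- as.numeric(stats::filter(x, h, method = "convolution", sides = 1L))
  y[is.na(y)] <- 0
  y
}
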