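# Shared fixture builders. Everything is generated in code at test time;
# no stored data.

# Quick single-focus contraction video.
make_video <- function(frequency = 1, amplitude = 0.1, duration = 4,
                       frame_rate = 30, noise_sd = 0, seed = 1, ...) {
  gen_contraction_video(synthetic_video_spec(
    beat_waveform_spec(frequency, amplitude = amplitude),
    duration = duration, frame_rate = frame_rate,
    noise_sd = noise_sd, seed = seed, ...))
}

# Corrected trace straight from the calcium generator.
make_calcium_trace <- function(spec, smoothing_samples = 5L) {
  g <- gen_calcium_trace(spec)
  list(trace = as_corrected_trace(g$trace$time_s, g$trace$value,
                                  smoothing_samples = smoothing_samples),
       truth = g$truth)
}

# Independent brute-force Tukey fence (sort + interpolated quartiles),
# used as the oracle for the classifier.
brute_force_tukey <- function(v) {
  s <- sort(v)
  n <- length(s)
  qi <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  q1 <- qi(0.25); q3 <- qi(0.75)
  v > q3 + 1.5 * (q3 - q1)
}

# Disk mask centred in an h x w image.
disk_mask <- function(h, w, center = c((h + 1) / 2, (w + 1) / 2), radius) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  sqrt((rows - center[1])^2 + (cols - center[2])^2) <= radius
}
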