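# Brute-force oracles, written independently of the package's fast paths.

# Single-level separable DWT by explicit convolution and even-index
# (0-based) downsampling: output pixel (i, j) of band (fv, fh) is
# sum over (a, b) of x[2i - 2 + a, 2j - 2 + b] * fv[a] * fh[b].
oracle_dwt <- function(x, kl, kh) {
  h2 <- nrow(x) %/% 2L
  w2 <- ncol(x) %/% 2L
  band <- function(fv, fh) {
    out <- matrix(0, h2, w2)
    for (i in seq_len(h2)) for (j in seq_len(w2)) {
      acc <- 0
      for (a in 1:2) for (b in 1:2)
        acc <- acc + x[2L * i - 2L + a, 2L * j - 2L + b] * fv[a] * fh[b]
      out[i, j] <- acc
    }
    out
  }
  list(ll = band(kl, kl), lh = band(kl, kh), hl = band(kh, kl), hh = band(kh, kh))
}

# the low-pass-only recurrence: iterate (x * kl)↓2 along both axes
oracle_lowpass_chain <- function(x, kl, times) {
  for (t in seq_len(times)) {
    h2 <- nrow(x) %/% 2L; w2 <- ncol(x) %/% 2L
    out <- matrix(0, h2, w2)
    for (i in seq_len(h2)) for (j in seq_len(w2)) {
      acc <- 0
      for (a in 1:2) for (b in 1:2)
        acc <- acc + x[2L * i - 2L + a, 2L * j - 2L + b] * kl[a] * kl[b]
      out[i, j] <- acc
    }
    x <- out
  }
  x
}

subband_energy <- function(s) sum(s$ll^2) + sum(s$lh^2) + sum(s$hl^2) + sum(s$hh^2)

# tiny balanced manifest in memory (no files needed)
toy_manifest <- function(counts, grades = seq_along(counts) - 1L) {
  rows <- mapply(function(n, g) {
    if (n == 0L) return(NULL)
    data.frame(image_id = sprintf("img_g%d_%03d", g, seq_len(n)),
               path = sprintf("img_g%d_%03d.png", g, seq_len(n)),
               grade = g, provenance = "original", transform = NA_character_,
               stringsAsFactors = FALSE)
  }, counts, grades, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
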