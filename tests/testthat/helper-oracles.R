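# Shared fixtures and independent oracles.

# Brute-force four-deep-loop convolution reference (the oracle conv2d_valid
# is checked against); intentionally naive and independent of im2col.
conv_reference <- function(x, kernels, biases, stride = 1L) {
  d <- dim(x); kd <- dim(kernels)
  oh <- (d[1] - kd[1]) %/% stride + 1L
  ow <- (d[2] - kd[2]) %/% stride + 1L
  n <- if (length(d) == 4L) d[4] else 1L
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  out <- array(0, c(oh, ow, kd[4], n))
  for (b in seq_len(n)) for (oc in seq_len(kd[4])) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    acc <- biases[oc]
    for (ic in seq_len(kd[3])) for (a in seq_len(kd[1])) for (cc in seq_len(kd[2]))
      acc <- acc + x[(i - 1L) * stride + a, (j - 1L) * stride + cc, ic, b] *
        kernels[a, cc, ic, oc]
    out[i, j, oc, b] <- acc
  }
  out
}

# Brute-force tiled average pooling reference.
pool_reference <- function(x, size, stride = size) {
  d <- dim(x)
  n <- if (length(d) == 4L) d[4] else 1L
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  oh <- (d[1] - size) %/% stride + 1L
  ow <- (d[2] - size) %/% stride + 1L
  out <- array(0, c(oh, ow, d[3], n))
  for (b in seq_len(n)) for (cc in seq_len(d[3])) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    ri <- (i - 1L) * stride + seq_len(size)
    rj <- (j - 1L) * stride + seq_len(size)
    out[i, j, cc, b] <- mean(x[ri, rj, cc, b])
  }
  out
}

# Central finite differences of a scalar function at every coordinate of a
# parameter vector.
numeric_gradient <- function(f, p, h = 1e-5) {
  vapply(seq_along(p), function(i) {
    pp <- p; pp[i] <- p[i] + h
    pm <- p; pm[i] <- p[i] - h
    (f(pp) - f(pm)) / (2 * h)
  }, numeric(1))
}

rel_err <- function(a, b) abs(a - b) / pmax(1e-6, abs(a) + abs(b))

# Small toy backbone used by gradient checks (10x10 input, 3x3 kernels).
toy_net <- function(seed = 3L) {
  build_network(2L, seed = seed, modality_tag = "CT",
                kernel_size = 3L, input_size = 10L)
}

# Tiny deterministic cohort for IO / pipeline tests.
tiny_cohort <- function(n = 10L, seed = 1L, noise_sd = 0.05) {
  generate_cohort(cohort_spec(n, 0.5, ct_effect = 1, xray_effect = 1,
                              noise_sd = noise_sd, seed = seed))
}
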