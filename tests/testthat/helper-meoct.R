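# Shared fixtures and independent oracles for the test suite.

# Brute-force per-pixel two-pass speckle variance (independent of the
# vectorized implementation): explicit loops, mean then squared deviations.
sv_oracle <- function(a, norm = c("n", "n-1")) {
  norm <- match.arg(norm)
  n <- dim(a)[1]
  out <- matrix(0, dim(a)[2], dim(a)[3])
  for (i in seq_len(dim(a)[2])) {
    for (j in seq_len(dim(a)[3])) {
      v <- a[, i, j]
      m <- sum(v) / n
      ss <- sum((v - m)^2)
      out[i, j] <- ss / (if (norm == "n") n else n - 1)
    }
  }
  out
}

# Closed-form expected intensity along one A-line: Beer-Lambert cumulative
# transmission with the attenuation sum excluding the voxel itself.
aline_oracle <- function(backscatter, attenuation, dz, noise_floor) {
  nz <- length(backscatter)
  mu <- numeric(nz)
  cum <- 0
  for (k in seq_len(nz)) {
    mu[k] <- backscatter[k] * exp(-2 * cum) + noise_floor
    cum <- cum + attenuation[k] * dz
  }
  mu
}

# Two-sided pooled-t p-value via the regularized incomplete beta function,
# written from the t-distribution CDF identity (independent of stats::pt).
pooled_p_beta <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  v1 <- sum((x1 - mean(x1))^2) / (n1 - 1)
  v2 <- sum((x2 - mean(x2))^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  t <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  # P(|T| > t) = I_{df/(df + t^2)}(df/2, 1/2)
  list(t = t, p = stats::pbeta(df / (df + t^2), df / 2, 0.5))
}

# small fast ear for pipeline tests
tiny_ear <- function(preset = "glomus", seed = 11L)
  simulate_ear(preset, seed = seed, grid_shape = c(12L, 48L, 96L),
               keep_stacks = TRUE)

# published clinical group summaries used in the statistics tests
published_summaries <- function() list(
  structural = list(
    normal = group_summary(n = 6, mean = 0.082, se = 0.008, label = "normal"),
    glomus = group_summary(n = 6, mean = 0.620, se = 0.095, label = "glomus"),
    cholesteatoma = group_summary(n = 4, mean = 0.558, se = 0.153,
                                  label = "cholesteatoma")),
  angio = list(
    normal = group_summary(n = 3, mean = 0.615, se = 0.198, label = "normal"),
    glomus = group_summary(n = 3, mean = 1.881, se = 0.212, label = "glomus"),
    cholesteatoma = group_summary(n = 3, mean = 0.709, se = 0.043,
                                  label = "cholesteatoma"))
)
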