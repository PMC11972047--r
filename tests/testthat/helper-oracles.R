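# Independent oracles reimplemented from scratch for dual-route checks.

# Bragg-additivity RSP oracle: Bethe mass stopping power ratio times density,
# written independently of the package internals (constants restated here).
oracle_rsp <- function(density_g_cm3, fractions, E_MeV = 80) {
  el <- data.frame(
    sym = c("H", "C", "N", "O", "Gd"),
    Z   = c(1, 6, 7, 8, 64),
    A   = c(1.008, 12.011, 14.007, 15.999, 157.25),
    I   = c(19.2, 78.0, 82.0, 95.0, 591.0)
  )
  gamma <- 1 + E_MeV / 938.272
  beta2 <- 1 - 1 / gamma^2
  mass_stop <- function(fr) {
    i <- match(names(fr), el$sym)
    sum(fr * el$Z[i] / el$A[i] *
          (log(2 * 0.510999e6 * beta2 * gamma^2 / el$I[i]) - beta2))
  }
  water <- c(H = 2 * 1.008, O = 15.999) / (2 * 1.008 + 15.999)
  density_g_cm3 * mass_stop(fractions) / mass_stop(water)
}

# First-flight Monte-Carlo oracle for the screened point kernel: neutrons
# leave an isotropic point source, fly one straight exponential path of mean
# L, and score track length inside an axis-aligned box. The estimator's
# expectation is the volume integral of exp(-r/L)/(4 pi r^2) over the box.
mc_first_flight <- function(src, lo, hi, L, n = 1e5, seed = 1) {
  set.seed(seed)
  u <- cbind(stats::rnorm(n), stats::rnorm(n), stats::rnorm(n))
  u <- u / sqrt(rowSums(u^2))
  flight <- stats::rexp(n, rate = 1 / L)
  t0 <- rep(-Inf, n); t1 <- rep(Inf, n)
  for (k in 1:3) {
    a <- (lo[k] - src[k]) / u[, k]
    b <- (hi[k] - src[k]) / u[, k]
    t0 <- pmax(t0, pmin(a, b))
    t1 <- pmin(t1, pmax(a, b))
  }
  t0 <- pmax(t0, 0)
  track <- pmax(0, pmin(flight, t1) - t0)
  track[t1 <= t0] <- 0
  list(mean = mean(track), se = stats::sd(track) / sqrt(n))
}

# Deterministic fine-grid volume integral of the package kernel over a box.
kernel_box_integral <- function(src, lo, hi, L, cells = 20) {
  gx <- lo[1] + (seq_len(cells) - 0.5) * (hi[1] - lo[1]) / cells
  gy <- lo[2] + (seq_len(cells) - 0.5) * (hi[2] - lo[2]) / cells
  gz <- lo[3] + (seq_len(cells) - 0.5) * (hi[3] - lo[3]) / cells
  pts <- expand.grid(x = gx, y = gy, z = gz)
  r <- sqrt((pts$x - src[1])^2 + (pts$y - src[2])^2 + (pts$z - src[3])^2)
  dv <- prod(hi - lo) / cells^3
  sum(capture_kernel(r, L)) * dv
}
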