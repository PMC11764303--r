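# fixtures are built in code; no binary data anywhere in the package

make_trace <- function(values, dt = 2, source = "synthetic") {
  conductance_trace(seq(0, by = dt, length.out = length(values)),
                    values, source = source)
}

# a stressed recording with the canonical latency-rise-plateau-decline
# morphology: flat 4.48 uS to 20 s, linear rise to 6.99 uS at 42 s, high
# plateau drifting to 6.90 uS at 94 s, then a slow decline that never reaches
# the half-recovery level before the recording ends at 174 s
worked_stress_trace <- function() {
  t <- seq(0, 174, by = 2)
  y <- numeric(length(t))
  y[t <= 20] <- 4.48
  r <- t > 20 & t <= 42
  y[r] <- 4.48 + (6.99 - 4.48) * (t[r] - 20) / 22
  p <- t > 42 & t <= 94
  y[p] <- 6.99 - 0.09 * (t[p] - 42) / 52
  d <- t > 94
  y[d] <- 6.90 - 0.60 * (t[d] - 94) / 80
  conductance_trace(t, y, source = "native")
}

# densely sampled symmetric triangular bump: linear up over `rise` s, linear
# down over `fall` s, atop a flat tonic level
dense_triangle_trace <- function(tonic = 2, amp = 1, onset = 10, rise = 10,
                                 fall = 10, total = 40, dt = 0.01) {
  t <- seq(0, total, by = dt)
  up <- t >= onset & t <= onset + rise
  dn <- t > onset + rise & t <= onset + rise + fall
  y <- rep(tonic, length(t))
  y[up] <- tonic + amp * (t[up] - onset) / rise
  y[dn] <- tonic + amp * (1 - (t[dn] - onset - rise) / fall)
  conductance_trace(t, y, source = "synthetic")
}

# two-blob and XOR toys for the ML layer
blob_toy <- function(n_per = 10, sep = 3, seed = 5) {
  set.seed(seed)
  x <- rbind(
    cbind(rnorm(n_per, 0, 0.2), rnorm(n_per, 0, 0.2)),
    cbind(rnorm(n_per, sep, 0.2), rnorm(n_per, sep, 0.2))
  )
  list(x = data.frame(peak_amplitude = x[, 1], phasic_max = x[, 2]),
       labels = rep(c("relaxed", "stressed"), each = n_per))
}

xor_toy <- function(n_per = 10, seed = 9) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  lab <- rep(c("a", "a", "b", "b"), each = n_per)
  x <- centers[rep(1:4, each = n_per), ] + matrix(rnorm(8 * n_per, 0, 0.08),
                                                  ncol = 2)
  list(x = data.frame(f1 = x[, 1], f2 = x[, 2]), labels = lab)
}
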