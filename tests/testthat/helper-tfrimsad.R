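# Shared helpers and independent oracles for the test suite.

# Closed-form RIC impedance, written independently of the package internals:
# Z(f) = R + j(2 pi f I - 1 / (2 pi f C)).
oracle_ric <- function(R, I, C, f) {
  complex(real = rep(R, length(f)),
          imaginary = 2 * pi * f * I - 1 / (2 * pi * f * C))
}

oracle_fres <- function(I, C) 1 / (2 * pi * sqrt(I * C))

# Reference noise-free RIC model used across the oracle tests.
ref_model <- function(noise = 0) {
  ios_impedance_model(R0 = 0.35, I = 0.00065, C = 0.20,
                      noise_sd_p = noise, noise_sd_f = noise)
}

# Naive step-by-step linear-scan oracle for the ZOH recurrence with constant
# per-step parameters (independent of the package scan implementation).
oracle_scan_fixed <- function(x, a, delta, b, c, Dskip = 0) {
  h <- rep(0, length(a))
  y <- numeric(length(x))
  for (t in seq_along(x)) {
    Abar <- exp(delta * a)
    bbar <- ifelse(abs(a) < 1e-14, delta * b, (exp(delta * a) - 1) / a * b)
    h <- Abar * h + bbar * x[t]
    y[t] <- sum(c * h) + Dskip * x[t]
  }
  y
}

# Naive selective-scan oracle: regenerates (Delta, b, c) from each input the
# same way the published recurrence prescribes, one step at a time.
oracle_scan_selective <- function(x, p) {
  L <- nrow(x); D <- ncol(x); N <- ncol(p$A)
  h <- matrix(0, D, N)
  y <- matrix(0, L, D)
  for (t in seq_len(L)) {
    xt <- x[t, ]
    delta <- log1p(exp(as.vector(t(p$W_delta) %*% xt) + p$b_delta))
    bt <- as.vector(t(p$W_b) %*% xt)
    ct <- as.vector(t(p$W_c) %*% xt)
    for (d in seq_len(D)) {
      for (nn in seq_len(N)) {
        a <- p$A[d, nn]
        Abar <- exp(delta[d] * a)
        bbar <- if (abs(a) < 1e-14) delta[d] * bt[nn] else
          (exp(delta[d] * a) - 1) / a * bt[nn]
        h[d, nn] <- Abar * h[d, nn] + bbar * xt[d]
      }
      y[t, d] <- sum(ct * h[d, ]) + p$Dskip[d] * xt[d]
    }
  }
  y
}

# Reduced architecture for fast network tests.
tiny_network_config <- function() {
  cfg <- default_config()$network
  cfg$stem_channels <- 4L
  cfg$branch_width1 <- 2L
  cfg$branch_width2 <- 2L
  cfg$cbam_reduction <- 2L
  cfg$temporal_channels <- 4L
  cfg$state_size <- 2L
  cfg$demo_hidden <- c(4L, 4L, 4L)
  cfg$head_hidden <- 4L
  cfg$dropout <- 0
  cfg
}

# Small-but-trainable architecture used by the end-to-end tests.
reduced_pipeline_config <- function() {
  cfg <- default_config()
  cfg$network$stem_channels <- 8L
  cfg$network$branch_width1 <- 8L
  cfg$network$branch_width2 <- 16L
  cfg$network$cbam_reduction <- 4L
  cfg$network$temporal_channels <- 16L
  cfg$network$state_size <- 4L
  cfg$network$demo_hidden <- c(8L, 16L, 16L)
  cfg$network$head_hidden <- 32L
  cfg$network$dropout <- 0.2
  cfg$training$lr <- 1e-3
  cfg$training$batch_size <- 16L
  cfg$training$max_epochs <- 45L
  cfg$training$patience <- 12L
  cfg
}

expect_rel_error <- function(est, truth, tol) {
  expect_lt(max(abs(est - truth) / abs(truth)), tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
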