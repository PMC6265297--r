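# Shared fixtures: small, fast configurations derived from the canonical
# study conditions, plus an independent brute-force secondary-structure
# oracle used to cross-check the package classifier.

# coarse ionic protocol (10 mV steps) for fast pipeline tests
coarse_ionic_protocol <- function() {
  ionic_protocol(step_voltages = seq(-80, 60, by = 10))
}

# coarse gating protocol (25 mV steps) for conservation checks
coarse_gating_protocol <- function(sample_rate = 200) {
  gating_protocol(by = 25, sample_rate = sample_rate)
}

artifact_free_cell <- function(seed = 1L) {
  cell_model(C_lin = 0, tau_clamp = 0.3, g_leak = 0, noise_sd = 0,
             seed = seed)
}

# Independent secondary-structure oracle: enumerates every donor/acceptor
# pair directly from raw coordinates (its own hydrogen placement and
# energy arithmetic, no package geometry helpers), then applies the
# two-consecutive-turn rule.  Deliberately plain and quadratic.
oracle_ss_labels <- function(structure, frame = 1L, cutoff = -0.5) {
  f <- structure$frames[[frame]]
  n <- length(structure$resno)
  dist3 <- function(a, b) sqrt(sum((a - b)^2))
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (!is.null(f$H) && !any(is.na(f$H[i, ]))) { H[i, ] <- f$H[i, ]; next }
    if (i == 1L) next
    if (structure$resno[i] %in% structure$ester_sites) next
    v1 <- f$N[i, ] - f$C[i - 1L, ]; v1 <- v1 / dist3(f$C[i - 1L, ], f$N[i, ])
    v2 <- f$N[i, ] - f$O[i - 1L, ]; v2 <- v2 / dist3(f$O[i - 1L, ], f$N[i, ])
    u <- v1 + v2; u <- u / sqrt(sum(u^2))
    H[i, ] <- f$N[i, ] + 1.01 * u
  }
  bond <- matrix(FALSE, n, n)  # bond[donor, acceptor]
  for (j in seq_len(n)) {
    if (any(is.na(H[j, ]))) next
    for (i in seq_len(n)) {
      if (abs(j - i) < 2L) next
      e <- 27.888 * (1 / dist3(f$O[i, ], f$N[j, ]) +
                     1 / dist3(f$C[i, ], H[j, ]) -
                     1 / dist3(f$O[i, ], H[j, ]) -
                     1 / dist3(f$C[i, ], f$N[j, ]))
      if (e < cutoff) bond[j, i] <- TRUE
    }
  }
  turn <- function(k) vapply(seq_len(n), function(i)
    i + k <= n && bond[i + k, i], TRUE)
  labels <- rep("C", n)
  for (cls in list(list(4L, "H"), list(3L, "G"), list(5L, "I"))) {
    k <- cls[[1L]]; lab <- cls[[2L]]
    t <- turn(k)
    for (i in seq_len(n)) {
      if (i > 1L && t[i] && t[i - 1L]) {
        span <- i:min(i + k - 1L, n)
        labels[span][labels[span] %in% c("C", "T")] <- lab
      }
    }
  }
  for (k in 3:5) {
    t <- turn(k)
    for (i in which(t)) {
      span <- (i + 1L):min(i + k - 1L, n)
      labels[span][labels[span] == "C"] <- "T"
    }
  }
  labels
}

# rigid-body transform of every frame of a structure
transform_structure <- function(structure, R = diag(3), shift = c(0, 0, 0)) {
  for (fr in seq_along(structure$frames)) {
    for (nm in names(structure$frames[[fr]])) {
      xyz <- structure$frames[[fr]][[nm]]
      if (is.null(xyz)) next
      ok <- !apply(is.na(xyz), 1, any)
      xyz[ok, ] <- sweep(xyz[ok, , drop = FALSE] %*% t(R), 2, shift, `+`)
      structure$frames[[fr]][[nm]] <- xyz
    }
  }
  structure
}

rotation_xyz <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}
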