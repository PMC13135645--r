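# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# brute-force Mann-Whitney AUC: explicit double loop over all pairs
oracle_auc <- function(values, labels, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  s <- 0
  for (i in pos) for (j in neg) {
    if (values[i] > values[j]) s <- s + 1
    else if (values[i] == values[j]) s <- s + 0.5
  }
  s / (length(pos) * length(neg))
}

# time-stepping Crank-Nicolson solve of the radial momentum equation for one
# harmonic of oscillatory tube flow, marched to periodicity; returns the
# complex wall-shear amplitude for a prescribed complex flow amplitude.
# Independent of the package's Bessel-series and harmonic-BVP paths.
oracle_fd_harmonic <- function(R, w, qn, mu, rho, n_r = 240,
                               n_periods = 24, steps_per_period = 256) {
  r <- seq(0, R, length.out = n_r)
  h <- r[2] - r[1]
  dt <- (2 * pi / w) / steps_per_period
  # operator L u = u'' + u'/r (axis by symmetry), Dirichlet at wall
  main <- rep(-2 / h^2, n_r); lo <- numeric(n_r); up <- numeric(n_r)
  lo[2:(n_r - 1)] <- 1 / h^2 - 1 / (2 * r[2:(n_r - 1)] * h)
  up[2:(n_r - 1)] <- 1 / h^2 + 1 / (2 * r[2:(n_r - 1)] * h)
  main[1] <- -4 / h^2; up[1] <- 4 / h^2
  main[n_r] <- 1; lo[n_r] <- 0; up[n_r] <- 0
  a <- mu * dt / (2 * rho)
  # (I - a L) u_new = (I + a L) u_old + dt/rho * G(t_mid)
  A_lo <- -a * lo; A_mn <- 1 - a * main; A_up <- -a * up
  A_mn[n_r] <- 1; A_lo[n_r] <- 0; A_up[n_r] <- 0
  thomas <- function(lo, mn, up, b) {
    n <- length(mn)
    cp <- numeric(n); dp <- complex(n)
    cp <- as.complex(cp)
    cp[1] <- up[1] / mn[1]; dp[1] <- b[1] / mn[1]
    for (i in 2:n) {
      m <- mn[i] - lo[i] * cp[i - 1]
      cp[i] <- if (i < n) up[i] / m else 0
      dp[i] <- (b[i] - lo[i] * dp[i - 1]) / m
    }
    x <- complex(n); x[n] <- dp[n]
    for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
    x
  }
  u <- complex(n_r)      # start from rest; G(t) = exp(i w t), unit amplitude
  t <- 0
  n_steps <- n_periods * steps_per_period
  tau_t <- complex(steps_per_period)
  q_t <- complex(steps_per_period)
  for (s in seq_len(n_steps)) {
    gmid <- exp(1i * w * (t + dt / 2))
    rhs <- u + a * (lo * c(0, u[-n_r]) + main * u + up * c(u[-1], 0)) +
      dt / rho * gmid
    rhs[n_r] <- 0
    u <- thomas(A_lo, A_mn, A_up, rhs)
    t <- t + dt
    if (s > (n_periods - 1) * steps_per_period) {
      k <- s - (n_periods - 1) * steps_per_period
      tau_t[k] <- -mu * (3 * u[n_r] - 4 * u[n_r - 1] + u[n_r - 2]) / (2 * h)
      q_t[k] <- 2 * pi * sum((r * u)[-n_r] + (r * u)[-1]) / 2 * h
    }
  }
  # project the last period onto exp(i w t)
  tt <- (seq_len(steps_per_period)) * dt + (n_periods - 1) * (2 * pi / w)
  basis <- exp(-1i * w * tt)
  tau_hat_unit <- mean(tau_t * basis) * 2 / 1   # complex amplitude wrt G=e^{iwt}
  q_hat_unit <- mean(q_t * basis) * 2 / 1
  tau_hat_unit / q_hat_unit * qn
}

# flat square patch mesh in the xy-plane (not closed; for metric tests)
flat_patch_mesh <- function(n = 10, L = 10) {
  xs <- seq(0, L, length.out = n + 1)
  grid <- as.matrix(expand.grid(x = xs, y = xs))
  verts <- cbind(grid, 0)
  idx <- function(i, j) (j - 1L) * (n + 1L) + i
  faces <- NULL
  for (j in seq_len(n)) for (i in seq_len(n)) {
    faces <- rbind(faces,
                   c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                   c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  tri_mesh(verts, faces)
}

# constant-direction traction series with magnitude profile mag_t
uniform_direction_series <- function(mesh, times, period, mag_t,
                                     dir = c(1, 0, 0)) {
  nf <- nrow(mesh$faces)
  arr <- array(0, dim = c(nf, 3, length(times)))
  for (j in seq_along(times))
    arr[, , j] <- matrix(dir * mag_t[j], nf, 3, byrow = TRUE)
  surface_field_series(mesh, times, period, arr)
}
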