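#' Pulsatile (Womersley) wall shear in a rigid straight tube
#'
#' Computes the wall-shear time series produced by a prescribed flow
#' waveform in fully developed axisymmetric flow through a rigid circular
#' tube. The steady component is Poiseuille shear `4 mu Q0 / (pi R^3)`. Each
#' harmonic is the classical rigid-tube oscillatory-flow solution with the
#' pressure-gradient amplitude scaled so that the harmonic's flow matches
#' the waveform; wall shear is `mu` times the radial velocity gradient at
#' the wall:
#' `tau_n = -mu Q_n Lambda J1(Lambda) / (pi R^3 F(Lambda) J0(Lambda))`,
#' with `Lambda = i^{3/2} alpha`, `alpha = R sqrt(n Omega rho / mu)` the
#' Womersley number and `F = 1 - 2 J1(Lambda) / (Lambda J0(Lambda))`.
#'
#' Bessel functions of complex argument are evaluated by power series, which
#' is accurate for the Womersley numbers of arm vessels; above
#' `alpha_max` the harmonic is instead solved by a radial finite-difference
#' discretisation of the oscillatory momentum equation (with a warning).
#'
#' @param radius tube radius, mm.
#' @param waveform a [flow_waveform()] (ml/min).
#' @param viscosity dynamic viscosity, Pa s (default blood, 3.5e-3).
#' @param density fluid density, kg/m^3 (default blood, 1050).
#' @param alpha_max Womersley number above which the finite-difference path
#'   is used.
#' @param n_radial radial nodes for the finite-difference path.
#' @return object of class `wall_shear_series`: `times` (s), `tau` signed
#'   axial wall shear (Pa), `tau_mag` its magnitude, `steady_tau` (Pa),
#'   per-harmonic `alpha` and complex `tau_hat`, and the inputs.
#' @export
womersley_wall_shear <- function(radius, waveform, viscosity = 3.5e-3,
                                 density = 1050, alpha_max = 40,
                                 n_radial = 200) {
  if (radius <= 0 || viscosity <= 0 || density <= 0)
    stop("radius, viscosity and density must be > 0")
  stopifnot(inherits(waveform, "flow_waveform"))
  R <- radius * 1e-3                       # m
  om <- 2 * pi / waveform$period
  q0 <- waveform$mean_flow * ml_min_to_m3s
  tau0 <- 4 * viscosity * q0 / (pi * R^3)
  t <- waveform$sample_times
  tau <- rep(tau0, length(t))
  nh <- length(waveform$harmonic_index)
  alphas <- numeric(nh)
  tau_hat <- complex(nh)
  methods <- character(nh)
  for (k in seq_len(nh)) {
    n <- waveform$harmonic_index[k]
    qn <- waveform$harmonic_amplitude[k] * ml_min_to_m3s
    alpha <- R * sqrt(n * om * density / viscosity)
    alphas[k] <- alpha
    if (alpha <= alpha_max) {
      lam <- complex(modulus = alpha, argument = 3 * pi / 4)
      j0 <- besselJ_series(lam, 0L)
      j1 <- besselJ_series(lam, 1L)
      Fl <- 1 - 2 * j1 / (lam * j0)
      tau_hat[k] <- -viscosity * qn * lam * j1 / (pi * R^3 * Fl * j0)
      methods[k] <- "bessel"
    } else {
      warning(sprintf("harmonic %d: Womersley number %.1f beyond series stability; using finite differences",
                      n, alpha))
      tau_hat[k] <- fd_harmonic_wall_shear(R, n * om, qn, viscosity, density,
                                           n_radial)
      methods[k] <- "fd"
    }
    tau <- tau + Re(tau_hat[k] * exp(1i * n * om * t))
  }
  structure(list(times = t, tau = tau, tau_mag = abs(tau), steady_tau = tau0,
                 alpha = alphas, tau_hat = tau_hat, method = methods,
                 radius = radius, viscosity = viscosity, density = density,
                 waveform = waveform),
            class = "wall_shear_series")
}

#' @export
print.wall_shear_series <- function(x, ...) {
  cat(sprintf("wall_shear_series: steady %.3f Pa, range [%.3f, %.3f] Pa, %d harmonic(s)\n",
              x$steady_tau, min(x$tau), max(x$tau), length(x$alpha)))
  if (length(x$alpha))
    cat(sprintf("  Womersley numbers: %s\n",
                paste(sprintf("%.2f", x$alpha), collapse = ", ")))
  invisible(x)
}

ml_min_to_m3s <- 1e-6 / 60

# Bessel J0/J1 of complex argument by power series; adequate for |z| <~ 40
besselJ_series <- function(z, nu) {
  term <- if (nu == 0L) 1 + 0i else z / 2
  total <- term
  for (k in 1:200) {
    term <- -term * (z / 2)^2 / (k * (k + nu))
    total <- total + term
    if (Mod(term) < 1e-17 * Mod(total)) break
  }
  total
}

# one harmonic of the oscillatory tube-flow problem by central differences:
# i rho w u = G + mu (u'' + u'/r), u(R) = 0, u'(0) = 0; solved with unit G,
# scaled so the flow matches qn; returns complex wall shear -mu u'(R) * scale
fd_harmonic_wall_shear <- function(R, w, qn, mu, rho, n_radial) {
  nr <- max(50L, n_radial)
  r <- seq(0, R, length.out = nr)
  h <- r[2] - r[1]
  # complex tridiagonal system A u = b
  lower <- complex(real = rep(0, nr)); diagv <- lower; upper <- lower
  b <- complex(real = rep(0, nr))
  iw <- 1i * rho * w
  for (j in 2:(nr - 1)) {
    lower[j] <- mu * (1 / h^2 - 1 / (2 * r[j] * h))
    diagv[j] <- -2 * mu / h^2 - iw
    upper[j] <- mu * (1 / h^2 + 1 / (2 * r[j] * h))
    b[j] <- -1
  }
  # r = 0: symmetry, u'' term -> 4(u1 - u0)/h^2 (L'Hopital for u'/r)
  diagv[1] <- -4 * mu / h^2 - iw
  upper[1] <- 4 * mu / h^2
  b[1] <- -1
  diagv[nr] <- 1 + 0i
  lower[nr] <- 0
  b[nr] <- 0
  u <- thomas_solve(lower, diagv, upper, b)
  q_unit <- 2 * pi * sum((r * u)[-nr] + (r * u)[-1]) / 2 * h   # trapezoid
  scale <- qn / q_unit
  dudr_wall <- (3 * u[nr] - 4 * u[nr - 1] + u[nr - 2]) / (2 * h)
  -mu * dudr_wall * scale
}

thomas_solve <- function(lower, diagv, upper, b) {
  n <- length(diagv)
  cp <- complex(n); dp <- complex(n)
  cp[1] <- upper[1] / diagv[1]
  dp[1] <- b[1] / diagv[1]
  for (i in 2:n) {
    m <- diagv[i] - lower[i] * cp[i - 1]
    cp[i] <- if (i < n) upper[i] / m else 0
    dp[i] <- (b[i] - lower[i] * dp[i - 1]) / m
  }
  x <- complex(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Map a tube wall-shear series onto a mesh as a traction field
#'
#' Builds a [surface_field_series()] whose per-face traction is the signed
#' axial wall shear directed along the surface-tangential projection of the
#' tube axis (or of the local centreline tangent).
#'
#' @param mesh a [tri_mesh()] of the tube.
#' @param shear a `wall_shear_series` from [womersley_wall_shear()].
#' @param axis 3-vector tube axis, or a [centreline()] for curved tubes.
#' @param faces optional face subset to populate (others get zero traction).
#' @return a [surface_field_series()].
#' @export
axial_traction_series <- function(mesh, shear, axis = c(1, 0, 0), faces = NULL) {
  nrm <- face_normals(mesh)
  nf <- nrow(nrm)
  if (inherits(axis, "centreline")) {
    cen <- face_centroids(mesh)
    idx <- vapply(seq_len(nf), function(i)
      which.min(colSums((t(axis$points) - cen[i, ])^2)), 0L)
    ax <- axis$tangent[idx, , drop = FALSE]
  } else {
    ax <- matrix(axis / sqrt(sum(axis^2)), nf, 3, byrow = TRUE)
  }
  tang <- ax - nrm * rowSums(ax * nrm)
  tl <- sqrt(rowSums(tang^2))
  ok <- tl > 1e-8
  tang[ok, ] <- tang[ok, ] / tl[ok]
  tang[!ok, ] <- 0
  if (!is.null(faces)) {
    keep <- logical(nf); keep[faces] <- TRUE
    tang[!keep, ] <- 0
  }
  nt <- length(shear$times)
  arr <- array(0, dim = c(nf, 3, nt))
  for (j in seq_len(nt)) arr[, , j] <- tang * shear$tau[j]
  surface_field_series(mesh, shear$times, shear$waveform$period, arr)
}
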