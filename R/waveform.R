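#' Pulsatile flow waveform
#'
#' A volumetric flow waveform over one cardiac cycle, represented as a steady
#' component plus complex Fourier harmonics:
#' `Q(t) = mean_flow + sum_k Re(A_k exp(i n_k Omega t))` with
#' `Omega = 2 pi / period`. Flow is in ml/min at the interface.
#'
#' @param mean_flow steady (cycle-mean) flow, ml/min.
#' @param harmonics list of `c(n = harmonic index, amplitude = complex
#'   ml/min)` entries, or a complex vector named by harmonic index.
#' @param period cardiac period, s (> 0).
#' @param n_samples number of uniform sample times over `[0, period)`.
#' @param sample_times explicit sample times (s): strictly increasing, first
#'   0, last < period; overrides `n_samples`.
#' @return object of class `flow_waveform`.
#' @export
flow_waveform <- function(mean_flow, harmonics = list(), period = 1,
                          n_samples = 64, sample_times = NULL) {
  if (period <= 0) stop("period must be > 0")
  if (is.complex(harmonics) || is.numeric(harmonics)) {
    idx <- as.integer(names(harmonics))
    if (any(is.na(idx))) stop("harmonic vector must be named by harmonic index")
    harmonics <- Map(function(n, a) list(n = n, amplitude = as.complex(a)),
                     idx, harmonics)
  }
  ns <- vapply(harmonics, function(h) as.integer(h[["n"]]), 0L)
  amp <- vapply(harmonics, function(h) as.complex(h[["amplitude"]]), complex(1))
  if (any(ns < 1)) stop("harmonic indices must be >= 1")
  if (anyDuplicated(ns)) stop("duplicate harmonic indices")
  if (is.null(sample_times)) {
    sample_times <- seq(0, period, length.out = n_samples + 1)[seq_len(n_samples)]
  } else {
    if (sample_times[1] != 0) stop("sample_times must start at 0")
    if (any(diff(sample_times) <= 0)) stop("sample_times must be strictly increasing")
    if (sample_times[length(sample_times)] >= period)
      stop("sample_times must stay below the period")
  }
  structure(list(period = period, mean_flow = mean_flow,
                 harmonic_index = ns, harmonic_amplitude = amp,
                 sample_times = sample_times),
            class = "flow_waveform")
}

#' @rdname flow_waveform
#' @param waveform a `flow_waveform`.
#' @param t times (s) at which to evaluate; defaults to the sample times.
#' @return `waveform_flow()`: Q(t) in ml/min.
#' @export
waveform_flow <- function(waveform, t = waveform$sample_times) {
  om <- 2 * pi / waveform$period
  q <- rep(waveform$mean_flow, length(t))
  for (k in seq_along(waveform$harmonic_index)) {
    q <- q + Re(waveform$harmonic_amplitude[k] *
                  exp(1i * waveform$harmonic_index[k] * om * t))
  }
  q
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("flow_waveform: mean %.0f ml/min, period %.2f s, %d harmonic(s), %d samples\n",
              x$mean_flow, x$period, length(x$harmonic_index),
              length(x$sample_times)))
  invisible(x)
}

#' Physiologic and test waveform presets
#'
#' `"steady"`: constant flow. `"pulsatile"`: steady plus two harmonics
#' (fundamental at 45% of mean with a quarter-cycle lag, second harmonic at
#' 15%), a compact stand-in for a fistula inflow waveform; positive
#' throughout for the default amplitudes. `"oscillatory"`: zero-mean
#' sinusoid, the fully-oscillatory end of the regime range.
#'
#' @param name preset name.
#' @param mean_flow cycle-mean flow in ml/min (amplitude scale for
#'   `"oscillatory"`).
#' @param period cardiac period (s).
#' @param n_samples samples per cycle.
#' @return a [flow_waveform()].
#' @export
waveform_preset <- function(name = c("pulsatile", "steady", "oscillatory"),
                            mean_flow = 600, period = 1, n_samples = 64) {
  name <- match.arg(name)
  switch(name,
    steady = flow_waveform(mean_flow, list(), period, n_samples),
    pulsatile = {
      wf <- flow_waveform(mean_flow,
                          list(list(n = 1L, amplitude = -0.45i * mean_flow),
                               list(n = 2L, amplitude = 0.15 * mean_flow)),
                          period, n_samples)
      if (any(waveform_flow(wf) <= 0))
        stop("pulsatile preset must remain positive")
      wf
    },
    oscillatory = flow_waveform(0, list(list(n = 1L, amplitude = mean_flow + 0i)),
                                period, n_samples))
}

#' Index of peak systole
#'
#' The sample index at which the reconstructed flow is largest; ties resolve
#' to the earliest sample.
#'
#' @param waveform a [flow_waveform()].
#' @return integer index into `waveform$sample_times`.
#' @export
peak_systole_index <- function(waveform) {
  q <- waveform_flow(waveform)
  which.max(round(q, 12))
}
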