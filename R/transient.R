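#' Inlet velocity waveform
#'
#' A periodic waveform normalized to unit mean: the instantaneous inlet
#' velocity is the prescribed mean velocity times
#' `s(t) = 1 + sum_k Re( c_k exp(i k w t) )`, `w = 2 pi / period`.
#'
#' @param period cardiac-cycle length, s.
#' @param harmonics data.frame with columns `k` (harmonic order), `amp`
#'   (modulus of the relative complex amplitude `c_k`) and `phase`
#'   (radians).
#' @return object of class `waveform` with the complex amplitudes attached.
#' @export
arterial_waveform <- function(period = 0.137, harmonics = NULL) {
  if (period <= 0) stop("period must be > 0")
  if (is.null(harmonics))
    harmonics <- data.frame(k = integer(), amp = numeric(), phase = numeric())
  ck <- complex(modulus = harmonics$amp, argument = harmonics$phase)
  wf <- structure(list(period = period, mean = 1,
                       harmonics = data.frame(k = harmonics$k, c = ck)),
                  class = "waveform")
  if (nrow(wf$harmonics) &&
      min(reconstruct_waveform(wf, seq(0, period, length.out = 1001))) <= 0)
    warning("waveform is not strictly positive over the cycle ",
            "(flow reversal at inlets)")
  wf
}

#' @rdname arterial_waveform
#' @param waveform a `waveform`.
#' @param times numeric vector, s.
#' @return `reconstruct_waveform` returns the dimensionless signal at
#'   `times`.
#' @export
reconstruct_waveform <- function(waveform, times) {
  w <- 2 * pi / waveform$period
  s <- rep(1, length(times))
  for (i in seq_len(nrow(waveform$harmonics))) {
    h <- waveform$harmonics[i, ]
    s <- s + Re(h$c * exp(1i * h$k * w * times))
  }
  s
}

#' Default parametric murine arterial waveform
#'
#' A smooth strictly positive pulse built from a von Mises-type shape
#' `exp(kappa (cos(2 pi (t - t0)/T) - 1))` whose Fourier coefficients are
#' modified Bessel ratios `c_k = 2 I_k(kappa)/I_0(kappa)`; with the default
#' `kappa = 0.55` the systolic peak is about 1.6x the cycle mean. This is a
#' documented stand-in for a measured murine velocity waveform; any measured
#' shape can be supplied through [arterial_waveform()].
#'
#' @param period cardiac-cycle length, s.
#' @param kappa pulse-shape concentration (larger = peakier).
#' @param peak_time_frac systolic peak position as a fraction of the cycle.
#' @param n_harmonics number of retained harmonics.
#' @return a `waveform`.
#' @export
default_waveform <- function(period = 0.137, kappa = 0.55,
                             peak_time_frac = 0.30, n_harmonics = 8) {
  k <- seq_len(n_harmonics)
  amp <- 2 * besselI(kappa, k) / besselI(kappa, 0)
  phase <- -k * 2 * pi * peak_time_frac
  arterial_waveform(period, data.frame(k = k, amp = amp, phase = phase))
}

#' Transient solver configuration
#'
#' @param time_step target time step, s. By default the step is snapped to a
#'   periodic grid (`period / ceiling(period / time_step)`, 28 intervals for
#'   the default 0.137 s cycle) so cycle averages are exact; `strict_grid =
#'   TRUE` keeps the literal step instead.
#' @param n_harmonics number of inlet-waveform harmonics to solve.
#' @param strict_grid keep the literal `time_step` (last interval short).
#' @param allow_reversal if `FALSE` (default), a waveform whose
#'   reconstructed inlet signal goes non-positive is rejected with an error;
#'   if `TRUE` it is only warned about.
#' @return object of class `transient_config`.
#' @export
transient_config <- function(time_step = 0.005, n_harmonics = 8,
                             strict_grid = FALSE, allow_reversal = FALSE) {
  if (time_step <= 0) stop("time_step must be > 0")
  structure(list(time_step = time_step, n_harmonics = n_harmonics,
                 strict_grid = strict_grid, allow_reversal = allow_reversal),
            class = "transient_config")
}

#' Pulsatile network blood-flow solve
#'
#' Harmonic-superposition counterpart of [solve_steady()]: the mean (DC)
#' component is the steady solve; each retained waveform harmonic is solved
#' on the same network with complex Womersley segment impedances at
#' `w_k = 2 pi k / T` and boundary flows scaled by that harmonic's complex
#' amplitude (so outlet flow stays proportional to outlet area at every
#' instant). Time series are reconstructed on a uniform one-cycle grid; the
#' cycle average of every flow equals the steady solution by construction.
#'
#' @param net a `vascular_network`.
#' @param inlets named mean inlet velocities, cm/s.
#' @param blood a [blood_properties()] object.
#' @param waveform a `waveform`; default [default_waveform()].
#' @param cfg a [transient_config()].
#' @return object of class `time_series_state`: `times` (s), `flows`
#'   (segments x times, mm^3/s), `pressures` (nodes x times, mmHg),
#'   `harmonics` (per-harmonic complex phasors and per-segment Womersley
#'   numbers), `steady` (the cycle-averaged `pressure_flow_state`),
#'   `waveform`, `blood`.
#' @export
solve_transient <- function(net, inlets, blood = blood_properties(),
                            waveform = default_waveform(),
                            cfg = transient_config()) {
  if (cfg$time_step >= waveform$period)
    stop("time_step must be smaller than the waveform period")
  smin <- min(reconstruct_waveform(
    waveform, seq(0, waveform$period, length.out = 1001)))
  if (smin <= 0) {
    msg <- "waveform reconstructs to non-positive inlet flow"
    if (cfg$allow_reversal) warning(msg) else stop(msg)
  }
  steady <- solve_steady(net, inlets, blood)
  inj0 <- steady$boundary$injection
  K <- min(cfg$n_harmonics, nrow(waveform$harmonics))
  harm <- vector("list", K)
  if (K > 0) for (ki in seq_len(K)) {
    h <- waveform$harmonics[ki, ]
    omega <- 2 * pi * h$k / waveform$period
    Z <- vapply(seq_len(nrow(net$segments)), function(e)
      segment_impedance(net$segments[e, ], blood, omega), complex(1))
    st <- .solve_injection(net, h$c * inj0, blood, weights = 1 / Z)
    alpha <- womersley_alpha(equivalent_radius(net$segments$area), omega,
                             blood$nu_mm2_s)
    harm[[ki]] <- list(k = h$k, omega = omega, c = h$c,
                       flows = st$flows, pressures = st$pressures,
                       alpha = setNames(alpha, net$segments$id))
  }
  n_steps <- if (cfg$strict_grid) ceiling(waveform$period / cfg$time_step)
  else ceiling(waveform$period / cfg$time_step)
  dt <- if (cfg$strict_grid) cfg$time_step else waveform$period / n_steps
  times <- (seq_len(n_steps) - 1) * dt
  flows <- matrix(rep(Re(steady$flows), length(times)),
                  nrow = nrow(net$segments),
                  dimnames = list(net$segments$id, NULL))
  prs <- matrix(rep(Re(steady$pressures), length(times)),
                nrow = nrow(net$nodes),
                dimnames = list(net$nodes$id, NULL))
  for (h in harm) {
    ph <- exp(1i * h$omega * times)
    flows <- flows + Re(outer(h$flows, ph))
    prs <- prs + Re(outer(h$pressures, ph))
  }
  avg <- rowMeans(flows)
  if (!cfg$strict_grid &&
      max(abs(avg - Re(steady$flows))) >
      1e-9 * max(abs(steady$boundary$injection)))
    stop("internal error: cycle-averaged flows deviate from the steady solve")
  structure(list(times = times, flows = flows, pressures = prs,
                 harmonics = harm, steady = steady, waveform = waveform,
                 blood = blood),
            class = "time_series_state")
}

#' Maximum blood-flow velocity through a section plane
#'
#' Steady mode: peak of the parabolic Poiseuille profile, twice the sectional
#' mean velocity. Transient mode: the Womersley radial profile of every
#' harmonic is reconstructed on a radial grid, superposed with the parabolic
#' mean profile at each time point, and the spatial maximum is averaged over
#' the cardiac cycle.
#'
#' @param state a `pressure_flow_state` or `time_series_state`.
#' @param net the network the state was solved on.
#' @param index section plane index.
#' @param blood a [blood_properties()] object.
#' @param n_radial radial grid size for the transient profile.
#' @return maximum velocity, cm/s.
#' @export
max_velocity <- function(state, net, index, blood = blood_properties(),
                         n_radial = 101) {
  i <- match(index, net$sections$index)
  if (is.na(i)) stop("unknown section index ", index)
  A <- net$sections$area[i]
  if (A <= 0) stop("section area must be > 0")
  seg <- net$sections$segment_id[i]
  if (inherits(state, "pressure_flow_state")) {
    vmean <- abs(state$flows[[seg]]) / A          # mm/s
    return(2 * vmean / .CMS_TO_MMS)
  }
  if (!inherits(state, "time_series_state"))
    stop("state must be a pressure_flow_state or time_series_state")
  y <- seq(0, 1, length.out = n_radial)
  v0 <- Re(state$steady$flows[[seg]]) / A
  prof <- outer(2 * v0 * (1 - y^2), rep(1, length(state$times)))
  r <- equivalent_radius(A)
  for (h in state$harmonics) {
    alpha <- womersley_alpha(r, h$omega, blood$nu_mm2_s)
    phi <- .womersley_profile(alpha, y)
    vk <- h$flows[[seg]] / A
    prof <- prof + Re(outer(vk * phi, exp(1i * h$omega * state$times)))
  }
  mean(apply(abs(prof), 2, max)) / .CMS_TO_MMS
}
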