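# Ultrasound exposure arithmetic and a zero-dimensional (Pennes-style)
# bio-heat estimate for pulsed protocols: absorption heating at rate
# dT/dt = 2 * alpha * I / (rho * c) during sonication, Newtonian perfusion
# cooling with time constant tau_perf otherwise. Intensities are handled in
# mW/cm^2 at the interface and converted to W/m^2 internally.

#' Duty cycle from tone burst duration and pulse repetition frequency
#'
#' @param tbd tone burst duration (ms).
#' @param prf pulse repetition frequency (kHz).
#' @return duty cycle fraction `tbd * prf`; errors if the burst exceeds the
#'   pulse period.
#' @export
duty_cycle <- function(tbd, prf) {
  check_number(tbd, "tbd", min = 0, strict = TRUE)
  check_number(prf, "prf", min = 0, strict = TRUE)
  if (tbd > 1 / prf)
    stopf("tone burst (%g ms) exceeds the pulse period (%g ms)", tbd, 1 / prf)
  tbd * prf
}

#' Temporal-average intensity from pulse-average intensity
#'
#' `Ispta = Isppa * dc` for a rectangular pulse train.
#'
#' @param isppa spatial-peak pulse-average intensity (mW/cm^2).
#' @param dc duty cycle fraction in `[0, 1]`.
#' @return Ispta (mW/cm^2).
#' @export
ispta_from_isppa <- function(isppa, dc) {
  check_number(isppa, "isppa", min = 0)
  check_number(dc, "dc", min = 0)
  if (dc > 1) stopf("`dc` must be a fraction in [0, 1]")
  isppa * dc
}

#' Mechanical index
#'
#' `MI = PNP / sqrt(fc)` with PNP in MPa and fc in MHz. Values above the
#' regulatory limit of 1.9 trigger a warning and are flagged in the
#' `exceeds_limit` attribute.
#'
#' @param pnp peak negative pressure (MPa).
#' @param fc center frequency (MHz).
#' @return the mechanical index (dimensionless).
#' @export
mechanical_index <- function(pnp, fc) {
  check_number(pnp, "pnp", min = 0, strict = TRUE)
  check_number(fc, "fc", min = 0, strict = TRUE)
  mi <- pnp / sqrt(fc)
  if (mi > 1.9)
    warning(sprintf("MI %.3g exceeds the 1.9 regulatory safety limit", mi))
  structure(mi, exceeds_limit = mi > 1.9)
}

#' Tissue parameters for the bio-heat estimate
#'
#' Defaults are standard brain-tissue literature values at 1 MHz: acoustic
#' absorption 0.04 Np/cm, density 1040 kg/m^3, specific heat 3630 J/kg/K,
#' perfusion cooling time constant 60 s.
#'
#' @param alpha acoustic absorption (Np/cm at the working frequency).
#' @param rho tissue density (kg/m^3).
#' @param c_heat specific heat capacity (J/kg/K).
#' @param tau_perf perfusion time constant (s); `Inf` disables cooling.
#' @return object of class `tissue_params`.
#' @export
tissue_params <- function(alpha = 0.04, rho = 1040, c_heat = 3630,
                          tau_perf = 60) {
  for (f in c("alpha", "rho", "c_heat"))
    check_number(get(f), f, min = 0, strict = TRUE)
  if (!(is.numeric(tau_perf) && length(tau_perf) == 1L && tau_perf > 0))
    stopf("`tau_perf` must be a positive number (Inf allowed)")
  structure(list(alpha = alpha, rho = rho, c_heat = c_heat,
                 tau_perf = tau_perf), class = "tissue_params")
}

# analytic one-segment update: heating rate H (K/s) against relaxation tau
heat_segment <- function(T0, H, tau, t) {
  if (is.infinite(tau)) T0 + H * t
  else T0 * exp(-t / tau) + H * tau * (1 - exp(-t / tau))
}

#' Temperature rise over a pulsed ultrasound train
#'
#' Zero-dimensional bio-heat estimate: during each sonication of `sd`
#' seconds the focus heats at `dT/dt = 2 alpha I / (rho c) - dT / tau`, and
#' relaxes with the perfusion time constant during each inter-stimulus
#' interval. `I` is the temporal-average intensity during sonication (the
#' calibrated Ispta level, which already averages over the within-burst duty
#' cycle). The trace is evaluated analytically segment by segment (the
#' piecewise-constant heating admits an exact exponential solution) and
#' sampled on a `dt` grid.
#'
#' @param protocol a [stim_protocol()] providing `sd` and `isi`.
#' @param ispta temporal-average intensity during sonication (mW/cm^2).
#' @param tissue a [tissue_params()].
#' @param n_pulses number of sonication pulses (>= 1).
#' @param dt trace sampling interval (s).
#' @return object of class `dose_report`: list with `dT_max` (deg C),
#'   `dT_trace` (data.frame `time`, `dT`), `ispta`, `isppa`, `pnp` (from the
#'   protocol calibration table when the level is listed, else `NA`), `mi`
#'   (when `pnp` known), `dc`.
#' @export
bioheat_rise <- function(protocol = stim_protocol(), ispta,
                         tissue = tissue_params(), n_pulses = 50, dt = 0.01) {
  validate_protocol(protocol)
  stopifnot(inherits(tissue, "tissue_params"))
  check_number(ispta, "ispta", min = 0)
  if (n_pulses < 1L) stopf("`n_pulses` must be >= 1")
  I_wm2 <- ispta * 10                       # mW/cm^2 -> W/m^2
  alpha_m <- tissue$alpha * 100             # Np/cm -> Np/m
  H <- 2 * alpha_m * I_wm2 / (tissue$rho * tissue$c_heat)   # K/s
  tau <- tissue$tau_perf
  times <- numeric(0); temps <- numeric(0)
  T0 <- 0; t_abs <- 0
  for (p in seq_len(n_pulses)) {
    for (seg in list(c(H, protocol$sd), c(0, protocol$isi))) {
      tt <- seq(dt, seg[2], by = dt)
      if (!length(tt) || tt[length(tt)] < seg[2]) tt <- c(tt, seg[2])
      temps <- c(temps, heat_segment(T0, seg[1], tau, tt))
      times <- c(times, t_abs + tt)
      T0 <- temps[length(temps)]
      t_abs <- t_abs + seg[2]
    }
  }
  structure(list(
    dT_max = max(temps), dT_trace = data.frame(time = times, dT = temps),
    ispta = ispta, isppa = ispta / protocol$dc,
    pnp = tryCatch(calibration_lookup(ispta, protocol$levels),
                   error = function(e) NA_real_),
    mi = NA_real_, dc = protocol$dc),
    class = "dose_report") -> rep_
  if (!is.na(rep_$pnp)) rep_$mi <- as.numeric(mechanical_index(rep_$pnp, protocol$ff))
  rep_
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> Ispta %g mW/cm^2 (Isppa %g, DC %g%%)\n",
              x$ispta, x$isppa, 100 * x$dc))
  if (!is.na(x$pnp)) cat(sprintf("  PNP %g MPa, MI %.3g\n", x$pnp, x$mi))
  cat(sprintf("  max temperature rise: %.4g degC over %g s\n",
              x$dT_max, max(x$dT_trace$time)))
  invisible(x)
}

#' Calibrated peak negative pressure for an intensity level
#'
#' Looks up the empirical intensity/pressure calibration table; the printed
#' pairs are measured, not derivable from the plane-wave relation, so exact
#' matches are preferred and interpolation is opt-in.
#'
#' @param level Ispta level (mW/cm^2).
#' @param table data.frame with `ispta` and `pnp` columns (e.g.
#'   `stim_protocol()$levels`).
#' @param interpolate allow linear interpolation between table entries.
#' @return PNP in MPa.
#' @export
calibration_lookup <- function(level, table = stim_protocol()$levels,
                               interpolate = FALSE) {
  hit <- which(abs(table$ispta - level) < 1e-9)
  if (length(hit)) return(table$pnp[hit[1L]])
  if (!interpolate)
    stopf("level %g mW/cm^2 not in the calibration table (use interpolate = TRUE)",
          level)
  if (level < min(table$ispta) || level > max(table$ispta))
    stopf("level %g outside the calibrated range %g-%g mW/cm^2",
          level, min(table$ispta), max(table$ispta))
  approx(table$ispta, table$pnp, xout = level)$y
}

#' Plane-wave intensity/pressure conversion (approximate)
#'
#' For a plane travelling wave, `I = p^2 / (2 rho c)`. Measured calibration
#' pairs in focused transcranial fields deviate from this relation; use the
#' empirical [calibration_lookup()] for dosimetry and this converter only as
#' a sanity check.
#'
#' @param pnp peak (negative) pressure in MPa.
#' @param rho medium density (kg/m^3), default soft tissue 1040.
#' @param c_sound speed of sound (m/s), default 1540.
#' @return pulse-average intensity (mW/cm^2).
#' @export
planewave_intensity <- function(pnp, rho = 1040, c_sound = 1540) {
  check_number(pnp, "pnp", min = 0)
  (pnp * 1e6)^2 / (2 * rho * c_sound) / 10   # W/m^2 -> mW/cm^2
}
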