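#' Load a packaged group preset as a synthesis specification
#'
#' The package ships generative presets for the four experimental groups
#' (`CON`, `MscL-G22S`, `MscL-G22N`, `MscS`) at the three calibrated
#' ultrasound intensities (100, 250, 400 mW/cm^2 Ispta). Three modes select
#' what the session is for:
#' \describe{
#'   \item{`"spontaneous"`}{background only: band composition at the full
#'     background scale, no stimulation gain, no evoked component.}
#'   \item{`"session"`}{full pre/stim/post session: stimulation power gain
#'     and evoked component for the chosen intensity.}
#'   \item{`"uep"`}{evoked-trial blocks: evoked component for the chosen
#'     intensity over a low-amplitude background (`uep_rms`), emulating the
#'     effective signal-to-noise of referenced evoked-potential recordings.}
#' }
#'
#' @param group one of `"CON"`, `"MscL-G22S"`, `"MscL-G22N"`, `"MscS"`.
#' @param intensity Ispta level in mW/cm^2: 100, 250 or 400.
#' @param mode `"spontaneous"`, `"session"` or `"uep"`.
#' @param fs sampling rate override (Hz); default from the preset file.
#' @param seed RNG seed stored in the returned spec.
#' @param line_noise logical: include the preset 50 Hz + odd-harmonic
#'   interference (default `TRUE` for `"session"`, `FALSE` otherwise, since
#'   spontaneous/UEP benchmarks target the biological signal).
#' @param path preset YAML; defaults to the file installed with the package.
#' @return a [synth_spec()].
#' @export
load_preset <- function(group = c("CON", "MscL-G22S", "MscL-G22N", "MscS"),
                        intensity = 400,
                        mode = c("session", "spontaneous", "uep"),
                        fs = NULL, seed = NULL, line_noise = NULL,
                        path = NULL) {
  group <- match.arg(group)
  mode <- match.arg(mode)
  path <- path %||% system.file("extdata", "presets.yaml", package = "sonolfp")
  if (!nzchar(path) || !file.exists(path)) stopf("preset file not found")
  cfg <- yaml::read_yaml(path)
  g <- cfg$groups[[group]]
  if (is.null(g)) stopf("no preset for group '%s'", group)
  key <- paste0("i", intensity)
  if (!key %in% names(g$stim_power_gain))
    stopf("no preset intensity %s for group '%s'", intensity, group)
  fractions <- unlist(g$band_fractions)
  evoked <- g$evoked[[key]]
  ln <- if (line_noise %||% (mode == "session")) {
    lapply(cfg$line_noise, function(v) if (is.list(v)) unlist(v) else v)
  } else NULL
  synth_spec(
    band_fractions = fractions,
    total_rms = if (mode == "uep") cfg$uep_rms else cfg$total_rms,
    evoked = if (mode == "spontaneous") NULL else evoked,
    stim_power_gain = if (mode == "session") g$stim_power_gain[[key]] else 0,
    line_noise = ln,
    fs = fs %||% cfg$fs,
    phase_len = cfg$phase_len,
    seed = seed)
}
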