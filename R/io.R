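# Recording file I/O: delimited text (one column per channel, header row) and
# an interleaved little-endian float32 container, both with a `<file>.json`
# metadata sidecar (fs, channel count/labels, units, t0, sync flag, onsets).

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(rec, path, format = "delimited", sync_channel = NULL) {
  meta <- list(format = format, fs = rec$fs, n_channels = nrow(rec$samples),
               channel_ids = rec$channel_ids, units = "uV", t0 = rec$t0,
               stim_onsets = rec$stim_onsets, sync_channel = sync_channel)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a recording to disk
#'
#' `delimited` writes tab-separated text with one column per channel and a
#' header row of channel labels; `binary` writes interleaved little-endian
#' float32 frames (all channels of sample 1, then sample 2, ...). Both
#' formats carry a JSON sidecar at `<path>.json` with sampling rate, channel
#' labels, units and stimulation onsets, so recordings round-trip.
#'
#' @param rec an [recording()].
#' @param path output file.
#' @param format `"delimited"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("delimited", "binary")) {
  stopifnot(inherits(rec, "lfp_recording"))
  format <- match.arg(format)
  if (format == "delimited") {
    d <- as.data.frame(t(rec$samples))
    names(d) <- rec$channel_ids
    utils::write.table(d, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(rec$samples), con, size = 4L, endian = "little")
  }
  write_sidecar(rec, path, format = format)
  invisible(path)
}

#' Read a recording from disk
#'
#' Inverse of [write_recording()]. A sidecar `<path>.json` is required for
#' the binary format (channel count is not recoverable without it) and used
#' when present for delimited text. If the sidecar flags a sync channel (or
#' `sync_channel` is given), that channel is consumed into `stim_onsets` via
#' [extract_sync_onsets()] and excluded from `samples`.
#'
#' @param path input file.
#' @param format `"auto"` (sniff: binary iff the sidecar says so or the file
#'   is not valid text), `"delimited"` or `"binary"`.
#' @param fs sampling rate (Hz); required if no sidecar provides it.
#' @param sync_channel label of the sync channel to consume, if any.
#' @param sync_threshold threshold for [extract_sync_onsets()] (default:
#'   midpoint of the sync-channel range).
#' @param refractory sync merge window (s).
#' @return an [recording()].
#' @export
read_recording <- function(path, format = c("auto", "delimited", "binary"),
                           fs = NULL, sync_channel = NULL,
                           sync_threshold = NULL, refractory = 0.3) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("recording file not found: %s", path)
  if (file.size(path) == 0L) stopf("structure error: empty recording file %s", path)
  meta <- read_sidecar(path)
  if (format == "auto")
    format <- if (!is.null(meta$format)) meta$format
      else if (grepl("\\.(bin|dat|raw)$", path, ignore.case = TRUE)) "binary"
      else "delimited"
  fs <- meta$fs %||% fs
  if (is.null(fs)) stopf("sampling rate unknown: pass `fs` or provide a sidecar")

  if (format == "binary") {
    if (is.null(meta))
      stopf("format error: binary recording %s has no JSON sidecar", path)
    nch <- meta$n_channels
    if (is.null(nch)) stopf("format error: sidecar lacks `n_channels`")
    nbytes <- file.size(path)
    nval <- nbytes %/% 4L
    if (nval %% nch != 0L)
      stopf("structure error: %d float32 values not divisible by %d channels",
            nval, nch)
    con <- file(path, "rb")
    on.exit(close(con))
    x <- readBin(con, what = "numeric", n = nval, size = 4L, endian = "little")
    samples <- matrix(x, nrow = nch)
  } else {
    d <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t",
                                    check.names = FALSE),
                  error = function(e) stopf("structure error reading %s: %s",
                                            path, conditionMessage(e)))
    if (!nrow(d) || !ncol(d)) stopf("structure error: no data in %s", path)
    samples <- t(as.matrix(d))
    if (!is.null(meta$n_channels) && nrow(samples) != meta$n_channels)
      stopf("structure error: sidecar says %d channels, file has %d",
            meta$n_channels, nrow(samples))
  }
  ids <- meta$channel_ids %||% rownames(samples) %||%
    paste0("ch", seq_len(nrow(samples)))
  rownames(samples) <- ids
  t0 <- meta$t0 %||% 0
  onsets <- as.numeric(meta$stim_onsets %||% numeric())

  sync_channel <- sync_channel %||% meta$sync_channel
  if (!is.null(sync_channel)) {
    if (!sync_channel %in% ids)
      stopf("sync channel '%s' not among channels: %s", sync_channel,
            paste(ids, collapse = ", "))
    sync <- samples[sync_channel, ]
    samples <- samples[setdiff(ids, sync_channel), , drop = FALSE]
    ids <- rownames(samples)
    onsets <- extract_sync_onsets(sync, fs, threshold = sync_threshold,
                                  refractory = refractory, t0 = t0)
  }
  recording(samples, fs = fs, t0 = t0, stim_onsets = onsets,
            channel_ids = ids, meta = as.list(meta$extra %||% list()))
}
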