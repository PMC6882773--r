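# Session container: paired multichannel neural recording, audio track,
# word-event annotations and per-channel anatomical region labels.

REGIONS <- c("IFG", "PMv", "M1v", "OTHER")

#' Construct a recording session
#'
#' The universal input record: a multichannel neural recording with
#' per-channel region labels (inferior frontal gyrus IFG, ventral premotor
#' PMv, ventral motor M1v, or OTHER), a simultaneously recorded mono audio
#' track, and word-event annotations.
#'
#' @param neural channels x samples numeric matrix.
#' @param neural_rate neural sampling rate in Hz (2000 in the reference
#'   recording setup).
#' @param audio numeric vector of audio samples.
#' @param audio_rate audio sampling rate in Hz (48000 in the reference setup).
#' @param channels data.frame with columns `name` and `region`
#'   (one of `"IFG"`, `"PMv"`, `"M1v"`, `"OTHER"`); one row per neural
#'   channel.  If omitted, regions are parsed from names of the form
#'   `REGION_idx` (unparseable prefixes map to OTHER).
#' @param words data.frame with columns `label`, `onset`, `offset`
#'   (seconds relative to recording start, half-open `[onset, offset)`).
#' @param session_id identifier string.
#' @return object of class `b2s_session`.
#' @export
session <- function(neural, neural_rate, audio, audio_rate,
                    channels = NULL, words = NULL, session_id = "session") {
  neural <- as.matrix(neural)
  if (is.null(channels)) {
    nm <- rownames(neural)
    if (is.null(nm)) nm <- sprintf("OTHER_%d", seq_len(nrow(neural)))
    channels <- data.frame(name = nm, region = parse_region(nm))
  }
  if (is.null(words))
    words <- data.frame(label = character(), onset = numeric(),
                        offset = numeric())
  s <- structure(list(
    neural = neural, neural_rate = neural_rate,
    audio = as.numeric(audio), audio_rate = audio_rate,
    channels = channels,
    words = words[, c("label", "onset", "offset")],
    session_id = session_id
  ), class = "b2s_session")
  validate_session(s)
}

#' Parse anatomical regions from channel names
#'
#' Names of the form `REGION_idx` (e.g. `"M1v_3"`) map to that region;
#' anything unparseable maps to `"OTHER"`.
#'
#' @param names character vector of channel names.
#' @return character vector of regions.
#' @export
parse_region <- function(names) {
  pre <- sub("_.*$", "", names)
  ifelse(pre %in% REGIONS, pre, "OTHER")
}

#' Validate a session's structural invariants
#'
#' Checks positive rates, channel-table/matrix agreement, region values, and
#' that every word event lies inside both recordings with positive length.
#'
#' @param s a `b2s_session`.
#' @return `s`, invisibly as itself, on success; otherwise an error naming
#'   the offending field or word event.
#' @export
validate_session <- function(s) {
  stopifnot(inherits(s, "b2s_session"))
  if (!(s$neural_rate > 0) || !(s$audio_rate > 0))
    stop("sampling rates must be positive")
  if (nrow(s$neural) < 1 || ncol(s$neural) < 1)
    stop("neural matrix must have >= 1 channel and >= 1 sample")
  if (nrow(s$channels) != nrow(s$neural))
    stop("channel table has ", nrow(s$channels), " rows but neural matrix has ",
         nrow(s$neural), " channels")
  bad <- setdiff(s$channels$region, REGIONS)
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  dur <- session_duration(s)
  w <- s$words
  if (nrow(w)) {
    if (any(!nzchar(w$label))) stop("empty word label at row ",
                                    which(!nzchar(w$label))[1])
    ok <- w$onset >= 0 & w$onset < w$offset & w$offset <= dur + 1e-9
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf(
        "word event %d ('%s', %.3f-%.3f s) outside recordings (duration %.3f s) or non-positive",
        i, w$label[i], w$onset[i], w$offset[i], dur))
    }
  }
  invisible(s)
}

#' Common duration of a session's recordings
#'
#' @param s a `b2s_session`.
#' @return `min(neural duration, audio duration)` in seconds.
#' @export
session_duration <- function(s) {
  min(ncol(s$neural) / s$neural_rate, length(s$audio) / s$audio_rate)
}

#' @export
print.b2s_session <- function(x, ...) {
  cat(sprintf("<b2s_session '%s'>\n", x$session_id))
  cat(sprintf("  neural: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$neural), ncol(x$neural), x$neural_rate,
              ncol(x$neural) / x$neural_rate))
  cat(sprintf("  audio:  %d samples @ %g Hz (%.1f s)\n",
              length(x$audio), x$audio_rate, length(x$audio) / x$audio_rate))
  rc <- table(factor(x$channels$region, levels = REGIONS))
  cat("  regions:", paste(sprintf("%s=%d", names(rc), rc), collapse = " "), "\n")
  cat(sprintf("  words:  %d events, %d distinct labels\n",
              nrow(x$words), length(unique(x$words$label))))
  invisible(x)
}

#' Write a session to a directory
#'
#' Emits the package's native container: `audio.wav` (16-bit PCM mono),
#' `neural.f64` (raw little-endian float64, sample-major: all channels of
#' sample 1, then sample 2, ...), `neural.json` (rate, dimensions, channel
#' name/region table, session id) and `words.tsv`
#' (`label<TAB>onset<TAB>offset`, header row, seconds).
#' [read_session()] inverts it; audio round-trips within one 16-bit LSB.
#'
#' @param s a valid `b2s_session`.
#' @param out_dir output directory (created if missing).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_session <- function(s, out_dir) {
  validate_session(s)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  paths <- c(neural = file.path(out_dir, "neural.json"),
             audio = file.path(out_dir, "audio.wav"),
             labels = file.path(out_dir, "words.tsv"))
  bin <- file.path(out_dir, "neural.f64")
  con <- file(bin, "wb")
  writeBin(as.vector(s$neural), con, size = 8, endian = "little")
  close(con)
  meta <- list(session_id = s$session_id, rate = s$neural_rate,
               n_channels = nrow(s$neural), n_samples = ncol(s$neural),
               audio_rate = s$audio_rate, data_file = "neural.f64",
               channels = s$channels)
  jsonlite::write_json(meta, paths[["neural"]], auto_unbox = TRUE,
                       digits = NA)
  write_wav(s$audio, s$audio_rate, paths[["audio"]])
  write.table(s$words, paths[["labels"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, neural_data = bin))
}

#' Read a session from its container files
#'
#' @param neural_path path to the `neural.json` metadata file; the raw
#'   float64 matrix is located through its `data_file` entry.
#' @param audio_path mono PCM WAV file.
#' @param labels_path TSV with header `label<TAB>onset<TAB>offset`.
#' @return a validated `b2s_session`.
#' @export
read_session <- function(neural_path, audio_path, labels_path) {
  for (p in c(neural_path, audio_path, labels_path))
    if (!file.exists(p)) stop("no such file: ", p)
  meta <- jsonlite::read_json(neural_path, simplifyVector = TRUE)
  bin <- file.path(dirname(neural_path), meta$data_file)
  if (!file.exists(bin)) stop("no such file: ", bin)
  n <- meta$n_channels * meta$n_samples
  con <- file(bin, "rb")
  vals <- readBin(con, "numeric", n, size = 8, endian = "little")
  close(con)
  if (length(vals) != n) stop("neural data file truncated: ", bin)
  neural <- matrix(vals, nrow = meta$n_channels)
  rownames(neural) <- meta$channels$name
  wav <- read_wav(audio_path)
  if (abs(wav$rate - meta$audio_rate) > 0.5)
    stop("audio rate mismatch between WAV and metadata")
  words <- read_words_tsv(labels_path)
  session(neural, meta$rate, wav$samples, wav$rate,
          channels = as.data.frame(meta$channels), words = words,
          session_id = meta$session_id)
}

#' Read a session given its directory
#'
#' Convenience wrapper over [read_session()] for the native layout.
#'
#' @param dir directory written by [write_session()].
#' @return a validated `b2s_session`.
#' @export
read_session_dir <- function(dir) {
  read_session(file.path(dir, "neural.json"), file.path(dir, "audio.wav"),
               file.path(dir, "words.tsv"))
}

#' Read word events from a TSV file
#'
#' @param path TSV with header `label<TAB>onset<TAB>offset` (seconds).
#' @return data.frame with columns `label`, `onset`, `offset`.
#' @export
read_words_tsv <- function(path) {
  w <- read.delim(path, sep = "\t", colClasses = c("character", "numeric",
                                                   "numeric"))
  if (!identical(names(w), c("label", "onset", "offset")))
    stop("labels TSV must have header 'label<TAB>onset<TAB>offset'")
  w
}
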