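# Minimal GDF 2.x reader/writer.
#
# No established GDF reader exists in this toolchain, so a small subset of the
# GDF 2.20 container is implemented directly: the 256-byte fixed header (we
# use the record count at byte 236, record duration at 244 and channel count
# at 252), the field-major per-channel header (labels, physical/digital
# ranges, samples per record, sample type), int16- or float32-coded data
# records, and a mode-1/mode-3 event table. This is sufficient for files laid
# out like the BCI Competition IV 2a/2b recordings; the writer exists so that
# fixtures can be synthesized and round-tripped in tests.

GDF_EVENT_TRIAL_START <- 768L
GDF_EVENT_CUES <- c(769L, 770L, 771L, 772L)
GDF_EVENT_REJECTED <- 1023L

read_fixed_string <- function(raw) {
  raw <- raw[raw != as.raw(0)]
  trimws(rawToChar(raw))
}

pad_raw <- function(s, n) {
  r <- charToRaw(s)
  if (length(r) > n) r <- r[seq_len(n)]
  c(r, rep(as.raw(0), n - length(r)))
}

#' Read a GDF file (minimal GDF 2.x subset)
#'
#' Parses the fixed header, per-channel header, the full signal matrix
#' (GDFTYP 3 = int16 with physical scaling, 16 = float32) and the event
#' table.
#'
#' @param path GDF file path.
#' @return list with \code{signals} (\code{[C, n_samples]} matrix, physical
#'   units), \code{fs}, \code{channel_names}, and \code{events}
#'   (data.frame with \code{pos} 1-based sample positions and \code{typ}
#'   event codes).
#' @export
read_gdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h1 <- readBin(con, "raw", 256L)
  if (length(h1) < 256L) stop_format("GDF header truncated in ", path)
  version <- read_fixed_string(h1[1:8])
  if (!startsWith(version, "GDF"))
    stop_format("not a GDF file (version string \"", version, "\")")
  hlen_blocks <- readBin(h1[185:186], "integer", 1L, size = 2L,
                         endian = "little", signed = FALSE)
  # record count is int64; low/high 32-bit words (counts here are < 2^31)
  lohi <- readBin(h1[237:244], "integer", 2L, size = 4L, endian = "little")
  ndr <- lohi[1] + lohi[2] * 2^32
  # record duration as a rational number (numerator / denominator)
  dur <- readBin(h1[245:252], "integer", 2L, size = 4L, endian = "little")
  ns <- readBin(h1[253:254], "integer", 1L, size = 2L, endian = "little",
                signed = FALSE)
  if (ns < 1) stop_format("GDF reports ", ns, " channels")
  h2 <- readBin(con, "raw", 256L * ns)
  labels <- vapply(seq_len(ns), function(i)
    read_fixed_string(h2[(i - 1L) * 16L + 1:16]), character(1))
  off <- 16L * ns + 80L * ns + 6L * ns + 2L * ns
  physmin <- readBin(h2[off + seq_len(8L * ns)], "double", ns, size = 8L,
                     endian = "little"); off <- off + 8L * ns
  physmax <- readBin(h2[off + seq_len(8L * ns)], "double", ns, size = 8L,
                     endian = "little"); off <- off + 8L * ns
  digmin <- readBin(h2[off + seq_len(8L * ns)], "double", ns, size = 8L,
                    endian = "little"); off <- off + 8L * ns
  digmax <- readBin(h2[off + seq_len(8L * ns)], "double", ns, size = 8L,
                    endian = "little"); off <- off + 8L * ns
  off <- off + 64L * ns + 4L * ns + 4L * ns + 4L * ns   # prefilter + lp/hp/notch
  spr <- readBin(h2[off + seq_len(4L * ns)], "integer", ns, size = 4L,
                 endian = "little"); off <- off + 4L * ns
  gdftyp <- readBin(h2[off + seq_len(4L * ns)], "integer", ns, size = 4L,
                    endian = "little")
  if (length(unique(spr)) != 1L)
    stop_format("mixed samples-per-record not supported")
  if (!all(gdftyp %in% c(3L, 16L)))
    stop_format("unsupported GDFTYP(s): ",
                paste(setdiff(unique(gdftyp), c(3L, 16L)), collapse = ", "))
  fs <- spr[1] * dur[2] / dur[1]
  # skip any extra header blocks beyond the channel fields we use
  extra <- (hlen_blocks - 1L - ns) * 256L
  if (extra > 0) readBin(con, "raw", extra)
  n_rec <- as.integer(ndr)
  total <- n_rec * spr[1]
  sig <- matrix(0, ns, total)
  for (r in seq_len(n_rec)) {
    at <- (r - 1L) * spr[1]
    for (ch in seq_len(ns)) {
      if (gdftyp[ch] == 16L) {
        v <- readBin(con, "numeric", spr[1], size = 4L, endian = "little")
      } else {
        raw_v <- readBin(con, "integer", spr[1], size = 2L,
                         endian = "little", signed = TRUE)
        v <- physmin[ch] + (raw_v - digmin[ch]) *
          (physmax[ch] - physmin[ch]) / (digmax[ch] - digmin[ch])
      }
      sig[ch, at + seq_len(spr[1])] <- v
    }
  }
  ev_head <- readBin(con, "raw", 8L)
  events <- data.frame(pos = integer(), typ = integer())
  if (length(ev_head) == 8L) {
    mode <- as.integer(ev_head[1])
    nev <- as.integer(ev_head[2]) + 256L * as.integer(ev_head[3]) +
      65536L * as.integer(ev_head[4])
    if (!mode %in% c(1L, 3L))
      stop_format("unsupported event-table mode ", mode)
    if (nev > 0) {
      pos <- readBin(con, "integer", nev, size = 4L, endian = "little")
      typ <- readBin(con, "integer", nev, size = 2L, endian = "little",
                     signed = FALSE)
      events <- data.frame(pos = pos, typ = typ)
    }
  }
  list(signals = sig, fs = fs, channel_names = labels, events = events)
}

#' Write a GDF file (minimal GDF 2.x subset)
#'
#' Stores signals as float32 with identity scaling and a mode-1 event table;
#' the exact inverse of [read_gdf()]. Intended for synthesizing test fixtures
#' laid out like BCI Competition IV recordings.
#'
#' @param path destination path.
#' @param signals \code{[C, n_samples]} numeric matrix.
#' @param fs sampling rate in Hz.
#' @param channel_names length-C channel names.
#' @param events data.frame with columns \code{pos} (1-based sample index)
#'   and \code{typ} (event code).
#' @return \code{path}, invisibly.
#' @export
write_gdf <- function(path, signals, fs, channel_names, events) {
  ns <- nrow(signals)
  stopifnot(length(channel_names) == ns)
  total <- ncol(signals)
  spr <- as.integer(fs)            # one record per second
  if (total %% spr != 0) {
    pad <- spr - total %% spr
    signals <- cbind(signals, matrix(0, ns, pad))
    total <- ncol(signals)
  }
  n_rec <- total %/% spr
  con <- file(path, "wb")
  on.exit(close(con))
  h1 <- rep(as.raw(0), 256L)
  h1[1:8] <- pad_raw("GDF 2.20", 8L)
  h1[185:186] <- writeBin(1L + ns, raw(), size = 2L,
                          endian = "little")[1:2]
  h1[237:244] <- c(writeBin(n_rec, raw(), size = 4L, endian = "little"),
                   writeBin(0L, raw(), size = 4L, endian = "little"))
  h1[245:252] <- writeBin(c(1L, 1L), raw(), size = 4L, endian = "little")
  h1[253:254] <- writeBin(ns, raw(), size = 2L, endian = "little")[1:2]
  writeBin(h1, con)
  h2 <- rep(as.raw(0), 256L * ns)
  for (i in seq_len(ns))
    h2[(i - 1L) * 16L + 1:16] <- pad_raw(channel_names[i], 16L)
  off <- 16L * ns + 80L * ns + 6L * ns + 2L * ns
  put_dbl <- function(h2, off, vals) {
    h2[off + seq_len(8L * ns)] <- writeBin(as.numeric(vals), raw(), size = 8L,
                                           endian = "little")
    h2
  }
  h2 <- put_dbl(h2, off, rep(-1e4, ns)); off <- off + 8L * ns  # physmin
  h2 <- put_dbl(h2, off, rep(1e4, ns)); off <- off + 8L * ns   # physmax
  h2 <- put_dbl(h2, off, rep(-1e4, ns)); off <- off + 8L * ns  # digmin
  h2 <- put_dbl(h2, off, rep(1e4, ns)); off <- off + 8L * ns   # digmax
  off <- off + 64L * ns + 4L * ns + 4L * ns + 4L * ns
  h2[off + seq_len(4L * ns)] <- writeBin(rep(spr, ns), raw(), size = 4L,
                                         endian = "little")
  off <- off + 4L * ns
  h2[off + seq_len(4L * ns)] <- writeBin(rep(16L, ns), raw(), size = 4L,
                                         endian = "little")
  writeBin(h2, con)
  for (r in seq_len(n_rec)) {
    at <- (r - 1L) * spr
    for (ch in seq_len(ns))
      writeBin(as.numeric(signals[ch, at + seq_len(spr)]), con, size = 4L,
               endian = "little")
  }
  nev <- nrow(events)
  writeBin(as.raw(c(1L, nev %% 256L, (nev %/% 256L) %% 256L,
                    nev %/% 65536L)), con)
  writeBin(writeBin(as.numeric(fs), raw(), size = 4L, endian = "little"), con)
  if (nev > 0) {
    writeBin(as.integer(events$pos), con, size = 4L, endian = "little")
    writeBin(as.integer(events$typ), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Load and epoch a GDF dataset
#'
#' Reads one or more GDF files (a single file, a character vector of files,
#' or a directory of \code{.gdf} files, each file one session), extracts one
#' epoch per cue event (codes 769-772 for the 4-class "2a" layout, 769-770
#' for the 2-class "2b" layout) over \code{window} seconds relative to cue
#' onset, maps cue codes to 0-based contiguous labels, drops EOG channels,
#' and (by default) excludes trials marked rejected (code 1023 within 2 s
#' before the cue).
#'
#' @param path file, files, or directory.
#' @param layout \code{"2a"} (4 classes, 22 EEG + 3 EOG channels) or
#'   \code{"2b"} (2 classes, 3 EEG + 3 EOG channels).
#' @param window numeric \code{c(start, end)} in seconds relative to cue
#'   onset; must be non-empty and lie inside the recording for every trial
#'   (the imagination period spans 4 s from the cue).
#' @param drop_channels channel names to remove (default: any whose name
#'   contains "EOG").
#' @param keep_rejected keep trials flagged by the artifact marker.
#' @param subject_id subject id stamped on the result.
#' @return an [epoch_set()]; \code{session_ids} number the files in order.
#' @export
load_gdf_dataset <- function(path, layout = c("2a", "2b"), window = c(0, 4),
                             drop_channels = NULL, keep_rejected = FALSE,
                             subject_id = "S1") {
  layout <- match.arg(layout)
  if (length(window) != 2L || !is.numeric(window) || diff(window) <= 0)
    stop_validation("window must be a non-empty c(start, end) interval in seconds")
  files <- if (length(path) == 1L && dir.exists(path))
    sort(list.files(path, pattern = "\\.gdf$", ignore.case = TRUE,
                    full.names = TRUE))
  else path
  if (length(files) == 0) stop("no GDF files found under ", path)
  for (f in files) if (!file.exists(f)) stop("no such file: ", f)
  cue_codes <- if (layout == "2a") GDF_EVENT_CUES else GDF_EVENT_CUES[1:2]
  class_names <- c("left_hand", "right_hand", "feet", "tongue")[
    seq_along(cue_codes)]
  all_data <- list(); all_labels <- list(); all_sessions <- list()
  chans <- NULL; fs <- NULL
  for (si in seq_along(files)) {
    g <- read_gdf(files[si])
    drop <- drop_channels %||% grep("EOG", g$channel_names, value = TRUE)
    keep <- !(g$channel_names %in% drop)
    if (is.null(chans)) {
      chans <- g$channel_names[keep]
      fs <- g$fs
    } else if (!identical(g$channel_names[keep], chans)) {
      stop_format("channel layout differs between sessions in ", files[si])
    }
    known <- c(GDF_EVENT_TRIAL_START, GDF_EVENT_CUES, GDF_EVENT_REJECTED,
               276L, 277L, 781L, 783L, 1072L, 1077L, 1078L, 1079L, 1081L,
               32766L)
    unknown <- setdiff(unique(g$events$typ), known)
    if (length(unknown) > 0)
      stop_format("unknown event code(s) in ", basename(files[si]), ": ",
                  paste(unknown, collapse = ", "))
    cues <- g$events[g$events$typ %in% cue_codes, , drop = FALSE]
    rej_pos <- g$events$pos[g$events$typ == GDF_EVENT_REJECTED]
    i0 <- round(window[1] * g$fs)
    i1 <- round(window[2] * g$fs)
    Tlen <- i1 - i0
    if (Tlen < 1) stop_validation("window shorter than one sample")
    for (j in seq_len(nrow(cues))) {
      p <- cues$pos[j]
      if (!keep_rejected &&
          any(rej_pos >= p - 2 * g$fs & rej_pos <= p)) next
      a <- p + i0
      b <- p + i1 - 1L
      if (a < 1 || b > ncol(g$signals))
        stop_validation("window [", window[1], ", ", window[2],
                        "] s exceeds recording bounds at cue sample ", p)
      all_data[[length(all_data) + 1L]] <- g$signals[keep, a:b, drop = FALSE]
      all_labels[[length(all_labels) + 1L]] <-
        match(cues$typ[j], cue_codes) - 1L
      all_sessions[[length(all_sessions) + 1L]] <- si
    }
  }
  K <- length(all_data)
  if (K == 0) stop_format("no usable cue events found")
  Tlen <- ncol(all_data[[1]])
  data <- array(0, dim = c(length(chans), Tlen, K))
  for (k in seq_len(K)) data[, , k] <- all_data[[k]]
  epoch_set(data, unlist(all_labels), fs, chans, subject_id,
            unlist(all_sessions), class_names)
}
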