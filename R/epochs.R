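#' Labelled EEG trial container
#'
#' Holds \code{K} epoched trials of \code{C} channels by \code{T} samples
#' (stored channel-first as a \code{[C, T, K]} array, in microvolts) together
#' with 0-based integer class labels, the sampling rate, channel names,
#' subject id and per-trial session ids.
#'
#' @param data numeric array \code{[C, T, K]}; all entries finite.
#' @param labels integer vector of length \code{K} with values in
#'   \code{0..(n_classes - 1)}.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector of length \code{C}.
#' @param subject_id subject identifier string.
#' @param session_ids integer vector of length \code{K} (default all 1).
#' @param class_names character vector naming the classes; its length fixes
#'   \code{n_classes} (default \code{class_0 ...} up to the largest label).
#' @return an object of class \code{epoch_set}.
#' @export
epoch_set <- function(data, labels, fs, channel_names,
                      subject_id = "S1", session_ids = NULL,
                      class_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_validation("data must be a [C, T, K] array")
  d <- dim(data)
  K <- d[3]
  labels <- as.integer(labels)
  if (length(labels) != K)
    stop_validation("length(labels) = ", length(labels), " but K = ", K)
  if (is.null(session_ids)) session_ids <- rep(1L, K)
  session_ids <- as.integer(session_ids)
  if (length(session_ids) != K)
    stop_validation("length(session_ids) must equal K = ", K)
  if (length(channel_names) != d[1])
    stop_validation("length(channel_names) = ", length(channel_names),
                    " but C = ", d[1])
  if (anyDuplicated(channel_names))
    stop_validation("channel names must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_validation("fs must be a positive sampling rate in Hz")
  if (d[2] < 1) stop_validation("T must be >= 1")
  if (K > 0 && (anyNA(labels) || any(labels < 0)))
    stop_validation("labels must be non-negative integers")
  if (is.null(class_names)) {
    n_cl <- if (K > 0) max(labels) + 1L else 0L
    class_names <- paste0("class_", seq_len(n_cl) - 1L)
  }
  if (K > 0 && any(labels >= length(class_names)))
    stop_validation("every label must be < n_classes = ", length(class_names))
  if (anyNA(data) || any(!is.finite(data)))
    stop_validation("data contains non-finite values")
  structure(list(
    data = data, labels = labels, fs = fs,
    channel_names = as.character(channel_names),
    subject_id = as.character(subject_id),
    session_ids = session_ids,
    class_names = as.character(class_names)
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("epoch_set: subject", x$subject_id, "-", d[3], "trials x", d[1],
      "channels x", d[2], "samples @", x$fs, "Hz\n")
  cat("  classes:", paste(x$class_names, collapse = ", "), "\n")
  cat("  trials/class:",
      paste(tabulate(x$labels + 1L, length(x$class_names)), collapse = "/"),
      "; sessions:", paste(sort(unique(x$session_ids)), collapse = ","), "\n")
  invisible(x)
}

n_trials <- function(es) dim(es$data)[3]

#' Session-based train/test split specification
#'
#' @param train_sessions,test_sessions disjoint integer session-id sets.
#' @param drop_channels channel names to drop on load (e.g. EOG channels).
#' @return an object of class \code{split_spec}.
#' @export
split_spec <- function(train_sessions, test_sessions,
                       drop_channels = character()) {
  train_sessions <- as.integer(train_sessions)
  test_sessions <- as.integer(test_sessions)
  if (length(intersect(train_sessions, test_sessions)) > 0)
    stop_validation("train and test sessions overlap: ",
                    paste(intersect(train_sessions, test_sessions),
                          collapse = ", "))
  structure(list(train_sessions = train_sessions,
                 test_sessions = test_sessions,
                 drop_channels = as.character(drop_channels)),
            class = "split_spec")
}

#' Partition an epoch set by session
#'
#' Trials whose session id is in \code{spec$train_sessions} form the training
#' set; those in \code{spec$test_sessions} form the test set. The two parts
#' are disjoint and share the original class coding.
#'
#' @param es an [epoch_set()].
#' @param spec a [split_spec()].
#' @return list with \code{train} and \code{test} epoch sets.
#' @export
split_by_session <- function(es, spec) {
  stopifnot(inherits(es, "epoch_set"), inherits(spec, "split_spec"))
  wanted <- c(spec$train_sessions, spec$test_sessions)
  missing <- setdiff(wanted, unique(es$session_ids))
  if (length(missing) > 0)
    stop_validation("sessions not present in the data: ",
                    paste(missing, collapse = ", "))
  take <- function(sess) {
    idx <- which(es$session_ids %in% sess)
    if (length(idx) == 0)
      stop_validation("empty split for sessions ",
                      paste(sess, collapse = ", "))
    epoch_set(es$data[, , idx, drop = FALSE], es$labels[idx], es$fs,
              es$channel_names, es$subject_id, es$session_ids[idx],
              es$class_names)
  }
  list(train = take(spec$train_sessions), test = take(spec$test_sessions))
}

#' Concatenate epoch sets along the trial axis
#'
#' All sets must agree on channels, samples, sampling rate and class coding.
#'
#' @param ... epoch sets (or one list of them).
#' @return a single [epoch_set()]; subject id is taken from the first set.
#' @export
combine_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "epoch_set"))
    sets <- sets[[1]]
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(dim(s$data)[1:2], dim(ref$data)[1:2]) ||
        !identical(s$channel_names, ref$channel_names) ||
        !identical(s$class_names, ref$class_names) || s$fs != ref$fs)
      stop_validation("epoch sets are not compatible for combination")
  }
  d <- dim(ref$data)
  Ks <- vapply(sets, n_trials, numeric(1))
  data <- array(0, dim = c(d[1], d[2], sum(Ks)))
  at <- 0L
  for (s in sets) {
    data[, , at + seq_len(n_trials(s))] <- s$data
    at <- at + n_trials(s)
  }
  epoch_set(data,
            unlist(lapply(sets, `[[`, "labels")),
            ref$fs, ref$channel_names, ref$subject_id,
            unlist(lapply(sets, `[[`, "session_ids")),
            ref$class_names)
}

# -- epoch archive ------------------------------------------------------------
# Single self-describing file: a 4-byte little-endian header length, a JSON
# header (dims + all metadata), then the trial tensor as little-endian
# float32, column-major in [C, T, K] order.

archive_keys <- c("format", "dims", "labels", "fs", "channel_names",
                  "subject_id", "session_ids", "class_names")

#' Save an epoch set to a self-describing archive
#'
#' The archive stores all metadata in a JSON header and the data as float32
#' (lossless for typical microvolt-scale EEG to within float32 precision).
#' [load_epochs()] is its inverse.
#'
#' @param es an [epoch_set()].
#' @param path destination file path.
#' @return \code{path}, invisibly.
#' @export
save_epochs <- function(es, path) {
  stopifnot(inherits(es, "epoch_set"))
  header <- list(format = "msatnet-epochs-v1",
                 dims = dim(es$data),
                 labels = es$labels,
                 fs = es$fs,
                 channel_names = es$channel_names,
                 subject_id = es$subject_id,
                 session_ids = es$session_ids,
                 class_names = es$class_names)
  json <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(length(json), con, size = 4L, endian = "little")
  writeBin(json, con)
  writeBin(as.numeric(es$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' Load an epoch set from an archive written by [save_epochs()]
#'
#' @param path archive file path.
#' @return an [epoch_set()].
#' @export
load_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(n) != 1L || is.na(n) || n <= 0 || n > 1e8)
    stop_format("corrupt archive header in ", path)
  header <- tryCatch(
    jsonlite::fromJSON(rawToChar(readBin(con, "raw", n))),
    error = function(e) stop_format("corrupt archive JSON header: ",
                                    conditionMessage(e)))
  for (k in archive_keys)
    if (is.null(header[[k]])) stop_format("archive missing required key \"",
                                          k, "\"")
  dims <- as.integer(header$dims)
  want <- prod(dims)
  data <- readBin(con, "numeric", want, size = 4L, endian = "little")
  if (length(data) != want)
    stop_format("archive data truncated: expected ", want, " values, got ",
                length(data))
  dim(data) <- dims
  epoch_set(data, header$labels, header$fs, header$channel_names,
            header$subject_id, header$session_ids, header$class_names)
}
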