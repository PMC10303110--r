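make_es <- function(K = 8L, C = 3L, T = 100L, n_classes = 2L,
                    sessions = NULL, seed = 1L) {
  set.seed(seed)
  epoch_set(array(rnorm(C * T * K), dim = c(C, T, K)),
            labels = rep_len(seq_len(n_classes) - 1L, K),
            fs = 250, channel_names = default_montage(C),
            session_ids = sessions %||% rep(1L, K))
}
`%||%` <- function(a, b) if (is.null(a)) b else a
n_trials_of <- function(es) dim(es$data)[3]

test_that("epoch_set enforces its invariants", {
  expect_s3_class(make_es(), "epoch_set")
  bad <- array(rnorm(6), dim = c(1, 2, 3))
  expect_error(epoch_set(bad, labels = 0:1, fs = 250, channel_names = "C3"),
               "labels")
  expect_error(epoch_set(bad, labels = c(0, 0, 0), fs = -1,
                         channel_names = "C3"), "fs")
  bad[1] <- NA
  expect_error(epoch_set(bad, labels = c(0, 0, 0), fs = 250,
                         channel_names = "C3"), "finite")
  expect_error(epoch_set(array(0, c(1, 2, 2)), labels = c(0, 5), fs = 250,
                         channel_names = "C3",
                         class_names = c("a", "b")), "n_classes")
})

test_that("split_by_session partitions trials and rejects bad specs", {
  es <- make_es(K = 10L, sessions = c(rep(1L, 6), rep(2L, 4)))
  sp <- split_by_session(es, split_spec(1, 2))
  expect_equal(n_trials_of(sp$train), 6)
  expect_equal(n_trials_of(sp$test), 4)
  # partition: sizes add up and the label multisets merge to the original
  expect_equal(sort(c(sp$train$labels, sp$test$labels)), sort(es$labels))
  expect_identical(sp$train$class_names, sp$test$class_names)
  expect_error(split_spec(1, 1), "overlap")
  expect_error(split_by_session(es, split_spec(1, 3)), "not present")
})

test_that("2b-style five-session convention splits 3 + 2", {
  es <- make_es(K = 25L, sessions = rep(1:5, each = 5L))
  sp <- split_by_session(es, split_spec(1:3, 4:5))
  expect_equal(n_trials_of(sp$train), 15)
  expect_equal(n_trials_of(sp$test), 10)
  expect_setequal(unique(sp$test$session_ids), 4:5)
})

test_that("epoch archive round-trips all fields", {
  es <- make_es(K = 8L, C = 3L, T = 100L)
  path <- withr::local_tempfile(fileext = ".eeg")
  save_epochs(es, path)
  back <- load_epochs(path)
  expect_identical(back$labels, es$labels)
  expect_identical(back$session_ids, es$session_ids)
  expect_identical(back$channel_names, es$channel_names)
  expect_identical(back$class_names, es$class_names)
  expect_identical(back$subject_id, es$subject_id)
  expect_equal(back$fs, es$fs)
  # float32 storage: agreement within float32 eps of the data magnitude
  tol <- 2^-23 * max(abs(es$data))
  expect_lt(max(abs(back$data - es$data)), tol)
  # and exactly equal to the independent float32 cast oracle
  cast <- readBin(writeBin(as.numeric(es$data), raw(), size = 4L),
                  "numeric", length(es$data), size = 4L)
  expect_identical(as.numeric(back$data), cast)
})

test_that("archive with a missing required key raises a format error", {
  es <- make_es(K = 2L, C = 2L, T = 10L)
  path <- withr::local_tempfile(fileext = ".eeg")
  save_epochs(es, path)
  # rewrite the archive without the labels key
  con <- file(path, "rb")
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n)))
  payload <- readBin(con, "raw", 1e6)
  close(con)
  header$labels <- NULL
  json <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE))
  con <- file(path, "wb")
  writeBin(length(json), con, size = 4L, endian = "little")
  writeBin(json, con); writeBin(payload, con)
  close(con)
  expect_error(load_epochs(path), "labels")
})

test_that("synthetic GDF fixture round-trips data, labels and events", {
  set.seed(7)
  fs <- 250
  sig <- matrix(rnorm(5 * fs * 4), 4)       # 4 channels, 5 s
  chans <- c("C3", "Cz", "C4", "EOG-left")
  events <- data.frame(pos = c(1 * fs, 2 * fs, 3 * fs, 4 * fs) + 1L,
                       typ = c(769L, 770L, 770L, 769L))
  path <- withr::local_tempfile(fileext = ".gdf")
  write_gdf(path, sig, fs, chans, events)
  g <- read_gdf(path)
  expect_equal(g$fs, fs)
  expect_identical(g$channel_names, chans)
  expect_equal(g$events$typ, events$typ)
  expect_equal(g$events$pos, as.integer(events$pos))
  expect_lt(max(abs(g$signals[, seq_len(ncol(sig))] - sig)),
            2^-23 * max(abs(sig)))

  es <- load_gdf_dataset(path, layout = "2b", window = c(0, 0.5))
  expect_equal(dim(es$data), c(3, 125, 4))       # EOG dropped
  expect_identical(es$labels, c(0L, 1L, 1L, 0L)) # 0-based contiguous coding
  expect_length(intersect(es$channel_names, "EOG-left"), 0)
  # epochs match the signal slices they were cut from
  for (k in 1:4) {
    a <- events$pos[k]
    expect_lt(max(abs(es$data[, , k] - sig[1:3, a:(a + 124)])), 1e-5)
  }
})

test_that("GDF epoching validates the window and flags rejected trials", {
  fs <- 250
  sig <- matrix(0, 3, 5 * fs)
  chans <- c("C3", "Cz", "C4")
  events <- data.frame(pos = c(2 * fs, 4 * fs), typ = c(769L, 770L))
  path <- withr::local_tempfile(fileext = ".gdf")
  write_gdf(path, sig, fs, chans, events)
  expect_error(load_gdf_dataset(path, "2b", window = c(1, 1)), "window")
  expect_error(load_gdf_dataset(path, "2b", window = c(0, 10)), "bounds")

  # a 1023 marker just before the first cue drops that trial by default
  events2 <- rbind(events, data.frame(pos = 2 * fs - 100L, typ = 1023L))
  write_gdf(path, sig, fs, chans, events2)
  es <- load_gdf_dataset(path, "2b", window = c(0, 0.5))
  expect_identical(es$labels, 1L)
  es_all <- load_gdf_dataset(path, "2b", window = c(0, 0.5),
                             keep_rejected = TRUE)
  expect_identical(es_all$labels, c(0L, 1L))
})

test_that("2a-layout fixture: 22 EEG channels survive, 4 classes map to 0..3", {
  set.seed(11)
  fs <- 250
  chans <- c(default_montage(22), paste0("EOG-", 1:3))
  n_cue <- 12L
  dur <- (n_cue + 2) * 5 * fs
  sig <- matrix(rnorm(25 * dur, sd = 5), 25)
  cue_pos <- (seq_len(n_cue) * 5 - 3) * fs
  events <- data.frame(
    pos = as.integer(c(cue_pos - 2 * fs, cue_pos)),
    typ = as.integer(c(rep(768L, n_cue), rep(769:772, 3))))
  events <- events[order(events$pos), ]
  path <- withr::local_tempfile(fileext = ".gdf")
  write_gdf(path, sig, fs, chans, events)
  es <- load_gdf_dataset(path, layout = "2a", window = c(0, 4))
  expect_equal(dim(es$data), c(22, 1000, n_cue))   # T = 4 s at 250 Hz
  expect_identical(sort(unique(es$labels)), 0:3)
  expect_identical(es$class_names,
                   c("left_hand", "right_hand", "feet", "tongue"))
  expect_length(grep("EOG", es$channel_names), 0)
})

test_that("unknown event codes produce a format error naming them", {
  fs <- 250
  path <- withr::local_tempfile(fileext = ".gdf")
  write_gdf(path, matrix(0, 2, fs * 2), fs, c("C3", "C4"),
            data.frame(pos = c(10L, 50L), typ = c(769L, 4242L)))
  expect_error(load_gdf_dataset(path, "2b", window = c(0, 0.1)), "4242")
})

test_that("combine_epochs concatenates and checks compatibility", {
  a <- make_es(K = 4L, seed = 1)
  b <- make_es(K = 6L, seed = 2)
  ab <- combine_epochs(a, b)
  expect_equal(dim(ab$data)[3], 10)
  expect_equal(ab$labels, c(a$labels, b$labels))
  bad <- make_es(K = 2L, C = 2L)
  expect_error(combine_epochs(a, bad), "compatible")
})
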