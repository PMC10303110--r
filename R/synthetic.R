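# Synthetic motor-imagery EEG.
#
# The generator emulates the features that matter to a motor-imagery decoder:
# 1/f-shaped background noise, mu (8-13 Hz) and beta (18-26 Hz) rhythms at
# every channel, and per-class event-related desynchronization (ERD) —
# fractional suppression of those rhythms at class-specific channels — plus
# per-subject gain / peak-frequency / noise shifts for the cross-subject
# setting. It is a fixture generator, not a biophysical forward model.

MU_AMP_UV <- 8     # mu rhythm amplitude, microvolts
BETA_AMP_UV <- 4   # beta rhythm amplitude, microvolts
NOISE_RMS_UV <- 10 # background 1/f noise RMS, microvolts

#' Per-subject generative model
#'
#' @param subject_id identifier string.
#' @param channel_gains positive per-channel gains (length C).
#' @param mu_peak_hz subject mu peak, in [6, 14] Hz (nominal 10).
#' @param beta_peak_hz subject beta peak, in [15, 30] Hz (nominal 22).
#' @param noise_scale positive multiplier on background-noise RMS.
#' @param seed integer seed; all trial synthesis is a pure function of the
#'   model parameters and this seed.
#' @return an object of class \code{subject_model}.
#' @export
subject_model <- function(subject_id, channel_gains, mu_peak_hz = 10,
                          beta_peak_hz = 22, noise_scale = 1, seed = 1L) {
  if (any(channel_gains <= 0)) stop_validation("all channel gains must be > 0")
  if (mu_peak_hz < 6 || mu_peak_hz > 14)
    stop_validation("mu_peak_hz must lie in [6, 14]")
  if (beta_peak_hz < 15 || beta_peak_hz > 30)
    stop_validation("beta_peak_hz must lie in [15, 30]")
  if (noise_scale <= 0) stop_validation("noise_scale must be > 0")
  structure(list(subject_id = as.character(subject_id),
                 channel_gains = as.numeric(channel_gains),
                 mu_peak_hz = mu_peak_hz, beta_peak_hz = beta_peak_hz,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "subject_model")
}

#' Per-class ERD effect
#'
#' With \code{erd_depth = 0} the class is indistinguishable from background in
#' expectation; \code{erd_depth = 1} fully suppresses the mu/beta rhythms at
#' \code{erd_channels} during the trial.
#'
#' @param class_id 0-based integer class id.
#' @param erd_channels channel names showing ERD for this class.
#' @param erd_depth fractional rhythm amplitude suppression in [0, 1].
#' @return an object of class \code{class_effect}.
#' @export
class_effect <- function(class_id, erd_channels, erd_depth) {
  assert_count(class_id, "class_id", min = 0L)
  if (!is.numeric(erd_depth) || erd_depth < 0 || erd_depth > 1)
    stop_validation("erd_depth must lie in [0, 1]")
  structure(list(class_id = as.integer(class_id),
                 erd_channels = as.character(erd_channels),
                 erd_depth = erd_depth),
            class = "class_effect")
}

#' Default 10-20 montage subset
#'
#' For \code{C = 22} the BCI-competition-style motor montage (including C3,
#' Cz, C4); \code{C = 3} gives \code{C3, Cz, C4}.
#'
#' @param C number of channels (3 or 22, or any C for generic names).
#' @return character vector of channel names.
#' @export
default_montage <- function(C = 22L) {
  if (C == 3L) return(c("C3", "Cz", "C4"))
  if (C == 22L)
    return(c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4",
             "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
             "CP3", "CP1", "CPz", "CP2", "CP4", "P1", "Pz", "P2", "POz"))
  paste0("CH", seq_len(C))
}

#' Default contralateral class-to-channel ERD map
#'
#' Left hand suppresses C4, right hand C3, feet Cz, tongue C3 and C4 jointly
#' (the contralateral ERD convention).
#'
#' @param n_classes 2 (left/right) or 4 (left/right/feet/tongue).
#' @param erd_depth shared suppression depth.
#' @return list of [class_effect()]s with a \code{class_names} attribute.
#' @export
default_class_effects <- function(n_classes = 4L, erd_depth = 0.8) {
  map <- list(left_hand = "C4", right_hand = "C3", feet = "Cz",
              tongue = c("C3", "C4"))
  if (!n_classes %in% c(2L, 4L))
    stop_validation("default effects are defined for 2 or 4 classes")
  nm <- names(map)[seq_len(n_classes)]
  eff <- lapply(seq_len(n_classes), function(i)
    class_effect(i - 1L, map[[i]], erd_depth))
  attr(eff, "class_names") <- nm
  eff
}

# 1/f-shaped Gaussian noise, synthesized in the frequency domain and scaled
# to approximately unit RMS. Returns a [C, T] matrix.
one_over_f_noise <- function(C, T, fs) {
  nf <- T %/% 2L
  freqs <- seq_len(nf) * fs / T
  amp <- 1 / sqrt(freqs)
  out <- matrix(0, C, T)
  for (ch in seq_len(C)) {
    re <- stats::rnorm(nf) * amp
    im <- stats::rnorm(nf) * amp
    spec <- complex(real = c(0, re), imaginary = c(0, im))
    full <- c(spec, Conj(rev(spec[2:(nf + 1L)])))[seq_len(T)]
    x <- Re(stats::fft(full, inverse = TRUE)) / sqrt(T)
    out[ch, ] <- x / stats::sd(x)
  }
  out
}

# One rhythm trace: amplitude-modulated sinusoid with random phase and a slow
# random modulation envelope.
rhythm_trace <- function(T, fs, freq, amp) {
  tt <- (seq_len(T) - 1L) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  mod_f <- stats::runif(1, 0.3, 1)
  mod_ph <- stats::runif(1, 0, 2 * pi)
  env <- 1 + 0.2 * sin(2 * pi * mod_f * tt + mod_ph)
  amp * env * sin(2 * pi * freq * tt + phase)
}

#' Generate one subject's labelled synthetic EEG
#'
#' Each trial is 1/f background noise plus mu and beta rhythms at every
#' channel; at the trial's class-specific ERD channels the rhythm amplitude is
#' multiplied by \code{(1 - erd_depth)}. Labels are balanced
#' (\code{n_per_class} per class, block-ordered) and generation is a pure
#' function of \code{(sm, effects, sizes, seed)}: every trial uses its own
#' counter-derived substream, so results do not depend on generation order.
#'
#' @param sm a [subject_model()].
#' @param effects list of [class_effect()]s with distinct class ids
#'   \code{0..n_classes-1}.
#' @param n_per_class trials per class (>= 1).
#' @param fs sampling rate in Hz (default 250).
#' @param T samples per trial (default 1000, i.e. 4 s at 250 Hz).
#' @param channel_names montage (default [default_montage()] of the gain
#'   vector's length).
#' @param session_id session id stamped on all trials (default 1).
#' @return an [epoch_set()] with \code{K = n_classes * n_per_class} trials.
#' @export
generate_subject <- function(sm, effects, n_per_class, fs = 250, T = 1000L,
                             channel_names = NULL, session_id = 1L) {
  stopifnot(inherits(sm, "subject_model"))
  assert_count(n_per_class, "n_per_class")
  C <- length(sm$channel_gains)
  if (is.null(channel_names)) channel_names <- default_montage(C)
  if (length(channel_names) != C)
    stop_validation("channel_names length must match channel_gains length")
  ids <- vapply(effects, function(e) e$class_id, numeric(1))
  if (anyDuplicated(ids)) stop_validation("duplicate class_ids in effects")
  if (!setequal(ids, seq_along(effects) - 1L))
    stop_validation("effects must cover class ids 0..",
                    length(effects) - 1L)
  for (e in effects) {
    unknown <- setdiff(e$erd_channels, channel_names)
    if (length(unknown) > 0)
      stop_validation("unknown ERD channel name(s): ",
                      paste(unknown, collapse = ", "))
  }
  cls_names <- attr(effects, "class_names")
  effects <- effects[order(ids)]
  n_classes <- length(effects)
  K <- n_classes * n_per_class
  labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  data <- array(0, dim = c(C, T, K))
  for (k in seq_len(K)) {
    eff <- effects[[labels[k] + 1L]]
    set.seed(derive_seed(sm$seed, 101L, k))
    x <- one_over_f_noise(C, T, fs) * (NOISE_RMS_UV * sm$noise_scale)
    erd <- channel_names %in% eff$erd_channels
    for (ch in seq_len(C)) {
      supp <- if (erd[ch]) 1 - eff$erd_depth else 1
      x[ch, ] <- x[ch, ] +
        rhythm_trace(T, fs, sm$mu_peak_hz, MU_AMP_UV * supp) +
        rhythm_trace(T, fs, sm$beta_peak_hz, BETA_AMP_UV * supp)
    }
    data[, , k] <- x * sm$channel_gains
  }
  cls <- cls_names %||% paste0("class_", seq_len(n_classes) - 1L)
  epoch_set(data, labels, fs, channel_names, sm$subject_id,
            rep(as.integer(session_id), K), cls)
}

#' Draw a cohort of subject models with controlled dispersion
#'
#' \code{shift_scale = 0} returns identical nominal models; larger values
#' increase between-subject dispersion of channel gains (log-normal, sd
#' \code{0.4 * shift_scale}), mu/beta peak frequencies (normal, sd \code{1.5}
#' and \code{2 * shift_scale} Hz, clipped to the valid ranges) and noise scale
#' (log-normal, sd \code{0.3 * shift_scale}).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param shift_scale non-negative dispersion dial.
#' @param seed integer seed.
#' @param C channels per subject (default 22).
#' @return list of [subject_model()]s.
#' @export
draw_subject_models <- function(n_subjects, shift_scale, seed, C = 22L) {
  assert_count(n_subjects, "n_subjects", min = 2L)
  if (shift_scale < 0) stop_validation("shift_scale must be >= 0")
  lapply(seq_len(n_subjects), function(i) {
    set.seed(derive_seed(seed, 211L, i))
    gains <- exp(stats::rnorm(C, 0, 0.4 * shift_scale))
    mu <- min(14, max(6, 10 + stats::rnorm(1, 0, 1.5 * shift_scale)))
    beta <- min(30, max(15, 22 + stats::rnorm(1, 0, 2 * shift_scale)))
    ns <- exp(stats::rnorm(1, 0, 0.3 * shift_scale))
    subject_model(sprintf("S%d", i), gains, mu, beta, ns,
                  seed = derive_seed(seed, 223L, i))
  })
}

#' Generate a multi-subject synthetic cohort
#'
#' Subjects share the class-effect structure but differ in their
#' [subject_model()] draws; dispersion is controlled by \code{shift_scale}
#' (0 means identical generative models, i.e. no subject shift).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param base_effects list of [class_effect()]s shared by all subjects.
#' @param shift_scale subject-shift dial (see [draw_subject_models()]).
#' @param seed integer seed.
#' @param n_per_class trials per class per subject.
#' @param fs,T,C sampling rate, samples per trial, channels.
#' @return list of [epoch_set()]s, one per subject.
#' @export
generate_cohort <- function(n_subjects, base_effects, shift_scale, seed,
                            n_per_class = 72L, fs = 250, T = 1000L, C = 22L) {
  sms <- draw_subject_models(n_subjects, shift_scale, seed, C)
  lapply(sms, generate_subject, effects = base_effects,
         n_per_class = n_per_class, fs = fs, T = T,
         channel_names = default_montage(C))
}

#' Per-trial band power
#'
#' Mean periodogram power inside a frequency band, averaged over the selected
#' channels; the feature a band-power baseline classifier uses and the
#' quantity ERD suppresses.
#'
#' @param es an [epoch_set()].
#' @param band two-element Hz interval (default mu, \code{c(8, 13)}).
#' @param channels channel names (default all).
#' @return numeric vector of length \code{K}.
#' @export
band_power <- function(es, band = c(8, 13), channels = NULL) {
  stopifnot(inherits(es, "epoch_set"))
  chs <- if (is.null(channels)) seq_along(es$channel_names)
         else match(channels, es$channel_names)
  if (anyNA(chs)) stop_validation("unknown channel name(s)")
  d <- dim(es$data)
  T <- d[2]
  freqs <- (seq_len(T %/% 2L)) * es$fs / T
  sel <- which(freqs >= band[1] & freqs <= band[2]) + 1L  # +1: skip DC bin
  vapply(seq_len(d[3]), function(k) {
    xm <- t(matrix(es$data[chs, , k], length(chs), T))  # [T, length(chs)]
    sp <- stats::mvfft(xm)
    mean(abs(sp[sel, , drop = FALSE])^2) / T
  }, numeric(1))
}
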