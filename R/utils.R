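#' @keywords internal
"_PACKAGE"

# -- small shared helpers ----------------------------------------------------

stop_validation <- function(...) {
  stop(structure(class = c("msat_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("msat_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_shape <- function(...) {
  stop(structure(class = c("msat_shape_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_validation(name, " must be TRUE or FALSE")
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_validation(name, " must be an integer >= ", min)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x >= 1)
    stop_validation(name, " must lie in [0, 1)")
}

# Deterministic substream seeds: fold (seed, stream ids) into [0, 2^31 - 2].
# Keeps every derived seed a valid 32-bit R integer regardless of input size.
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 69069 + (v %% 2147483647) + 1) %% 2147483647
  as.integer(h)
}

# Polynomial rolling hash over a serialized object; used for config hashes.
hash_object <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483629
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
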