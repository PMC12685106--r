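# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# Simple deterministic 32-bit FNV-1a hash of a character string; used to
# derive stable binary-file identifiers without consuming the RNG stream.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) # keep within int range
    h <- (h + 2^30) %% 2^32
    h <- (h * 16777619) %% 2^32
  }
  h
}

# 16 raw bytes derived from a string, formatted as a UUID-like identifier.
derive_uuid <- function(s) {
  parts <- vapply(1:4, function(i) fnv1a32(paste0(i, ":", s)), numeric(1))
  raw16 <- as.raw(unlist(lapply(parts, function(p) {
    c(p %/% 2^24, (p %/% 2^16) %% 256, (p %/% 2^8) %% 256, p %% 256)
  })))
  raw16
}

uuid_string <- function(raw16) {
  hx <- format(raw16)
  paste0(
    paste(hx[1:4], collapse = ""), "-", paste(hx[5:6], collapse = ""), "-",
    paste(hx[7:8], collapse = ""), "-", paste(hx[9:10], collapse = ""), "-",
    paste(hx[11:16], collapse = "")
  )
}

# log-normal parameterization from mean 1 and coefficient of variation
lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))
lnorm_meanlog <- function(cv) -0.5 * log(1 + cv^2)
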