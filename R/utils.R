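# Stable 32-bit hash of a string (FNV-1a), used to derive per-well seeds.
# Independent of R's RNG so well order never matters.
stable_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- (h %% 4294967296)
    # xor on values >= 2^31: split into high bit + rest for bitwXor
    lo31 <- h %% 2147483648
    hi <- h - lo31
    h <- hi + bitwXor(as.integer(lo31), as.integer(b))
    # multiply by FNV prime modulo 2^32, split to stay within exact doubles
    h_hi <- h %/% 65536
    h_lo <- h %% 65536
    h <- (h_lo * p + ((h_hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Derive a reproducible per-well seed from a master seed
#'
#' The per-well seed is the master seed XOR a stable hash of the well
#' identifier, reduced below 2^31 so it is a valid R integer seed. Wells are
#' therefore reproducible independently of the order in which they are
#' simulated.
#'
#' @param master_seed integer master seed.
#' @param well_id character well identifier (e.g. `"A01"`).
#' @return integer seed.
#' @export
well_seed <- function(master_seed, well_id) {
  h <- stable_hash(as.character(well_id)) %% 2147483648
  as.integer(bitwXor(as.integer(master_seed %% 2147483648), as.integer(h)) %% 2147483647)
}

# intensity column name for a channel in a cell table
int_col <- function(channel) paste0(channel, "_integrated")
mean_col <- function(channel) paste0(channel, "_mean")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
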