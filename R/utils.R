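# Seed derivation, scoped RNG and config digests shared across modules.

#' Derive a child seed from a master seed
#'
#' A counter-based mixing scheme: every (module, record) index tuple maps
#' deterministically to a distinct 31-bit seed, so a single master seed
#' governs all randomness in the package without any RNG-state coupling
#' between records.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the consumer (e.g. specimen id,
#'   screw id, sweep index).
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  ks <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(master) %% m
  # LCG-style mixing; all intermediates < 2^53 so exact in doubles
  s <- (s * 69069 + 12345) %% m
  for (k in ks) {
    s <- (s * 69069 + (as.numeric(k) + 1) * 2246822519) %% m
    s <- (s * 40692 + 3266489917) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Evaluate expr with a temporarily seeded RNG, restoring prior state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Digest of a configuration object
#'
#' Stable FNV-1a hash over the deparsed configuration, used to stamp
#' manifests and reports so reruns can be matched to their exact settings.
#'
#' @param x any serializable R object.
#' @return an 8-character hexadecimal string.
#' @export
config_digest <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    hs <- if (h >= 2147483648) h - 4294967296 else h # to signed 32-bit
    h <- bitwXor(as.integer(hs), as.integer(b))
    if (h < 0) h <- h + 4294967296
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# internal: stop with a classed condition
vs_stop <- function(msg, class) {
  stop(structure(class = c(class, "vibroscrew_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
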