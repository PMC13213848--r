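# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so seeded operations never perturb it.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic rolling digest of a character scalar; used to stamp reports
# with a parameter fingerprint without a hashing dependency.
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# A statistic that is undefined on the data: NA value plus machine-readable
# reason, serialized to JSON as null + reason string.
undefinedStat <- function(fields, reason) {
  out <- as.list(rep(NA_real_, length(fields)))
  names(out) <- fields
  out$reason <- reason
  out
}

isUndefined <- function(stat) !is.null(stat$reason) && !is.na(stat$reason)

# Derive a per-component substream seed from a master seed, staying inside
# the 32-bit integer range.
derivedSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + index * 1299721) %% 2147483647L) + 1L
}
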