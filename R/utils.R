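# Internal helpers shared across modules.

# Deterministic 31-bit substream seed from a master seed and a stream name,
# so each synthetic-data component (demographics, networks, cognition,
# dementia) draws from its own reproducible stream.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` with a local RNG state: seeds with `seed`, restores the
# caller's .Random.seed on exit.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# FNV-style rolling hash of a character scalar, as 8 hex digits; used to
# fingerprint configurations in run manifests.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- xor_32(h, b)
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

xor_32 <- function(a, b) {
  # bitwXor on doubles that may exceed .Machine$integer.max
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  as.double(hi) * 65536 + as.double(lo)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", ""))))
}

# Fixed-width numeric formatting used by every table writer so that repeated
# runs with the same seed are byte-identical.
num_fmt <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}
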