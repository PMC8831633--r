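# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed from a master seed; stays below 2^31 - 1.
derive_seed <- function(master, k) {
  as.integer((as.double(master) * 48271 + 1000003 * as.double(k)) %%
               (.Machine$integer.max - 1L)) + 1L
}

# Round-trip a double through IEEE 754 binary32, i.e. the value actually
# stored in a float32 GeoTIFF cell.
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "numeric", n = length(x), size = 4L, endian = "little")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
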