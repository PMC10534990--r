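# internal helpers shared across modules

# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# .Random.seed afterwards. seed = NULL leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 32-bit polynomial rolling hash of a character vector; used to fingerprint
# configurations in output manifests (not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

stop_domain <- function(...) stop(..., call. = FALSE)
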