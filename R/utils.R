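# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.rd_cache <- new.env(parent = emptyenv())

# Evaluate expr with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Multiplicative lognormal noise with unit mean and the given coefficient of variation.
lognorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

stop_validation <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

colwise_max <- function(m) {
  # max of each column without apply() overhead in hot loops
  if (!is.matrix(m)) return(max(m))
  out <- m[1L, ]
  for (i in seq_len(nrow(m))[-1L]) {
    row <- m[i, ]
    gt <- row > out
    if (any(gt)) out[gt] <- row[gt]
  }
  out
}
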