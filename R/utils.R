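# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(structure(
  class = c("sdrs_domain_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))))

stop_structural <- function(...) stop(structure(
  class = c("sdrs_structural_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))))

stop_range <- function(...) stop(structure(
  class = c("sdrs_range_error", "error", "condition"),
  list(message = paste0(...), call = sys.call(-1))))

check_number <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || anyNA(x)) stop_domain(name, " must be numeric and non-missing")
  if (strict_lower) {
    if (any(x <= lower)) stop_domain(name, " must be > ", lower)
  } else if (any(x < lower)) stop_domain(name, " must be >= ", lower)
  if (any(x > upper)) stop_domain(name, " must be <= ", upper)
  invisible(x)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`;
# restores (or removes) the caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# cheap deterministic checksum of a numeric vector (tamper detection only)
value_checksum <- function(x) {
  x <- as.double(x)
  n <- length(x)
  w <- (seq_len(n) %% 97L) + 1L
  sprintf("%.12e|%.12e|%d", sum(x * w), sum(abs(x)), n)
}

linear_interp <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 1)$y
}
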