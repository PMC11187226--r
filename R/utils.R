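# internal helpers: validation and seeded RNG management

stop_domain <- function(...) {
  stop(structure(class = c("splicekin_domain_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stop_fit <- function(msg, diagnostics = NULL) {
  stop(structure(class = c("splicekin_fit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1),
                      diagnostics = diagnostics)))
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain("`%s` must be a single finite number", name)
  if (strict && x <= lower) stop_domain("`%s` must be > %g", name, lower)
  if (!strict && x < lower) stop_domain("`%s` must be >= %g", name, lower)
  invisible(x)
}

# Derive a child seed deterministically from a root seed and a stream index.
# Kept in [1, 2^31 - 2] so it is always a valid integer seed.
derive_seed <- function(seed, stream) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  for (i in seq_len(2L)) s <- (s * 48271 + stream * 9349 + 1) %% m
  as.integer(s %% (m - 1L) + 1L)
}

# Run `expr` under `set.seed(seed)` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

fmt_num <- function(x) sprintf("%.17g", x)
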