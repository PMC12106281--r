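# internal assertion helpers ------------------------------------------------

stop_hs <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_hs(sprintf("`%s` must be a single finite number", name))
  if (x < lower || x > upper)
    stop_hs(sprintf("`%s` must be in [%s, %s], got %s", name,
                    format(lower), format(upper), format(x)))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min)
    stop_hs(sprintf("`%s` must be an integer >= %d", name, min))
  invisible(as.integer(x))
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_hs(sprintf("%s is missing column(s): %s", what,
                    paste(missing, collapse = ", ")))
  invisible(df)
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators never perturb the global stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic child seeds for pipeline stages
child_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% 2147483629L
}
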