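# Internal helpers: seed splitting, config hashing, input checks.

# Derive `n` independent substream seeds from one master seed. Used so that
# pipeline stages (and per-unit analyses within a stage) consume stable,
# order-independent random streams: regenerating one stage does not disturb
# another.
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master %% 2147483647))
  sample.int(2147483646L, n)
}

config_hash <- function(x) rlang::hash(x)

check_number <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || (finite && !is.finite(x)))
    abort(sprintf("`%s` must be a single finite number.", name))
  if (x < lower || x > upper)
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  invisible(x)
}

check_prob_level <- function(level) {
  check_number(level, "level", lower = 0, upper = 1)
  if (level <= 0 || level >= 1) abort("`level` must be strictly inside (0, 1).")
  invisible(level)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
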