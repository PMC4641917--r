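# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so simulation functions are pure in (parameters, seed).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`%s` must be a single finite number", name)
  }
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stop_input("`%s` = %g is outside the allowed range [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

# Wavelength keys used throughout: the instrument's two LED peak wavelengths.
WAVELENGTHS <- c(750, 850)

wl_key <- function(wavelength) {
  if (!wavelength %in% WAVELENGTHS) {
    stop_input("unknown wavelength %s nm (instrument emits 750 and 850 nm)",
               format(wavelength))
  }
  as.character(wavelength)
}
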