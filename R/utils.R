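# Internal helpers shared across modules.

# Near-integer test robust to floating-point representation of e.g. 30 * 5.
is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

stop_input <- function(msg) abort(msg, class = c("ptashb_input_error", "ptashb_error"))
stop_config <- function(msg) abort(msg, class = c("ptashb_config_error", "ptashb_error"))
stop_numeric <- function(msg) abort(msg, class = c("ptashb_numeric_error", "ptashb_error"))

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    stop_config(sprintf("`%s` = %g is outside its valid range", name, x))
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream; seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is_whole(seed) || seed < 0 || seed >= 2^31) {
    stop_config("`seed` must be an integer in [0, 2^31)")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sub-seeds for multi-part simulations, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2^31 - 1, n))
}
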