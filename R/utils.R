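# Internal argument checks. All user-facing errors are rlang conditions with
# a class so the CLI can map them to exit codes.

stop_param <- function(msg, class = NULL) {
  rlang::abort(msg, class = c(class, "pttkit_param_error"))
}

stop_io <- function(msg, class = NULL) {
  rlang::abort(msg, class = c(class, "pttkit_io_error"))
}

stop_analysis <- function(msg, class = NULL) {
  rlang::abort(msg, class = c(class, "pttkit_analysis_error"))
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    stop_param(sprintf("`%s` must be > %g (got %g).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    stop_param(sprintf("`%s` must be >= %g (got %g).", name, lower, x))
  }
  if (x > upper) {
    stop_param(sprintf("`%s` must be <= %g (got %g).", name, upper, x))
  }
  invisible(x)
}

check_increasing <- function(x, name) {
  if (length(x) > 1L && any(diff(x) <= 0)) {
    stop_param(sprintf("`%s` must be strictly increasing.", name))
  }
  invisible(x)
}

# Deterministic sub-seed derivation: one user seed fans out to independent
# streams (per channel / per noise component) without stream reuse.
derive_seed <- function(seed, stream) {
  # double arithmetic: products stay exact below 2^53, result fits an int
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
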