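# Internal helpers: classed errors, seed scoping, small validators.

tri_abort <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "tricadence_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, class = "invalid_config") {
  if (!is_scalar_num(x)) {
    tri_abort(sprintf("`%s` must be a single finite number", name), class)
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  if (!ok_lo || x > upper) {
    tri_abort(sprintf("`%s` = %g is outside its valid range", name, x), class)
  }
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Derive a deterministic child seed
#'
#' Deterministic child seed from a master seed and a stage index, used to
#' fan one pipeline seed out into independent per-stage and per-recording
#' streams. Stays within the signed 32-bit integer range.
#'
#' @param master Master integer seed.
#' @param stage Integer stage/recording index.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(stage)) %%
               2147483647)
}
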