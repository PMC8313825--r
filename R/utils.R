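#' Derive a reproducible sub-seed for a named pipeline stage
#'
#' All randomness in the package flows from one integer seed. Each stage
#' (simulation, cross-validation folds, ...) draws from its own substream so
#' that reordering or re-running stages cannot silently change results.
#' The derived seed is a deterministic hash of the master seed and the stage
#' name, kept inside the 32-bit signed integer range.
#'
#' @param seed master integer seed
#' @param stage character stage name
#' @return an integer seed in `[0, 2^31 - 1)`
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- as.double(seed) %% 2147483647
  for (c in codes) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

# internal: stop with a classed condition so callers/tests can be specific
lp_stop <- function(msg, class) {
  stop(structure(class = c(class, "lncpair_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# internal: strictly positive finite scalar check
check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0)) {
    lp_stop(sprintf("'%s' must be a finite %s scalar", name,
                    if (positive) "positive" else "numeric"),
            "lncpair_config_error")
  }
  invisible(x)
}
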