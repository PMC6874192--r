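#' @keywords internal
"_PACKAGE"

# Structured error conditions shared across the package. Each maps to a CLI
# exit code: invalid input -> 2, degenerate plan -> 3, fixture error -> 4.

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("protoscatter_invalid_input", "protoscatter_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("protoscatter_config_error", "protoscatter_error")))
}

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("protoscatter_degenerate_plan", "protoscatter_error")))
}

stop_fixture <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("protoscatter_fixture_error", "protoscatter_error")))
}

stop_insufficient <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("protoscatter_insufficient_data", "protoscatter_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
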