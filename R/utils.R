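# Internal helpers: classed conditions and seed handling.

`%||%` <- function(a, b) if (is.null(a)) b else a

synthrep_error <- function(message, class) {
  stop(structure(
    class = c(class, "synthrep_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stop_config <- function(msg) synthrep_error(msg, "synthrep_config_error")
stop_value <- function(msg) synthrep_error(msg, "synthrep_value_error")
stop_schema <- function(msg) synthrep_error(msg, "synthrep_schema_error")

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded operations do not perturb surrounding streams.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(expr)
}

#' Spawn a child seed from a master seed
#'
#' All randomness in the simulation engine flows from one master seed through
#' this deterministic spawning scheme: each child seed is a Lehmer-style hash
#' of the master seed and a path of integer identifiers (iteration, purpose,
#' dataset index, ...). Because a dataset's seed depends only on its own path
#' and not on how many sibling datasets are requested, runs that generate a
#' prefix of the datasets reproduce exactly the prefix of a longer run.
#'
#' @param master Integer master seed (kept below 2^31).
#' @param ... Integer path components identifying the consumer.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' spawn_seed(1, 5, 2)
spawn_seed <- function(master, ...) {
  ids <- c(...)
  s <- as.double(master) %% 2147483647
  for (id in ids) {
    s <- (s * 48271 + as.double(id) * 9461 + 1) %% 2147483647
  }
  as.integer(s)
}
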