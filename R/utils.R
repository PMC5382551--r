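#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' Every generator takes one integer seed and splits it into independent
#' per-stream seeds by stable string hashing, so adding a stream never
#' perturbs the draws of another.
#'
#' @param seed master integer seed.
#' @param label character stream label.
#' @return an integer in \[0, 2^31 - 2\].
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647          # 2^31 - 1, Mersenne prime
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_mircons <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(class = c(class, "mircons_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != round(x)) {
    stop_mircons("mircons_parameter_error", name, " must be a positive integer")
  }
  as.integer(x)
}

check_positive_real <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_mircons("mircons_parameter_error", name, " must be a positive number")
  }
  as.numeric(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_mircons("mircons_parameter_error", name, " must lie in [0, 1]")
  }
  as.numeric(x)
}

# geometric mean of strictly positive values
geo_mean <- function(x) exp(mean(log(x)))
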