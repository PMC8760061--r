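# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so seeded generators never perturb the caller's
#' random stream.  A `NULL` seed evaluates `code` against the current
#' stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# scalar checks -------------------------------------------------------------

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_fraction <- function(x) {
  is_number(x) && x >= 0 && x <= 1
}

stop_config <- function(...) {
  stop("configuration error: ", ..., call. = FALSE)
}

# Truncated-normal draws on [0, 1] by rejection.  `mean` may be a vector
# (one value per draw); sd is scalar.
rtruncnorm01 <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0 | out > 1)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- bad[out[bad] < 0 | out[bad] > 1]
  }
  out
}

# All permutations of seq_len(n), as an n! x n integer matrix.  Only used
# for exhaustive enumeration on small instances (n <= 8 or so).
all_permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

trapezoid <- function(x, y) {
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}
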