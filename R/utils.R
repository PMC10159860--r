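# internal helpers shared across stages

#' @keywords internal
#' @noRd
.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# All randomized operations take an explicit seed; the caller's RNG state is
# never touched.
#' @keywords internal
#' @noRd
.with_seed <- function(seed, code) {
  .assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
          "`seed` must be a single finite number")
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream of child seeds from one parent seed (kept below 2^31).
#' @keywords internal
#' @noRd
.child_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Structured log line to stderr: stage, then name=value pairs.
# Silenced by options(gutlink.verbose = FALSE).
#' @keywords internal
#' @noRd
.log_stage <- function(stage, ...) {
  if (!isTRUE(getOption("gutlink.verbose", TRUE))) return(invisible())
  kv <- list(...)
  parts <- if (length(kv)) paste(names(kv), unlist(kv), sep = "=") else character()
  message(sprintf("[gutlink:%s] %s", stage, paste(parts, collapse = " ")))
}

#' @keywords internal
#' @noRd
.is_binary <- function(x) all(x %in% c(0, 1))

# Multivariate normal draws via Cholesky (deterministic given RNG state).
#' @keywords internal
#' @noRd
.rmvnorm <- function(n, sigma) {
  d <- nrow(sigma)
  L <- chol(sigma)
  matrix(stats::rnorm(n * d), n, d) %*% L
}

# Dirichlet draws, one row per alpha row.
#' @keywords internal
#' @noRd
.rdirichlet <- function(alpha) {
  g <- matrix(stats::rgamma(length(alpha), shape = alpha, rate = 1),
              nrow = nrow(alpha))
  g / rowSums(g)
}

# circular distance between bin indices (1-based) on a genome of n bins
#' @keywords internal
#' @noRd
.circ_dist <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}
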