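#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join bind_rows bind_cols n distinct pull rename row_number
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median sd quantile setNames
NULL

# Trapezoidal integral of y over t. Tolerates duplicated abscissae (zero-width
# panels contribute nothing), which is how piecewise-constant signals carry
# their jumps exactly.
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((t[-1L] - t[-n]) * (y[-1L] + y[-n])) / 2
}

# Trapezoidal quadrature weights: w_i such that sum(w * y) == trapz(t, y).
trapz_weights <- function(t) {
  n <- length(t)
  if (n == 1L) return(1)
  dt <- t[-1L] - t[-n]
  c(dt, 0) / 2 + c(0, dt) / 2
}

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

rownorm <- function(m) sqrt(rowSums(m * m))

stopifnot_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive and finite.", name))
  }
  invisible(x)
}

# Scoped RNG: run `expr` under `seed` without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}
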