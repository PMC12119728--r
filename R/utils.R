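#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef sd var median quantile rnorm runif rexp rlnorm
#'   wilcox.test t.test p.adjust prcomp convolve optim setNames approx
#'   binomial glm predict qnorm
#' @importFrom utils head tail read.csv write.csv
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Every simulator routes randomness through
# this so no function mutates global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Trapezoidal integral of y over x.
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Cumulative trapezoidal integral, same length as x, starting at 0.
cumtrapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

# Relative difference |a - b| / max(|b|, eps)
rel_err <- function(a, b, eps = .Machine$double.eps) {
  abs(a - b) / pmax(abs(b), eps)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}
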