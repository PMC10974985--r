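# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# The caller's .Random.seed is restored afterwards so library code does not
# disturb user-level reproducibility. `seed = NULL` evaluates as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Geometric mean
#'
#' Computed as `exp(mean(log(x)))` so long products neither overflow nor
#' underflow. All inputs must be strictly positive.
#'
#' @param x numeric vector of strictly positive values.
#' @return the geometric mean of `x`.
#' @examples
#' geometric_mean(c(4, 1)) # 2
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L) {
    stop("geometric mean of an empty vector is undefined", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean requires strictly positive finite values", call. = FALSE)
  }
  exp(mean(log(x)))
}

# Stop with a formatted message (sprintf-style).
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
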