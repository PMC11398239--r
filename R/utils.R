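# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so deterministic generation does
#' not disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(d) d * pi / 180

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

#' Rotation taking a unit vector onto the +z axis (Rodrigues construction)
#' @noRd
rotation_to_z <- function(n) {
  n <- n / sqrt(sum(n^2))
  e3 <- c(0, 0, 1)
  v <- c(n[2] * e3[3] - n[3] * e3[2],
         n[3] * e3[1] - n[1] * e3[3],
         n[1] * e3[2] - n[2] * e3[1])
  s2 <- sum(v^2)
  c_ <- sum(n * e3)
  if (s2 < 1e-30) {
    if (c_ > 0) return(diag(3))
    # 180 degrees: flip about x
    return(diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s2)
}

#' Trapezoidal integral of y over x (x strictly increasing)
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Reflection (mirror) padding supporting pad lengths beyond the signal length
#'
#' Index i of the infinite even-reflected extension of x, for any integer i.
#' @noRd
reflect_index <- function(i, n) {
  q <- (i - 1) %% (2L * n)
  ifelse(q < n, q + 1L, 2L * n - q)
}

reflect_pad <- function(x, pad) {
  n <- length(x)
  idx <- reflect_index(seq.int(1L - pad, n + pad), n)
  x[idx]
}
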