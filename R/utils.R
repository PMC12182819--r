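# internal helpers shared across modules

# Run an expression under a temporary RNG state. `seed = NULL` leaves the
# global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# trapezoidal integral over a possibly non-uniform grid
trapz_int <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2L, length(y) == n)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

stop_lungecv <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean magnitude of a Rice(nu, sigma) variate, vectorized in nu:
# E|M| = sigma sqrt(pi/2) e^{-z/2} [(1+z) I0(z/2) + z I1(z/2)],
# z = nu^2 / (2 sigma^2). Exponentially-scaled Bessel terms keep large z
# stable; the large-z limit is E|M| -> nu, the z = 0 value sigma sqrt(pi/2).
rice_mean <- function(nu, sigma) {
  if (sigma <= 0) return(abs(nu))
  z <- (nu / sigma)^2 / 2
  i0 <- besselI(z / 2, 0, expon.scaled = TRUE)
  i1 <- besselI(z / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * ((1 + z) * i0 + z * i1)
}

# Invert rice_mean in nu for a vector of observed mean magnitudes, by a
# monotone spline on a fixed grid of nu/sigma. Values at or below the noise
# floor map to 0.
rice_invert <- function(m, sigma) {
  if (sigma <= 0) return(m)
  grid_nu <- c(seq(0, 6, by = 0.05), seq(6.25, 60, by = 0.25)) * sigma
  grid_m <- rice_mean(grid_nu, sigma)
  out <- numeric(length(m))
  floor_m <- grid_m[1]              # sigma * sqrt(pi/2)
  hi <- m > grid_m[length(grid_m)]
  mid <- m > floor_m & !hi
  out[hi] <- m[hi]                  # asymptotically E|M| ~ nu, <0.1% there
  if (any(mid)) {
    out[mid] <- stats::approx(grid_m, grid_nu, xout = m[mid])$y
  }
  out
}
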