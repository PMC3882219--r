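#' Fixed-step classical RK4 integration of a small autonomous system
#'
#' Utility used by R-level oracles and the isolated-network helper; the
#' coupled model solver is compiled (see [simulate_model()]).
#'
#' @param y0 named numeric initial state.
#' @param f derivative function `f(y) -> dy`.
#' @param t_end horizon.
#' @param dt step.
#' @return state at `t_end` (names preserved).
#' @keywords internal
rk4_integrate <- function(y0, f, t_end, dt) {
  n <- ceiling(t_end / dt - 1e-12)
  h <- t_end / n
  y <- y0
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# run code with a locally-set RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# trapezoid integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
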