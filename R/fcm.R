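# Fuzzy c-means on the one-dimensional feature "pressure value".
#
# The clustering objective is
#   J_m(mu, V) = sum_i sum_k mu_ik^m ||x_i - v_k||^2
# minimized by alternating optimization: memberships from current centers,
# centers from current memberships.  Spatial structure enters later, through
# connected-component post-processing of the label map, not here.

# evaluate a function with a temporary RNG state; leaves the caller's
# .Random.seed untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Fuzzy c-means clustering of pressure values
#'
#' Alternating-optimization fuzzy c-means on a 1-D set of pressure values.
#' Centers are initialized at evenly spaced percentiles of the data plus a
#' small seeded jitter, which is reproducible and robust for the unimodal-ish
#' pressure distributions this package works with. Convergence is declared
#' when the largest center shift drops below `tol`; non-convergence within
#' `max_iter` iterations is flagged in the result, not raised.
#'
#' @param values numeric vector of pressures (the contact cells of a matrix).
#' @param c number of clusters (default 3).
#' @param m_fuzz fuzzifier exponent m > 1 (default 2).
#' @param tol convergence tolerance on the centers (default 1e-6).
#' @param max_iter iteration cap (default 300).
#' @param seed integer seed for the center jitter.
#' @return an `fcm_result`: `memberships` (n x c, rows sum to 1), `centers`
#'   (sorted ascending), `objective_trace` (J_m per iteration,
#'   non-increasing), `c`, `m_fuzz`, `converged`, `iterations`.
#' @export
fcm <- function(values, c = 3L, m_fuzz = 2, tol = 1e-6, max_iter = 300L,
                seed = 1L) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  if (length(unique(x)) < c)
    stop(sprintf("need at least %d distinct values for c = %d clusters", c, c),
         call. = FALSE)
  if (m_fuzz <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  n <- length(x)
  probs <- seq_len(c) / (c + 1)
  v <- as.numeric(stats::quantile(x, probs, names = FALSE))
  jit <- with_seed(seed, stats::rnorm(c, 0, 1e-3 * max(diff(range(x)), 1e-12)))
  v <- sort(v + jit)

  expo <- 2 / (m_fuzz - 1)
  memberships_for <- function(v) {
    d2 <- outer(x, v, function(a, b) (a - b)^2)
    zero <- d2 < .Machine$double.eps
    u <- matrix(0, n, length(v))
    any_zero <- rowSums(zero) > 0L
    if (any(any_zero)) # crisp assignment where a point sits on a center
      u[any_zero, ] <- zero[any_zero, , drop = FALSE] / rowSums(zero[any_zero, , drop = FALSE])
    if (any(!any_zero)) {
      dd <- d2[!any_zero, , drop = FALSE]
      inv <- dd^(-1 / (m_fuzz - 1))
      u[!any_zero, ] <- inv / rowSums(inv)
    }
    list(u = u, d2 = d2)
  }
  objective <- function(u, d2) sum(u^m_fuzz * d2)

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mu <- memberships_for(v)
    um <- mu$u^m_fuzz
    v_new <- as.numeric(crossprod(um, x) / colSums(um))
    trace <- c(trace, objective(mu$u, outer(x, v_new, function(a, b) (a - b)^2)))
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  ord <- order(v)
  mu <- memberships_for(v)
  structure(
    list(memberships = mu$u[, ord, drop = FALSE],
         centers = v[ord],
         objective_trace = trace,
         c = as.integer(c), m_fuzz = m_fuzz,
         converged = converged, iterations = iter,
         values = x, seed = seed),
    class = "fcm_result")
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("<fcm_result> c=%d m=%g, centers: %s, %d iterations%s\n",
              x$c, x$m_fuzz, paste(sprintf("%.3f", x$centers), collapse = " "),
              x$iterations, if (x$converged) "" else " (not converged)"))
  invisible(x)
}
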