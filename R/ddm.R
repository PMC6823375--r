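#' Specify a drift-diffusion decision process
#'
#' Bundles the parameters of an unbiased Wiener diffusion between two
#' absorbing boundaries: evidence starts at `z = a/2`, drifts at rate `v`
#' (evidence units per second) with diffusion coefficient `s`
#' (evidence units per sqrt-second), and a decision is made when the path
#' reaches the upper boundary `a` (correct) or the lower boundary 0 (error).
#' The observed initiation time is the decision time plus the non-decision
#' time `ter`, which absorbs perceptual and motor latencies.
#'
#' The starting point is pinned at `a/2` because the estimator this process
#' feeds assumes an unbiased start; it is not a free parameter here.
#'
#' @param a Boundary separation (> 0), evidence units.
#' @param v Drift rate, evidence units per second.
#' @param ter Non-decision time, seconds (>= 0).
#' @param s Diffusion coefficient (noise scale), default 1.
#' @param step_dt Euler time step in seconds; must be in (0, 0.005].
#' @param max_time Maximum decision time in seconds before a path is
#'   re-drawn; must exceed `ter`.
#' @return An object of class `ddm_spec`.
#' @export
ddm_spec <- function(a, v, ter, s = 1, step_dt = 5e-4, max_time = 10) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(v), length(v) == 1L, is.finite(v),
            is.numeric(ter), length(ter) == 1L, is.finite(ter))
  if (a <= 0) stop("boundary separation 'a' must be positive")
  if (s <= 0) stop("noise scale 's' must be positive")
  if (ter < 0) stop("non-decision time 'ter' must be non-negative")
  if (step_dt <= 0 || step_dt > 0.005)
    stop("'step_dt' must lie in (0, 0.005] seconds")
  if (max_time <= ter) stop("'max_time' must exceed 'ter'")
  structure(
    list(a = a, v = v, ter = ter, s = s, z = a / 2,
         step_dt = step_dt, max_time = max_time),
    class = "ddm_spec"
  )
}

#' @export
print.ddm_spec <- function(x, ...) {
  cat(sprintf(
    "ddm_spec: a=%.4g  v=%.4g  Ter=%.4g s  s=%.3g  (z=a/2, dt=%.4g s)\n",
    x$a, x$v, x$ter, x$s, x$step_dt))
  invisible(x)
}

#' Simulate first-passage times of a Wiener diffusion
#'
#' Draws `n` decision trials from the process in `spec` by Euler-Maruyama
#' integration: each step adds `v * dt` drift and `s * sqrt(dt) * N(0,1)`
#' diffusion, starting from `z = a/2`, until the path crosses the upper
#' boundary `a` (a correct response) or the lower boundary 0 (an error).
#' Returned decision times exclude the non-decision time. Paths still
#' unabsorbed at `max_time` are re-drawn so the sample size is exact; the
#' number of re-draws is attached as an attribute.
#'
#' @param spec A [ddm_spec()].
#' @param n Number of trials (>= 1).
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible and the caller's RNG state is left untouched.
#' @return A data.frame with columns `decision_time` (seconds) and
#'   `hit_upper` (logical), with attribute `n_redrawn`.
#' @examples
#' fp <- sample_first_passage(ddm_spec(a = 1, v = 2, ter = 0.3), 1000, seed = 1)
#' mean(fp$hit_upper)  # close to 1 / (1 + exp(-2))
#' @export
sample_first_passage <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "ddm_spec")) stop("'spec' must be a ddm_spec")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  n <- as.integer(n)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }

  dt <- spec$step_dt
  mu <- spec$v * dt
  sd_step <- spec$s * sqrt(dt)
  max_steps <- ceiling(spec$max_time / dt)

  dtime <- numeric(n)
  upper <- logical(n)
  n_redrawn <- 0L
  todo <- seq_len(n)                       # indices still needing a draw

  while (length(todo) > 0L) {
    m <- length(todo)
    x <- rep.int(spec$z, m)
    t_steps <- integer(m)
    alive <- seq_len(m)
    res_t <- integer(m)                    # absorption step, 0 = not yet
    res_up <- logical(m)
    step <- 0L
    while (length(alive) > 0L && step < max_steps) {
      step <- step + 1L
      x[alive] <- x[alive] + mu + sd_step * stats::rnorm(length(alive))
      hit_hi <- x[alive] >= spec$a
      hit_lo <- x[alive] <= 0
      done <- hit_hi | hit_lo
      if (any(done)) {
        idx <- alive[done]
        res_t[idx] <- step
        res_up[idx] <- hit_hi[done]
        alive <- alive[!done]
      }
    }
    absorbed <- res_t > 0L
    dtime[todo[absorbed]] <- res_t[absorbed] * dt
    upper[todo[absorbed]] <- res_up[absorbed]
    n_redrawn <- n_redrawn + sum(!absorbed)
    todo <- todo[!absorbed]
  }

  out <- data.frame(decision_time = dtime, hit_upper = upper)
  attr(out, "n_redrawn") <- n_redrawn
  out
}
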