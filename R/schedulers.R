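#' Scheduler specifications
#'
#' A scheduler decides the stochastic rate (reviewing intensity) at which one
#' item is sent for review.
#'
#' * `scheduler_memorize(q)`: the optimal controller. Intensity
#'   `u(t) = q^(-1/2) (1 - m(t))` — an affine function of the recall
#'   probability with negative slope, so reviews concentrate when the item is
#'   about to be forgotten. Larger `q` means fewer reviews.
#' * `scheduler_uniform(mu)`: reviews at a constant rate `mu` (1/day),
#'   independent of memory state.
#' * `scheduler_threshold(c, zeta, m_th)`: no reviews until the recall
#'   probability first falls below `m_th`; from that crossing time `s` the
#'   intensity grows exponentially, `u(t) = c exp((t - s) / zeta)`. After each
#'   review the recall probability resets to 1, the intensity returns to 0 and
#'   a new crossing time is computed.
#'
#' @param q Review-cost trade-off, > 0.
#' @param mu Constant reviewing rate (1/day), >= 0.
#' @param c Base intensity at the crossing (1/day), >= 0.
#' @param zeta E-folding time of the intensity ramp (day), > 0.
#' @param m_th Recall-probability threshold in (0, 1).
#' @return A `scheduler_spec` object with a `variant` field.
#' @examples
#' scheduler_memorize(q = 1)
#' scheduler_threshold(c = 1, zeta = 2, m_th = 0.6)
#' @export
scheduler_memorize <- function(q) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0) {
    stop("`q` must be a single positive value", call. = FALSE)
  }
  structure(list(variant = "memorize", q = q), class = "scheduler_spec")
}

#' @rdname scheduler_memorize
#' @export
scheduler_uniform <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1 || mu < 0) {
    stop("`mu` must be a single nonnegative value", call. = FALSE)
  }
  structure(list(variant = "uniform", mu = mu), class = "scheduler_spec")
}

#' @rdname scheduler_memorize
#' @export
scheduler_threshold <- function(c, zeta, m_th) {
  if (!is.numeric(c) || length(c) != 1 || c < 0) {
    stop("`c` must be a single nonnegative value", call. = FALSE)
  }
  if (!is.numeric(zeta) || length(zeta) != 1 || zeta <= 0) {
    stop("`zeta` must be a single positive value", call. = FALSE)
  }
  if (!is.numeric(m_th) || length(m_th) != 1 || m_th <= 0 || m_th >= 1) {
    stop("`m_th` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(variant = "threshold", c = c, zeta = zeta, m_th = m_th),
            class = "scheduler_spec")
}

#' @export
print.scheduler_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "variant")]
  cat(sprintf("<scheduler_spec> %s(%s)\n", x$variant,
              paste(names(pars), unlist(pars), sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Optimal (MEMORIZE) reviewing intensity
#'
#' The optimal intensity under the quadratic recall/effort loss:
#' `u = q^(-1/2) (1 - m)`, bounded by `q^(-1/2)` and vanishing when recall is
#' certain (`m = 1`).
#'
#' @param m Recall probability in `[0, 1]` (vectorised).
#' @param q Review-cost trade-off, > 0.
#' @return Intensity in 1/day.
#' @examples
#' memorize_intensity(m = 0.5, q = 4) # 0.25
#' @export
memorize_intensity <- function(m, q) {
  if (any(q <= 0)) stop("`q` must be positive", call. = FALSE)
  stopifnot(all(m >= -1e-12 & m <= 1 + 1e-12))
  (1 - pmin(pmax(m, 0), 1)) / sqrt(q)
}

#' Constant reviewing intensity of the uniform scheduler
#'
#' @param spec A `scheduler_spec` from [scheduler_uniform()].
#' @return The rate `mu`, constant in time.
#' @export
uniform_intensity <- function(spec) {
  stopifnot(spec$variant == "uniform")
  spec$mu
}

#' Time at which the recall probability crosses a threshold
#'
#' Under the exponential forgetting curve, `m(t) = m_th` has the unique
#' solution `t = t_last - log(m_th) / n`. Returns `Inf` ("never") for the
#' degenerate permanently-remembered state `n = 0`.
#'
#' @param state A [memory_state()].
#' @param m_th Threshold in (0, 1).
#' @return Crossing time in days (possibly `Inf`).
#' @examples
#' threshold_crossing_time(memory_state(n = log(2), t_last = 3), 0.5) # 4
#' @export
threshold_crossing_time <- function(state, m_th) {
  stopifnot(m_th > 0, m_th < 1)
  if (state$n == 0) return(Inf)
  state$t_last - log(m_th) / state$n
}

#' Threshold-scheduler intensity
#'
#' Zero before the crossing time `s`; `c exp((t - s) / zeta)` afterwards.
#'
#' @param t Evaluation time (day), vectorised.
#' @param s Crossing time (day), `Inf` if the threshold was never crossed.
#' @param spec A `scheduler_spec` from [scheduler_threshold()].
#' @return Intensity in 1/day.
#' @export
threshold_intensity <- function(t, s, spec) {
  stopifnot(spec$variant == "threshold")
  ifelse(t >= s, spec$c * exp((t - s) / spec$zeta), 0)
}

#' Sample the next event of an inhomogeneous Poisson process by thinning
#'
#' Distributionally exact rejection sampling: candidate times are proposed
#' from a dominating piecewise-constant rate and accepted with probability
#' `u(t) / bound(t)`. The bound schedule is supplied as a function
#' `bound(t)` returning `list(rate, until)` — the constant dominating rate
#' valid on `[t, until)`. A proposal where `u(t)` exceeds the bound is a hard
#' error (the sample would be biased), never silently accepted.
#'
#' @param intensity Function `u(t)` giving the target intensity (1/day).
#' @param bound Function `t -> list(rate, until)`, the piecewise-constant
#'   majorant.
#' @param t_now Left edge of the sampling interval (exclusive).
#' @param t_f Right edge (inclusive).
#' @return The first event time in `(t_now, t_f]`, or `NA_real_` if the
#'   process produces no event in the window. Uses R's global RNG.
#' @examples
#' set.seed(1)
#' sample_next_event(function(t) 2, function(t) list(rate = 2, until = Inf), 0, 10)
#' @export
sample_next_event <- function(intensity, bound, t_now, t_f) {
  t <- t_now
  repeat {
    if (t >= t_f) return(NA_real_)
    b <- bound(t)
    win_end <- min(b$until, t_f)
    if (b$rate <= 0) {
      if (win_end >= t_f) return(NA_real_)
      t <- win_end
      next
    }
    w <- stats::rexp(1, rate = b$rate)
    if (t + w > win_end) {
      if (win_end >= t_f) return(NA_real_)
      t <- win_end
      next
    }
    t <- t + w
    u <- intensity(t)
    if (u > b$rate * (1 + 1e-9) + 1e-12) {
      stop(sprintf(
        "thinning bound violated: intensity %.6g exceeds bound %.6g at t = %.6g",
        u, b$rate, t
      ), call. = FALSE)
    }
    if (stats::runif(1) <= u / b$rate) return(t)
  }
}

#' Sample the next review time under a scheduler
#'
#' Draws the first review time after `t_now` from the scheduler's
#' state-dependent intensity by exact thinning, using the variant's
#' majorant: the global bound `q^(-1/2)` for the optimal scheduler (since
#' `1 - m <= 1`), the rate itself for the uniform scheduler, and — for the
#' threshold scheduler, whose post-crossing intensity is unbounded —
#' adaptive look-ahead windows of length `zeta/4`, each bounded by its
#' window-end intensity.
#'
#' @param spec A `scheduler_spec`.
#' @param state The current [memory_state()].
#' @param t_now,t_f Sampling window (days).
#' @param model Forgetting-curve variant.
#' @return Next review time, or `NA_real_` if none falls in the window.
#' @examples
#' set.seed(1)
#' next_review_time(scheduler_memorize(1), memory_state(n = 0.5), 0, 30)
#' @export
next_review_time <- function(spec, state, t_now, t_f,
                             model = exponential_model()) {
  switch(spec$variant,
    memorize = {
      ub <- 1 / sqrt(spec$q)
      sample_next_event(
        intensity = function(t) {
          memorize_intensity(model$recall(state$n, t - state$t_last), spec$q)
        },
        bound = function(t) list(rate = ub, until = Inf),
        t_now = t_now, t_f = t_f
      )
    },
    uniform = {
      sample_next_event(
        intensity = function(t) spec$mu,
        bound = function(t) list(rate = spec$mu, until = Inf),
        t_now = t_now, t_f = t_f
      )
    },
    threshold = {
      s <- threshold_model_crossing(state, spec, model)
      if (!is.finite(s) || s >= t_f) return(NA_real_)
      delta <- spec$zeta / 4
      sample_next_event(
        intensity = function(t) threshold_intensity(t, s, spec),
        bound = function(t) {
          if (t < s) return(list(rate = 0, until = s))
          k <- max(0, floor((t - s) / delta))
          win_end <- s + (k + 1) * delta
          if (win_end <= t) win_end <- t + delta  # guard fp edge at window seams
          list(rate = spec$c * exp((win_end - s) / spec$zeta), until = win_end)
        },
        t_now = t_now, t_f = t_f
      )
    },
    stop("unknown scheduler variant: ", spec$variant, call. = FALSE)
  )
}

# Crossing time m(t) = m_th under an arbitrary forgetting-curve variant.
# Exponential model has the closed form; other variants are inverted
# numerically on a bracketed monotone curve.
threshold_model_crossing <- function(state, spec, model) {
  if (state$n == 0) return(Inf)
  if (identical(model$name, "exponential")) {
    return(threshold_crossing_time(state, spec$m_th))
  }
  f <- function(dt) model$recall(state$n, dt) - spec$m_th
  hi <- 1
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 2
  if (f(hi) > 0) return(Inf)
  state$t_last + stats::uniroot(f, c(0, hi), tol = 1e-12)$root
}
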