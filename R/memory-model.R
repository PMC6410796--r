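#' Per-item memory parameters
#'
#' Bundles the three parameters of the multiplicative forgetting-rate model
#' for one item: a successful recall at a review multiplies the forgetting
#' rate by `1 - alpha`, an unsuccessful one multiplies it by `1 + beta`, and
#' `n0` (in 1/day) is the initial forgetting rate, which captures item
#' difficulty.
#'
#' @param n0 Initial forgetting rate, in 1/day. Must be >= 0.
#' @param alpha Success multiplier deficit, in `[0, 1]`.
#' @param beta Failure multiplier excess, >= 0.
#' @param item_id Opaque item identifier (any scalar), default `"item"`.
#' @return An object of class `item_params`.
#' @examples
#' item_params(n0 = 0.1, alpha = 0.3, beta = 0.2)
#' @export
item_params <- function(n0, alpha = 0, beta = 0, item_id = "item") {
  stopifnot(is.numeric(n0), length(n0) == 1, is.finite(n0))
  if (n0 < 0) stop("`n0` must be nonnegative", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single value in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0) {
    stop("`beta` must be a single nonnegative value", call. = FALSE)
  }
  structure(
    list(n0 = as.numeric(n0), alpha = as.numeric(alpha),
         beta = as.numeric(beta), item_id = item_id),
    class = "item_params"
  )
}

#' Memory state of one (learner, item) pair
#'
#' Tracks the current forgetting rate `n` (1/day), the time of the last
#' review `t_last` (days since first exposure; the first exposure itself
#' counts as time 0), and the number of successful / failed recalls so far.
#' States are immutable values: [apply_review()] returns a new state.
#'
#' @param n Current forgetting rate (1/day), >= 0. `n = 0` is admitted as a
#'   degenerate "permanently remembered" state with recall probability 1.
#' @param t_last Time of the last review in days; for a never-reviewed item
#'   this is the exposure time (0 by convention).
#' @param k_success,k_fail Nonnegative recall outcome counts.
#' @return An object of class `memory_state`.
#' @examples
#' memory_state(n = 0.1)
#' @export
memory_state <- function(n, t_last = 0, k_success = 0L, k_fail = 0L) {
  stopifnot(is.numeric(n), length(n) == 1, is.finite(n))
  if (n < 0) stop("forgetting rate `n` must be nonnegative", call. = FALSE)
  if (k_success < 0 || k_fail < 0) {
    stop("recall counts must be nonnegative", call. = FALSE)
  }
  structure(
    list(n = as.numeric(n), t_last = as.numeric(t_last),
         k_success = as.integer(k_success), k_fail = as.integer(k_fail)),
    class = "memory_state"
  )
}

#' Initial memory state for an item
#'
#' @param params An [item_params()] object.
#' @param t0 Exposure time (day), default 0.
#' @return A `memory_state` with `n = n0`, zero counts.
#' @export
initial_state <- function(params, t0 = 0) {
  memory_state(n = params$n0, t_last = t0, k_success = 0L, k_fail = 0L)
}

#' Recall probability under the exponential forgetting curve
#'
#' The probability that the learner recalls the item at time `t`,
#' `m(t) = exp(-n (t - t_r))`, where `t_r` is the time of the last review
#' (or first exposure) and `n` the current forgetting rate. With `n = 0`
#' the item is permanently remembered and `m(t) = 1` for all `t`.
#'
#' @param state A [memory_state()].
#' @param t Evaluation time in days; must satisfy `t >= state$t_last`.
#' @return Recall probability in `(0, 1]`.
#' @examples
#' s <- memory_state(n = log(2), t_last = 0)
#' recall_probability(s, 1) # one half-life later: 0.5
#' @export
recall_probability <- function(state, t) {
  if (t < state$t_last) {
    stop("evaluation time precedes the last review (t < t_last)", call. = FALSE)
  }
  exp(-state$n * (t - state$t_last))
}

#' Apply a review outcome to a memory state
#'
#' At a review at time `t` with recall outcome `r`, the forgetting rate
#' jumps multiplicatively: `n' = (1 - alpha) n` on success (`r=1`),
#' `n' = (1 + beta) n` on failure (`r=0`). The recall probability resets
#' to 1 at the review (the last-review clock restarts). The input state is
#' not modified; a new state is returned.
#'
#' @param state A [memory_state()].
#' @param params An [item_params()] supplying `alpha` and `beta`.
#' @param t Review time in days, `t >= state$t_last`.
#' @param r Recall outcome, 0 or 1.
#' @return The post-review `memory_state`.
#' @examples
#' s <- memory_state(n = 2)
#' apply_review(s, item_params(1, alpha = 0.5, beta = 1), t = 1, r = 1)$n # 1
#' @export
apply_review <- function(state, params, t, r) {
  if (!r %in% c(0, 1)) stop("recall outcome `r` must be 0 or 1", call. = FALSE)
  if (t < state$t_last) {
    stop("review time precedes the last review (t < t_last)", call. = FALSE)
  }
  if (r == 1) {
    memory_state(
      n = (1 - params$alpha) * state$n, t_last = t,
      k_success = state$k_success + 1L, k_fail = state$k_fail
    )
  } else {
    memory_state(
      n = (1 + params$beta) * state$n, t_last = t,
      k_success = state$k_success, k_fail = state$k_fail + 1L
    )
  }
}

#' Instantaneous quadratic loss
#'
#' The running loss traded off by the optimal controller:
#' `l(m, u) = (1 - m)^2 / 2 + q u^2 / 2`. It penalises both forgetting
#' (low recall probability `m`) and reviewing effort (intensity `u`), with
#' `q > 0` setting the exchange rate between the two.
#'
#' @param m Recall probability in `[0, 1]`.
#' @param u Reviewing intensity (1/day), >= 0.
#' @param q Review-cost trade-off, > 0.
#' @return Loss value (dimensionless).
#' @examples
#' instantaneous_loss(m = 0.5, u = 1, q = 2) # 0.125 + 1
#' @export
instantaneous_loss <- function(m, u, q) {
  if (any(q <= 0)) stop("`q` must be positive", call. = FALSE)
  stopifnot(all(m >= 0 & m <= 1), all(u >= 0))
  0.5 * (1 - m)^2 + 0.5 * q * u^2
}

# ---- pluggable forgetting-curve variants -----------------------------------

#' Forgetting-curve model variants
#'
#' The scheduler and simulator only need a recall-probability function of the
#' elapsed time and current forgetting rate; the multiplicative jump dynamics
#' at reviews are shared. `exponential_model()` is the default
#' `m = exp(-n dt)`. `powerlaw_model(omega)` is a heavier-tailed variant
#' `m = (1 + omega * dt)^(-n)` with time-scale parameter `omega` (1/day);
#' as `omega * dt -> 0` it approaches the exponential curve with rate
#' `n * omega`.
#'
#' @param omega Power-law time scale (1/day), > 0.
#' @return A `forgetting_model` object with a `recall(n, dt)` function.
#' @examples
#' exponential_model()$recall(0.1, 10) # exp(-1)
#' powerlaw_model(1)$recall(1, 1)      # 0.5
#' @export
exponential_model <- function() {
  structure(
    list(name = "exponential", recall = function(n, dt) exp(-n * dt)),
    class = "forgetting_model"
  )
}

#' @rdname exponential_model
#' @export
powerlaw_model <- function(omega = 1) {
  stopifnot(omega > 0)
  structure(
    list(name = "powerlaw", omega = omega,
         recall = function(n, dt) (1 + omega * dt)^(-n)),
    class = "forgetting_model"
  )
}

#' @export
print.memory_state <- function(x, ...) {
  cat(sprintf(
    "<memory_state> n = %.6g /day, t_last = %.6g d, successes = %d, failures = %d\n",
    x$n, x$t_last, x$k_success, x$k_fail
  ))
  invisible(x)
}

#' @export
print.item_params <- function(x, ...) {
  cat(sprintf(
    "<item_params> item '%s': n0 = %.6g /day, alpha = %.3g, beta = %.3g\n",
    x$item_id, x$n0, x$alpha, x$beta
  ))
  invisible(x)
}
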