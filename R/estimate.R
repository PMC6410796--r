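#' Empirical recall probability of a review session
#'
#' The fraction of correct answers in a session is the model-free estimate
#' of the recall probability at the session time. A perfect session
#' (`correct == seen`) is the binary success mark `r=1`; anything less is
#' `r=0`.
#'
#' @param seen Attempts in the session, >= 1 (vectorised).
#' @param correct Correct answers, `0 <= correct <= seen`.
#' @return `correct / seen`.
#' @examples
#' estimate_empirical_recall(4, 3) # 0.75
#' @export
estimate_empirical_recall <- function(seen, correct) {
  if (any(seen < 1)) stop("`seen` must be at least 1", call. = FALSE)
  if (any(correct < 0) || any(correct > seen)) {
    stop("`correct` must lie in [0, seen]", call. = FALSE)
  }
  correct / seen
}

#' Filter a review log to well-observed learners and items
#'
#' Keeps learners with at least `min_events_learner` review rows and items
#' reviewed at least `min_reviews_item` times, re-applying both thresholds
#' until a fixed point (removing a learner can push an item below threshold
#' and vice versa).
#'
#' @param log A review-log tibble (canonical columns).
#' @param min_events_learner,min_reviews_item Thresholds, defaults 30/30.
#' @return The filtered log.
#' @export
filter_log <- function(log, min_events_learner = 30, min_reviews_item = 30) {
  repeat {
    n_before <- nrow(log)
    keep_l <- log |>
      dplyr::count(.data$learner_id) |>
      dplyr::filter(.data$n >= min_events_learner) |>
      dplyr::pull(.data$learner_id)
    log <- dplyr::filter(log, .data$learner_id %in% keep_l)
    keep_i <- log |>
      dplyr::count(.data$item_id) |>
      dplyr::filter(.data$n >= min_reviews_item) |>
      dplyr::pull(.data$item_id)
    log <- dplyr::filter(log, .data$item_id %in% keep_i)
    if (nrow(log) == n_before) return(log)
  }
}

# Per-event regression table: elapsed time since the previous review (the
# first exposure counts as time 0), success/failure counts accumulated
# before the event, and the clamped empirical recall.
hlr_observations <- function(log, clamp = 1e-4) {
  log |>
    dplyr::group_by(.data$learner_id, .data$item_id) |>
    dplyr::arrange(.data$t_days, .by_group = TRUE) |>
    dplyr::mutate(
      r_bin = as.integer(.data$session_correct == .data$session_seen),
      dt = .data$t_days - dplyr::lag(.data$t_days, default = 0),
      k_success = cumsum(dplyr::lag(.data$r_bin, default = 0L)),
      k_fail = cumsum(dplyr::lag(1L - .data$r_bin, default = 0L)),
      m_hat = pmin(pmax(.data$session_correct / .data$session_seen, clamp), 1)
    ) |>
    dplyr::ungroup()
}

#' Fit the multiplicative forgetting-rate model by half-life regression
#'
#' Estimates one global pair `(alpha, beta)` and one initial forgetting rate
#' `n0` per item by minimising the squared error between the empirical
#' recall `m_hat` of each session and the model prediction
#' `exp(-n dt)`, where `n = n0_i (1-alpha)^k_success (1+beta)^k_fail`
#' accumulates the multiplicative jumps of the preceding reviews. The
#' problem is reparameterised as `a = -log(1-alpha) >= 0`,
#' `b = log(1+beta) >= 0` and `g_i = log n0_i`, with an L2 penalty
#' `lambda (a^2 + b^2)`, and solved by L-BFGS-B with analytic gradients from
#' a fixed deterministic initialisation (`a = b = 0`; `g_i` from the
#' closed-form single-review estimate `-log(m_hat)/dt`).
#'
#' @param log A review-log tibble; filter with [filter_log()] first if the
#'   30/30 well-observedness rule is wanted.
#' @param lambda L2 penalty on `a` and `b` (default 0.01).
#' @param clamp Lower clamp applied to `m_hat` before logarithms.
#' @param max_iter Optimiser iteration cap (default 500).
#' @return A `memory_fit` object: `alpha`, `beta`, an `items` tibble
#'   (`item_id`, `n0`), the best-loss-so-far trace, a convergence flag, and
#'   the observation count. Non-convergence is flagged, not an error.
#' @export
fit_memory_model <- function(log, lambda = 0.01, clamp = 1e-4, max_iter = 500) {
  obs <- hlr_observations(log, clamp)
  items <- sort(unique(obs$item_id))
  idx <- match(obs$item_id, items)
  first <- obs[obs$k_success + obs$k_fail == 0L & obs$dt > 0, ]
  g_init <- rep(NA_real_, length(items))
  if (nrow(first) > 0) {
    by_item <- tapply(-log(first$m_hat) / first$dt, match(first$item_id, items),
                      mean)
    g_init[as.integer(names(by_item))] <- log(pmax(by_item, 1e-4))
  }
  g_init[!is.finite(g_init)] <- log(1e-2)

  trace_env <- new.env()
  trace_env$trace <- numeric(0)
  loss_fn <- function(theta) {
    a <- theta[1]; b <- theta[2]; g <- theta[-(1:2)]
    n <- exp(g[idx] - a * obs$k_success + b * obs$k_fail)
    p <- exp(-n * obs$dt)
    val <- sum((obs$m_hat - p)^2) + lambda * (a^2 + b^2)
    trace_env$trace <- c(trace_env$trace, val)
    val
  }
  grad_fn <- function(theta) {
    a <- theta[1]; b <- theta[2]; g <- theta[-(1:2)]
    n <- exp(g[idx] - a * obs$k_success + b * obs$k_fail)
    p <- exp(-n * obs$dt)
    dL_dn <- 2 * (p - obs$m_hat) * (-obs$dt) * p
    c(
      sum(dL_dn * (-obs$k_success) * n) + 2 * lambda * a,
      sum(dL_dn * obs$k_fail * n) + 2 * lambda * b,
      as.numeric(tapply(dL_dn * n, idx, sum)[as.character(seq_along(g))]) |>
        (\(x) ifelse(is.na(x), 0, x))()
    )
  }
  theta0 <- c(0, 0, g_init)
  opt <- stats::optim(
    theta0, loss_fn, grad_fn, method = "L-BFGS-B",
    lower = c(0, 0, rep(-Inf, length(items))),
    upper = c(5, 5, rep(Inf, length(items))),
    control = list(maxit = max_iter, factr = 1e-8 / .Machine$double.eps)
  )
  structure(
    list(
      alpha = 1 - exp(-opt$par[1]),
      beta = exp(opt$par[2]) - 1,
      items = tibble::tibble(item_id = items, n0 = exp(opt$par[-(1:2)])),
      loss = opt$value,
      loss_trace = cummin(trace_env$trace),
      # L-BFGS-B reports an abnormal line search when it lands on a flat
      # optimum; a vanishing gradient is still convergence
      converged = opt$convergence == 0 ||
        max(abs(grad_fn(opt$par))) < 1e-6,
      n_obs = nrow(obs),
      lambda = lambda, clamp = clamp
    ),
    class = "memory_fit"
  )
}

#' @export
print.memory_fit <- function(x, ...) {
  cat(sprintf(
    "<memory_fit> alpha = %.4f, beta = %.4f, %d items, loss = %.6g (%s, %d obs)\n",
    x$alpha, x$beta, nrow(x$items), x$loss,
    if (x$converged) "converged" else "NOT converged", x$n_obs
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted memory model
#'
#' @param x A `memory_fit`.
#' @param items If `TRUE`, also return one `n0` row per item.
#' @param ... Unused.
#' @return A tibble of terms and estimates.
#' @export
tidy.memory_fit <- function(x, items = FALSE, ...) {
  out <- tibble::tibble(term = c("alpha", "beta"),
                        estimate = c(x$alpha, x$beta))
  if (items) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("n0[", x$items$item_id, "]"), estimate = x$items$n0
    ))
  }
  out
}

#' @rdname tidy.memory_fit
#' @export
glance.memory_fit <- function(x, ...) {
  tibble::tibble(
    loss = x$loss, n_obs = x$n_obs, n_items = nrow(x$items),
    iterations = length(x$loss_trace), converged = x$converged
  )
}

#' Replay a reviewing sequence through the memory model
#'
#' Reconstructs the latent forgetting-rate / recall-probability trajectory
#' of one (learner, item) sequence from its logged binary recalls and a set
#' of item parameters: the deterministic inverse of the simulator.
#'
#' @param events A tibble of one pair's reviews, time-ordered, with
#'   `t_days` and either `r` or `session_seen`/`session_correct`.
#' @param params An [item_params()].
#' @return The events tibble with `n_before`, `m_before`, `n_after` columns
#'   recomputed under `params` (exponential forgetting curve).
#' @export
replay_sequence <- function(events, params) {
  r <- if ("r" %in% names(events)) events$r else {
    as.integer(events$session_correct == events$session_seen)
  }
  k <- nrow(events)
  n_before <- m_before <- n_after <- numeric(k)
  state <- initial_state(params)
  for (j in seq_len(k)) {
    n_before[j] <- state$n
    m_before[j] <- recall_probability(state, events$t_days[j])
    state <- apply_review(state, params, events$t_days[j], r[j])
    n_after[j] <- state$n
  }
  events$r <- r
  events$n_before <- n_before
  events$m_before <- m_before
  events$n_after <- n_after
  events
}

# Compensator of the MEMORIZE intensity over [t_start, T] divided by
# q^(-1/2): A = integral of (1 - m(t)) dt, piecewise closed form
# Delta + (exp(-n Delta) - 1) / n on each inter-review interval.
memorize_area <- function(times, rates, T, t_start = 0) {
  edges <- c(t_start, times[times <= T], T)
  edges <- edges[!duplicated(edges)]
  if (length(edges) < 2) return(0)
  dl <- diff(edges)
  nn <- rates[seq_along(dl)]
  sum(ifelse(nn > 0, dl + (exp(-nn * dl) - 1) / nn, 0))
}

#' Maximum-likelihood trade-off parameter of the optimal scheduler
#'
#' Under the intensity `u(t) = q^(-1/2) (1 - m(t))`, the log-likelihood of
#' `k` observed review times is maximised in closed form by
#' `q_hat = (A / k)^2`, where `A` is the integral of `1 - m(t)` over the
#' observation window (piecewise closed form between reviews).
#'
#' @param trajectory A replayed sequence (see [replay_sequence()]) holding
#'   the training reviews with `t_days`, `n_before`, `n_after`.
#' @param T Right edge of the observation window; defaults to the last
#'   review time.
#' @return `q_hat`, with the area `A` attached as attribute `"area"`.
#' @export
fit_q_mle <- function(trajectory, T = max(trajectory$t_days)) {
  k <- nrow(trajectory)
  if (k < 1) stop("at least one review event is required", call. = FALSE)
  A <- memorize_area(trajectory$t_days,
                     c(trajectory$n_before, trajectory$n_after[k]), T)
  if (A <= 0) {
    stop("degenerate sequence: recall probability is identically 1", call. = FALSE)
  }
  structure((A / k)^2, area = A)
}

#' Maximum-likelihood rate of the uniform scheduler
#'
#' The standard homogeneous-Poisson estimate `mu_hat = k / T`.
#'
#' @param k Number of review events in the window.
#' @param T Window length (days), > 0.
#' @return `mu_hat` in 1/day.
#' @export
fit_uniform_mle <- function(k, T) {
  stopifnot(T > 0, k >= 0)
  k / T
}

# Threshold-scheduler geometry for one replayed sequence: each inter-review
# segment contributes a crossing time s (where m falls to m_th) and, if
# crossed before the segment ends, an exposure integral
# zeta * (exp((end - s)/zeta) - 1) = integral of exp((t-s)/zeta).
# Returns per-event ramp elapsed time (t_i - s, NA if the event precedes its
# segment's crossing) and the total exposure over [0, T].
threshold_geometry <- function(trajectory, m_th, zeta, T) {
  times <- trajectory$t_days
  k <- length(times)
  seg_start <- c(0, times)
  seg_rate <- c(trajectory$n_before[1], trajectory$n_after)
  seg_end <- c(times, T)
  s <- ifelse(seg_rate > 0, seg_start - log(m_th) / seg_rate, Inf)
  exposure <- sum(ifelse(
    s < seg_end, zeta * (exp((pmin(seg_end, T) - s) / zeta) - 1), 0
  ))
  ramp <- times - s[seq_len(k)]   # event i sits in segment i (starts at i-1)
  ramp[ramp < 0] <- NA_real_
  list(ramp = ramp, exposure = exposure, crossings = s)
}

#' Fit the threshold scheduler to a user's sequences
#'
#' For each sequence, the base intensity `c` has the closed-form Poisson
#' maximum-likelihood estimate `k / E` where `E` is the integral of
#' `exp((t - s)/zeta)` over the post-crossing segments; `zeta` is chosen per
#' sequence and the threshold `m_th` per user, both by profile-likelihood
#' grid search. A sequence with a review before its first crossing has
#' likelihood `-Inf` under that threshold; thresholds are ranked first by
#' how many sequences they leave feasible, then by total log-likelihood.
#'
#' @param trajectories A named list (keys identify sequences) of replayed
#'   training trajectories for one user, each as in [replay_sequence()].
#' @param T_per_seq Numeric vector of observation-window ends, same order.
#' @param zeta_grid,m_th_grid Search grids (days; probability). Defaults
#'   `{0.5, 1, 2, 4, 8, 16}` and `{0.3, ..., 0.9}`.
#' @return A list with the selected `m_th` and a tibble `fits` of
#'   per-sequence `c`, `zeta`, `ll`.
#' @export
fit_threshold <- function(trajectories, T_per_seq,
                          zeta_grid = c(0.5, 1, 2, 4, 8, 16),
                          m_th_grid = seq(0.3, 0.9, by = 0.1)) {
  stopifnot(length(trajectories) == length(T_per_seq))
  eval_seq <- function(traj, T, m_th) {
    k <- nrow(traj)
    if (k == 0) return(list(ll = 0, c = 0, zeta = zeta_grid[1]))
    best <- list(ll = -Inf, c = 0, zeta = zeta_grid[1])
    for (zeta in zeta_grid) {
      geo <- threshold_geometry(traj, m_th, zeta, T)
      if (anyNA(geo$ramp)) next   # an event before the crossing: u = 0 there
      if (geo$exposure <= 0) next
      c_hat <- k / geo$exposure
      ll <- k * log(c_hat) + sum(geo$ramp) / zeta - k
      if (ll > best$ll) best <- list(ll = ll, c = c_hat, zeta = zeta)
    }
    best
  }
  per_mth <- purrr::map(m_th_grid, function(m_th) {
    fits <- purrr::map2(trajectories, T_per_seq, eval_seq, m_th = m_th)
    lls <- vapply(fits, `[[`, numeric(1), "ll")
    list(fits = fits, n_feasible = sum(is.finite(lls)),
         total = sum(lls[is.finite(lls)]))
  })
  nf <- vapply(per_mth, `[[`, numeric(1), "n_feasible")
  tot <- vapply(per_mth, `[[`, numeric(1), "total")
  best_i <- order(-nf, -tot)[1]
  chosen <- per_mth[[best_i]]
  list(
    m_th = m_th_grid[best_i],
    fits = tibble::tibble(
      key = names(trajectories),
      c = unname(vapply(chosen$fits, `[[`, numeric(1), "c")),
      zeta = unname(vapply(chosen$fits, `[[`, numeric(1), "zeta")),
      ll = unname(vapply(chosen$fits, `[[`, numeric(1), "ll"))
    )
  )
}
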