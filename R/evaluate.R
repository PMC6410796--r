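#' Log-likelihood of review times under an intensity
#'
#' The temporal point-process log-likelihood
#' `LL = sum_i log u(t_i) - integral_0^T u(t) dt`. The generic form takes
#' the intensity values at the events and the compensator (the integral);
#' the per-scheduler helpers below supply both in closed form. An event
#' where the intensity vanishes yields the `-Inf` sentinel.
#'
#' @param u_at_events Intensity evaluated at each event time.
#' @param compensator Integral of the intensity over the window.
#' @return The log-likelihood (possibly `-Inf`).
#' @export
log_likelihood <- function(u_at_events, compensator) {
  if (any(u_at_events <= 0)) return(-Inf)
  sum(log(u_at_events)) - compensator
}

#' Closed-form scheduler log-likelihoods for a replayed sequence
#'
#' Each helper evaluates the log-likelihood of a training trajectory (a
#' replayed sequence, see [replay_sequence()]) over the window `[0, T]`
#' using the scheduler's exact compensator: `mu * T` for the uniform
#' schedule; `q^(-1/2) * A` with the piecewise closed-form area `A` of
#' `1 - m(t)` for the optimal schedule; and exponential-ramp segments for
#' the threshold schedule.
#'
#' @param trajectory Replayed training reviews (`t_days`, `m_before`,
#'   `n_before`, `n_after`).
#' @param q,mu,c,zeta,m_th Scheduler parameters.
#' @param T Window end (days); defaults to the last training review.
#' @return Log-likelihood (possibly `-Inf`).
#' @export
loglik_memorize <- function(trajectory, q, T = max(trajectory$t_days)) {
  k <- nrow(trajectory)
  A <- memorize_area(trajectory$t_days,
                     c(trajectory$n_before, trajectory$n_after[k]), T)
  log_likelihood(memorize_intensity(trajectory$m_before, q), A / sqrt(q))
}

#' @rdname loglik_memorize
#' @export
loglik_uniform <- function(trajectory, mu, T = max(trajectory$t_days)) {
  k <- nrow(trajectory)
  if (mu == 0) return(if (k == 0) 0 else -Inf)
  k * log(mu) - mu * T
}

#' @rdname loglik_memorize
#' @export
loglik_threshold <- function(trajectory, c, zeta, m_th,
                             T = max(trajectory$t_days)) {
  geo <- threshold_geometry(trajectory, m_th, zeta, T)
  if (anyNA(geo$ramp) || c <= 0) {
    return(if (nrow(trajectory) == 0 && c * geo$exposure == 0) 0 else -Inf)
  }
  nrow(trajectory) * log(c) + sum(geo$ramp) / zeta - c * geo$exposure
}

#' Empirical forgetting rate from the final (test) review
#'
#' A model-free retention quality metric: `-log(m_hat) / (t_n - t_{n-1})`,
#' the exponential rate that would take a just-refreshed memory down to the
#' empirical recall `m_hat` observed at the test review after the retention
#' interval. Lower is better. Returns 0 for perfect recall (`m_hat = 1`).
#'
#' @param m_hat Empirical recall probability at the test review, in (0, 1]
#'   after clamping (vectorised).
#' @param t_n Test review time (day).
#' @param t_prev Last training review time; must satisfy `t_n > t_prev`.
#' @return Rate in 1/day.
#' @examples
#' empirical_forgetting_rate(0.5, 2, 0) # log(2) / 2
#' @export
empirical_forgetting_rate <- function(m_hat, t_n, t_prev) {
  if (any(t_n <= t_prev)) {
    stop("test review must be strictly after the last training review",
         call. = FALSE)
  }
  stopifnot(all(m_hat > 0), all(m_hat <= 1))
  -log(m_hat) / (t_n - t_prev)
}

#' Normalise a forgetting rate by its item baseline
#'
#' Divides the empirical forgetting rate by the item's average initial
#' forgetting rate (estimated across all pairs that reviewed the item), so
#' item difficulty cancels in cross-item comparisons.
#'
#' @param n_hat Empirical forgetting rate(s).
#' @param n_hat0 Item-level baseline, > 0.
#' @return The ratio `n_hat / n_hat0`.
#' @export
normalize_forgetting_rate <- function(n_hat, n_hat0) {
  if (any(n_hat0 <= 0)) {
    stop("item baseline `n_hat0` must be positive; exclude zero-baseline items",
         call. = FALSE)
  }
  n_hat / n_hat0
}

#' Build per-sequence evaluation records
#'
#' The full natural-experiment measurement pipeline. Each (learner, item)
#' sequence is split into training reviews (all but the last) and one test
#' review. The memory trajectory of the training reviews is replayed under
#' the fitted (or true) parameters; scheduler parameters are then fitted per
#' learner (`q` and `mu` pooled over the learner's sequences, threshold
#' `c`/`zeta` per sequence and `m_th` per learner) and each sequence's
#' training times are scored by the closed-form log-likelihood of each
#' scheduler over `[0, t_{n-1}]`. The test review supplies the empirical
#' forgetting rate, normalised by the item's average initial rate.
#'
#' Sequences with fewer than `min_reviews` total reviews, or a test review
#' not strictly after the last training review, are dropped (count reported
#' in attribute `"n_dropped"`).
#'
#' @param log A canonical review-log tibble.
#' @param fit A `memory_fit`, or a list with `alpha`, `beta` and an `items`
#'   tibble (`item_id`, `n0`) — e.g. the true simulation parameters.
#' @param clamp Lower clamp for empirical recall before logarithms.
#' @param min_reviews Minimum reviews per sequence (default 3: at least two
#'   training reviews so the training period is positive).
#' @param zeta_grid,m_th_grid Grids for the threshold fit.
#' @return A tibble with one row per sequence: identifiers, `scheduler`
#'   label when present in the log, `n_reviews`, training period `T_train`,
#'   `ll_memorize`, `ll_uniform`, `ll_threshold`, `n_hat`, `n_hat0` and
#'   `n_hat_norm`, plus the fitted `q` and `mu` per learner.
#' @export
evaluation_records <- function(log, fit, clamp = 1e-4, min_reviews = 3,
                               zeta_grid = c(0.5, 1, 2, 4, 8, 16),
                               m_th_grid = seq(0.3, 0.9, by = 0.1)) {
  par_of <- function(item) {
    n0 <- fit$items$n0[match(item, fit$items$item_id)]
    item_params(n0 = n0, alpha = fit$alpha, beta = fit$beta, item_id = item)
  }
  seqs <- log |>
    dplyr::arrange(.data$learner_id, .data$item_id, .data$t_days) |>
    dplyr::group_by(.data$learner_id, .data$item_id) |>
    dplyr::group_split()
  keep <- vapply(seqs, function(s) {
    nrow(s) >= min_reviews &&
      s$t_days[nrow(s)] > s$t_days[nrow(s) - 1] &&
      s$item_id[1] %in% fit$items$item_id
  }, logical(1))
  n_dropped <- sum(!keep)
  seqs <- seqs[keep]
  if (length(seqs) == 0) {
    stop("no sequence satisfies the evaluation preconditions", call. = FALSE)
  }

  per_seq <- purrr::map(seqs, function(s) {
    n <- nrow(s)
    train <- replay_sequence(s[seq_len(n - 1), ], par_of(s$item_id[1]))
    test <- s[n, ]
    m_hat_test <- pmin(pmax(test$session_correct / test$session_seen, clamp), 1)
    m_hat_first <- pmin(pmax(s$session_correct[1] / s$session_seen[1], clamp), 1)
    list(
      learner_id = s$learner_id[1], item_id = s$item_id[1],
      scheduler = if ("scheduler" %in% names(s)) s$scheduler[1] else NA_character_,
      train = train, T_window = train$t_days[n - 1],
      n_reviews = n, T_train = train$t_days[n - 1] - train$t_days[1],
      n_hat = empirical_forgetting_rate(m_hat_test, test$t_days,
                                        train$t_days[n - 1]),
      n_hat0_pair = if (s$t_days[1] > 0) -log(m_hat_first) / s$t_days[1] else NA_real_
    )
  })

  # item baseline: average initial empirical rate over all pairs of the item
  base <- tibble::tibble(
    item_id = vapply(per_seq, `[[`, "", "item_id"),
    n0_pair = vapply(per_seq, `[[`, numeric(1), "n_hat0_pair")
  ) |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(n_hat0 = mean(.data$n0_pair, na.rm = TRUE))

  learners <- split(per_seq, vapply(per_seq, `[[`, "", "learner_id"))
  rows <- purrr::map(learners, function(ps) {
    areas <- vapply(ps, function(x) {
      k <- nrow(x$train)
      memorize_area(x$train$t_days,
                    c(x$train$n_before, x$train$n_after[k]), x$T_window)
    }, numeric(1))
    ks <- vapply(ps, function(x) nrow(x$train), numeric(1))
    Ts <- vapply(ps, `[[`, numeric(1), "T_window")
    q_user <- if (sum(areas) > 0) (sum(areas) / sum(ks))^2 else NA_real_
    mu_user <- if (sum(Ts) > 0) sum(ks) / sum(Ts) else 0
    th <- fit_threshold(
      stats::setNames(purrr::map(ps, "train"),
                      vapply(ps, `[[`, "", "item_id")),
      Ts, zeta_grid = zeta_grid, m_th_grid = m_th_grid
    )
    tibble::tibble(
      learner_id = vapply(ps, `[[`, "", "learner_id"),
      item_id = vapply(ps, `[[`, "", "item_id"),
      scheduler = vapply(ps, `[[`, "", "scheduler"),
      n_reviews = vapply(ps, `[[`, numeric(1), "n_reviews"),
      T_train = vapply(ps, `[[`, numeric(1), "T_train"),
      q = q_user, mu = mu_user, m_th = th$m_th,
      ll_memorize = purrr::map2_dbl(ps, q_user, function(x, q) {
        if (is.na(q)) -Inf else loglik_memorize(x$train, q, x$T_window)
      }),
      ll_uniform = purrr::map_dbl(ps, function(x) {
        loglik_uniform(x$train, mu_user, x$T_window)
      }),
      ll_threshold = purrr::pmap_dbl(
        list(ps, th$fits$c, th$fits$zeta),
        function(x, c, zeta) loglik_threshold(x$train, c, zeta, th$m_th,
                                              x$T_window)
      ),
      n_hat = vapply(ps, `[[`, numeric(1), "n_hat")
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::left_join(base, by = "item_id") |>
    dplyr::mutate(
      n_hat_norm = dplyr::if_else(.data$n_hat0 > 0,
                                  .data$n_hat / .data$n_hat0, NA_real_)
    )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Assign sequences to likelihood-matched scheduler groups
#'
#' Within each cell of sequences with the same review count and similar
#' training period, the top fraction (default 25%) by log-likelihood under
#' each scheduler forms that scheduler's group; any sequence qualifying for
#' more than one scheduler is skipped from all groups. Ties are broken
#' deterministically by (log-likelihood, learner, item).
#'
#' @param records An [evaluation_records()] tibble.
#' @param fraction Top fraction per scheduler, in (0, 1].
#' @param T_edges Half-open training-period bin edges in days.
#' @param ll_cols Named character vector mapping group labels to
#'   log-likelihood columns.
#' @return `records` restricted to grouped sequences, with `group` and
#'   `cell` columns.
#' @export
assign_groups <- function(records, fraction = 0.25,
                          T_edges = c(0, 1, 2, 4, 8, 16, 32, Inf),
                          ll_cols = c(memorize = "ll_memorize",
                                      uniform = "ll_uniform",
                                      threshold = "ll_threshold")) {
  stopifnot(fraction > 0, fraction <= 1)
  records <- dplyr::mutate(
    records,
    cell = paste0("n", .data$n_reviews, ":T",
                  cut(.data$T_train, T_edges, right = FALSE, labels = FALSE))
  )
  picks <- purrr::imap_dfr(ll_cols, function(col, label) {
    records |>
      dplyr::filter(is.finite(.data[[col]])) |>
      dplyr::group_by(.data$cell) |>
      dplyr::arrange(dplyr::desc(.data[[col]]), .data$learner_id,
                     .data$item_id, .by_group = TRUE) |>
      dplyr::mutate(.rank = dplyr::row_number(),
                    .keep_n = ceiling(fraction * dplyr::n())) |>
      dplyr::filter(.data$.rank <= .data$.keep_n) |>
      dplyr::ungroup() |>
      dplyr::select(-".rank", -".keep_n") |>
      dplyr::mutate(group = label)
  })
  dup <- picks |>
    dplyr::count(.data$learner_id, .data$item_id) |>
    dplyr::filter(.data$n > 1)
  dplyr::anti_join(picks, dup, by = c("learner_id", "item_id"))
}

#' Compare two groups of forgetting rates
#'
#' Mann-Whitney U comparison with box summaries. For combined sample sizes
#' of at most 12 the two-sided p-value is computed by exact enumeration of
#' all group assignments of the pooled values (ties handled by the 1/2
#' convention in U); larger samples use the normal approximation with tie
#' correction. Quartiles use the type-7 (linear interpolation) convention.
#'
#' @param treatment,control Numeric vectors (both nonempty).
#' @return A one-row tibble: medians, quartiles, `U` (for the treatment
#'   group), and the two-sided `p_value`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
compare_groups <- function(treatment, control) {
  if (length(treatment) == 0 || length(control) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  m <- length(treatment); n <- length(control)
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  U <- u_stat(treatment, control)
  if (m + n <= 12) {
    pool <- c(treatment, control)
    combos <- utils::combn(m + n, m)
    us <- apply(combos, 2, function(ix) u_stat(pool[ix], pool[-ix]))
    p <- min(1, 2 * min(mean(us <= U), mean(us >= U)))
  } else {
    N <- m + n
    ties <- table(c(treatment, control))
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - m * n / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                    names = FALSE)
  qt <- qs(treatment); qc <- qs(control)
  tibble::tibble(
    median_treatment = qt[2], q25_treatment = qt[1], q75_treatment = qt[3],
    median_control = qc[2], q25_control = qc[1], q75_control = qc[3],
    n_treatment = m, n_control = n, U = U, p_value = p
  )
}

#' Per-learner correlation between scheduler conformance and retention
#'
#' For each learner with enough sequences in a training-period band, takes
#' the top and bottom halves of their sequences by log-likelihood under the
#' optimal scheduler and computes the Pearson correlation between
#' log-likelihood and empirical forgetting rate. Negative correlations mean
#' retention improves when the learner's spacing conforms to the optimal
#' schedule.
#'
#' @param records An [evaluation_records()] tibble.
#' @param min_sequences Eligibility threshold per learner (default 70).
#' @param T_center,T_halfwidth Training-period band in days (default
#'   8 +/- 3.2).
#' @param split Fraction taken from each end of the likelihood ranking
#'   (default 0.5: both halves, i.e. all sequences).
#' @param ll_col Likelihood column used for ranking (default
#'   `"ll_memorize"`).
#' @param metric Column correlated against the likelihood (default
#'   `"n_hat"`).
#' @return A tibble of `learner_id`, `r`, `n_sequences`; learners with zero
#'   variance in either variate are skipped.
#' @export
learner_correlation <- function(records, min_sequences = 70, T_center = 8,
                                T_halfwidth = 3.2, split = 0.5,
                                ll_col = "ll_memorize", metric = "n_hat") {
  band <- records |>
    dplyr::filter(.data$T_train >= T_center - T_halfwidth,
                  .data$T_train <= T_center + T_halfwidth,
                  is.finite(.data[[ll_col]]))
  band |>
    dplyr::group_by(.data$learner_id) |>
    dplyr::group_split() |>
    purrr::map(function(s) {
      N <- nrow(s)
      if (N < min_sequences) return(NULL)
      ord <- order(s[[ll_col]], decreasing = TRUE)
      k <- ceiling(split * N)
      sel <- s[union(ord[seq_len(k)], rev(ord)[seq_len(k)]), ]
      if (stats::sd(sel[[ll_col]]) == 0 || stats::sd(sel[[metric]]) == 0) {
        return(NULL)
      }
      tibble::tibble(
        learner_id = s$learner_id[1],
        r = stats::cor(sel[[ll_col]], sel[[metric]]),
        n_sequences = N
      )
    }) |>
    dplyr::bind_rows()
}
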