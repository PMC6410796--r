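test_that("empirical recall is the session success fraction", {
  expect_identical(estimate_empirical_recall(4, 3), 0.75)
  expect_identical(estimate_empirical_recall(4, 4), 1)
  expect_identical(estimate_empirical_recall(5, 0), 0)
  expect_error(estimate_empirical_recall(0, 0), "at least 1")
  expect_error(estimate_empirical_recall(4, 5), "lie in")
})

test_that("log filtering reaches the brute-force fixed point", {
  # 5 learners x 5 items; removing learner u1 pushes item iA below threshold,
  # which cascades to learner u2
  log <- toy_log(
    list(learner = "u1", item = "iA", t = 1),
    list(learner = "u2", item = "iA", t = c(1, 2)),
    list(learner = "u2", item = "iB", t = 1),
    list(learner = "u3", item = "iB", t = c(1, 2)),
    list(learner = "u3", item = "iC", t = c(1, 2)),
    list(learner = "u4", item = "iC", t = c(1, 2, 3)),
    list(learner = "u4", item = "iD", t = c(1, 2)),
    list(learner = "u5", item = "iE", t = 1)
  )
  # brute-force oracle: exhaustively re-apply both rules
  oracle <- log
  repeat {
    tl <- table(oracle$learner_id)
    oracle <- oracle[tl[oracle$learner_id] >= 2, ]
    ti <- table(oracle$item_id)
    oracle <- oracle[ti[oracle$item_id] >= 2, ]
    if (all(table(oracle$learner_id) >= 2) && all(table(oracle$item_id) >= 2)) break
  }
  got <- filter_log(log, 2, 2)
  expect_identical(
    dplyr::arrange(got, learner_id, item_id, t_days),
    dplyr::arrange(tibble::as_tibble(oracle), learner_id, item_id, t_days)
  )
  expect_identical(filter_log(log, 0, 0), log)
  expect_identical(nrow(filter_log(log, 100, 100)), 0L)
})

test_that("a single noiseless review recovers n0 in closed form", {
  # one review at dt = 2 with empirical recall exactly 0.5: n0 = log(2)/2
  log <- toy_log(list(learner = "u1", item = "iA", t = 2, seen = 2, correct = 1))
  fit <- fit_memory_model(log)
  expect_equal(fit$items$n0, log(2) / 2, tolerance = 1e-5)
  expect_true(fit$converged)
})

test_that("memory-model fitting is deterministic and its loss trace monotone", {
  set.seed(41)
  cfg <- population_config(6, 4, scheduler_uniform(0.3), tf = 30,
                           attempts = 10L, seed = 17)
  log <- simulate_population(cfg)
  f1 <- fit_memory_model(log)
  f2 <- fit_memory_model(log)
  expect_identical(f1[c("alpha", "beta", "items", "loss")],
                   f2[c("alpha", "beta", "items", "loss")])
  expect_true(all(diff(f1$loss_trace) <= 0))
  td <- tidy(f1)
  expect_identical(td$term, c("alpha", "beta"))
  expect_identical(nrow(tidy(f1, items = TRUE)), 2L + nrow(f1$items))
  expect_identical(glance(f1)$converged, f1$converged)
})

test_that("closed-form q MLE maximises the likelihood (grid oracle)", {
  traj <- toy_trajectory(t = c(1, 2.5, 4), n_before = c(0.8, 0.5, 0.9),
                         n_after = c(0.5, 0.9, 0.6))
  q_hat <- fit_q_mle(traj)
  A <- attr(q_hat, "area")
  ll <- function(q) {
    sum(log(memorize_intensity(traj$m_before, q))) - A / sqrt(q)
  }
  q_num <- grid_argmax(ll, 1e-4, 1e4)
  expect_equal(as.numeric(q_hat), q_num, tolerance = 1e-4)
  expect_equal(as.numeric(q_hat), (A / 3)^2, tolerance = 1e-12)
  expect_error(fit_q_mle(toy_trajectory(numeric(0), numeric(0), numeric(0))),
               "at least one")
  # degenerate: permanently-remembered item, m = 1 throughout
  expect_error(fit_q_mle(toy_trajectory(1, 0, 0)), "degenerate")
})

test_that("uniform-rate MLE matches the grid oracle and the count ratio", {
  expect_identical(fit_uniform_mle(10, 5), 2)
  expect_identical(fit_uniform_mle(0, 5), 0)
  k <- 7; T <- 3.5
  ll <- function(mu) k * log(mu) - mu * T
  expect_equal(fit_uniform_mle(k, T), grid_argmax(ll, 1e-3, 1e3),
               tolerance = 1e-4)
})

test_that("threshold base-intensity MLE has the closed Poisson form", {
  # single segment: n = log(2), m_th = 0.5 -> crossing at t = 1;
  # one event at t = 1 + zeta*log(1 + 2/zeta) makes the exposure exactly 2
  zeta <- 2
  t_ev <- 1 + zeta * log(1 + 2 / zeta)
  traj <- toy_trajectory(t = t_ev, n_before = log(2), n_after = log(2))
  fit <- fit_threshold(list(s1 = traj), T_per_seq = t_ev,
                       zeta_grid = zeta, m_th_grid = 0.5)
  expect_equal(fit$fits$c, 0.5, tolerance = 1e-10)
  # zero events after crossing: c = 0
  fit0 <- fit_threshold(list(s0 = traj[0, ]), T_per_seq = 3,
                        zeta_grid = zeta, m_th_grid = 0.5)
  expect_identical(fit0$fits$c, 0)
})

test_that("threshold grids recover the generating parameters", {
  set.seed(42)
  zeta_grid <- c(0.5, 1, 2, 4, 8, 16)
  true <- list(c = 0.4, zeta = 2, m_th = 0.6)
  p <- item_params(n0 = 0.4, alpha = 0.3, beta = 0.2)
  spec <- scheduler_threshold(true$c, true$zeta, true$m_th)
  n_users <- 200
  hits <- vapply(seq_len(n_users), function(u) {
    trajs <- list()
    for (s in 1:6) {
      ev <- simulate_sequence(p, spec, tf = 50)
      if (nrow(ev) >= 3) {
        trajs[[length(trajs) + 1]] <- replay_sequence(ev[, c("t_days", "r")], p)
      }
    }
    if (length(trajs) == 0) return(NA)
    names(trajs) <- paste0("s", seq_along(trajs))
    Ts <- vapply(trajs, function(x) max(x$t_days), 0)
    fit <- fit_threshold(trajs, Ts)
    # the user-level zeta: profile likelihood pooled over the sequences
    pooled <- vapply(zeta_grid, function(z) {
      f <- fit_threshold(trajs, Ts, zeta_grid = z, m_th_grid = fit$m_th)
      sum(f$fits$ll[is.finite(f$fits$ll)])
    }, numeric(1))
    abs(fit$m_th - true$m_th) < 1e-9 &&
      zeta_grid[which.max(pooled)] == true$zeta
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
})

test_that("scheduler MLE error shrinks with more data", {
  p <- item_params(n0 = 0.6, alpha = 0.3, beta = 0.2)
  err_at <- function(n_seq, seed) {
    set.seed(seed)
    qs <- replicate(20, {
      trajs <- lapply(seq_len(n_seq), function(i) {
        ev <- simulate_sequence(p, scheduler_memorize(1), tf = 30)
        if (nrow(ev) == 0) return(NULL)
        replay_sequence(ev[, c("t_days", "r")], p)
      })
      trajs <- trajs[!vapply(trajs, is.null, TRUE)]
      A <- sum(vapply(trajs, function(tr) {
        attr(fit_q_mle(tr), "area")
      }, numeric(1)))
      k <- sum(vapply(trajs, nrow, numeric(1)))
      (A / k)^2
    })
    mean(abs(qs - 1))
  }
  expect_lt(err_at(40, 43), err_at(4, 44))
})
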