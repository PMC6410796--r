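test_that("point-process log-likelihood has the closed form", {
  # uniform rate 2, events at 0.5 and 1.0, window 2
  traj <- toy_trajectory(t = c(0.5, 1), n_before = c(1, 1), n_after = c(1, 1))
  expect_equal(loglik_uniform(traj, mu = 2, T = 2), 2 * log(2) - 4,
               tolerance = 1e-12)
  expect_equal(loglik_uniform(traj[0, ], mu = 3, T = 2), -6, tolerance = 1e-12)
  expect_identical(log_likelihood(c(1, 0), 5), -Inf)
  # scaling a constant intensity by g shifts LL by k log g - (g-1) mu T
  k <- 4; mu <- 1.5; T <- 3; g <- 2.5
  tr <- toy_trajectory(t = c(0.2, 0.9, 1.8, 2.7), n_before = rep(1, 4),
                       n_after = rep(1, 4))
  expect_equal(
    loglik_uniform(tr, g * mu, T) - loglik_uniform(tr, mu, T),
    k * log(g) - (g - 1) * mu * T,
    tolerance = 1e-12
  )
})

test_that("closed-form compensators agree with adaptive quadrature", {
  set.seed(51)
  p <- item_params(n0 = 0.7, alpha = 0.3, beta = 0.2)
  for (i in 1:10) {
    ev <- simulate_sequence(p, scheduler_memorize(0.7), tf = 30)
    if (nrow(ev) < 2) next
    traj <- replay_sequence(ev[, c("t_days", "r")], p)
    T <- max(traj$t_days)
    q <- 0.7
    # piecewise state-dependent intensity as an explicit function of time
    u_fn <- function(t) {
      j <- findInterval(t, traj$t_days)
      n <- if (j == 0) traj$n_before[1] else traj$n_after[j]
      t_r <- if (j == 0) 0 else traj$t_days[j]
      memorize_intensity(exp(-n * (t - t_r)), q)
    }
    closed <- spacedrep:::memorize_area(
      traj$t_days, c(traj$n_before, traj$n_after[nrow(traj)]), T
    ) / sqrt(q)
    edges <- c(0, traj$t_days)
    num <- sum(vapply(seq_len(length(edges) - 1), function(j) {
      spacedrep:::numeric_compensator(u_fn, edges[j], edges[j + 1])
    }, numeric(1)))
    expect_equal(closed, num, tolerance = 1e-8)
  }
})

test_that("empirical forgetting rate follows its defining formula", {
  expect_equal(empirical_forgetting_rate(0.5, 2, 0), log(2) / 2,
               tolerance = 1e-12)
  expect_identical(empirical_forgetting_rate(1, 5, 3), 0)
  expect_equal(empirical_forgetting_rate(exp(-3), 1.5, 0), 2,
               tolerance = 1e-12)
  expect_error(empirical_forgetting_rate(0.5, 2, 2), "strictly after")
})

test_that("normalisation divides by the item baseline", {
  expect_identical(normalize_forgetting_rate(0.4, 0.2), 2)
  expect_identical(normalize_forgetting_rate(0.3, 0.3), 1)
  expect_equal(mean(c(0.1, 0.3)), 0.2)  # baseline is the plain pair average
  expect_error(normalize_forgetting_rate(0.4, 0), "positive")
})

test_that("group assignment matches exhaustive enumeration on a toy table", {
  # 8 records in one cell; LLs arranged so exactly one sequence is top-2
  # under both schedulers
  rec <- tibble::tibble(
    learner_id = sprintf("u%d", 1:8), item_id = "i1",
    n_reviews = 5, T_train = 3,
    ll_memorize = c(10, 9, 1, 2, 3, 4, 5, 6),
    ll_uniform = c(10, 1, 9, 2, 3, 4, 5, 6),
    ll_threshold = rep(-Inf, 8),
    n_hat = 1, n_hat_norm = 1
  )
  got <- assign_groups(rec, fraction = 0.25,
                       ll_cols = c(memorize = "ll_memorize",
                                   uniform = "ll_uniform"))
  # brute force: top-2 memorize = {u1,u2}, top-2 uniform = {u1,u3}; u1 overlaps
  expect_setequal(got$learner_id[got$group == "memorize"], "u2")
  expect_setequal(got$learner_id[got$group == "uniform"], "u3")
  # fraction 1, single scheduler: everything is selected
  all_in <- assign_groups(rec, fraction = 1,
                          ll_cols = c(memorize = "ll_memorize"))
  expect_identical(nrow(all_in), 8L)
  # deterministic tie-break on equal likelihoods: lexicographic by key
  tie <- dplyr::mutate(rec, ll_memorize = 7, ll_uniform = 1:8)
  g1 <- assign_groups(tie, fraction = 0.25,
                      ll_cols = c(memorize = "ll_memorize",
                                  uniform = "ll_uniform"))
  g2 <- assign_groups(tie, fraction = 0.25,
                      ll_cols = c(memorize = "ll_memorize",
                                  uniform = "ll_uniform"))
  expect_identical(g1, g2)
  expect_setequal(g1$learner_id[g1$group == "memorize"], c("u1", "u2"))
  expect_setequal(g1$learner_id[g1$group == "uniform"], c("u7", "u8"))
})

test_that("group assignment never duplicates a sequence and caps cell counts", {
  set.seed(52)
  rec <- tibble::tibble(
    learner_id = sprintf("u%02d", 1:40), item_id = "i1",
    n_reviews = sample(3:5, 40, TRUE), T_train = runif(40, 0, 10),
    ll_memorize = rnorm(40), ll_uniform = rnorm(40), ll_threshold = rnorm(40),
    n_hat = runif(40), n_hat_norm = runif(40)
  )
  got <- assign_groups(rec, fraction = 0.25)
  key <- paste(got$learner_id, got$item_id)
  expect_identical(anyDuplicated(key), 0L)
  caps <- rec |>
    dplyr::mutate(cell = paste0("n", n_reviews, ":T",
                                cut(T_train, c(0, 1, 2, 4, 8, 16, 32, Inf),
                                    right = FALSE, labels = FALSE))) |>
    dplyr::count(cell, name = "N")
  per <- dplyr::count(got, cell, group)
  per <- dplyr::left_join(per, caps, by = "cell")
  expect_true(all(per$n <= ceiling(0.25 * per$N)))
})

test_that("Mann-Whitney comparison is exact for small samples", {
  out <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_identical(out$U, 0)
  expect_equal(out$p_value, 0.1, tolerance = 1e-12)
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  qs <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(qs$median_treatment, 2.5, tolerance = 1e-12)
  expect_equal(qs$q25_treatment, 1.75, tolerance = 1e-12)
  expect_equal(qs$q75_treatment, 3.25, tolerance = 1e-12)
  expect_error(compare_groups(numeric(0), 1), "nonempty")
})

test_that("Mann-Whitney agrees with the reference implementation", {
  set.seed(53)
  # exact branch, no ties
  x <- rnorm(5); y <- rnorm(6)
  ref <- wilcox.test(x, y, exact = TRUE)
  got <- compare_groups(x, y)
  expect_equal(got$U, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  # large-sample branch with ties
  x2 <- sample(1:6, 40, TRUE); y2 <- sample(2:7, 35, TRUE)
  ref2 <- wilcox.test(x2, y2, exact = FALSE, correct = FALSE)
  got2 <- compare_groups(x2, y2)
  expect_equal(got2$p_value, ref2$p.value, tolerance = 1e-9)
})

test_that("learner correlation identifies conformance-driven retention", {
  rec <- tibble::tibble(
    learner_id = "u1", item_id = sprintf("i%d", 1:3),
    T_train = 8, ll_memorize = c(1, 2, 3), n_hat = c(2, 4, 6)
  )
  out <- learner_correlation(rec, min_sequences = 3)
  expect_equal(out$r, 1, tolerance = 1e-12)
  rec$n_hat <- c(6, 4, 2)
  expect_equal(learner_correlation(rec, min_sequences = 3)$r, -1,
               tolerance = 1e-12)
  # zero variance in the metric: learner skipped
  rec$n_hat <- c(1, 1, 1)
  expect_identical(nrow(learner_correlation(rec, min_sequences = 3)), 0L)
  # outside the training-period band: ineligible
  rec2 <- dplyr::mutate(rec, T_train = 20, n_hat = c(2, 4, 6))
  expect_identical(nrow(learner_correlation(rec2, min_sequences = 3)), 0L)
})

test_that("evaluation records split training and test reviews correctly", {
  set.seed(54)
  cfg <- population_config(
    9, 4,
    list(memorize = scheduler_memorize(1), uniform = scheduler_uniform(0.25),
         threshold = scheduler_threshold(0.5, 2, 0.6)),
    tf = 30, test_delay = 7, attempts = 10L, seed = 31
  )
  log <- simulate_population(cfg)
  fit <- list(alpha = 0.3, beta = 0.2, items = population_items(cfg))
  rec <- evaluation_records(log, fit)
  expect_true(all(rec$n_reviews >= 3))
  expect_true(all(rec$T_train >= 0))
  # training period excludes the test review: T_train < test time span
  expect_true(all(rec$T_train < 30))
  expect_true(all(is.finite(rec$n_hat)))
  expect_setequal(unique(rec$scheduler),
                  c("memorize", "uniform", "threshold"))
  # likelihoods are finite for the generating scheduler's own sequences
  expect_true(all(is.finite(rec$ll_memorize[rec$scheduler == "memorize"])))
  expect_true(all(is.finite(rec$ll_uniform)))
})
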