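# Shared helpers for building tiny in-code fixtures.

# A canonical log tibble from compact per-sequence event lists.
toy_log <- function(...) {
  seqs <- list(...)
  purrr::imap_dfr(seqs, function(s, i) {
    tibble::tibble(
      learner_id = s$learner %||% sprintf("u%02d", i),
      item_id = s$item %||% "i01",
      t_days = s$t,
      session_seen = as.integer(s$seen %||% rep(1L, length(s$t))),
      session_correct = as.integer(s$correct %||% rep(1L, length(s$t)))
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built replayed trajectory (what replay_sequence would produce) for
# closed-form likelihood checks.
toy_trajectory <- function(t, n_before, n_after, m_before = NULL) {
  tibble::tibble(
    t_days = t, n_before = n_before, n_after = n_after,
    m_before = m_before %||% exp(-n_before * (t - dplyr::lag(t, default = 0)))
  )
}

# Numeric maximiser of a scheduler log-likelihood over a positive parameter,
# the independent oracle for the closed-form MLEs.
grid_argmax <- function(ll_fn, lower, upper) {
  stats::optimize(ll_fn, c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}
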