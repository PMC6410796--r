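#' Time-rescaling transform of a simulated sequence
#'
#' By the time-rescaling theorem, the compensator increments
#' `Lambda(t_i) - Lambda(t_{i-1})` between successive events of a point
#' process are i.i.d. Exp(1) when the events were generated by the claimed
#' intensity. Each scheduler's compensator is evaluated in closed form on
#' the inter-review intervals, using the forgetting-rate trajectory logged
#' by the simulator. A Kolmogorov-Smirnov test of the pooled increments
#' against Exp(1) is the standard exactness check for the thinning sampler.
#'
#' @param events One simulated sequence (from [simulate_sequence()]), with
#'   `t_days` and `n_before`.
#' @param spec The `scheduler_spec` that generated it.
#' @return Numeric vector of compensator increments, one per event.
#' @examples
#' set.seed(1)
#' ev <- simulate_sequence(item_params(0.3, 0.3, 0.2), scheduler_memorize(1),
#'                         tf = 50)
#' gaps <- rescaled_gaps(ev, scheduler_memorize(1))
#' @export
rescaled_gaps <- function(events, spec) {
  k <- nrow(events)
  if (k == 0) return(numeric(0))
  t_prev <- c(0, events$t_days[-k])
  dl <- events$t_days - t_prev
  n <- events$n_before
  switch(spec$variant,
    memorize = (dl + ifelse(n > 0, (exp(-n * dl) - 1) / n, -dl)) / sqrt(spec$q),
    uniform = spec$mu * dl,
    threshold = {
      s <- ifelse(n > 0, t_prev - log(spec$m_th) / n, Inf)
      ifelse(events$t_days > s,
             spec$c * spec$zeta * (exp((events$t_days - s) / spec$zeta) - 1),
             0)
    },
    stop("unknown scheduler variant: ", spec$variant, call. = FALSE)
  )
}

# Compensator of an intensity by adaptive quadrature; the numerical oracle
# the closed forms are verified against in the tests.
numeric_compensator <- function(intensity, lower, upper, rel_tol = 1e-10) {
  stats::integrate(Vectorize(intensity), lower, upper, rel.tol = rel_tol,
                   subdivisions = 2000L)$value
}
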