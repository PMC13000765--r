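# Build a singles_stream by hand from explicit event fields (times in ps).
make_stream <- function(time_ps, decay_id = seq_along(time_ps),
                        kind = rep(0L, length(time_ps)),
                        block_id = rep(0L, length(time_ps)),
                        duration_ps = max(time_ps, 0) + 1e7,
                        eps1 = 0.4, eps2 = 0.14, eps_gamma = 0,
                        activity_bq = 1e6) {
  ord <- order(time_ps)
  ev <- data.frame(time_ps = as.numeric(time_ps)[ord],
                   decay_id = as.numeric(decay_id)[ord],
                   kind = as.integer(kind)[ord],
                   block_id = as.integer(block_id)[ord],
                   energy_kev = numeric(length(time_ps)))
  petrand:::new_singles_stream(
    ev, duration_ps = duration_ps, activity_bq = activity_bq,
    isotope = isotope_model("test", eps1, eps2, eps_gamma),
    detector = detector_model(n_blocks = 10L))
}

# Random small stream with clustered (paired) singles for property tests.
random_test_stream <- function(n_decays, span_ps = 5e4, p_pair = 0.3,
                               p_gamma = 0) {
  t0 <- sort(floor(runif(n_decays, 0, span_ps)))
  id <- seq_len(n_decays)
  times <- t0; ids <- id; kinds <- rep(0L, n_decays)
  paired <- runif(n_decays) < p_pair
  times <- c(times, t0[paired] + round(rnorm(sum(paired), 0, 300)))
  ids <- c(ids, id[paired]); kinds <- c(kinds, rep(0L, sum(paired)))
  g <- runif(n_decays) < p_gamma
  times <- c(times, t0[g] + round(rnorm(sum(g), 0, 300)))
  ids <- c(ids, id[g]); kinds <- c(kinds, rep(1L, sum(g)))
  times <- pmax(times, 0)
  make_stream(times, ids, kinds, duration_ps = span_ps + 1e7)
}
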