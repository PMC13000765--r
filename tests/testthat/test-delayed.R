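tau <- 2600
delta <- 5e6
t0 <- 1e6

test_that("an isolated opener/partner pair is counted by every family", {
  s <- make_stream(c(t0, t0 + delta + 1000), decay_id = c(1, 2))
  for (fam in c("vouter", "vinner", "vbetween", "vno")) {
    for (v in c("d1", "d2", "d3")) {
      dc <- count_delayed_doubles(s, tau, delayed_scheme(fam, v, delta))
      expect_equal(dc$count, 1, info = paste(fam, v))
    }
  }
})

test_that("delayed-doubles vetoes reject exactly their own intervals", {
  # extra single near the opener: both outer intervals around i contain it
  s_open <- make_stream(c(t0, t0 + 500, t0 + delta + 1000))
  for (v in c("d1", "d2", "d3"))
    expect_equal(count_delayed_doubles(
      s_open, tau, delayed_scheme("vouter", v, delta))$count, 0, info = v)

  # extra single near the partner only (inside the outer interval around k,
  # outside the inner one): d1 rejects, d2/d3 (opener-side only) count
  s_part <- make_stream(c(t0, t0 + delta + 1000, t0 + delta + 3000))
  cnt <- function(fam, v) count_delayed_doubles(
    s_part, tau, delayed_scheme(fam, v, delta))$count
  expect_equal(cnt("vouter", "d1"), 0)
  expect_equal(cnt("vouter", "d2"), 1)
  expect_equal(cnt("vouter", "d3"), 1)
  expect_equal(cnt("vinner", "d1"), 1)  # [t_k - tau, t_k + tau - u] misses it
  expect_equal(cnt("vbetween", "d1"), 1)

  # between-family: doubling the partner-side gap interval catches a single
  # that the plain interval misses
  s_btw <- make_stream(c(t0, t0 + delta - 500, t0 + delta + 1000))
  expect_equal(cnt2 <- count_delayed_doubles(
    s_btw, tau, delayed_scheme("vbetween", "d2", delta))$count, 1)
  expect_equal(count_delayed_doubles(
    s_btw, tau, delayed_scheme("vbetween", "d3", delta))$count, 0)
})

test_that("overlapping prompt and delayed windows are rejected", {
  s <- make_stream(c(t0, t0 + 1000))
  expect_error(count_delayed_doubles(s, tau, delayed_scheme("vouter", "d1",
                                                            delta_ps = 2000)),
               "delta > tau")
})

test_that("the ratio estimator combines the three window schemes", {
  mk <- function(rate, v) petrand:::.new_delayed_counts(
    rate, 1e12, delayed_scheme("vouter", v, delta))
  est <- estimate_randoms_doubles(mk(100, "d1"), mk(300, "d2"), mk(300, "d3"))
  expect_equal(est$estimate_rate, 100)
  expect_error(
    estimate_randoms_doubles(mk(100, "d1"), mk(300, "d2"), mk(0, "d3")),
    "zero counts")
  # vno: the veto-free delayed count is the estimate
  est_no <- estimate_randoms_doubles(petrand:::.new_delayed_counts(
    42, 1e12, delayed_scheme("vno", "d1", delta)))
  expect_equal(est_no$estimate_rate, 42)
})

test_that("a true double plus a delayed single forms one counted config", {
  # case III geometry: odd single after the (virtual) double
  s <- make_stream(c(t0, t0 + 200, t0 + delta + 1000), decay_id = c(1, 1, 2))
  for (fam in c("vouter", "vno")) {
    dc <- count_delayed_triples(s, tau, delayed_scheme(fam, "t_1delay", delta))
    expect_equal(dc$count, 1, info = fam)
  }
})

test_that("the k window is exactly the 2*tau - dt union interval", {
  u <- 200
  edges_in <- c(t0 + delta - (tau - u), t0 + delta + tau)       # closed edges
  edges_out <- c(t0 + delta - (tau - u) - 1, t0 + delta + tau + 1)
  for (tk in edges_in) {
    s <- make_stream(c(t0, t0 + u, tk), decay_id = c(1, 1, 2))
    expect_equal(count_delayed_triples(
      s, tau, delayed_scheme("vno", "t_1delay", delta))$count, 1,
      info = paste("edge", tk))
  }
  for (tk in edges_out) {
    s <- make_stream(c(t0, t0 + u, tk), decay_id = c(1, 1, 2))
    expect_equal(count_delayed_triples(
      s, tau, delayed_scheme("vno", "t_1delay", delta))$count, 0,
      info = paste("outside", tk))
  }
})

test_that("two-delay configurations require both delayed gaps", {
  # j delayed by delta from i, k anchored at 2*delta
  s <- make_stream(c(t0, t0 + delta + 300, t0 + 2 * delta + 500))
  dc <- count_delayed_triples(s, tau, delayed_scheme("vouter", "t_2delays", delta))
  expect_equal(dc$count, 1)
  # an empty stream counts nothing
  s0 <- make_stream(numeric(0), duration_ps = 1e9)
  expect_equal(count_delayed_triples(
    s0, tau, delayed_scheme("vouter", "t_2delays", delta))$count, 0)
})

test_that("subtraction and scale estimators follow their definitions", {
  mk <- function(rate, v) petrand:::.new_delayed_counts(
    rate, 1e12, delayed_scheme("vouter", v, delta))
  est <- estimate_two_decay_triples_beta(mk(500, "t_1delay"),
                                         mk(60, "t_2delays"))
  expect_equal(est$estimate_rate, 440)
  expect_warning(
    est0 <- estimate_two_decay_triples_beta(mk(10, "t_1delay"),
                                            mk(60, "t_2delays")),
    "clipped")
  expect_equal(est0$estimate_rate, 0)

  # halving rule in the no-veto limit scale1 = scale3
  e3 <- estimate_three_decay_triples(mk(80, "t_scale1"), mk(80, "t_scale3"))
  expect_equal(e3$estimate_rate, 40)
  expect_error(estimate_three_decay_triples(mk(80, "t_scale1"),
                                            mk(0, "t_scale3")), "zero")

  # beta+-gamma combination vanishes when all components are equal
  eq <- estimate_two_decay_triples_betagamma(
    mk(5, "t_1delay_dveto"), mk(5, "t_2delays_dveto"),
    mk(5, "t_scale1"), mk(5, "t_scale2"), mk(5, "t_scale3"))
  expect_equal(eq$estimate_rate, 0)
})

test_that("scale schemes coincide for an isolated configuration", {
  s <- make_stream(c(t0, t0 + delta + 100, t0 + 2 * delta + 200))
  cnts <- vapply(c("t_scale1", "t_scale2", "t_scale3"), function(v)
    count_delayed_triples(s, tau, delayed_scheme("vouter", v, delta))$count,
    numeric(1))
  expect_true(all(cnts == 1))
})

test_that("scale-scheme veto attenuation matches the Poisson prediction", {
  # homogeneous singles at rate S: log(scale1/scale3) ~ 2 * S * <L>
  iso <- isotope_model("poisson", eps1 = 1, eps2 = 0)
  s <- simulate_stream(2e7, 0.1, iso, detector_model(), seed = 31)
  st <- delayed_triples_suite(s, tau, delta, "beta")
  S <- n_singles(s) / 0.1
  Lbar <- (2 * tau + 2 / 3 * tau) * 1e-12       # E[max(u,w)] = 2*tau/3
  pred <- 2 * S * Lbar
  obs <- log(st$scale1$count / st$scale3$count)
  se <- sqrt(1 / st$scale3$count + 1 / st$scale1$count)
  expect_lt(abs(obs - pred), 3 * se + 0.01)
})

test_that("fully uncorrelated delayed triples scale as activity cubed", {
  iso <- isotope_model("pairs", eps1 = 0, eps2 = 1)
  acts <- c(3e7, 6e7, 9e7)
  cnt <- vapply(seq_along(acts), function(i) {
    s <- simulate_stream(acts[i], 0.02, iso, detector_model(), seed = 40 + i)
    count_delayed_triples(s, tau,
                          delayed_scheme("vno", "t_2delays", delta))$count
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(cnt) ~ log(acts)))[[2L]]
  expect_lt(abs(slope - 3), 0.1)
})

test_that("without paired singles the two-decay triple estimate is zero", {
  # no paired singles -> no correlated doubles -> the one-delay and
  # two-delay counts estimate the same uncorrelated population; their
  # difference must be statistically zero (configs share singles, so the
  # spread is taken empirically over independent streams)
  iso <- isotope_model("unpaired", eps1 = 0.5, eps2 = 0)
  diffs <- vapply(1:6, function(sd) {
    s <- simulate_stream(4e7, 0.03, iso, detector_model(), seed = 100 + sd)
    st <- delayed_triples_suite(s, tau, delta, "beta")
    st$one_delay$count - st$two_delays$count
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)))
  # and the one-delay count dominates the two-delay count on real streams
  s2 <- simulate_stream(4e7, 0.02, isotope_presets()$cs_ideal_c11,
                        detector_model(), seed = 34)
  st2 <- delayed_triples_suite(s2, tau, delta, "beta")
  expect_gt(st2$one_delay$count, st2$two_delays$count)
})

test_that("delayed counts are invariant under the choice of delay", {
  s <- simulate_stream(4e7, 0.02, isotope_presets()$cs_ideal_c11,
                       detector_model(), seed = 35)
  c5 <- count_delayed_doubles(s, tau, delayed_scheme("vouter", "d1", 5e6))
  c10 <- count_delayed_doubles(s, tau, delayed_scheme("vouter", "d1", 1e7))
  expect_lt(abs(c5$count - c10$count) / sqrt(c5$count + c10$count), 4)
})

test_that("ground-truth random rates equal the brute-force classifier", {
  set.seed(36)
  for (rep in 1:4) {
    s <- random_test_stream(60, span_ps = 4e4, p_pair = 0.4, p_gamma = 0.3)
    for (sc in c("vouter", "vno")) {
      cfg <- window_config(tau, sc, 3)
      expect_equal(ground_truth_randoms(s, cfg, "doubles")$count,
                   oracle_ground_truth(s, tau, sc, "doubles"))
      expect_equal(ground_truth_randoms(s, cfg, "triples_2decay")$count,
                   oracle_ground_truth(s, tau, sc, "triples_2decay"))
      expect_equal(ground_truth_randoms(s, cfg, "triples_3decay")$count,
                   oracle_ground_truth(s, tau, sc, "triples_3decay"))
    }
  }
  s1 <- make_stream(c(0, 300) + 1e4, decay_id = c(1, 1))
  expect_equal(ground_truth_randoms(s1, window_config(tau, "vno"),
                                    "doubles")$count, 0)
})

test_that("true-double rates decay with the outer veto exponential", {
  iso <- isotope_presets()$cs_ideal_c11
  acts <- c(4e7, 8e7)
  r <- vapply(seq_along(acts), function(i) {
    s <- simulate_stream(acts[i], 0.05, iso, detector_model(), seed = 50 + i)
    d <- find_prompt_doubles(s, window_config(tau, "vouter"))
    sum(classify_coincidences(d, s)$is_true) / 0.05
  }, numeric(1))
  slope_obs <- log(r[1] / acts[1] * acts[2] / r[2]) / (acts[2] - acts[1])
  dtt <- sqrt(2 / pi) * 500 / 2.3548
  slope_exp <- iso$eps_ge1 * (2 * tau + dtt) * 1e-12
  expect_lt(abs(slope_obs - slope_exp) / slope_exp, 0.05)
})
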