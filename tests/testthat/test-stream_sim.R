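test_that("decay simulation is Poisson, uniform and reproducible", {
  expect_error(simulate_decays(-1, 100), "positive")
  expect_error(simulate_decays(100, 0), "positive")

  # determinism
  a <- simulate_decays(1e8, 1e8, seed = 3)
  b <- simulate_decays(1e8, 1e8, seed = 3)
  expect_identical(a, b)
  expect_false(is.unsorted(a))

  # mean count ~ A*T: 1e8 Bq * 1e-4 s = 1e4 expected
  n <- vapply(1:20, function(s) length(simulate_decays(1e8, 1e8, seed = s)),
              numeric(1))
  expect_lt(abs(mean(n) - 1e4), 3 * sqrt(1e4 / 20))

  # vanishing mean: 0.001 Bq for 1 ps
  expect_equal(length(simulate_decays(0.001, 1, seed = 1)), 0L)
})

test_that("per-decay detection outcomes are multinomial at the set efficiencies", {
  iso <- isotope_model("PS", eps1 = 0.22, eps2 = 0.23)
  det <- detector_model()
  n <- 2e5
  set.seed(10)
  dt <- sort(floor(runif(n, 0, 1e12)))
  s <- emit_singles(dt, iso, det, seed = 11, activity_bq = 1, duration_ps = 1e12)

  ann <- s$events[s$events$kind == 0L, ]
  per_decay <- tabulate(ann$decay_id, nbins = n)
  expect_true(all(per_decay <= 2))
  n2 <- sum(per_decay == 2); n1 <- sum(per_decay == 1); n0 <- sum(per_decay == 0)
  sd2 <- sqrt(n * 0.23 * 0.77); sd1 <- sqrt(n * 0.22 * 0.78)
  sd0 <- sqrt(n * 0.55 * 0.45)
  expect_lt(abs(n2 - 0.23 * n), 4 * sd2)
  expect_lt(abs(n1 - 0.22 * n), 4 * sd1)
  expect_lt(abs(n0 - 0.55 * n), 4 * sd0)
  # detection of at least one annihilation photon: eps_ge1 = 0.45
  expect_lt(abs((n1 + n2) / n - 0.45), 4 * sqrt(0.45 * 0.55 / n))

  # ground-truth bookkeeping: each decay contributes at most 3 events
  expect_true(all(tabulate(s$events$decay_id, nbins = n) <= 3))
})

test_that("zero efficiency yields an empty stream, gammas only for b+g", {
  iso0 <- isotope_model("null", 0, 0)
  s <- emit_singles(c(0, 10, 20), iso0, detector_model(), seed = 1)
  expect_equal(n_singles(s), 0L)

  iso <- isotope_model("na22", eps1 = 0.3, eps2 = 0.2, eps_gamma = 0.5)
  s2 <- simulate_stream(1e7, 1e-4, iso, detector_model(), seed = 2)
  expect_true(any(s2$events$kind == 1L))
  s3 <- simulate_stream(1e7, 1e-4, isotope_model("c11", 0.3, 0.2),
                        detector_model(), seed = 2)
  expect_true(all(s3$events$kind == 0L))
})

test_that("pair time differences have the configured CTR FWHM", {
  iso <- isotope_model("pairs", eps1 = 0, eps2 = 1)
  det <- detector_model(ctr_fwhm_ps = 500)
  n <- 1e5
  set.seed(4)
  dt <- sort(floor(runif(n, 0, 1e12)))  # well separated decays
  s <- emit_singles(dt, iso, det, seed = 5)
  diffs <- tapply(s$events$time_ps, s$events$decay_id,
                  function(x) diff(range(x)))
  # |N(0, sigma_pair)| with sigma_pair = 500/2.3548; empirical FWHM from sd
  sd_obs <- sqrt(mean(diffs^2))          # diffs are |differences|
  fwhm_obs <- 2 * sqrt(2 * log(2)) * sd_obs
  expect_lt(abs(fwhm_obs - 500) / 500, 0.05)
})

test_that("stationarity: singles rate equal in both acquisition halves", {
  s <- simulate_stream(5e7, 0.002, isotope_presets()$cs_ideal_c11,
                       detector_model(), seed = 6)
  half <- s$duration_ps / 2
  n1 <- sum(s$events$time_ps < half)
  n2 <- n_singles(s) - n1
  expect_lt(abs(n1 - n2) / sqrt(n1 + n2), 4)
})

test_that("non-paralyzable dead time removes per-block close followers", {
  s <- make_stream(c(0, 5000) + 100, block_id = c(0L, 0L))
  out <- apply_dead_time(s, 10e3)
  expect_equal(n_singles(out), 1L)

  s2 <- make_stream(c(0, 5000) + 100, block_id = c(0L, 1L))
  expect_equal(n_singles(apply_dead_time(s2, 10e3)), 2L)

  # non-paralyzable chain: B killed by A, C survives (beyond d of A)
  s3 <- make_stream(c(0, 6000, 12000) + 100, block_id = c(0L, 0L, 0L))
  out3 <- apply_dead_time(s3, 10e3)
  expect_equal(out3$events$time_ps, c(100, 12100))

  expect_error(apply_dead_time(s, -5), ">= 0")
})

test_that("dead-time loss follows the non-paralyzable closed form", {
  # Poisson singles at rate S with dead time d: accepted ~ S/(1+S*d)
  iso <- isotope_model("single", eps1 = 1, eps2 = 0)
  det <- detector_model(n_blocks = 2L, ctr_fwhm_ps = 0)
  s <- simulate_stream(2e7, 0.005, iso, det, seed = 8)  # S*d = 0.1 per block
  d <- 10e3  # 10 ns
  out <- apply_dead_time(s, d)
  S_blk <- n_singles(s) / 2 / 0.005       # per-block input rate
  expect_gt(n_singles(s), 9e4)
  exp_keep <- 1 / (1 + S_blk * d * 1e-12)
  expect_lt(abs(n_singles(out) / n_singles(s) - exp_keep) / exp_keep, 0.01)
})

test_that("list-mode round trips are exact in both layouts", {
  s <- simulate_stream(2e7, 1e-4, isotope_presets()$cs_ideal_na22,
                       detector_model(energy_resolution_frac = 0.14),
                       seed = 9)
  for (fmt in c("text", "binary")) {
    p <- tempfile(fileext = ".lm")
    write_listmode(s, p, format = fmt)
    r <- read_listmode(p)
    expect_equal(r$events, s$events, info = fmt)
    expect_equal(r$duration_ps, s$duration_ps)
    expect_equal(r$activity_bq, s$activity_bq)
    expect_equal(r$isotope$eps1, s$isotope$eps1)
    expect_equal(r$seed, s$seed)
    unlink(p)
  }
})

test_that("list-mode reader rejects malformed and unsorted files", {
  s <- make_stream(c(100, 200, 300))
  p <- tempfile()
  write_listmode(s, p)
  lines <- readLines(p)
  # swap two records -> decreasing timestamps
  body <- which(!grepl("^#", lines))
  bad <- lines; bad[body[1:2]] <- bad[body[2:1]]
  writeLines(bad, p)
  expect_error(read_listmode(p), "not sorted")

  bad2 <- lines; bad2[body[2]] <- "oops\t0"
  writeLines(bad2, p)
  expect_error(read_listmode(p), "malformed")
  unlink(p)

  # empty stream round trip
  s0 <- make_stream(numeric(0), duration_ps = 1e6)
  p0 <- tempfile()
  write_listmode(s0, p0)
  expect_equal(n_singles(read_listmode(p0)), 0L)
  unlink(p0)
})

test_that("identical seeds give identical streams", {
  iso <- isotope_presets()$cs_ideal_c11
  s1 <- simulate_stream(1e8, 1e-4, iso, detector_model(), seed = 12)
  s2 <- simulate_stream(1e8, 1e-4, iso, detector_model(), seed = 12)
  expect_identical(s1$events, s2$events)
})
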