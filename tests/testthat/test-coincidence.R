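tau <- 2600  # 2.6 ns

test_that("three equidistant singles reproduce the per-scheme double counts", {
  t <- c(0, 1000, 2000) + 5e4  # isolated group, 1 ns apart
  expect_equal(nrow(find_prompt_doubles(t, window_config(tau, "vno"))), 3L)
  expect_equal(nrow(find_prompt_doubles(t, window_config(tau, "vbetween"))), 2L)
  # t3 - t1 = 2.0 ns <= tau violates both inner guards
  expect_equal(nrow(find_prompt_doubles(t, window_config(tau, "vinner"))), 0L)
  # middle single vetoes both outer pairs
  expect_equal(nrow(find_prompt_doubles(t, window_config(tau, "vouter"))), 0L)
})

test_that("an isolated pair is one double under every scheme", {
  t <- c(0, 1000) + 5e4
  for (sc in c("vno", "vbetween", "vinner", "vouter"))
    expect_equal(nrow(find_prompt_doubles(t, window_config(tau, sc))), 1L,
                 info = sc)
})

test_that("the outer scheme recovers the triple that its double stage vetoes", {
  t <- c(0, 1000, 2000) + 5e4
  cfg <- window_config(tau, "vouter", max_order = 3L)
  tr <- find_prompt_multiples(t, cfg, 3L)
  expect_equal(nrow(tr$members), 1L)
  expect_equal(tr$span_ps, 2000)
  # spread the singles beyond the window: no triple, and still no doubles
  t2 <- c(0, 2000, 4000) + 5e4
  expect_equal(nrow(find_prompt_multiples(t2, cfg, 3L)$members), 0L)
  expect_equal(nrow(find_prompt_doubles(t2, window_config(tau, "vouter"))), 0L)
  # an isolated pair yields no multiples of order >= 3
  expect_equal(nrow(find_prompt_multiples(c(0, 1000) + 5e4, cfg, 3L)$members), 0L)
})

test_that("single-pass identification equals the brute-force oracle", {
  set.seed(7)
  for (rep in 1:12) {
    s <- random_test_stream(n_decays = sample(20:90, 1),
                            span_ps = sample(c(2e4, 5e4, 2e5), 1))
    t <- s$events$time_ps
    for (sc in c("vno", "vbetween", "vinner", "vouter")) {
      d <- find_prompt_doubles(t, window_config(tau, sc))
      o <- oracle_doubles(t, tau, sc)
      expect_equal(unname(cbind(d$i, d$j)), o, info = paste(sc, "doubles"))
      for (m in 3:4) {
        mm <- find_prompt_multiples(t, window_config(tau, sc, m), m)$members
        om <- oracle_multiples(t, tau, m, sc)
        expect_equal(unname(mm)[order(mm[, 1], mm[, 2]), , drop = FALSE],
                     om[order(om[, 1], om[, 2]), , drop = FALSE],
                     info = paste(sc, "order", m))
      }
    }
  }
})

test_that("accepted doubles are ordered vouter <= vinner <= vbetween <= vno", {
  set.seed(11)
  for (rep in 1:6) {
    s <- random_test_stream(n_decays = 150, span_ps = 1e5)
    cnt <- vapply(c("vouter", "vinner", "vbetween", "vno"), function(sc)
      nrow(find_prompt_doubles(s, window_config(tau, sc))), numeric(1))
    expect_true(all(diff(cnt) >= 0))
  }
})

test_that("classification follows the decay IDs, including triple positions", {
  s <- make_stream(c(0, 100, 200) + 5e4, decay_id = c(7, 7, 7))
  lab <- classify_coincidences(matrix(1:3, 1), s)
  expect_true(lab$is_true)
  expect_equal(lab$n_decays, 1L)

  s <- make_stream(c(0, 100, 200) + 5e4, decay_id = c(9, 7, 7))
  lab <- classify_coincidences(matrix(1:3, 1), s)
  expect_equal(lab$n_decays, 2L)
  expect_equal(lab$odd_position, "I")

  s <- make_stream(c(0, 100, 200) + 5e4, decay_id = c(7, 9, 7))
  expect_equal(classify_coincidences(matrix(1:3, 1), s)$odd_position, "II")
  s <- make_stream(c(0, 100, 200) + 5e4, decay_id = c(7, 7, 9))
  expect_equal(classify_coincidences(matrix(1:3, 1), s)$odd_position, "III")

  s <- make_stream(c(0, 100, 200) + 5e4, decay_id = c(7, 9, 8))
  lab <- classify_coincidences(matrix(1:3, 1), s)
  expect_equal(lab$n_decays, 3L)
  expect_true(is.na(lab$odd_position))

  s <- make_stream(c(0, 100), decay_id = c(-1, 2))
  expect_error(classify_coincidences(matrix(1:2, 1), s), "ground truth")
})

test_that("paired/unpaired flags match the annihilation-partner definition", {
  s <- make_stream(c(0, 120, 5000, 5100) + 1e4,
                   decay_id = c(1, 1, 2, 3), kind = c(0, 0, 0, 1))
  expect_equal(flag_paired_singles(s),
               c("paired", "paired", "unpaired", "gamma"))
  # a gamma does not make its decay's lone annihilation photon "paired"
  s2 <- make_stream(c(0, 50) + 1e4, decay_id = c(4, 4), kind = c(0, 1))
  expect_equal(flag_paired_singles(s2), c("unpaired", "gamma"))
  s3 <- make_stream(c(0, 100), decay_id = c(-1, 2))
  expect_error(flag_paired_singles(s3), "ground truth")
})

test_that("multiples histogram is deterministic and vanishes with efficiency", {
  iso0 <- isotope_model("null", eps1 = 0, eps2 = 0)
  s0 <- simulate_stream(1e6, 1e-4, iso0, detector_model(), seed = 1)
  h0 <- multiples_histogram(s0, window_config(tau, "vouter"))
  expect_true(all(h0$count == 0))

  s <- simulate_stream(5e7, 2e-3, isotope_presets()$cs_ideal_c11,
                       detector_model(), seed = 5)
  cfg <- window_config(tau, "vouter")
  h1 <- multiples_histogram(s, cfg, orders = 2:6)
  h2 <- multiples_histogram(s, cfg, orders = 2:6)
  expect_identical(h1, h2)
  expect_true(all(diff(h1$count) <= 0))  # non-increasing in order
})

test_that("the trues fraction of accepted prompts falls with activity", {
  iso <- isotope_presets()$cs_ideal_c11
  frac <- vapply(c(2e7, 8e7), function(A) {
    s <- simulate_stream(A, 0.01, iso, detector_model(), seed = 61)
    d <- find_prompt_doubles(s, window_config(2600, "vouter"))
    mean(classify_coincidences(d, s)$is_true)
  }, numeric(1))
  expect_gt(frac[1], frac[2])
})

test_that("composition filter keeps two annihilation photons plus one gamma", {
  s <- make_stream(c(0, 100, 200, 3000, 3100, 3200) + 5e4,
                   decay_id = c(1, 2, 3, 4, 5, 6),
                   kind = c(0, 1, 0, 0, 0, 0))
  cfg <- window_config(tau, "vbetween", 3)
  all3 <- find_prompt_multiples(s, cfg, 3L)
  flt <- find_prompt_multiples(s, cfg, 3L, composition = "two_annih_one_gamma")
  expect_equal(nrow(all3$members), 2L)
  expect_equal(nrow(flt$members), 1L)
  expect_equal(flt$members[1, ], 1:3)
})
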