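test_that("the two-phase model evaluates its closed form", {
  expect_equal(two_phase_model(70, -42, -28, 1, 0.05, 0), 0)
  expect_equal(two_phase_model(70, -42, -28, 1, 0.05, 1000), 70,
               tolerance = 1e-6)
  # direct arithmetic: 70 - 42 e^-10 - 28 e^-0.5
  expect_equal(two_phase_model(70, -42, -28, 1, 0.05, 10),
               70 - 42 * exp(-10) - 28 * exp(-0.5), tolerance = 1e-12)
  expect_equal(round(two_phase_model(70, -42, -28, 1, 0.05, 10), 2), 53.02)
  expect_error(two_phase_model(70, -42, -28, 1, 0.05, -1), "negative")
  expect_error(two_phase_model(70, -42, -28, 0, 0.05, 1), "positive")
})

test_that("noiseless two-phase data is recovered essentially exactly", {
  tc <- simulate_timecourse(A = 70, B = -42, C = -28, k1 = 1, k2 = 0.05,
                            noise_sd = 0)
  f <- fit_two_phase(tc)
  expect_lt(abs(f$A - 70) / 70, 1e-3)
  expect_lt(abs(f$B + 42) / 42, 1e-3)
  expect_lt(abs(f$C + 28) / 28, 1e-3)
  expect_lt(abs(f$k1 - 1), 1e-3)
  expect_lt(abs(f$k2 - 0.05) / 0.05, 1e-3)
  expect_gte(f$r2, 1 - 1e-9)
  expect_true(f$converged)
  expect_gte(f$n_starts_used, 25)
})

test_that("noisy fits agree with an independent grid + polish optimiser", {
  tc <- simulate_timecourse(A = 70, B = -42, C = -28, k1 = 1, k2 = 0.05,
                            noise_sd = 2, rng_seed = 11)
  f <- fit_two_phase(tc)
  expect_lte(abs(f$A - 70), 2)
  orc <- oracle_two_phase(tc$time_min, tc$fc_pct)
  # same optimum: equal plateau and no worse residual sum
  expect_equal(f$A, orc$A, tolerance = 0.05)
  expect_lte(f$ss_res, orc$sse + 1e-6)
})

test_that("rates come out ordered and flat data degenerates gracefully", {
  tc <- simulate_timecourse(A = 60, B = -30, C = -30, k1 = 2, k2 = 0.02,
                            noise_sd = 1, rng_seed = 3)
  f <- fit_two_phase(tc)
  expect_gte(f$k1, f$k2)
  flat <- tibble::tibble(time_min = c(0, 1, 2, 5, 10, 20),
                         fc_pct = rep(0, 6))
  f0 <- fit_two_phase(flat)
  expect_lt(abs(f0$A), 0.5)
  expect_error(fit_two_phase(flat[1:5, ]), "6 time points")
})

test_that("plateau recovery is unbiased across plateau levels", {
  for (A in c(40, 70, 95)) {
    est <- vapply(1:100, function(s) {
      tc <- simulate_timecourse(A = A, B = -0.6 * A, C = -0.4 * A,
                                k1 = 1, k2 = 0.05, noise_sd = 2,
                                rng_seed = 7000 + s)
      fit_two_phase(tc)$A
    }, 1)
    expect_lte(abs(mean(est) - A), 1)
    expect_lte(sd(est), 2)
  }
})

test_that("noiseless hyperbolic data is recovered exactly", {
  t <- c(0, 1, 2, 5, 10, 20, 40, 80, 160)
  tc <- tibble::tibble(time_min = t, fc_pct = 80 * t / (5 + t))
  h <- fit_hyperbolic(tc)
  expect_equal(h$Amax, 80, tolerance = 1e-6)
  expect_equal(h$K, 5, tolerance = 1e-6)
  expect_gte(h$r2, 1 - 1e-12)
})

test_that("the hyperbolic model cannot absorb a pre-cleaved fraction at t = 0", {
  t <- c(0, 1, 2, 5, 10, 20, 40, 80)
  tc <- tibble::tibble(time_min = t,
                       fc_pct = pmin(100, 50 + 30 * (1 - exp(-0.2 * t))))
  cmp <- compare_models(tc)
  expect_equal(cmp$winner, "two_phase")
  expect_lt(cmp$hyperbolic$r2, cmp$two_phase$r2)
})

test_that("two-phase data with separated rates beats the hyperbolic fit", {
  tc <- simulate_timecourse(A = 70, B = -42, C = -28, k1 = 1, k2 = 0.05,
                            noise_sd = 2, rng_seed = 5)
  cmp <- compare_models(tc)
  expect_gte(cmp$two_phase$r2, cmp$hyperbolic$r2)
  expect_equal(cmp$winner, "two_phase")
})

test_that("a perfect tie is reported as ambiguous in favour of two-phase", {
  flat <- tibble::tibble(time_min = c(0, 1, 2, 5, 10, 20),
                         fc_pct = rep(0, 6))
  cmp <- compare_models(flat)
  expect_true(cmp$ambiguous)
  expect_equal(cmp$winner, "two_phase")
})

test_that("cleavage fractions follow U-count molar normalisation", {
  lane <- tibble::tibble(band = c("uncleaved", "frag3p", "frag5p"),
                         intensity = c(100, 200, 50),
                         u_count = c(30L, 20L, 10L))
  res <- cleavage_fraction(lane)
  # molar amounts 10/3, 10, 5 -> 100 * 10 / (10 + 10/3) = 75
  expect_equal(res$cleavage_pct, 75)
  expect_equal(res$cleavage_pct_5p, 100 * 5 / (5 + 10 / 3))
  zero3 <- lane; zero3$intensity[2] <- 0
  expect_equal(cleavage_fraction(zero3)$cleavage_pct, 0)
  zerou <- lane; zerou$intensity[1] <- 0
  expect_equal(cleavage_fraction(zerou)$cleavage_pct, 100)
  allz <- lane; allz$intensity <- 0
  expect_error(cleavage_fraction(allz), "zero")
})

test_that("cleavage fractions are invariant to uniform intensity rescaling", {
  withr::with_seed(77, {
    for (i in 1:20) {
      lane <- tibble::tibble(band = c("uncleaved", "frag3p", "frag5p"),
                             intensity = runif(3, 1, 1000),
                             u_count = sample(5:40, 3))
      a <- cleavage_fraction(lane)
      lane$intensity <- lane$intensity * runif(1, 0.01, 100)
      b <- cleavage_fraction(lane)
      expect_equal(a$cleavage_pct, b$cleavage_pct, tolerance = 1e-12)
    }
  })
})

test_that("tidy, glance and the table writer expose the fit results", {
  tc <- simulate_timecourse(A = 70, B = -42, C = -28, k1 = 1, k2 = 0.05,
                            noise_sd = 0)
  f <- fit_two_phase(tc)
  td <- tidy(f)
  expect_equal(td$term, c("A", "B", "C", "k1", "k2"))
  expect_equal(td$estimate[1], 70, tolerance = 1e-4)
  expect_equal(glance(f)$r.squared, 1, tolerance = 1e-9)
  # multi-series table in the published layout
  tcs <- dplyr::bind_rows(lapply(c(10, 1, 0.1), function(mg)
    simulate_timecourse(A = 70, B = -42, C = -28, k1 = 1, k2 = 0.05,
                        noise_sd = 1, rng_seed = round(mg * 10),
                        mg_mM = mg, replicate_id = "Rz1")))
  fits <- fit_kinetics_table(tcs)
  expect_equal(nrow(fits), 3L)
  expect_true(all(fits$winner == "two_phase"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fit_tsv(fits, path)
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(wide), 1L)
  expect_true(all(c("r2_two_phase_mg10", "plateau_pct_mg0.1") %in%
                    names(wide)))
})
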