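rev_times <- c(10, 30, 60, 120, 300, 600, 1200, 1800)

test_that("CheY6-P does not phosphorylate CheA2 in the reverse assay", {
  p <- che_parameters()
  des <- assay_design("reverse_transfer", donor0 = 30, rr0 = 10, a2_0 = 5,
                      times = rev_times, rr_name = "CheY6")
  tc <- simulate_assay(des, list(k_f = p$k5, k_r = p$k5r, k_d = 5e4,
                                 k_auto = p$k12))
  expect_true(all(abs(tc$value[tc$species == "a2_p"]) < 1e-12))
  # label still flows from the P1 donor into the RR
  expect_gt(max(tc$value[tc$species == "rr_p"]), 0)
})

test_that("CheB2-P phosphorylates CheA2 in the reverse assay", {
  p <- che_parameters()
  des <- assay_design("reverse_transfer", donor0 = 30, rr0 = 10, a2_0 = 5,
                      times = rev_times, rr_name = "CheB2")
  tc <- simulate_assay(des, list(k_f = p$k7, k_r = p$k7r, k_d = 5e4,
                                 k_auto = p$k14))
  a2p <- tc$value[tc$species == "a2_p"]
  expect_true(all(a2p > 0))
  expect_gt(a2p[2], a2p[1])  # rising from the start
})

test_that("a buffer control without RR shows no transfer", {
  des <- assay_design("reverse_transfer", donor0 = 30, rr0 = 0, a2_0 = 5,
                      times = rev_times)
  tc <- simulate_assay(des, list(k_f = 1e5, k_r = 1e4, k_d = 5e4,
                                 k_auto = 0.01))
  expect_equal(tc$value[tc$species == "donor_p"],
               rep(30, length(rev_times)), tolerance = 1e-10)
  expect_true(all(tc$value[tc$species != "donor_p"] == 0))
  # with donor hydrolysis on, only the donor band decays
  tc2 <- simulate_assay(des, list(k_f = 1e5, k_r = 1e4, k_d = 5e4,
                                  k_auto = 0.01, k_d_hyd = 1e-3))
  dp <- tc2$value[tc2$species == "donor_p"]
  expect_true(all(diff(dp) < 0))
  expect_equal(dp, 30 * exp(-1e-3 * rev_times), tolerance = 1e-8)
})

test_that("label is conserved up to hydrolysis", {
  p <- che_parameters()
  des <- assay_design("reverse_transfer", donor0 = 30, rr0 = 10, a2_0 = 5,
                      times = seq(5, 2000, by = 5))
  # no hydrolysis anywhere: total label constant
  tc <- simulate_assay(des, list(k_f = p$k7, k_r = p$k7r, k_d = 5e4,
                                 k_auto = 0))
  total <- tapply(tc$value, tc$time, sum)
  expect_equal(as.numeric(total), rep(30, length(total)), tolerance = 1e-8)
  # with RR-P autodephosphorylation: total label non-increasing
  tc2 <- simulate_assay(des, list(k_f = p$k7, k_r = p$k7r, k_d = 5e4,
                                  k_auto = p$k14))
  total2 <- tapply(tc2$value, tc2$time, sum)
  expect_true(all(diff(unname(total2)) <= 1e-10))
  expect_true(all(total2 <= 30 + 1e-10))
})

test_that("zero-CV synthetic data equals the deterministic simulation", {
  des <- assay_design("forward_transfer", donor0 = 30, rr0 = 10,
                      times = c(5, 50, 500))
  rates <- list(k_f = 6.15e4, k_r = 3.1e3, k_auto = 0.0133)
  clean <- simulate_assay(des, rates)
  noisy0 <- generate_synthetic_data(des, rates, noise_model(0, seed = 3))
  expect_equal(noisy0$value, clean$value)
})

test_that("synthetic data are reproducible and RNG-isolated", {
  des <- assay_design("forward_transfer", donor0 = 30, rr0 = 10,
                      times = c(5, 50, 500))
  rates <- list(k_f = 6.15e4, k_r = 3.1e3, k_auto = 0.0133)
  set.seed(1234)
  before <- stats::runif(1)
  set.seed(1234)
  a <- generate_synthetic_data(des, rates, noise_model(0.1, seed = 42))
  b <- generate_synthetic_data(des, rates, noise_model(0.1, seed = 42))
  expect_identical(a, b)
  # the caller's RNG stream is untouched by the generator
  expect_identical(stats::runif(1), before)
  # different seeds give different draws
  c <- generate_synthetic_data(des, rates, noise_model(0.1, seed = 43))
  expect_false(identical(a$value, c$value))
})

test_that("the noise model delivers the requested coefficient of variation", {
  des <- assay_design("forward_transfer", donor0 = 30, rr0 = 10,
                      times = c(5, 50, 500))
  rates <- list(k_f = 6.15e4, k_r = 3.1e3, k_auto = 0.0133)
  dat <- generate_synthetic_data(des, rates, noise_model(0.1, seed = 7),
                                 replicates = 100)
  cvs <- tapply(dat$value, paste(dat$time, dat$species), function(v)
    stats::sd(v) / mean(v))
  expect_true(all(abs(cvs - 0.1) < 0.03))
})

test_that("designs are validated", {
  expect_error(assay_design("reverse_transfer", donor0 = 30, rr0 = 10,
                            a2_0 = 0, times = 1:3), "acceptor")
  expect_error(assay_design("forward_transfer", donor0 = -1, rr0 = 10,
                            times = 1:3), ">= 0")
  expect_error(assay_design("forward_transfer", donor0 = 1, rr0 = 1,
                            times = c(3, 2)), "increasing")
  des <- assay_design("forward_transfer", donor0 = 1, rr0 = 1, times = 1:3)
  expect_error(simulate_assay(des, list(k_f = 1)), "missing rate")
  expect_error(noise_model(-0.1), ">= 0")
})
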