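test_that("the crossing locator reproduces first-order decay exactly", {
  k <- 0.137
  tt <- c(0, 10^seq(-3, 3, length.out = 2000))
  ht <- phosrelay:::.first_crossing(tt, exp(-k * tt), 0.5)
  expect_equal(ht, log(2) / k, tolerance = 1e-4)
  # never-crossing series is NA (censoring upstream)
  expect_true(is.na(phosrelay:::.first_crossing(tt, exp(-1e-9 * tt), 0.5)))
  # already below target at t = 0
  expect_equal(phosrelay:::.first_crossing(tt, exp(-k * tt), 1.5), 0)
})

test_that("wild-type shut-off half-times show the phosphate-sink speedup", {
  wt <- decay_half_times(che_parameters())
  ht <- stats::setNames(wt$half_time, wt$species)
  auto <- autodephos_half_times()
  # every RR-P terminates much faster than it autodephosphorylates,
  # except CheY6-P which is already fast and has its own phosphatase
  expect_true(all(ht < auto[names(ht)]))
  expect_true(all(ht[c("CheY3-P", "CheY4-P", "CheB1-P", "CheB2-P")] < 10))
  expect_equal(unname(which.min(ht)), 3)  # CheY6-P terminates fastest
  expect_false(any(wt$censored))
  expect_true(all(wt$steady_level > 0))
})

test_that("deleting the CheY6 sink slows every remaining RR-P >= 10-fold", {
  wt <- decay_half_times(che_parameters())
  d6 <- decay_half_times(che_parameters(), scenario(knockouts = "CheY6"))
  keep <- c("CheY3-P", "CheY4-P", "CheB1-P", "CheB2-P")
  ratio <- stats::setNames(d6$half_time, d6$species)[keep] /
    stats::setNames(wt$half_time, wt$species)[keep]
  expect_true(all(ratio >= 10))
  expect_true(d6$absent[d6$species == "CheY6-P"])
  expect_true(is.na(d6$half_time[d6$species == "CheY6-P"]))
})

test_that("removing the phosphatase raises every fraction and half-time", {
  p <- che_parameters()
  np_scn <- scenario(phosphatase_off = TRUE)
  wt_f <- steady_fractions(p)
  np_f <- steady_fractions(apply_scenario(p, np_scn))
  expect_true(all(np_f$fractions > wt_f$fractions))
  wt_h <- decay_half_times(p)
  np_h <- decay_half_times(p, np_scn)
  expect_true(all(np_h$half_time > wt_h$half_time))
})

test_that("sink ablation restores near-autodephosphorylation kinetics", {
  p <- che_parameters()
  ht <- sink_ablation_half_time(p)
  d6_b1 <- decay_half_times(p, scenario(knockouts = "CheY6"))
  expect_gt(ht, d6_b1$half_time[d6_b1$species == "CheB1-P"])
  expect_gt(ht, 0.8 * log(2) / p$k13)
  # in the near-first-order limit, doubling k13 roughly halves the
  # half-time (the residual rephosphorylation delay does not scale)
  ht2 <- sink_ablation_half_time(che_parameters(k13 = 2 * 1.73e-4))
  expect_lt(abs(ht2 / ht - 0.5), 0.1)
})

test_that("half-times are robust to the output-grid resolution", {
  coarse <- decay_half_times(che_parameters(), n_grid = 800)
  fine <- decay_half_times(che_parameters(), n_grid = 4000)
  expect_equal(coarse$half_time, fine$half_time, tolerance = 0.01)
})

test_that("unreachable half-levels are censored at the horizon", {
  # wild-type decays resolve within a 10-s window ...
  tab <- decay_half_times(che_parameters(), horizon = 10, n_grid = 500)
  expect_false(any(tab$censored))
  # ... but with the sink deleted nothing reaches half-level by then
  d6 <- decay_half_times(che_parameters(), scenario(knockouts = "CheY6"),
                         horizon = 10, n_grid = 500)
  expect_true(all(d6$censored[!d6$absent]))
  expect_true(all(d6$half_time[!d6$absent] == 10))
})

test_that("the protocol refuses a system with no input to shut off", {
  expect_error(decay_half_times(che_parameters(k1 = 0, k2 = 0)),
               "already off")
})
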