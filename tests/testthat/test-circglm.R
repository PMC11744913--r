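fit_quick <- function(data, formula = "side", ...) {
  fit_pn_glm(data, formula, iters = 1500, burnin = 400, chains = 2, ...)
}

test_that("a degenerate single-direction group pins the posterior", {
  d <- data.frame(theta_deg = rep(90, 500), side = "L")
  fit <- fit_quick(d, seed = 1, track_loglik = FALSE)
  expect_equal(fit$summary$mean_deg, 90, tolerance = 0.005)
  expect_lt(fit$summary$hpd_upper - fit$summary$hpd_lower, 1.5)
  expect_true(in_hpd(90, c(lower = fit$summary$hpd_lower,
                           upper = fit$summary$hpd_upper)))
})

test_that("record order does not change the posterior", {
  d <- gen_orientation_samples(side_design(88, 93, n = 2500, seed = 2))
  f1 <- fit_quick(d, seed = 5, track_loglik = FALSE)
  set.seed(3)
  f2 <- fit_quick(d[sample(nrow(d)), ], seed = 5, track_loglik = FALSE)
  expect_equal(f1$summary$mean_deg, f2$summary$mean_deg, tolerance = 0.002)
  expect_equal(f1$summary$hpd_upper - f1$summary$hpd_lower,
               f2$summary$hpd_upper - f2$summary$hpd_lower, tolerance = 0.1)
})

test_that("rotating all angles rotates every posterior mean, widths fixed", {
  d <- gen_orientation_samples(side_design(70, 75, n = 5000, seed = 4))
  delta <- 30
  d2 <- d; d2$theta_deg <- wrap180(d2$theta_deg + delta)
  f1 <- fit_pn_glm(d, "side", iters = 2500, burnin = 500, seed = 6,
                   track_loglik = FALSE)
  f2 <- fit_pn_glm(d2, "side", iters = 2500, burnin = 500, seed = 6,
                   track_loglik = FALSE)
  shift <- circ_diff_deg(f2$summary$mean_deg, f1$summary$mean_deg)
  expect_equal(shift, rep(delta, 2), tolerance = 0.05 / delta)
  w1 <- f1$summary$hpd_upper - f1$summary$hpd_lower
  w2 <- f2$summary$hpd_upper - f2$summary$hpd_lower
  expect_lt(max(abs(w1 - w2)), 0.05)
})

test_that("95% HPD intervals are calibrated across simulated datasets", {
  hits <- 0; total <- 0
  for (s in 1:50) {
    d <- gen_orientation_samples(side_design(88, 92, n = 300, kappa = 8,
                                             seed = 100 + s))
    fit <- fit_pn_glm(d, "side", iters = 1700, burnin = 200, chains = 2,
                      seed = 200 + s, track_loglik = FALSE)
    su <- fit$summary
    hits <- hits + in_hpd(88, c(lower = su$hpd_lower[1], upper = su$hpd_upper[1])) +
      in_hpd(92, c(lower = su$hpd_lower[2], upper = su$hpd_upper[2]))
    total <- total + 2
  }
  expect_gte(hits / total, 0.90)
  expect_lte(hits / total, 0.995)
})

test_that("design-cell validation names the offending cell", {
  d <- data.frame(theta_deg = c(10, 20, 30), side = c("L", "L", "L"),
                  layer = c("L4", "L4", "L4"))
  expect_error(fit_pn_glm(rbind(d, data.frame(theta_deg = 5, side = "R",
                                              layer = "L4")),
                          c("side", "layer")),
               "fewer than 2")
  expect_error(fit_pn_glm(data.frame(theta_deg = 200, side = "L"), "side"),
               "\\[0, 180\\)")
  expect_error(fit_pn_glm(d, c("side", "missing_cov")), "missing_cov")
})

test_that("HPD non-overlap separates distinct groups and not equal ones", {
  d <- gen_orientation_samples(side_design(60, 120, n = 1500, seed = 7))
  f <- fit_quick(d, seed = 8, track_loglik = FALSE)
  expect_false(hpd_overlap(f, "L", "R"))
  d2 <- gen_orientation_samples(side_design(90, 90, n = 1500, seed = 9))
  f2 <- fit_quick(d2, seed = 10, track_loglik = FALSE)
  expect_true(hpd_overlap(f2, "L", "R"))
})

test_that("DIC behaves like a deviance: additive, honest without an effect", {
  d <- gen_orientation_samples(side_design(89, 91, n = 1200, seed = 11))
  f1 <- fit_quick(d, seed = 12)
  fdup <- fit_quick(rbind(d, d), seed = 13)
  expect_equal(dic(fdup) / dic(f1), 2, tolerance = 0.1)
  # no layer effect: the richer model must not look dramatically better
  st <- expand.grid(side = c("L", "R"), layer = c("L2/3", "L4", "L5"))
  st$mu_deg <- 90; st$kappa <- 10; st$n <- 800
  dn <- gen_orientation_samples(pn_group_design(st, seed = 14))
  m1 <- fit_quick(dn, "side", seed = 15)
  m2 <- fit_quick(dn, c("side", "layer"), seed = 16)
  expect_gte(dic(m2), dic(m1) - 10)
  expect_error(dic(fit_quick(d, seed = 17, track_loglik = FALSE)),
               "track_loglik")
})

test_that("stratified bootstrap reproduces the full-data fit", {
  d <- gen_orientation_samples(side_design(89.5, 91, n = 4000, seed = 18))
  bt <- bootstrap_fit(d, "side", n_boot = 3, subsample_per_stratum = 1500,
                      seed = 19, iters = 1200, burnin = 300,
                      track_loglik = FALSE)
  full <- fit_quick(d, seed = 20, track_loglik = FALSE)
  expect_equal(bt$aggregate$mean_deg, full$summary$mean_deg, tolerance = 0.01)
  expect_false(any(bt$flagged_distribution))
  # a single repetition is just one subsample fit
  bt1 <- bootstrap_fit(d, "side", n_boot = 1, subsample_per_stratum = 1500,
                       seed = 19, iters = 1200, burnin = 300,
                       track_loglik = FALSE)
  expect_equal(bt1$aggregate$mean_deg, bt1$repetitions[[1]]$summary$mean_deg)
  expect_error(bootstrap_fit(d, "side", subsample_per_stratum = 10000),
               "smaller")
  expect_equal(formals(bootstrap_fit)$n_boot, 25)
})

test_that("model-1 posterior means recover injected group means", {
  d <- gen_orientation_samples(side_design(90.9, 90.2, n = 4000, seed = 21))
  f <- fit_pn_glm(d, "side", iters = 2500, burnin = 500, seed = 22,
                  track_loglik = FALSE)
  expect_lt(abs(circ_diff_deg(posterior_mean_dir(f, "L"), 90.9)), 0.2)
  expect_lt(abs(circ_diff_deg(posterior_mean_dir(f, "R"), 90.2)), 0.2)
  expect_true(all(f$summary$ess > 100))
})
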