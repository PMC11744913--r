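test_that("structure tensor analytics: single direction, homogeneity,
           isotropy", {
  # intensity varying along exactly one axis: full coherence
  st <- structure_tensor_window(stripe_pattern(24, 90))
  expect_equal(st$coherence, 1)
  expect_equal(st$phi_deg, 90)
  st0 <- structure_tensor_window(stripe_pattern(24, 0))
  expect_equal(st0$coherence, 1)
  expect_equal(st0$phi_deg, 0)
  # constant window: E = 0, C = 0 by convention
  stc <- structure_tensor_window(matrix(3.2, 24, 24))
  expect_identical(stc$energy, 0)
  expect_identical(stc$coherence, 0)
  # equal-eigenvalue window: C = 0
  sti <- structure_tensor_window(isotropic_pattern(25))
  expect_lt(sti$coherence, 1e-12)
  expect_gt(sti$energy, 0)
  expect_error(structure_tensor_window(matrix(1, 2, 2)), "3x3")
})

test_that("stripes at known angles are measured to a degree", {
  for (th in c(0, 30, 45, 120)) {
    st <- structure_tensor_window(stripe_pattern(48, th))
    expect_lt(abs(circ_diff_deg(st$phi_deg, th)), 1.1)
  }
})

test_that("coherence is invariant to affine intensity rescaling", {
  set.seed(2)
  w <- stripe_pattern(24, 30) + matrix(rnorm(24^2, sd = 0.1), 24)
  a <- structure_tensor_window(w)
  b <- structure_tensor_window(5 * w + 11)
  expect_equal(b$coherence, a$coherence, tolerance = 1e-12)
  expect_equal(b$energy, 25 * a$energy, tolerance = 1e-12)
  expect_equal(b$phi_deg, a$phi_deg, tolerance = 1e-9)
})

test_that("half-angle orientation agrees with direct eigendecomposition", {
  set.seed(4)
  for (i in 1:20) {
    g <- matrix(rnorm(100), 50)  # random gradient pairs (gx, gy)
    J <- crossprod(g) / 50
    phi_formula <- (atan2(2 * J[1, 2], J[1, 1] - J[2, 2]) / 2 * 180 / pi)
    ev <- eigen(J)
    v <- ev$vectors[, 1]  # gradient direction = major eigenvector
    phi_eigen <- atan2(v[2], v[1]) * 180 / pi
    expect_lt(abs(circ_diff_deg(phi_formula, phi_eigen)), 1e-6)
  }
})

test_that("rotating a plane by 90 degrees rotates retained orientations", {
  f <- gen_fibre_volume(c(192, 192, 1),
                        data.frame(layer = "L4", mean_deg = 60, sd_deg = 10,
                                   n_fibres = 150),
                        c(0, 0, 8), layer_fractions = c("L4" = 1), seed = 14)
  plane <- f$stack$data[, , 1]
  rot <- t(plane)[, rev(seq_len(nrow(plane)))]  # 90 deg rotation
  a <- orientation_field(plane, 24)
  b <- orientation_field(rot, 24)
  nb <- nrow(plane) / 24
  for (i in which(a$retained)) {
    bi <- (a$row[i] + 12) / 24; bj <- (a$col[i] + 12) / 24
    # window (bi, bj) maps to (bj, nb + 1 - bi) under the rotation
    j <- which(abs(b$row - ((bj - 1) * 24 + 12.5)) < 1 &
                 abs(b$col - ((nb - bi) * 24 + 12.5)) < 1)
    expect_length(j, 1)
    expect_lt(abs(circ_diff_deg(b$phi_raw[j], a$phi_raw[i] + 90)), 2)
  }
})

test_that("orientation field gating retains or rejects as thresholded", {
  plane <- stripe_pattern(96, 45)
  all_in <- orientation_field(plane, 24, gate_threshold = 0)
  expect_true(all(all_in$retained))
  none <- orientation_field(plane, 24, gate_threshold = max(all_in$ec) * 1.01)
  expect_false(any(none$retained))
  # quantile gate keeps the requested fraction
  set.seed(6)
  noisy <- matrix(runif(96^2), 96)
  q <- orientation_field(noisy, 24, gate_quantile = 0.5)
  expect_lt(abs(mean(q$retained) - 0.5), 0.15)
  expect_error(orientation_field(matrix(0, 10, 10), 24), "larger")
})

test_that("myelin preprocessing enhances ridges and normalises range", {
  expect_warning(out <- preprocess_myelin(matrix(2, 40, 40)), "constant")
  expect_true(all(out == 0))
  img <- matrix(0, 60, 60); img[, 29:31] <- 1  # bright vertical line
  out <- preprocess_myelin(img)
  expect_equal(median(apply(out[5:55, ], 1, which.max)), 30)
  set.seed(10)
  for (i in 1:3) {
    x <- matrix(runif(40 * 40, 0, 10), 40)
    out <- preprocess_myelin(x)
    expect_gte(min(out), 0); expect_lte(max(out), 1)
  }
})

test_that("cortical surface fit recovers coefficients and distance geometry", {
  coeffs <- c(0.002, -0.3, 40)
  af <- gen_af_surface(coeffs, c(220, 160, 1))
  sf <- fit_cortical_surface(af$data[, , 1])
  expect_equal(unname(sf$coeffs), coeffs, tolerance = 0.01)
  # distance increases monotonically with depth below the surface
  expect_true(all(diff(sf$distance_px[60:220, 80]) > 0))
  # flat surface: a ~ 0, tangent 0 (normal points down the depth axis)
  af2 <- gen_af_surface(c(0, 0, 30), c(120, 100, 1))
  sf2 <- fit_cortical_surface(af2$data[, , 1])
  expect_lt(abs(sf2$coeffs[1]), 1e-4)
  expect_equal(unname(sf2$coeffs[3]), 30, tolerance = 0.3)
  tg <- sf2$tangent_deg[60:100, 20:80]
  expect_lt(max(abs(circ_diff_deg(tg, 0))), 0.5)
  expect_error(fit_cortical_surface(matrix(1, 50, 50)), "boundary")
})

test_that("curvature correction is tangent-relative and the layer tie goes
           deeper", {
  # flat surface: corrected equals raw
  field <- data.frame(row = c(60, 100, 140, 180), col = rep(50, 4),
                      phi_raw = c(10, 95, 170, 44), energy = 1, coherence = 1,
                      ec = 1, retained = TRUE)
  n <- 220
  surface <- list(distance_px = matrix(rep(pmax(seq_len(n) - 20, 0), 100), n),
                  tangent_deg = matrix(0, n, 100))
  bounds <- c(10, 35, 50, 75) / 0.54 * 0.54  # um
  out <- correct_and_layer(field, surface, c(10, 35, 50, 75))
  expect_equal(out$phi_corr, out$phi_raw)
  # depths 40*0.54=21.6, 80*0.54=43.2, 120*0.54=64.8, 160*0.54=86.4 -> layers
  expect_equal(out$layer, c("L2/3", "L4", "L5", "L5")[seq_len(nrow(out))])
  # exact boundary depth goes to the deeper layer
  field2 <- data.frame(row = 85, col = 50, phi_raw = 90,
                       energy = 1, coherence = 1, ec = 1, retained = TRUE)
  out2 <- correct_and_layer(field2, surface, c(10, (85 - 20) * 0.54, 50, 75))
  expect_equal(out2$layer, "L4")
  # windows beyond the deepest boundary (L6) are dropped
  field3 <- data.frame(row = 219, col = 50, phi_raw = 90, energy = 1,
                       coherence = 1, ec = 1, retained = TRUE)
  out3 <- correct_and_layer(field3, surface, c(10, 35, 50, 75))
  expect_equal(nrow(out3), 0)
})

test_that("radial fibres on a curved surface read 90 degrees after
           correction", {
  des <- data.frame(layer = c("L2/3", "L4", "L5"), mean_deg = 90, sd_deg = 0,
                    n_fibres = c(120, 80, 80))
  fr <- c("L1" = 0.02, "L2/3" = 0.45, "L4" = 0.65, "L5" = 1.0)
  # vertex at x = 80; radius of curvature (1/2a = 625 px) well above the
  # cortical depth, as for real cortex at this field of view
  coeffs <- c(0.0008, -0.128, 25)
  sim <- gen_fibre_volume(c(260, 160, 1), des, coeffs, fr, seed = 15)
  af <- gen_af_surface(coeffs, c(260, 160, 1))
  rec <- quantify_orientations(sim$stack, af, sim$truth$layer_boundaries_um,
                               preprocess = FALSE)
  expect_gt(nrow(rec), 20)
  # raw orientations vary with lateral position, corrected ones do not
  expect_gt(diff(range(rec$phi_raw)), 5)
  expect_lt(abs(circ_diff_deg(circ_mean_deg(rec$phi_corr), 90)), 1)
})

test_that("per-layer tangent-relative means are recovered end to end", {
  des <- default_fibre_design(mean_deg = c(0, 90.1, 90.9, 91.4),
                              sd_deg = c(5, 3, 3, 3),
                              n_fibres = c(60, 130, 90, 90))
  coeffs <- c(0.0008, -0.128, 26)
  sim <- gen_fibre_volume(c(240, 208, 6), des, coeffs, seed = 16)
  af <- gen_af_surface(coeffs, c(240, 208, 6))
  rec <- quantify_orientations(sim$stack, af, sim$truth$layer_boundaries_um,
                               preprocess = TRUE)
  for (l in c("L2/3", "L4", "L5")) {
    mu <- des$mean_deg[des$layer == l]
    expect_lt(abs(circ_diff_deg(circ_mean_deg(rec$phi_corr[rec$layer == l]),
                                mu)), 1)
  }
  expect_lt(abs(circ_diff_deg(circ_mean_deg(rec$phi_corr[rec$layer == "L1"]),
                              0)), 3)
})
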