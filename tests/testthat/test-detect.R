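test_that("shell kernel matches brute-force evaluation of its formula", {
  k <- build_shell_kernel(r0 = 4, sigma = 2, f0 = 0.1, phase = 0.7,
                          z_compression = 2, truncate = 2)
  half <- ceiling(4 + 2 * 2); zhalf <- ceiling(half / 2)
  expect_equal(dim(k$real_part), c(2 * half + 1, 2 * half + 1, 2 * zhalf + 1))
  # independent oracle: evaluate the formula voxel by voxel in a loop
  A <- 1 / (2 * pi * 2 * 4)
  for (pt in list(c(0, 0, 0), c(4, 0, 0), c(1, -2, 3), c(-5, 2, -1))) {
    rp <- sqrt(pt[1]^2 + pt[2]^2 + (2 * pt[3])^2)
    expect_equal(k$real_part[half + 1 + pt[2], half + 1 + pt[1],
                             zhalf + 1 + pt[3]],
                 A * exp(-pi * ((rp - 4) / 2)^2) * cos(2 * pi * 0.1 * (rp - 4) + 0.7))
    expect_equal(k$imag_part[half + 1 + pt[2], half + 1 + pt[1],
                             zhalf + 1 + pt[3]],
                 A * exp(-pi * ((rp - 4) / 2)^2) * sin(2 * pi * 0.1 * (rp - 4) + 0.7))
  }
  # point symmetry
  expect_equal(k$real_part, k$real_part[rev(seq_len(dim(k$real_part)[1])),
                                        rev(seq_len(dim(k$real_part)[2])),
                                        rev(seq_len(dim(k$real_part)[3]))])
  # phase 0 on the shell: envelope maximum A on the XY mid-plane at radius r0
  zmid <- zhalf + 1
  k0 <- build_shell_kernel(4, 2, 0.1, 0, 1, truncate = 2)
  expect_equal(k0$real_part[half + 1, half + 1 + 4, half + 1], A)
  expect_error(build_shell_kernel(-1, 2), "positive")
  expect_error(build_shell_kernel(4, 2, z_compression = 0.5), ">= 1")
})

test_that("published kernel parameters put the magnitude ring at r0", {
  k <- build_shell_kernel(22, 12, 0.1, 3.7, 2)
  d <- dim(k$real_part)
  expect_equal(d[3], 71)  # Z extent compressed by the factor 2
  ctr <- (d[1] + 1) / 2; zmid <- (d[3] + 1) / 2
  mag <- sqrt(k$real_part[, , zmid]^2 + k$imag_part[, , zmid]^2)
  prof <- mag[ctr, ctr:d[2]]
  expect_equal(which.max(prof) - 1, 22, tolerance = 0.5)
})

test_that("FFT convolution equals direct spatial convolution", {
  set.seed(21)
  vol <- array(runif(24 * 20 * 16), c(24, 20, 16))
  kern <- array(rnorm(7 * 5 * 3), c(7, 5, 3))
  a <- convolve_fft3(vol, kern)
  b <- direct_conv3(vol, kern)
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-10)
  expect_error(convolve_fft3(array(1, c(4, 4, 4)), array(1, c(5, 5, 5))),
               "larger")
  expect_error(convolve_fft3(vol, array(1, c(4, 4, 2))), "odd")
})

test_that("a single noiseless shell is detected within one voxel", {
  vox <- c(0.54, 0.54, 1.08)
  k <- build_shell_kernel(6, 3, 0.1, 0, 2, truncate = 3)
  r_um <- kernel_matched_radius_px(k) * vox[1]
  ctr <- c(30 * vox[1], 35 * vox[2], 25 * vox[3])
  vol <- render_shell(c(64, 64, 48), ctr, r_um, 1.2, vox)
  det <- detect_cells(volume_stack(vol, vox), k)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_um - ctr[1]), vox[1])
  expect_lt(abs(det$y_um - ctr[2]), vox[2])
  expect_lt(abs(det$z_um - ctr[3]), vox[3])
})

test_that("detection is translation-equivariant and linear in the input", {
  vox <- c(0.54, 0.54, 1.08)
  k <- build_shell_kernel(6, 3, 0.1, 0, 2, truncate = 3)
  r_um <- kernel_matched_radius_px(k) * vox[1]
  sh <- c(72, 72, 56)
  c1 <- c(24.5 * vox[1], 27.5 * vox[2], 21.5 * vox[3])  # on voxel centres
  shift_vox <- c(3, 2, 4)  # (x, y, z) voxels
  c2 <- c1 + shift_vox * vox
  v1 <- render_shell(sh, c1, r_um, 1.2, vox)
  v2 <- render_shell(sh, c2, r_um, 1.2, vox)
  d1 <- detect_cells(volume_stack(v1, vox), k)
  d2 <- detect_cells(volume_stack(v2, vox), k)
  expect_equal(nrow(d1), 1); expect_equal(nrow(d2), 1)
  expect_equal(c(d2$x_um - d1$x_um, d2$y_um - d1$y_um, d2$z_um - d1$z_um),
               shift_vox * vox, tolerance = 1e-9)
  # linearity: response to two well-separated shells is the sum of singles
  far <- c(55 * vox[1], 58 * vox[2], 40 * vox[3])
  v3 <- render_shell(sh, far, r_um, 1.2, vox)
  r_pair <- convolve_fft3(v1 + v3, k$real_part)
  r_sum <- convolve_fft3(v1, k$real_part) + convolve_fft3(v3, k$real_part)
  expect_lt(max(abs(r_pair - r_sum)) / max(abs(r_sum)), 1e-6)
})

test_that("a background-only volume yields no detections", {
  vox <- c(0.54, 0.54, 1.08)
  k <- build_shell_kernel(6, 3, 0.1, 0, 2, truncate = 3)
  det <- detect_cells(volume_stack(array(0.05, c(64, 64, 48)), vox), k)
  expect_equal(nrow(det), 0)
})

test_that("a noisy 48-cell lattice is fully recovered with no false
           positives", {
  vox <- c(0.54, 0.54, 4)
  cv <- gen_cell_volume(c(148, 148, 40), spacing_um = 12, pitch_um = 20,
                        jitter_sd_um = 0.3, cell_radius_um = 3.2,
                        rim_width_um = 1.3, snr = 10, seed = 31,
                        voxel_size_um = vox)
  n_true <- nrow(cv$truth$cell_centres_um)
  expect_gt(n_true, 40)
  k <- build_shell_kernel(r0 = 3.2 / vox[1],
                          sigma = 1.3 * sqrt(2 * pi) / vox[1],
                          f0 = 0.1, phase = 0, z_compression = vox[3] / vox[1],
                          truncate = 3)
  # minimum separation of 8 um (below the 12 um intra-column spacing) so
  # duplicate responses on adjacent z planes collapse onto one detection
  det <- detect_cells(cv$stack, k, min_distance_um = 8)
  tru <- cell_centres(cv$truth$cell_centres_um, voxel_size_um = vox,
                      extent_um = stack_extent_um(cv$stack))
  sc <- score_detection(det, tru, match_radius_um = 5)
  expect_equal(sc$accuracy_pct, 100)
  expect_equal(sc$false_positive_pct, 0)
})

test_that("detection scoring enumerates matches as defined", {
  set.seed(17)
  pts <- cbind(runif(10, 20, 80), runif(10, 20, 80), runif(10, 20, 80))
  tru <- cell_centres(pts)
  expect_equal(score_detection(tru, tru)$accuracy_pct, 100)
  expect_equal(score_detection(tru, tru)$false_positive_pct, 0)
  # one spurious detection among 11: FP = 1/11
  det <- cell_centres(rbind(pts, c(5, 5, 5)))
  sc <- score_detection(det, tru)
  expect_equal(sc$false_positive_pct, 100 / 11, tolerance = 1e-9)
  expect_equal(sc$false_negative_pct, 0)
  # nothing detected
  sc0 <- score_detection(cell_centres(matrix(numeric(0), 0, 3)), tru)
  expect_equal(sc0$accuracy_pct, 0)
  expect_equal(sc0$false_negative_pct, 100)
  expect_error(score_detection(tru, cell_centres(matrix(numeric(0), 0, 3))),
               "empty truth")
})
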