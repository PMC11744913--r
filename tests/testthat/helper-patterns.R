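# Shared fixtures, all generated in code.

# stripe pattern with ridges running along direction theta (axial degrees);
# intensity varies only across the ridges
stripe_pattern <- function(n, theta_deg, period = 12) {
  xs <- matrix(rep(seq_len(n), each = n), n)  # column (x) index
  ys <- matrix(rep(seq_len(n), n), n)         # row (y) index
  th <- theta_deg * pi / 180
  sin(2 * pi * (-xs * sin(th) + ys * cos(th)) / period)
}

# window whose structure tensor has exactly equal eigenvalues: the sum of a
# pattern varying only along x and its transpose, with the end values equal
# so the replicated-border gradient sums vanish identically
isotropic_pattern <- function(n = 25, period = 8) {
  stopifnot((n - 1) %% period == 0)
  f <- sin(2 * pi * (seq_len(n) - 1) / period)
  outer(rep(1, n), f) + outer(f, rep(1, n))
}

# direct (spatial-domain, triple-loop over kernel taps) 3D convolution with
# "same" extent and zero padding; independent oracle for the FFT route
direct_conv3 <- function(vol, kern) {
  dv <- dim(vol); dk <- dim(kern)
  h <- (dk - 1L) / 2L
  out <- array(0, dv)
  for (a in seq_len(dk[1])) for (b in seq_len(dk[2])) for (cc in seq_len(dk[3])) {
    w <- kern[a, b, cc]
    if (w == 0) next
    # out[i] += w * vol[i + h + 1 - a] with zero padding (true convolution)
    si <- (h[1] + 1L - a); sj <- (h[2] + 1L - b); sk <- (h[3] + 1L - cc)
    ti <- max(1L, 1L + si):min(dv[1], dv[1] + si)
    tj <- max(1L, 1L + sj):min(dv[2], dv[2] + sj)
    tk <- max(1L, 1L + sk):min(dv[3], dv[3] + sk)
    out[ti - si, tj - sj, tk - sk] <- out[ti - si, tj - sj, tk - sk] +
      w * vol[ti, tj, tk]
  }
  out
}

# render a single spherical shell at a given centre (um) on an arbitrary grid
render_shell <- function(shape, centre_um, radius_um, width_um, voxel_size_um) {
  dx <- (seq_len(shape[2]) - 0.5) * voxel_size_um[1] - centre_um[1]
  dy <- (seq_len(shape[1]) - 0.5) * voxel_size_um[2] - centre_um[2]
  dz <- (seq_len(shape[3]) - 0.5) * voxel_size_um[3] - centre_um[3]
  rho <- sqrt(outer(outer(dy^2, dx^2, "+"), dz^2, "+"))
  array(exp(-((rho - radius_um)^2) / (2 * width_um^2)), shape)
}

# side-only projected-normal design at given per-side means
side_design <- function(mu_l, mu_r, n = 10000, kappa = 10, seed = 1) {
  pn_group_design(data.frame(side = c("L", "R"), mu_deg = c(mu_l, mu_r),
                             kappa = kappa, n = n), seed = seed)
}
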