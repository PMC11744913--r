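#' Build a complex 3D Gabor spherical-shell kernel
#'
#' The kernel is a Gaussian envelope of width `sigma` offset by radius `r0`
#' from the origin and modulated by a radially expanding plane wave with
#' frequency `f0` and phase `phase`:
#' \deqn{K(x,y,z) = \frac{1}{2\pi\sigma r_0}
#'   e^{-\pi((r'-r_0)/\sigma)^2} e^{i(2\pi f_0 (r'-r_0)+\varphi)}}
#' where `r'` is the radial distance with the z coordinate scaled by
#' `z_compression` to account for the Z anisotropy of light-sheet data.
#' Acting as an edge detector for hollow-shell objects, its real part is
#' convolved with the soma channel to highlight cell bodies.
#'
#' The support is truncated at `r' = r0 + truncate * sigma` (odd box); with
#' the default `truncate = 4` the envelope there is below `exp(-16 pi)`.
#'
#' @param r0 shell radius in (XY) pixels, > 0.
#' @param sigma envelope standard deviation in pixels, > 0.
#' @param f0 radial frequency in cycles/px.
#' @param phase phase offset in radians.
#' @param z_compression factor >= 1 compressing the kernel along Z; the Z
#'   extent is the XY extent divided by this factor (rounded odd).
#' @param truncate support radius in envelope widths.
#' @return object of class `shell_kernel` with 3D arrays `real_part` and
#'   `imag_part` (dimensions `[y, x, z]`, cubic in XY) and the parameters.
#' @export
build_shell_kernel <- function(r0, sigma, f0 = 0.1, phase = 0,
                               z_compression = 1, truncate = 4) {
  if (r0 <= 0 || sigma <= 0) stop("`r0` and `sigma` must be positive")
  if (z_compression < 1) stop("`z_compression` must be >= 1")
  half <- ceiling(r0 + truncate * sigma)
  zhalf <- ceiling(half / z_compression)
  xs <- -half:half
  zs <- -zhalf:zhalf
  # r' with z scaled by the compression factor; constant amplitude prefactor
  r2xy <- outer(xs^2, xs^2, "+")
  rp <- sqrt(outer(c(r2xy), (zs * z_compression)^2, "+"))
  dim(rp) <- c(length(xs), length(xs), length(zs))
  A <- 1 / (2 * pi * sigma * r0)
  env <- A * exp(-pi * ((rp - r0) / sigma)^2)
  arg <- 2 * pi * f0 * (rp - r0) + phase
  structure(list(real_part = env * cos(arg), imag_part = env * sin(arg),
                 r0 = r0, sigma = sigma, f0 = f0, phase = phase,
                 z_compression = z_compression, truncate = truncate),
            class = "shell_kernel")
}

#' Shell radius to which a kernel responds maximally
#'
#' The phase offset shifts the radius of the kernel's positive crest away
#' from `r0`: the real part peaks where the envelope-weighted cosine is
#' largest, not at the envelope centre. A bright shell of this radius
#' (in kernel/XY pixels, on a grid whose Z anisotropy equals the kernel's
#' `z_compression`) yields a positive convolution response that is maximal
#' at the shell centre, which makes local-maxima detection well posed.
#'
#' @param kernel a [build_shell_kernel()] result.
#' @return matched shell radius in XY pixels.
#' @export
kernel_matched_radius_px <- function(kernel) {
  r <- seq(0, kernel$r0 + kernel$truncate * kernel$sigma, by = 0.01)
  prof <- exp(-pi * ((r - kernel$r0) / kernel$sigma)^2) *
    cos(2 * pi * kernel$f0 * (r - kernel$r0) + kernel$phase)
  r[which.max(prof)]
}

#' @export
print.shell_kernel <- function(x, ...) {
  cat("shell_kernel:", paste(dim(x$real_part), collapse = " x "),
      sprintf("(r0=%g px, sigma=%g, f0=%g, phase=%g, z compression=%g)\n",
              x$r0, x$sigma, x$f0, x$phase, x$z_compression))
  invisible(x)
}

#' 3D FFT convolution with "same" extent
#'
#' Zero-padded FFT convolution of a volume with a (odd-sized) kernel,
#' returning an array the size of the input. Equivalent to direct spatial
#' convolution up to floating-point error.
#'
#' @param vol 3D numeric array.
#' @param kern 3D numeric array with odd dimensions, no larger than `vol`.
#' @return 3D array, same dimensions as `vol`.
#' @export
convolve_fft3 <- function(vol, kern) {
  dv <- dim(vol); dk <- dim(kern)
  stopifnot(length(dv) == 3, length(dk) == 3)
  if (any(dk > dv)) stop("kernel is larger than the volume")
  if (any(dk %% 2 == 0)) stop("kernel dimensions must be odd")
  np <- sapply(dv + dk - 1L, nextn, factors = c(2, 3, 5))
  pv <- array(0, np); pv[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3])] <- vol
  pk <- array(0, np); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kern
  full <- Re(fft(fft(pv) * fft(pk), inverse = TRUE)) / prod(np)
  h <- (dk - 1L) / 2L
  full[h[1] + seq_len(dv[1]), h[2] + seq_len(dv[2]), h[3] + seq_len(dv[3])]
}

#' Construct a cell-centre set
#'
#' @param points_um matrix/data.frame with columns `x_um, y_um, z_um`.
#' @param voxel_size_um voxel size used for the px representation.
#' @param extent_um physical extent of the source volume (x, y, z) in um,
#'   needed by the neighbourhood statistics for edge exclusion and density.
#' @param scores optional per-point maxima heights.
#' @param border optional logical flag per point (within kernel half-width of
#'   the volume border).
#' @param sample_id,side labels.
#' @return data.frame of class `cell_centres` with um and px coordinates.
#' @export
cell_centres <- function(points_um, voxel_size_um = c(0.54, 0.54, 4),
                         extent_um = NULL, scores = NULL, border = NULL,
                         sample_id = "sim01", side = "L") {
  pts <- as.data.frame(points_um)
  names(pts)[1:3] <- c("x_um", "y_um", "z_um")
  if (!is.null(extent_um)) {
    if (any(pts$x_um < 0 | pts$x_um > extent_um[1] |
            pts$y_um < 0 | pts$y_um > extent_um[2] |
            pts$z_um < 0 | pts$z_um > extent_um[3]))
      stop("points must lie inside the volume bounds")
  }
  pts$x_px <- pts$x_um / voxel_size_um[1] + 0.5
  pts$y_px <- pts$y_um / voxel_size_um[2] + 0.5
  pts$z_px <- pts$z_um / voxel_size_um[3] + 0.5
  pts$score <- if (is.null(scores)) rep(NA_real_, nrow(pts)) else scores
  pts$border <- if (is.null(border)) rep(FALSE, nrow(pts)) else border
  structure(pts, class = c("cell_centres", "data.frame"),
            voxel_size_um = voxel_size_um, extent_um = extent_um,
            sample_id = sample_id, side = side)
}

#' Annotate cell centres by shell-kernel convolution and local maxima
#'
#' Convolves the (single-channel) soma volume with the real part of the
#' Gabor spherical-shell kernel by FFT and marks 3D local maxima of the
#' response that (i) exceed `rel_threshold` times the global response
#' maximum and (ii) are separated by at least `min_distance_um` (anisotropic,
#' in physical units). Maxima within half a kernel width of the volume
#' border are kept but flagged in the `border` column.
#'
#' @param stack single-channel [volume_stack()].
#' @param kernel a [build_shell_kernel()] result; must fit inside the stack.
#' @param min_distance_um minimum separation between detections; default is
#'   the kernel radius `r0` converted to um via the XY voxel size.
#' @param rel_threshold fraction of the global response maximum below which
#'   maxima are discarded.
#' @param sample_id,side labels passed to the result.
#' @return a [cell_centres()] data.frame with detection scores.
#' @export
detect_cells <- function(stack, kernel, min_distance_um = NULL,
                         rel_threshold = 0.3, sample_id = "sim01",
                         side = "L") {
  stopifnot(inherits(stack, "volume_stack"), inherits(kernel, "shell_kernel"))
  if (length(dim(stack$data)) != 3L)
    stop("`stack` must be single-channel; use get_channel()")
  vox <- stack$voxel_size_um
  if (is.null(min_distance_um)) min_distance_um <- kernel$r0 * vox[1]
  # subtract the volume mean so the response reflects local contrast and is
  # invariant to the global intensity offset (a background-only volume gives
  # a zero response)
  resp <- convolve_fft3(stack$data - mean(stack$data), kernel$real_part)
  mx <- max(resp)
  rng <- max(stack$data) - min(stack$data)
  if (mx <= 1e-10 * rng || rng == 0) {
    return(cell_centres(matrix(numeric(0), 0, 3), vox,
                        extent_um = stack_extent_um(stack),
                        sample_id = sample_id, side = side))
  }
  cand <- local_maxima_3d(resp, rel_threshold * mx)
  if (nrow(cand) == 0) {
    return(cell_centres(matrix(numeric(0), 0, 3), vox,
                        extent_um = stack_extent_um(stack),
                        sample_id = sample_id, side = side))
  }
  # greedy minimum-separation pruning, strongest responses first
  cand <- cand[order(-cand[, 4]), , drop = FALSE]
  pos_um <- cbind((cand[, 2] - 0.5) * vox[1],   # x from col
                  (cand[, 1] - 0.5) * vox[2],   # y from row
                  (cand[, 3] - 0.5) * vox[3])   # z from plane
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- colSums((t(pos_um[keep, , drop = FALSE]) - pos_um[i, ])^2)
    if (min(d2) >= min_distance_um^2) keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  pos_um <- pos_um[keep, , drop = FALSE]
  hk <- (dim(kernel$real_part) - 1L) / 2L
  dvol <- dim(stack$data)
  border <- cand[, 1] <= hk[1] | cand[, 1] > dvol[1] - hk[1] |
            cand[, 2] <= hk[2] | cand[, 2] > dvol[2] - hk[2] |
            cand[, 3] <= hk[3] | cand[, 3] > dvol[3] - hk[3]
  cell_centres(pos_um, vox, extent_um = stack_extent_um(stack),
               scores = cand[, 4], border = border,
               sample_id = sample_id, side = side)
}

# 26-neighbourhood local maxima above an absolute threshold, implemented
# with shifted-array comparisons; ties on symmetric plateaus are kept here
# and resolved by the caller's minimum-separation pruning
local_maxima_3d <- function(resp, threshold) {
  d <- dim(resp)
  is_max <- resp >= threshold
  pad <- array(-Inf, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- resp
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    if (!any(is_max)) break
    nb <- pad[1 + di + seq_len(d[1]), 1 + dj + seq_len(d[2]),
              1 + dk + seq_len(d[3])]
    is_max <- is_max & (resp >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  cbind(idx, score = resp[is_max])
}

#' Score detections against ground truth
#'
#' Greedy one-to-one nearest matching within `match_radius_um` (pairs are
#' accepted in order of increasing distance). Accuracy is the percentage of
#' truth points matched; false positives are unmatched detections as a
#' percentage of detections; false negatives are unmatched truth points as a
#' percentage of truth.
#'
#' @param detected,truth [cell_centres()] objects (or data.frames with
#'   `x_um, y_um, z_um`).
#' @param match_radius_um matching radius, default 5 um (about a soma radius).
#' @return list with `accuracy_pct`, `false_positive_pct`,
#'   `false_negative_pct`, `n_matched`, `n_detected`, `n_truth`.
#' @export
score_detection <- function(detected, truth, match_radius_um = 5) {
  tp <- as.matrix(truth[, c("x_um", "y_um", "z_um")])
  if (nrow(tp) == 0) stop("empty truth: detection scores are undefined")
  dp <- as.matrix(detected[, c("x_um", "y_um", "z_um"), drop = FALSE])
  nd <- nrow(dp); nt <- nrow(tp)
  matched_d <- logical(nd); matched_t <- logical(nt)
  if (nd > 0) {
    pairs <- NULL
    for (i in seq_len(nd)) {
      d <- sqrt(colSums((t(tp) - dp[i, ])^2))
      j <- which(d <= match_radius_um)
      if (length(j)) pairs <- rbind(pairs, cbind(i, j, d[j]))
    }
    if (!is.null(pairs)) {
      pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (!matched_d[i] && !matched_t[j]) {
          matched_d[i] <- TRUE; matched_t[j] <- TRUE
        }
      }
    }
  }
  nm <- sum(matched_t)
  list(accuracy_pct = 100 * nm / nt,
       false_positive_pct = if (nd > 0) 100 * sum(!matched_d) / nd else 0,
       false_negative_pct = 100 * sum(!matched_t) / nt,
       n_matched = nm, n_detected = nd, n_truth = nt)
}
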