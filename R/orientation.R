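#' Preprocess a myelin-channel plane for orientation analysis
#'
#' Median filter (impulse-noise removal), multiscale Hessian ridge
#' enhancement of bright curvilinear structures (a Sato-style tubeness
#' filter), then min-max normalisation to \[0, 1\]. A constant plane cannot
#' be normalised and returns all zeros with a warning.
#'
#' @param plane 2D numeric matrix.
#' @param median_radius radius of the median filter in px.
#' @param sigmas ridge-filter scales in px.
#' @return matrix with values in \[0, 1\].
#' @export
preprocess_myelin <- function(plane, median_radius = 1, sigmas = c(1, 2)) {
  if (length(plane) == 0) stop("empty plane")
  rng <- range(plane)
  if (diff(rng) == 0) {
    warning("constant plane: normalisation returns all zeros")
    return(matrix(0, nrow(plane), ncol(plane)))
  }
  x <- (plane - rng[1]) / diff(rng)
  x <- EBImage::medianFilter(x, median_radius)
  x <- sato_ridge(x, sigmas)
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("ridge response is constant: returning all zeros")
    return(matrix(0, nrow(plane), ncol(plane)))
  }
  (x - rng[1]) / diff(rng)
}

#' Multiscale Hessian ridge (tubeness) filter for bright curvilinear
#' structures
#'
#' At each scale the image is Gaussian-smoothed, the Hessian is computed by
#' central differences, and the scale-normalised negative minimum eigenvalue
#' (strong negative curvature across a bright ridge) is taken; the response
#' is the maximum over scales.
#'
#' @param img 2D matrix.
#' @param sigmas smoothing scales in px.
#' @export
sato_ridge <- function(img, sigmas = c(1, 2)) {
  best <- matrix(0, nrow(img), ncol(img))
  for (s in sigmas) {
    g <- EBImage::gblur(img, sigma = s)
    gx <- grad_x(g); gy <- grad_y(g)
    hxx <- grad_x(gx); hyy <- grad_y(gy); hxy <- grad_y(gx)
    tr <- hxx + hyy
    det_s <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
    lmin <- (tr - det_s) / 2
    best <- pmax(best, s^2 * pmax(-lmin, 0))
  }
  best
}

# central differences with replicated (reflect) borders
grad_x <- function(img) {
  n <- ncol(img)
  (img[, c(2:n, n)] - img[, c(1, 1:(n - 1))]) / 2
}
grad_y <- function(img) {
  n <- nrow(img)
  (img[c(2:n, n), ] - img[c(1, 1:(n - 1)), ]) / 2
}

#' Structure tensor of a single window
#'
#' Computes image gradients by central differences, averages the gradient
#' products over the window to form the 2x2 structure tensor `J`
#' (a covariance matrix of the localised gradient), and derives
#' \itemize{
#'   \item the dominant orientation `phi` in degrees \[0, 180), reported as
#'     the *structure* (ridge) direction, i.e. the gradient direction
#'     rotated by 90 degrees, so that fibres running along the image y axis
#'     read 90;
#'   \item the energy `E = trace(J)`, near 0 for homogeneous windows;
#'   \item the coherence `C = (lmax - lmin)/(lmax + lmin)` in \[0, 1\]
#'     (1 = one distinct dominant direction, 0 = isotropic; defined as 0
#'     when `E = 0`).
#' }
#' The quadrant ambiguity of the half-angle arctangent is resolved with the
#' two-argument form.
#'
#' @param window 2D matrix, at least 3x3.
#' @return list with `phi_deg`, `energy`, `coherence` and the tensor entries
#'   `J11`, `J12`, `J22`.
#' @export
structure_tensor_window <- function(window) {
  if (nrow(window) < 3 || ncol(window) < 3) stop("window must be >= 3x3")
  gx <- grad_x(window); gy <- grad_y(window)
  J11 <- mean(gx * gx); J12 <- mean(gx * gy); J22 <- mean(gy * gy)
  E <- J11 + J22
  if (E <= 0) {
    return(list(phi_deg = NA_real_, energy = 0, coherence = 0,
                J11 = J11, J12 = J12, J22 = J22))
  }
  disc <- sqrt(max((J11 - J22)^2 + 4 * J12^2, 0))
  C <- disc / E
  phi_grad <- rad2deg(0.5 * atan2(2 * J12, J11 - J22))
  list(phi_deg = wrap180(phi_grad + 90), energy = E, coherence = C,
       J11 = J11, J12 = J12, J22 = J22)
}

#' Orientation field of one plane by tiled structure-tensor windows
#'
#' Tiles the plane with non-overlapping `window x window` px windows,
#' computes the dominant orientation, energy and coherence per window, and
#' gates records by the product `E * C`: a record is retained when
#' `E * C >= threshold`. When no absolute threshold is given, the
#' `gate_quantile` quantile of `E * C` within the plane is used (the source
#' analysis used an unspecified predefined threshold; a per-plane 60th
#' percentile is the package default).
#'
#' @param plane 2D matrix (typically a [preprocess_myelin()] output).
#' @param window window edge in px (default 24).
#' @param gate_threshold absolute threshold on `E * C`, overrides the
#'   quantile gate.
#' @param gate_quantile quantile of `E * C` used when no absolute threshold
#'   is supplied.
#' @return data.frame with window centres (`row`, `col`, px), `phi_raw`
#'   (deg), `energy`, `coherence`, `ec` and `retained`.
#' @export
orientation_field <- function(plane, window = 24, gate_threshold = NULL,
                              gate_quantile = 0.6) {
  if (window > nrow(plane) || window > ncol(plane))
    stop("window larger than the plane")
  nr <- floor(nrow(plane) / window); nc <- floor(ncol(plane) / window)
  out <- vector("list", nr * nc)
  k <- 0L
  for (bi in seq_len(nr)) for (bj in seq_len(nc)) {
    rows <- ((bi - 1L) * window + 1L):(bi * window)
    cols <- ((bj - 1L) * window + 1L):(bj * window)
    st <- structure_tensor_window(plane[rows, cols])
    k <- k + 1L
    out[[k]] <- data.frame(row = mean(rows), col = mean(cols),
                           phi_raw = st$phi_deg, energy = st$energy,
                           coherence = st$coherence,
                           ec = st$energy * st$coherence)
  }
  df <- do.call(rbind, out)
  thr <- if (is.null(gate_threshold))
    as.numeric(quantile(df$ec, gate_quantile)) else gate_threshold
  df$retained <- df$ec >= thr & !is.na(df$phi_raw)
  attr(df, "gate_threshold") <- thr
  df
}

#' Fit the cortical surface of an autofluorescence plane
#'
#' Thresholds the plane (Otsu by default) into tissue/background, extracts
#' the per-column tissue boundary with subpixel precision (linear
#' interpolation of the threshold crossing), fits the quadratic
#' `row = a col^2 + b col + c` by least squares, and builds the distance
#' field to the fitted surface: every pixel's distance to its nearest point
#' on the continuous fitted curve (vectorised Newton projection, exact for
#' a smooth quadratic where a binarised discrete transform would quantise
#' shallow curvature away). A gradient filter over this distance field
#' yields the local surface-normal direction per pixel; the local tangent
#' is the normal rotated by 90 degrees.
#'
#' @param af_plane 2D matrix.
#' @param threshold optional absolute threshold; default Otsu on the
#'   rescaled plane.
#' @return list with `coeffs` (a, b, c), `distance_px` (depth below the
#'   fitted surface, 0 above it), `tangent_deg` and `normal_deg` (per-pixel
#'   orientation maps, axial degrees) and the thresholded `mask`.
#' @export
fit_cortical_surface <- function(af_plane, threshold = NULL) {
  rng <- range(af_plane)
  if (diff(rng) == 0) stop("plane has no tissue/background boundary")
  x <- (af_plane - rng[1]) / diff(rng)
  thr <- if (is.null(threshold)) EBImage::otsu(x, range = c(0, 1)) else threshold
  mask <- x > thr
  if (all(mask) || !any(mask))
    stop("threshold yields an all-tissue or all-background mask")
  boundary <- apply(x, 2, function(cc) {
    w <- which(cc > thr)
    if (!length(w)) return(NA_real_)
    r <- w[1]
    if (r == 1) return(1)
    # subpixel crossing between the last background and first tissue row
    (r - 1) + (thr - cc[r - 1]) / (cc[r] - cc[r - 1])
  })
  xs <- which(!is.na(boundary))
  if (length(xs) < 3) stop("too few boundary points to fit a quadratic")
  fit <- lm(boundary[xs] ~ xs + I(xs^2))
  coeffs <- c(a = unname(coef(fit)[3]), b = unname(coef(fit)[2]),
              c = unname(coef(fit)[1]))
  ny <- nrow(af_plane); nx <- ncol(af_plane)
  px <- matrix(rep(seq_len(nx), each = ny), ny)
  py <- matrix(rep(seq_len(ny), nx), ny)
  t <- project_to_curve(coeffs, px, py)
  f <- surface_row(coeffs, t)
  dist <- sign(py - surface_row(coeffs, px)) * sqrt((t - px)^2 + (f - py)^2)
  dist[dist < 0] <- 0
  gxd <- grad_x(dist); gyd <- grad_y(dist)
  normal <- wrap180(rad2deg(atan2(gyd, gxd)))
  normal[dist == 0] <- NA
  tangent <- wrap180(normal + 90)
  list(coeffs = coeffs, distance_px = dist, tangent_deg = tangent,
       normal_deg = normal, mask = mask)
}

#' Curvature-correct orientations and assign cortical layers
#'
#' Subtracts the local surface-tangent angle from each window's raw
#' orientation (so corrected angles are tangent-relative: 0 = parallel to
#' the surface, 90 = radial) and assigns a cortical layer from the window
#' centre's depth below the fitted surface. A window whose depth falls
#' exactly on a boundary goes to the deeper layer. Windows above the surface
#' are dropped, and windows deeper than the last boundary (layer 6, excluded
#' from analysis because of poor staining contrast) are dropped too; counts
#' are reported in attributes.
#'
#' @param field an [orientation_field()] data.frame.
#' @param surface a [fit_cortical_surface()] result for the same plane.
#' @param layer_boundaries_um strictly increasing depths (um) closing L1,
#'   L2/3, L4 and L5.
#' @param pixel_size_um in-plane pixel size used to convert depth to um.
#' @param side,sex,sample_id,plane labels added to the records.
#' @return the retained records with `phi_corr`, `depth_um` and `layer`.
#' @export
correct_and_layer <- function(field, surface, layer_boundaries_um,
                              pixel_size_um = 0.54, side = "L", sex = "F",
                              sample_id = "sim01", plane = 1L) {
  stopifnot(length(layer_boundaries_um) == 4,
            all(diff(layer_boundaries_um) > 0))
  layers <- c("L1", "L2/3", "L4", "L5")
  ij <- cbind(round(field$row), round(field$col))
  depth_um <- surface$distance_px[ij] * pixel_size_um
  tang <- surface$tangent_deg[ij]
  keep <- field$retained & depth_um > 0 & !is.na(tang)
  idx <- findInterval(depth_um, layer_boundaries_um)  # boundary -> deeper
  in_cortex <- idx <= 3
  n_l6 <- sum(keep & !in_cortex)
  out <- field[keep & in_cortex, , drop = FALSE]
  out$phi_corr <- wrap180(out$phi_raw - tang[keep & in_cortex])
  out$depth_um <- depth_um[keep & in_cortex]
  out$layer <- layers[idx[keep & in_cortex] + 1L]
  out$side <- rep(side, nrow(out))
  out$sex <- rep(sex, nrow(out))
  out$sample_id <- rep(sample_id, nrow(out))
  out$plane <- rep(plane, nrow(out))
  attr(out, "n_dropped_l6") <- n_l6
  attr(out, "n_dropped_surface") <- sum(field$retained) - sum(keep)
  out
}

#' Run the full orientation pipeline on a myelin + autofluorescence stack
#'
#' Per plane: preprocess the myelin channel, tile structure-tensor windows,
#' fit the cortical surface on the autofluorescence channel, gate, correct
#' for curvature and assign layers. Returns the tidy record table that feeds
#' the circular regression.
#'
#' @param mbp,af single-channel [volume_stack()]s with identical geometry.
#' @param layer_boundaries_um see [correct_and_layer()].
#' @param window,gate_quantile,gate_threshold see [orientation_field()].
#' @param preprocess logical; set `FALSE` when `mbp` is already a clean
#'   synthetic render.
#' @param side,sex,sample_id labels.
#' @return data.frame of per-window records across planes.
#' @export
quantify_orientations <- function(mbp, af, layer_boundaries_um,
                                  window = 24, gate_quantile = 0.6,
                                  gate_threshold = NULL, preprocess = TRUE,
                                  side = "L", sex = "F", sample_id = "sim01") {
  stopifnot(inherits(mbp, "volume_stack"), inherits(af, "volume_stack"))
  nz <- dim(mbp$data)[3]
  px <- mbp$voxel_size_um[1]
  recs <- vector("list", nz)
  for (z in seq_len(nz)) {
    plane <- mbp$data[, , z]
    if (preprocess) plane <- preprocess_myelin(plane)
    # layer assignment first, quantile gate second: the gate quantile is
    # taken over in-cortex windows, so empty background above the surface
    # cannot dilute it
    fld <- orientation_field(plane, window, gate_threshold = 0)
    surf <- fit_cortical_surface(af$data[, , z])
    rec <- correct_and_layer(fld, surf, layer_boundaries_um,
                             pixel_size_um = px, side = side, sex = sex,
                             sample_id = sample_id, plane = z)
    thr <- if (is.null(gate_threshold))
      as.numeric(quantile(rec$ec, gate_quantile)) else gate_threshold
    recs[[z]] <- rec[rec$ec >= thr, , drop = FALSE]
  }
  do.call(rbind, recs)
}
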