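#' Ground-truth container for synthetic tissue volumes
#'
#' Bundles everything a measurement stage can be scored against: soma centres
#' (um) with microcolumn membership, rendered fibre segments with their
#' tangent-relative angles, cortical-layer boundary depths, the quadratic
#' surface coefficients and the group labels of the simulated sample.
#'
#' @param cell_centres_um matrix with columns `x_um, y_um, z_um` (or NULL).
#' @param column_ids integer vector partitioning the cell centres (or NULL).
#' @param fibre_segments data.frame of rendered segments (or NULL).
#' @param layer_boundaries_um strictly increasing depths (um below surface)
#'   at which L1, L2/3, L4 and L5 end (or NULL).
#' @param surface_coeffs quadratic coefficients `c(a, b, c)` of the cortical
#'   surface `row = a col^2 + b col + c`, in pixel units (or NULL).
#' @param side,sex,sample_id group labels.
#' @export
tissue_truth <- function(cell_centres_um = NULL, column_ids = NULL,
                         fibre_segments = NULL, layer_boundaries_um = NULL,
                         surface_coeffs = NULL, side = "L", sex = "F",
                         sample_id = "sim01") {
  if (!is.null(layer_boundaries_um) &&
      any(diff(layer_boundaries_um) <= 0))
    stop("layer boundaries must be strictly increasing")
  if (!is.null(cell_centres_um)) {
    cell_centres_um <- as.matrix(cell_centres_um)
    stopifnot(ncol(cell_centres_um) == 3)
    if (!is.null(column_ids) && length(column_ids) != nrow(cell_centres_um))
      stop("column_ids must label every cell centre")
  }
  structure(list(cell_centres_um = cell_centres_um, column_ids = column_ids,
                 fibre_segments = fibre_segments,
                 layer_boundaries_um = layer_boundaries_um,
                 surface_coeffs = surface_coeffs,
                 side = side, sex = sex, sample_id = sample_id),
            class = "tissue_truth")
}

#' Default cortical layer boundaries as fractions of cortical depth
#'
#' Mouse-cortex-plausible defaults used whenever no expert annotation is
#' available: L1 ends at 10% of the cortical depth, L2/3 at 35%, L4 at 50%,
#' L5 at 75%; the remainder is L6 (excluded from orientation analysis because
#' of poor antibody penetration in the source assay).
#' @export
default_layer_fractions <- function() {
  c("L1" = 0.10, "L2/3" = 0.35, "L4" = 0.50, "L5" = 0.75)
}

#' Generate a synthetic soma volume with microcolumnar organisation
#'
#' Places cell bodies on radial microcolumns (columns run along the depth
#' axis y, from cortical surface towards white matter), renders each soma as
#' a hollow spherical shell (bright rim, dim core) with the Z extent
#' compressed by the voxel anisotropy, and adds Poisson shot noise plus
#' Gaussian read noise. The default geometry reproduces the hallmark
#' intra-column spacing of ~6 um, so the radial neighbour distribution of the
#' ground-truth points peaks near 6 and 12 um.
#'
#' @param shape integer triple `(ny, nx, nz)` in voxels.
#' @param spacing_um intra-column (depth) spacing between somata, > 0.
#' @param pitch_um lateral distance between columns in x and z.
#' @param jitter_sd_um isotropic Gaussian positional jitter; must satisfy
#'   `spacing_um > 2 * jitter_sd_um`.
#' @param cell_radius_um soma shell radius.
#' @param rim_width_um Gaussian width of the shell rim.
#' @param snr peak shell amplitude over the background-noise standard
#'   deviation; `snr = 0` renders pure background while the truth is
#'   unchanged.
#' @param profile `"shell"` (hollow rim, the default) or `"solid"`
#'   (filled soma with a soft edge of width `rim_width_um`).
#' @param background baseline intensity.
#' @param photons photon scale of the Poisson shot-noise model.
#' @param n_columns optionally keep only the first `n_columns` columns.
#' @param noise logical; `FALSE` returns the noiseless render.
#' @param voxel_size_um voxel size (x, y, z) in um.
#' @param side,sex,sample_id labels stored in the truth.
#' @param seed integer; fixing it fixes all outputs bit-for-bit.
#' @return list with elements `stack` (a [volume_stack()]) and `truth`
#'   (a [tissue_truth()]).
#' @export
gen_cell_volume <- function(shape, spacing_um = 6, pitch_um = 20,
                            jitter_sd_um = 0.5, cell_radius_um = 3.2,
                            rim_width_um = 1.3, snr = 10, background = 0.05,
                            photons = 200, n_columns = NULL, noise = TRUE,
                            profile = c("shell", "solid"),
                            voxel_size_um = c(0.54, 0.54, 4),
                            side = "L", sex = "F", sample_id = "sim01",
                            seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(length(shape) == 3)
  if (spacing_um <= 0) stop("`spacing_um` must be positive")
  if (spacing_um <= 2 * jitter_sd_um)
    stop("`spacing_um` must exceed twice the jitter sd")
  set.seed(seed)
  ext <- c(shape[2] * voxel_size_um[1], shape[1] * voxel_size_um[2],
           shape[3] * voxel_size_um[3])  # (x, y, z) um
  seq_safe <- function(from, to, by)
    if (to < from) numeric(0) else seq(from, to, by = by)
  marg_xz <- cell_radius_um + 2 * rim_width_um
  xs <- seq_safe(marg_xz + pitch_um / 2, ext[1] - marg_xz, by = pitch_um)
  zs <- seq_safe(marg_xz + pitch_um / 2, ext[3] - marg_xz, by = pitch_um)
  marg_y <- cell_radius_um + 2 * rim_width_um + spacing_um / 2
  ys <- seq_safe(marg_y, ext[2] - marg_y, by = spacing_um)
  if (length(xs) * length(zs) < 2)
    stop("shape too small to hold at least two columns at this pitch")
  if (length(ys) < 2)
    stop("shape too small to hold a column of at least two cells")
  cols <- expand.grid(x = xs, z = zs)
  if (!is.null(n_columns)) {
    if (n_columns < 1 || n_columns > nrow(cols))
      stop("`n_columns` out of range")
    cols <- cols[seq_len(n_columns), , drop = FALSE]
  }
  pts <- do.call(rbind, lapply(seq_len(nrow(cols)), function(ci) {
    cbind(x_um = cols$x[ci], y_um = ys, z_um = cols$z[ci], column_id = ci)
  }))
  if (jitter_sd_um > 0)
    pts[, 1:3] <- pts[, 1:3] + rnorm(3 * nrow(pts), sd = jitter_sd_um)
  pts[, 1] <- pmin(pmax(pts[, 1], marg_xz), ext[1] - marg_xz)
  pts[, 2] <- pmin(pmax(pts[, 2], marg_xz), ext[2] - marg_xz)
  pts[, 3] <- pmin(pmax(pts[, 3], marg_xz), ext[3] - marg_xz)

  clean <- array(background, shape)
  amp <- snr * sqrt(background / photons)
  if (amp > 0) {
    # render each shell in a local bounding box, physical (um) distances
    reach_um <- cell_radius_um + 3 * rim_width_um
    for (p in seq_len(nrow(pts))) {
      cx <- pts[p, 1]; cy <- pts[p, 2]; cz <- pts[p, 3]
      j <- seq(max(1, floor((cx - reach_um) / voxel_size_um[1])),
               min(shape[2], ceiling((cx + reach_um) / voxel_size_um[1])))
      i <- seq(max(1, floor((cy - reach_um) / voxel_size_um[2])),
               min(shape[1], ceiling((cy + reach_um) / voxel_size_um[2])))
      k <- seq(max(1, floor((cz - reach_um) / voxel_size_um[3])),
               min(shape[3], ceiling((cz + reach_um) / voxel_size_um[3])))
      dx <- (j - 0.5) * voxel_size_um[1] - cx
      dy <- (i - 0.5) * voxel_size_um[2] - cy
      dz <- (k - 0.5) * voxel_size_um[3] - cz
      rho <- sqrt(outer(outer(dy^2, dx^2, "+"), dz^2, "+"))
      obj <- if (profile == "shell")
        exp(-((rho - cell_radius_um)^2) / (2 * rim_width_um^2))
      else 1 / (1 + exp((rho - cell_radius_um) / rim_width_um))
      clean[i, j, k] <- clean[i, j, k] + amp * obj
    }
  }
  out <- if (noise) {
    n <- length(clean)
    shot <- array(stats::rpois(n, clean * photons) / photons, shape)
    pmax(shot + array(rnorm(n, sd = 0.25 * sqrt(background / photons)), shape), 0)
  } else clean
  list(stack = volume_stack(out, voxel_size_um, "huc"),
       truth = tissue_truth(cell_centres_um = pts[, 1:3, drop = FALSE],
                            column_ids = pts[, 4],
                            side = side, sex = sex, sample_id = sample_id))
}

#' Default per-layer fibre orientation design
#'
#' Tangent-relative axial means: L1 fibres run parallel to the cortical
#' surface (0 deg), L2/3-L5 predominantly radial (90 deg). Angular spreads
#' are free parameters of the simulation (the source study only constrains
#' the spread of the *means*); 5 deg is used as a realistic per-layer default.
#'
#' @param mean_deg,sd_deg,n_fibres per-layer values, recycled as needed.
#' @export
default_fibre_design <- function(mean_deg = c(0, 90, 90, 90),
                                 sd_deg = c(8, 5, 5, 5),
                                 n_fibres = c(40, 120, 80, 80)) {
  data.frame(layer = c("L1", "L2/3", "L4", "L5"),
             mean_deg = mean_deg, sd_deg = sd_deg, n_fibres = n_fibres,
             stringsAsFactors = FALSE)
}

surface_row <- function(coeffs, x) coeffs[1] * x^2 + coeffs[2] * x + coeffs[3]

# parameter t of the nearest point on row = a t^2 + b t + c to (px, py),
# by Newton iteration on the projection equation; vectorised over pixels.
# The local surface tangent/normal at a tissue point refer to this nearest
# surface point, which is what a gradient over the distance field measures.
project_to_curve <- function(coeffs, px, py, iters = 12) {
  a <- coeffs[1]; b <- coeffs[2]; cc <- coeffs[3]
  t <- px
  for (i in seq_len(iters)) {
    f <- a * t^2 + b * t + cc
    fp <- 2 * a * t + b
    g1 <- (t - px) + fp * (f - py)
    g2 <- 1 + 2 * a * (f - py) + fp^2
    t <- t - g1 / pmax(g2, 0.05)
  }
  t
}

# tangent angle (axial degrees) of the surface at the point nearest (px, py)
local_tangent_deg <- function(coeffs, px, py) {
  t <- project_to_curve(coeffs, px, py)
  wrap180(rad2deg(atan2(2 * coeffs[1] * t + coeffs[2], 1)))
}

#' Generate a synthetic myelin-channel volume of layered fibres
#'
#' Draws anti-aliased fibre segments whose angle *relative to the local
#' cortical-surface tangent* is sampled per layer from a wrapped-normal axial
#' distribution. The cortical surface is the quadratic
#' `row = a x^2 + b x + c` (pixel units); layers tile the depth below the
#' surface according to `layer_fractions`. By construction the exported
#' tangent-relative truth angles are invariant to surface curvature.
#'
#' @param shape `(ny, nx, nz)` voxels; each plane gets its own fibres.
#' @param design data.frame with columns `layer, mean_deg, sd_deg, n_fibres`
#'   (means in \[0, 180)); see [default_fibre_design()].
#' @param surface_coeffs quadratic surface coefficients `c(a, b, c)` (px).
#' @param layer_fractions cumulative depth fractions closing each layer,
#'   see [default_layer_fractions()].
#' @param fibre_length_px,width_px rendered segment geometry.
#' @param background baseline intensity; `noise_sd` adds Gaussian noise.
#' @param voxel_size_um,side,sex,sample_id,seed as in [gen_cell_volume()].
#' @return list(stack, truth); `truth$fibre_segments` holds per-segment
#'   endpoints (px), plane, layer, the sampled tangent-relative angle
#'   `theta_rel_deg` and the absolute in-plane angle `theta_abs_deg`.
#' @export
gen_fibre_volume <- function(shape, design = default_fibre_design(),
                             surface_coeffs = c(0, 0, 8),
                             layer_fractions = default_layer_fractions(),
                             fibre_length_px = 30, width_px = 2,
                             background = 0.03, noise_sd = 0,
                             voxel_size_um = c(0.54, 0.54, 4),
                             side = "L", sex = "F", sample_id = "sim01",
                             seed = 1L) {
  if (is.null(design) || nrow(design) == 0) stop("empty layer design")
  stopifnot(all(c("layer", "mean_deg", "sd_deg", "n_fibres") %in% names(design)))
  if (any(design$mean_deg < 0 | design$mean_deg >= 180))
    stop("layer means must lie in [0, 180)")
  if (!all(design$layer %in% names(layer_fractions)))
    stop("every design layer needs a boundary fraction")
  set.seed(seed)
  ny <- shape[1]; nx <- shape[2]; nz <- shape[3]
  xs_all <- seq_len(nx)
  surf <- surface_row(surface_coeffs, xs_all)
  if (any(surf < 1 | surf > ny - 4)) stop("surface leaves the frame")
  depth_total <- ny - max(surf) - 1
  if (depth_total < 10) stop("no room below the surface for cortex layers")
  half <- fibre_length_px / 2
  # all tangent-relative angles are drawn before any placement, so the truth
  # angles depend only on (design, seed) and are invariant to the surface
  th_store <- lapply(seq_len(shape[3]), function(z)
    lapply(seq_len(nrow(design)), function(li)
      wrap180(design$mean_deg[li] + rnorm(design$n_fibres[li], 0,
                                          design$sd_deg[li]))))
  vol <- array(background, shape)
  segs <- vector("list", nz * nrow(design))
  si <- 0L
  for (z in seq_len(nz)) {
    img <- matrix(0, ny, nx)
    for (li in seq_len(nrow(design))) {
      lay <- design$layer[li]
      k <- match(lay, names(layer_fractions))
      d_lo <- depth_total * if (k == 1) 0 else layer_fractions[k - 1]
      d_hi <- depth_total * layer_fractions[k]
      nf <- design$n_fibres[li]
      th_rel_all <- th_store[[z]][[li]]
      rec <- matrix(NA_real_, nf, 6)
      for (f in seq_len(nf)) {
        th_rel <- th_rel_all[f]
        for (try in 1:25) {
          # place the fibre at depth `dep` along the surface normal from a
          # random surface point, so its depth equals the distance-to-surface
          # the analysis measures
          xs0 <- runif(1, half + 2, nx - half - 2)
          dep <- runif(1, d_lo, d_hi)
          fp <- 2 * surface_coeffs[1] * xs0 + surface_coeffs[2]
          nrm <- c(-fp, 1) / sqrt(1 + fp^2)
          x0 <- xs0 + dep * nrm[1]
          y0 <- surface_row(surface_coeffs, xs0) + dep * nrm[2]
          tang <- wrap180(rad2deg(atan2(fp, 1)))
          th_abs <- wrap180(tang + th_rel)
          dx <- cos(deg2rad(th_abs)); dy <- sin(deg2rad(th_abs))
          p1 <- c(x0 - half * dx, y0 - half * dy)
          p2 <- c(x0 + half * dx, y0 + half * dy)
          if (all(c(p1, p2) >= 1.5) && p1[1] <= nx - 0.5 && p2[1] <= nx - 0.5 &&
              p1[2] <= ny - 0.5 && p2[2] <= ny - 0.5) break
        }
        img <- draw_segment(img, p1, p2, width_px)
        rec[f, ] <- c(p1, p2, th_rel, th_abs)
      }
      si <- si + 1L
      segs[[si]] <- data.frame(x1 = rec[, 1], y1 = rec[, 2], x2 = rec[, 3],
                               y2 = rec[, 4], plane = z, layer = lay,
                               theta_rel_deg = rec[, 5],
                               theta_abs_deg = rec[, 6],
                               stringsAsFactors = FALSE)
    }
    vol[, , z] <- vol[, , z] + img
  }
  if (noise_sd > 0)
    vol <- pmax(vol + array(rnorm(length(vol), sd = noise_sd), shape), 0)
  boundaries_um <- depth_total * layer_fractions * voxel_size_um[2]
  list(stack = volume_stack(vol, voxel_size_um, "mbp"),
       truth = tissue_truth(fibre_segments = do.call(rbind, segs[seq_len(si)]),
                            layer_boundaries_um = boundaries_um,
                            surface_coeffs = surface_coeffs,
                            side = side, sex = sex, sample_id = sample_id))
}

# additive anti-aliased segment rendering: Gaussian profile across the
# segment, evaluated on the local bounding box only
draw_segment <- function(img, p1, p2, width_px) {
  ny <- nrow(img); nx <- ncol(img)
  s <- width_px / 2
  xmin <- max(1, floor(min(p1[1], p2[1]) - 3 * s))
  xmax <- min(nx, ceiling(max(p1[1], p2[1]) + 3 * s))
  ymin <- max(1, floor(min(p1[2], p2[2]) - 3 * s))
  ymax <- min(ny, ceiling(max(p1[2], p2[2]) + 3 * s))
  xs <- xmin:xmax; ys <- ymin:ymax
  v <- p2 - p1
  L2 <- sum(v^2)
  px <- matrix(rep(xs, each = length(ys)), length(ys))
  py <- matrix(rep(ys, times = length(xs)), length(ys))
  t <- ((px - p1[1]) * v[1] + (py - p1[2]) * v[2]) / L2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (px - (p1[1] + t * v[1]))^2 + (py - (p1[2] + t * v[2]))^2
  img[ys, xs] <- img[ys, xs] + exp(-d2 / (2 * s^2))
  img
}

#' Generate a synthetic autofluorescence volume with a curved surface
#'
#' Renders, identically in every plane, a smooth intensity step across the
#' quadratic cortical surface `row = a x^2 + b x + c`: background (above the
#' curve) dark, tissue (below) bright.
#'
#' @param surface_coeffs `c(a, b, c)` in pixel units.
#' @param shape `(ny, nx, nz)`.
#' @param blur softness of the step edge in px.
#' @inheritParams gen_cell_volume
#' @return a [volume_stack()] with one `af` channel.
#' @export
gen_af_surface <- function(surface_coeffs, shape, blur = 2,
                           voxel_size_um = c(0.54, 0.54, 4)) {
  ny <- shape[1]; nx <- shape[2]; nz <- shape[3]
  surf <- surface_row(surface_coeffs, seq_len(nx))
  if (any(surf < 2 | surf > ny - 2)) stop("surface leaves the frame")
  rows <- matrix(seq_len(ny), ny, nx)
  f <- matrix(surf, ny, nx, byrow = TRUE)
  plane <- 1 / (1 + exp(-(rows - f) / blur))
  volume_stack(array(rep(plane, nz), c(ny, nx, nz)), voxel_size_um, "af")
}

#' Stratified design for projected-normal orientation sampling
#'
#' @param strata data.frame with columns `side`, `mu_deg` (circular mean on
#'   the axial \[0, 180) scale), `kappa` (latent mean-vector length; larger =
#'   more concentrated) and `n`; optional columns `layer`, `sex`, `sample_id`.
#' @param seed integer RNG seed.
#' @return object of class `pn_group_design`.
#' @export
pn_group_design <- function(strata, seed = 1L) {
  stopifnot(is.data.frame(strata),
            all(c("side", "mu_deg", "kappa", "n") %in% names(strata)))
  if (any(strata$n < 1)) stop("each stratum needs n >= 1")
  if (any(strata$mu_deg < 0 | strata$mu_deg >= 180))
    stop("stratum means must lie in [0, 180)")
  if (any(strata$kappa <= 0)) stop("spread parameter kappa must be positive")
  structure(list(strata = strata, seed = as.integer(seed)),
            class = "pn_group_design")
}

#' Sample axial orientation data from projected-normal group models
#'
#' For each stratum, draws latent bivariate normal vectors with identity
#' covariance and mean `kappa * (cos 2mu, sin 2mu)` -- angles are doubled so
#' that axial \[0, 180) orientations live on the full circle -- takes the
#' vector direction and halves it back. The circular mean of the draws is the
#' stratum mean `mu_deg`; their spread shrinks as `kappa` grows (for large
#' `kappa` the axial circular sd is approximately `1/(2 kappa)` radians).
#'
#' @param design a [pn_group_design()].
#' @return data.frame with `theta_deg` plus the stratum covariates.
#' @export
gen_orientation_samples <- function(design) {
  stopifnot(inherits(design, "pn_group_design"))
  set.seed(design$seed)
  st <- design$strata
  out <- lapply(seq_len(nrow(st)), function(i) {
    n <- st$n[i]
    mu2 <- deg2rad(2 * st$mu_deg[i])
    y1 <- st$kappa[i] * cos(mu2) + rnorm(n)
    y2 <- st$kappa[i] * sin(mu2) + rnorm(n)
    d <- data.frame(theta_deg = wrap180(rad2deg(atan2(y2, y1)) / 2),
                    side = st$side[i], stringsAsFactors = FALSE)
    for (cv in c("layer", "sex", "sample_id"))
      if (cv %in% names(st)) d[[cv]] <- st[[cv]][i]
    d
  })
  do.call(rbind, out)
}
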