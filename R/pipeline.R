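#' Default per-(sex, side, layer) orientation design of a simulated cohort
#'
#' Tangent-relative axial circular means of the myelin orientation in each
#' hemisphere and cortical layer. Defaults inject a layer-dependent
#' hemispheric asymmetry with the left-right differences largest in L2/3
#' (1.1 deg), then L4 (0.7) and L5 (0.6), on top of predominantly radial
#' (90 deg) fibres, with L1 parallel to the surface; both sexes share the
#' same table unless a sex-specific one is supplied.
#'
#' @param sexes which sexes to include.
#' @return data.frame with `sex`, `side`, `layer`, `mean_deg`.
#' @export
default_cohort_design <- function(sexes = c("F", "M")) {
  base <- data.frame(
    layer = rep(c("L1", "L2/3", "L4", "L5"), each = 2),
    side = rep(c("L", "R"), 4),
    mean_deg = c(0, 0, 90.1, 89.0, 90.9, 90.2, 91.4, 90.8))
  do.call(rbind, lapply(sexes, function(s) cbind(sex = s, base)))
}

#' Build a reproducible cohort run configuration
#'
#' A cohort run is a pure function of (config, seed): the master seed fans
#' out into per-sample and per-stage sub-seeds drawn once up front.
#'
#' @param n_female,n_male animals per sex (study cohort: 6 female, 5 male).
#' @param design per-(sex, side, layer) mean table, see
#'   [default_cohort_design()].
#' @param sd_deg angular dispersion of individual fibres around the layer
#'   mean (degrees).
#' @param shape volume shape `(ny, nx, nz)` per hemisphere; the desk-scale
#'   default keeps every cortical layer thicker than one analysis window
#'   (L1 occupies 10% of the depth and must exceed 24 px).
#' @param fibres_per_layer rendered fibres per layer and plane.
#' @param window,gate_quantile orientation-analysis settings.
#' @param layer_fractions cortical layer boundaries (depth fractions).
#' @param mcmc list with `iters`, `burnin`, `chains`.
#' @param by_sex also fit side-only models per sex.
#' @param run_cells run the soma simulation / detection / neighbourhood
#'   stage as well.
#' @param cell_params list passed to [gen_cell_volume()] for that stage.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_female = 2, n_male = 2,
                       design = default_cohort_design(),
                       sd_deg = 5, shape = c(400, 160, 2),
                       fibres_per_layer = 90, window = 24,
                       gate_quantile = 0.6,
                       layer_fractions = default_layer_fractions(),
                       mcmc = list(iters = 2000, burnin = 500, chains = 2),
                       by_sex = FALSE, run_cells = FALSE,
                       cell_params = list(shape = c(128, 128, 24)),
                       seed = 1L) {
  structure(list(n_female = n_female, n_male = n_male, design = design,
                 sd_deg = sd_deg, shape = shape,
                 fibres_per_layer = fibres_per_layer, window = window,
                 gate_quantile = gate_quantile,
                 layer_fractions = layer_fractions, mcmc = mcmc,
                 by_sex = by_sex, run_cells = run_cells,
                 cell_params = cell_params, seed = as.integer(seed)),
            class = "run_config")
}

#' Run a simulated cohort end to end
#'
#' For every animal and hemisphere: render a curved-surface
#' autofluorescence volume and a layered fibre volume from the cohort
#' design, quantify local dominant orientations (structure tensor windows,
#' E*C gating, curvature correction, layer assignment), pool the records,
#' and fit the side-only (model 1) and side-by-layer (model 2) circular
#' regressions, with DIC for comparison. Optionally also simulates somata
#' and runs detection plus neighbourhood statistics per hemisphere.
#'
#' @param config a [run_config()].
#' @return list of class `cohort_report` with the pooled `records`,
#'   `fit_side`, `fit_side_layer`, optional per-sex fits, the cell-stage
#'   results, and provenance (`config`, sub-seeds).
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  sexes <- rep(c("F", "M"), c(config$n_female, config$n_male))
  n_anim <- length(sexes)
  seeds <- matrix(sample.int(.Machine$integer.max, n_anim * 4), n_anim)
  all_rec <- list()
  cells_out <- list()
  ny <- config$shape[1]; nx <- config$shape[2]
  for (a in seq_len(n_anim)) {
    sid <- sprintf("sim%02d", a)
    for (side in c("L", "R")) {
      sseed <- seeds[a, if (side == "L") 1 else 2]
      set.seed(sseed)
      # per-hemisphere curved surface; the radius of curvature (1/2a) stays
      # above 2.5x the frame depth, as for real cortex at this field of view,
      # so nearest-surface-point projection is well defined everywhere
      amax <- 1 / (5 * ny)
      coeffs <- c(runif(1, 0.2, 1) * amax, 0, runif(1, 8, 16))
      coeffs[2] <- -coeffs[1] * nx  # vertex mid-frame
      coeffs[3] <- coeffs[3] + coeffs[1] * (nx / 2)^2
      des <- config$design[config$design$sex == sexes[a] &
                             config$design$side == side, ]
      fib_design <- data.frame(layer = des$layer, mean_deg = des$mean_deg,
                               sd_deg = config$sd_deg,
                               n_fibres = config$fibres_per_layer)
      sim <- gen_fibre_volume(config$shape, fib_design, coeffs,
                              config$layer_fractions,
                              side = side, sex = sexes[a], sample_id = sid,
                              seed = sseed)
      af <- gen_af_surface(coeffs, config$shape)
      rec <- quantify_orientations(sim$stack, af,
                                   sim$truth$layer_boundaries_um,
                                   window = config$window,
                                   gate_quantile = config$gate_quantile,
                                   preprocess = TRUE, side = side,
                                   sex = sexes[a], sample_id = sid)
      all_rec[[length(all_rec) + 1L]] <- rec
      if (config$run_cells) {
        cp <- config$cell_params
        cp$side <- side; cp$sex <- sexes[a]; cp$sample_id <- sid
        cp$seed <- seeds[a, if (side == "L") 3 else 4]
        cv <- do.call(gen_cell_volume, cp)
        vx <- cv$stack$voxel_size_um
        radius <- if (is.null(cp$cell_radius_um)) 3.2 else cp$cell_radius_um
        rim <- if (is.null(cp$rim_width_um)) 1.3 else cp$rim_width_um
        spacing <- if (is.null(cp$spacing_um)) 6 else cp$spacing_um
        # kernel matched to the rendered shells and the voxel anisotropy
        kern <- build_shell_kernel(r0 = radius / vx[1],
                                   sigma = rim * sqrt(2 * pi) / vx[1],
                                   f0 = 0.1, phase = 0,
                                   z_compression = vx[3] / vx[1], truncate = 3)
        det <- detect_cells(cv$stack, kern,
                            min_distance_um = 2 * spacing / 3,
                            sample_id = sid, side = side)
        cells_out[[paste(sid, side)]] <-
          list(detected = det, truth = cv$truth,
               score = score_detection(det, cell_centres(
                 cv$truth$cell_centres_um,
                 voxel_size_um = cv$stack$voxel_size_um,
                 extent_um = stack_extent_um(cv$stack))))
      }
    }
  }
  records <- do.call(rbind, all_rec)
  dat <- data.frame(theta_deg = records$phi_corr, side = records$side,
                    layer = records$layer, sex = records$sex,
                    sample_id = records$sample_id, stringsAsFactors = FALSE)
  m <- config$mcmc
  fit1 <- fit_pn_glm(dat, c("side"), iters = m$iters, burnin = m$burnin,
                     chains = m$chains, seed = seeds[1, 1])
  fit2 <- fit_pn_glm(dat, c("side", "layer"), iters = m$iters,
                     burnin = m$burnin, chains = m$chains, seed = seeds[1, 2])
  fits_sex <- NULL
  if (config$by_sex) {
    fits_sex <- lapply(split(dat, dat$sex), function(d)
      fit_pn_glm(d, c("side"), iters = m$iters, burnin = m$burnin,
                 chains = m$chains, seed = seeds[1, 3]))
  }
  structure(list(records = records, data = dat, fit_side = fit1,
                 fit_side_layer = fit2, fits_by_sex = fits_sex,
                 cells = cells_out, config = config, seeds = seeds),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Simulated cohort report:", length(unique(x$data$sample_id)),
      "samples,", nrow(x$data), "orientation records\n")
  cat("\nModel 1 (side):\n"); print(x$fit_side)
  cat("\nModel 2 (side x layer):\n"); print(x$fit_side_layer)
  cat(sprintf("\nDIC: side %.0f vs side x layer %.0f (lower is better)\n",
              x$fit_side$dic, x$fit_side_layer$dic))
  invisible(x)
}
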