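#' Fit a Bayesian projected-normal circular GLM to axial orientation data
#'
#' Models axial orientations (degrees in \[0, 180)) as directions of a
#' latent bivariate normal vector with identity covariance whose mean
#' depends on categorical covariates. Angles are doubled onto the full
#' circle before fitting (axial correction) and all reported quantities are
#' halved back. The design is parameterised in cell-means form -- one latent
#' mean vector per covariate cell (side, or side crossed with layer) -- so
#' per-cell posterior mean directions and their contrasts are read off
#' directly, matching how hemispheric differences are reported per layer.
#'
#' The Gibbs sampler alternates exact slice-sampling updates of the latent
#' vector lengths with conjugate normal updates of the cell mean vectors
#' (diffuse N(0, 1/prior_prec) priors on each coordinate). Per design cell
#' the circular posterior mean direction, posterior sd, 95% highest
#' posterior density interval and effective sample size are summarised from
#' the pooled post-burn-in draws of both chains.
#'
#' @param data data.frame with `theta_deg` in \[0, 180) and the covariate
#'   columns named in `formula` (`side`, optionally `layer`).
#' @param formula character vector of covariate names defining the design
#'   cells; `c("side")` is model 1, `c("side", "layer")` model 2.
#' @param iters,burnin,chains MCMC settings (defaults 5000 / 1000 / 2).
#' @param seed integer RNG seed; `NULL` leaves the RNG state alone.
#' @param track_loglik keep per-draw projected-normal log-likelihoods
#'   (needed for [dic()]); disable for speed.
#' @param prior_prec prior precision of the latent regression coefficients.
#' @param hpd_mass posterior mass of the HPD intervals.
#' @return object of class `pn_glm_fit`: `summary` data.frame (one row per
#'   cell: `mean_deg`, `sd_deg`, `hpd_lower`, `hpd_upper`, `ess`, `n_obs`),
#'   `angle_draws` matrix of axial per-cell posterior angle draws, the raw
#'   coefficient draws, `dic`, `pd` and bookkeeping.
#' @export
fit_pn_glm <- function(data, formula = c("side"), iters = 5000,
                       burnin = 1000, chains = 2, seed = NULL,
                       track_loglik = TRUE, prior_prec = 1e-4,
                       hpd_mass = 0.95) {
  stopifnot(is.data.frame(data), "theta_deg" %in% names(data))
  th <- data$theta_deg
  if (anyNA(th) || any(th < 0 | th >= 180))
    stop("theta_deg must be complete and in [0, 180)")
  for (v in formula) {
    if (!v %in% names(data)) stop(sprintf("covariate `%s` missing", v))
    if (anyNA(data[[v]])) stop(sprintf("covariate `%s` has missing values", v))
  }
  cells <- interaction(data[formula], sep = ":", drop = FALSE, lex.order = TRUE)
  tab <- table(cells)
  if (any(tab == 0))
    stop("empty design cell(s): ", paste(names(tab)[tab == 0], collapse = ", "))
  if (any(tab < 2))
    stop("design cell(s) with fewer than 2 observations: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  cell_levels <- levels(cells)
  cell_idx <- as.integer(cells) - 1L
  a2 <- deg2rad(2 * th)
  cx <- cos(a2); sx <- sin(a2)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(seq_len(chains), function(ch)
    pn_gibbs_chain(cell_idx, cx, sx, length(cell_levels),
                   as.integer(iters), as.integer(burnin),
                   prior_prec, track_loglik))
  b1 <- do.call(rbind, lapply(res, `[[`, "b1"))
  b2 <- do.call(rbind, lapply(res, `[[`, "b2"))
  colnames(b1) <- colnames(b2) <- cell_levels
  # per-draw cell directions on the doubled circle, halved back to axial
  ang_axial <- wrap180(rad2deg(atan2(b2, b1)) / 2)

  summ <- do.call(rbind, lapply(seq_along(cell_levels), function(j) {
    hpd <- hpd_interval(ang_axial[, j], mass = hpd_mass, axial = TRUE)
    per_chain_ess <- vapply(res, function(r)
      min(ess(cos(2 * deg2rad(wrap180(rad2deg(atan2(r$b2[, j], r$b1[, j])) / 2)))),
          ess(sin(2 * deg2rad(wrap180(rad2deg(atan2(r$b2[, j], r$b1[, j])) / 2))))),
      numeric(1))
    data.frame(cell = cell_levels[j],
               mean_deg = circ_mean_deg(ang_axial[, j]),
               sd_deg = circ_sd_deg(ang_axial[, j]),
               hpd_lower = hpd[["lower"]], hpd_upper = hpd[["upper"]],
               ess = sum(per_chain_ess), n_obs = as.integer(tab[cell_levels[j]]),
               stringsAsFactors = FALSE)
  }))
  if (any(summ$ess < 100))
    warning("low effective sample size (< 100) for cell(s): ",
            paste(summ$cell[summ$ess < 100], collapse = ", "))

  dic <- pd <- NA_real_
  if (track_loglik) {
    ll <- unlist(lapply(res, `[[`, "loglik"))
    dbar <- -2 * mean(ll)
    # deviance at the posterior mean of the latent coefficients
    dhat <- -2 * pn_loglik_cpp(colMeans(b1), colMeans(b2), cell_idx, cx, sx)
    pd <- dbar - dhat
    dic <- dbar + pd
  }
  structure(list(summary = summ, angle_draws = ang_axial,
                 b1 = b1, b2 = b2, cells = cell_levels, formula = formula,
                 dic = dic, pd = pd, n_obs = length(th),
                 iters = iters, burnin = burnin, chains = chains,
                 hpd_mass = hpd_mass),
            class = "pn_glm_fit")
}

#' @export
print.pn_glm_fit <- function(x, ...) {
  cat("Projected-normal circular GLM (", paste(x$formula, collapse = " x "),
      "), ", x$n_obs, " observations\n", sep = "")
  s <- x$summary
  s[, sapply(s, is.numeric)] <- round(s[, sapply(s, is.numeric)], 2)
  print(s, row.names = FALSE)
  if (!is.na(x$dic)) cat("DIC:", round(x$dic, 1), " (pD =", round(x$pd, 1), ")\n")
  invisible(x)
}

#' Posterior mean direction of one design cell
#' @param fit a `pn_glm_fit`.
#' @param cell cell label as in `fit$summary$cell`.
#' @export
posterior_mean_dir <- function(fit, cell) {
  i <- match(cell, fit$summary$cell)
  if (is.na(i)) stop("unknown design cell: ", cell)
  fit$summary$mean_deg[i]
}

#' Signed circular difference between two cells' posterior means
#'
#' Convenience contrast: `circ_diff_deg(mean[a], mean[b])` on the axial
#' scale, e.g. the left-minus-right hemispheric orientation difference.
#' @param fit a `pn_glm_fit`.
#' @param a,b cell labels.
#' @export
posterior_mean_diff <- function(fit, a, b) {
  circ_diff_deg(posterior_mean_dir(fit, a), posterior_mean_dir(fit, b))
}

#' Do two cells' HPD intervals overlap?
#'
#' Implements the distinctness rule used for circular effects: two effects
#' are considered distinct when their 95% HPD intervals do not overlap.
#' @param fit a `pn_glm_fit`.
#' @param a,b cell labels.
#' @return `TRUE` when the intervals intersect.
#' @export
hpd_overlap <- function(fit, a, b) {
  s <- fit$summary
  ia <- s[match(a, s$cell), ]; ib <- s[match(b, s$cell), ]
  if (anyNA(ia$hpd_lower) || anyNA(ib$hpd_lower)) stop("unknown cell label")
  seg_overlap <- function(l1, u1, l2, u2) {
    # compare on the circle: shift both intervals near each other
    d <- circ_diff_deg(l2, l1)
    l2s <- l1 + d; u2s <- l2s + (u2 - l2)
    (l1 <= u2s && l2s <= u1)
  }
  seg_overlap(ia$hpd_lower, ia$hpd_upper, ib$hpd_lower, ib$hpd_upper) ||
    seg_overlap(ib$hpd_lower, ib$hpd_upper, ia$hpd_lower, ia$hpd_upper)
}

#' Deviance information criterion of a fitted model
#'
#' Spiegelhalter's form: `DIC = Dbar + pD` with
#' `pD = Dbar - D(posterior mean)`. Lower is better.
#' @param fit a `pn_glm_fit` fitted with `track_loglik = TRUE`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "pn_glm_fit"))
  if (is.na(fit$dic))
    stop("no likelihood trace: refit with track_loglik = TRUE")
  fit$dic
}

#' Stratified bootstrap of the projected-normal circular GLM
#'
#' Repeatedly draws equal-size random subsamples from every design cell
#' (respecting equal sizes for the model parameters), fits the model on each
#' subsample, and aggregates the per-cell posterior mean directions across
#' repetitions. Each subsample is checked against the full stratum with a
#' two-sample Kuiper test; repetitions whose subsample distorts any stratum
#' distribution at `alpha` are flagged.
#'
#' @inheritParams fit_pn_glm
#' @param n_boot number of repetitions (default 25).
#' @param subsample_per_stratum subsample size per design cell (default
#'   5000); must not exceed the smallest stratum.
#' @param alpha significance level of the distribution-recovery check.
#' @param ... further arguments to [fit_pn_glm()].
#' @return object of class `pn_boot`: per-repetition summaries, aggregate
#'   per-cell circular mean of posterior means and across-repetition
#'   circular sd.
#' @export
bootstrap_fit <- function(data, formula = c("side"), n_boot = 25,
                          subsample_per_stratum = 5000, seed = 1L,
                          alpha = 0.01, ...) {
  cells <- interaction(data[formula], sep = ":", drop = FALSE, lex.order = TRUE)
  tab <- table(cells)
  if (any(tab < subsample_per_stratum))
    stop("stratum smaller than the requested subsample: ",
         paste(names(tab)[tab < subsample_per_stratum], collapse = ", "))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_boot)
  reps <- vector("list", n_boot)
  flagged <- logical(n_boot)
  for (r in seq_len(n_boot)) {
    set.seed(sub_seeds[r])
    idx <- unlist(lapply(levels(cells), function(lv)
      sample(which(cells == lv), subsample_per_stratum)))
    sub <- data[idx, , drop = FALSE]
    pvals <- vapply(levels(cells), function(lv)
      kuiper_test(data$theta_deg[cells == lv],
                  sub$theta_deg[interaction(sub[formula], sep = ":",
                                            lex.order = TRUE) == lv])$p.value,
      numeric(1))
    flagged[r] <- any(pvals < alpha)
    reps[[r]] <- fit_pn_glm(sub, formula, seed = sub_seeds[r], ...)
  }
  cells_lv <- reps[[1]]$summary$cell
  means <- sapply(reps, function(f) f$summary$mean_deg)
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  agg <- data.frame(cell = cells_lv,
                    mean_deg = apply(means, 1, circ_mean_deg),
                    across_rep_sd_deg = apply(means, 1, circ_sd_deg),
                    stringsAsFactors = FALSE)
  structure(list(repetitions = reps, aggregate = agg,
                 subsample_per_stratum = subsample_per_stratum,
                 n_boot = n_boot, flagged_distribution = flagged),
            class = "pn_boot")
}
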