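# Scale-invariance analysis: log-log power-law fits of the hydropathic
# imbalance, bi-phasic (pre/post-inflection) exponents, detection of
# scale-invariant pore regions, the composite dipole-field model and derived
# energetics.

#' Power-law fit in log-log space
#'
#' Ordinary least squares of `log(y)` on `log(x)`: `log y = gamma log x +
#' beta` (natural logarithm), with the Pearson correlation of the same pairs
#' as the goodness measure. Non-positive `y` (or `x`) values are masked with
#' a warning; fewer than 3 surviving points is an error.
#'
#' @param x positive abscissa (scaling index alpha or physical scale l).
#' @param y positive ordinate (e.g. hydropathic imbalance I).
#' @return list with `gamma` (slope), `beta` (intercept), `pc` (Pearson
#'   coefficient) and `n` (points used).
#' @export
powerlaw_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (any(is.finite(y) & y <= 0))
    warning("non-positive values masked in power-law fit")
  if (sum(ok) < 3) stop("fewer than 3 usable points for power-law fit")
  lx <- log(x[ok]); ly <- log(y[ok])
  ft <- stats::lm(ly ~ lx)
  # a flat trace has zero slope and, by convention, zero correlation
  pc <- if (stats::sd(ly) == 0 || stats::sd(lx) == 0) 0 else stats::cor(lx, ly)
  list(gamma = unname(stats::coef(ft)[2]), beta = unname(stats::coef(ft)[1]),
       pc = pc, n = sum(ok))
}

#' Bi-phasic power-law fit of the hydropathic imbalance
#'
#' Fits two power laws to an imbalance trace: the pre-inflection segment
#' `s < l <= xi` and the post-inflection segment `l > xi`. The regression
#' abscissa is either the scaling index alpha (`x_axis = "alpha_index"`, the
#' aggregate-figure convention) or the physical scale l
#' (`x_axis = "physical_l"`, the convention of the composite dipole-field
#' model); segment boundaries are always defined on the physical scale.
#'
#' When the trace carries an atom-count column `N`, the post-inflection
#' segment is capped at the last scale where an atom still enters the sphere:
#' past the outermost atom center all cumulative quantities are constant by
#' definition (the remaining spheres only pad out to the van der Waals outer
#' surface), so those points carry no scaling information.
#'
#' @param trace a `radial_trace`, or any data frame with columns `l`, `I` and
#'   (for `alpha_index`) `alpha`; an `N` column enables the saturation cap.
#' @param s lag-domain end (Angstrom).
#' @param xi inflection scale (Angstrom).
#' @param x_axis `"alpha_index"` or `"physical_l"`.
#' @return an object of class `biphasic_fit` with `gamma_pre`, `beta_pre`,
#'   `pc_pre`, `gamma_post`, `beta_post`, `pc_post` and the ranges used.
#' @export
fit_biphasic <- function(trace, s, xi, x_axis = c("alpha_index", "physical_l")) {
  x_axis <- match.arg(x_axis)
  if (!(s < xi)) stop("need s < xi")
  l <- trace$l
  if (xi <= min(l) || s >= max(l)) stop("s/xi outside the trace's scale range")
  xv <- if (x_axis == "alpha_index") trace$alpha else trace$l
  l_cap <- if (!is.null(trace$N) && any(diff(trace$N) > 0))
    l[max(which(diff(c(trace$N[1] - 1L, trace$N)) > 0))] else max(l)
  pre_idx <- which(l > s & l <= xi)
  post_idx <- which(l > xi & l <= max(l_cap, xi + .Machine$double.eps))
  if (length(pre_idx) < 3 || length(post_idx) < 3)
    stop("a bi-phasic segment has fewer than 3 points")
  pre <- powerlaw_fit(xv[pre_idx], trace$I[pre_idx])
  post <- powerlaw_fit(xv[post_idx], trace$I[post_idx])
  structure(list(
    x_axis = x_axis,
    gamma_pre = pre$gamma, beta_pre = pre$beta, pc_pre = pre$pc,
    gamma_post = post$gamma, beta_post = post$beta, pc_post = post$pc,
    range_pre = c(s, xi), range_post = c(xi, l_cap),
    n_pre = pre$n, n_post = post$n
  ), class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat("Bi-phasic power-law fit (x =", x$x_axis, ")\n")
  cat(sprintf("  pre  (%.2f, %.2f]: gamma = %+.3f, beta = %+.3f, PC = %+.3f (n=%d)\n",
              x$range_pre[1], x$range_pre[2], x$gamma_pre, x$beta_pre, x$pc_pre, x$n_pre))
  cat(sprintf("  post (%.2f, %.2f]: gamma = %+.3f, beta = %+.3f, PC = %+.3f (n=%d)\n",
              x$range_post[1], x$range_post[2], x$gamma_post, x$beta_post, x$pc_post, x$n_post))
  invisible(x)
}

#' @export
coef.biphasic_fit <- function(object, ...) {
  c(gamma_pre = object$gamma_pre, beta_pre = object$beta_pre,
    gamma_post = object$gamma_post, beta_post = object$beta_post)
}

#' Aggregate radial traces across pore points
#'
#' Cross-point statistical summary of a per-point quantity on the shared
#' scaling-index grid: each point's trace is max-normalized, then the per-index
#' mean and 2.5/97.5 percentiles are taken across points. When per-point
#' domain boundaries are supplied, the aggregate boundary indices
#' (`alpha_s`, `alpha_xi`, `alpha_nu`, `alpha_o`) are the means of the
#' per-point indices closest to each boundary scale.
#'
#' @param traces a `radial_traces` list sharing `k_alpha`.
#' @param quantity column to aggregate (`"N"`, `"I"`, `"AE"`, `"h_z"`).
#' @param boundaries optional data frame (one row per point, profile order)
#'   with any of the columns `s`, `xi`, `nu`, `o` in Angstrom.
#' @param normalize max-normalize each per-point trace first (default TRUE).
#' @return an `aggregate_trace` list: `alpha`, `mean`, `lo95`, `hi95`,
#'   `l_mean`, and `alpha_s`/`alpha_xi`/`alpha_nu`/`alpha_o` when available.
#' @export
aggregate_traces <- function(traces, quantity = "N", boundaries = NULL,
                             normalize = TRUE) {
  if (!length(traces)) stop("empty set of traces")
  k <- nrow(traces[[1]])
  if (!all(vapply(traces, nrow, 0L) == k))
    stop("all traces must share the same number of spheres")
  mat <- vapply(traces, function(tr) {
    v <- tr[[quantity]]
    if (normalize) {
      m <- max(abs(v), na.rm = TRUE)
      if (m > 0) v <- v / m
    }
    v
  }, numeric(k))
  mat <- matrix(mat, nrow = k)
  lmat <- vapply(traces, function(tr) tr$l, numeric(k))
  out <- list(
    alpha = seq_len(k),
    mean = rowMeans(mat, na.rm = TRUE),
    lo95 = apply(mat, 1, stats::quantile, 0.025, na.rm = TRUE),
    hi95 = apply(mat, 1, stats::quantile, 0.975, na.rm = TRUE),
    l_mean = rowMeans(matrix(lmat, nrow = k)),
    n_points = length(traces)
  )
  if (!is.null(boundaries)) {
    idx_of <- function(col) {
      if (is.null(boundaries[[col]])) return(NA_real_)
      v <- vapply(seq_along(traces), function(i) {
        b <- boundaries[[col]][i]
        if (!is.finite(b)) return(NA_real_)
        which.min(abs(traces[[i]]$l - b))
      }, 0)
      mean(v, na.rm = TRUE)
    }
    out$alpha_s <- idx_of("s"); out$alpha_xi <- idx_of("xi")
    out$alpha_nu <- idx_of("nu"); out$alpha_o <- idx_of("o")
  }
  class(out) <- "aggregate_trace"
  out
}

#' @export
print.aggregate_trace <- function(x, ...) {
  cat("Aggregate trace over", x$n_points, "pore points,",
      length(x$alpha), "scales\n")
  bs <- c(alpha_s = x$alpha_s, alpha_xi = x$alpha_xi,
          alpha_nu = x$alpha_nu, alpha_o = x$alpha_o)
  bs <- bs[!vapply(bs, is.null, TRUE)]
  if (length(bs))
    cat("  boundary indices:",
        paste(names(bs), sprintf("%.1f", unlist(bs)), sep = " = ",
              collapse = ", "), "\n")
  invisible(x)
}

#' Detect scale-invariant pore regions
#'
#' Maximal contiguous `p_z` intervals over which both bi-phasic Pearson
#' coefficients are strong: `min(|pc_pre|, |pc_post|) >= pc_threshold`.
#'
#' @param per_point data frame with columns `p_z`, `pc_pre`, `pc_post`
#'   (NA rows count as below threshold).
#' @param pc_threshold detection threshold (default 0.97).
#' @return data frame of regions with `z_min`, `z_max`, `n_points`; zero rows
#'   when nothing passes.
#' @export
scale_invariant_regions <- function(per_point, pc_threshold = 0.97) {
  o <- order(per_point$p_z)
  pz <- per_point$p_z[o]
  ok <- pmin(abs(per_point$pc_pre[o]), abs(per_point$pc_post[o])) >= pc_threshold
  ok[is.na(ok)] <- FALSE
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values)
  data.frame(z_min = pz[starts[hit]], z_max = pz[ends[hit]],
             n_points = r$lengths[hit])
}

#' Composite dipole-field model from packing fit and bi-phasic exponents
#'
#' Models the axial dipole-field magnitude as the product of the fitted
#' packing curve and a phase-specific power of the scale:
#' `|h_z|(l) ~ C_phase * n(l) * l^gamma_phase`, with the pre-inflection
#' exponent on `s < l <= xi` and the post-inflection exponent on `l > xi`.
#' The proportionality constants are estimated per phase by least squares on
#' the log scale. Mean absolute relative errors (MAFE) are reported for the
#' pre and post segments and for the extrapolation of the pre-phase model
#' below the lag boundary `l <= s`. The packing-energy model is the dipole
#' model divided by `l`.
#'
#' @param fit a converged `packing_fit` (a non-Richards best model triggers a
#'   warning; the selected sigmoid is still used).
#' @param biphasic a `biphasic_fit` with `x_axis = "physical_l"`.
#' @param trace a `radial_trace` (needs `l`, `h_z`).
#' @return an object of class `chdf_model`: `l`, `model_h` (magnitude),
#'   `model_ae`, `mafe_pre`, `mafe_post`, `mafe_lag`, `orientation` (sign of
#'   the observed axial field) and the per-phase constants.
#' @export
chdf_composite <- function(fit, biphasic, trace) {
  if (!isTRUE(fit$converged)) stop("packing fit did not converge")
  if (fit$model != "richards")
    warning("best packing model is ", fit$model,
            "; composite dipole model evaluated with it nonetheless")
  if (biphasic$x_axis != "physical_l")
    warning("biphasic exponents were fitted on the index axis; ",
            "physical-scale exponents are the intended input")
  l <- trace$l
  habs <- abs(trace$h_z)
  ncurve <- packing_curve(fit$model, fit$par, l)
  s <- fit$s; xi <- fit$xi
  seg <- list(lag = which(l <= s),
              pre = which(l > s & l <= xi),
              post = which(l > xi))
  base <- function(idx, gamma) ncurve[idx] * l[idx]^gamma
  const <- function(idx, gamma) {
    ok <- idx[habs[idx] > 0 & ncurve[idx] > 0]
    if (length(ok) < 1) return(NA_real_)
    exp(mean(log(habs[ok]) - log(ncurve[ok] * l[ok]^gamma)))
  }
  C_pre <- const(seg$pre, biphasic$gamma_pre)
  C_post <- const(seg$post, biphasic$gamma_post)
  model_h <- rep(NA_real_, length(l))
  model_h[seg$lag] <- C_pre * base(seg$lag, biphasic$gamma_pre)
  model_h[seg$pre] <- C_pre * base(seg$pre, biphasic$gamma_pre)
  model_h[seg$post] <- C_post * base(seg$post, biphasic$gamma_post)
  mafe <- function(idx) {
    ok <- idx[habs[idx] > 0]
    if (!length(ok)) return(NA_real_)
    mean(abs(model_h[ok] - habs[ok]) / habs[ok])
  }
  structure(list(
    l = l, model_h = model_h, model_ae = model_h / l,
    C_pre = C_pre, C_post = C_post,
    gamma_pre = biphasic$gamma_pre, gamma_post = biphasic$gamma_post,
    mafe_pre = mafe(seg$pre), mafe_post = mafe(seg$post),
    mafe_lag = mafe(seg$lag),
    orientation = sign(mean(trace$h_z[c(seg$pre, seg$post)]))
  ), class = "chdf_model")
}

#' @export
print.chdf_model <- function(x, ...) {
  cat("Composite dipole-field model\n")
  cat(sprintf("  gamma_pre = %+.3f, gamma_post = %+.3f, orientation = %s\n",
              x$gamma_pre, x$gamma_post,
              if (x$orientation < 0) "out (h_z < 0)" else "in (h_z > 0)"))
  cat(sprintf("  MAFE: pre = %.3g, post = %.3g, lag extrapolation = %.3g\n",
              x$mafe_pre, x$mafe_post, x$mafe_lag))
  invisible(x)
}

#' Coupling energy from the packing-energy trace
#'
#' Maximum of the atom-packing energy over the window between the PD-VSD
#' crossover scale `nu` and the inflection scale `xi` (the pore-domain /
#' voltage-sensor coupling energy), together with the packing energy of the
#' first and last sampled clusters.
#'
#' @param trace a `radial_trace` (needs `l`, `AE`).
#' @param nu crossover scale (Angstrom).
#' @param xi inflection scale (Angstrom), `nu < xi`.
#' @return list with `max` (kcal/mol), `l_at_max`, `first`, `last`.
#' @export
coupling_energy <- function(trace, nu, xi) {
  if (!(nu < xi)) stop("need nu < xi")
  idx <- which(trace$l >= nu & trace$l <= xi)
  if (!length(idx)) stop("empty [nu, xi] window in the trace")
  k <- idx[which.max(trace$AE[idx])]
  list(max = trace$AE[k], l_at_max = trace$l[k],
       first = trace$AE[1], last = trace$AE[nrow(trace)])
}

#' Correlation between inflection and PD-VSD crossover traces
#'
#' Summary of how closely the per-point inflection scale follows the PD-VSD
#' geometrical crossover along the pore: mean and standard deviation of
#' `|xi - nu|`, and Spearman rank correlations computed separately on the two
#' z-sign subsets of the pore axis (a subset with fewer than 3 points reports
#' NA).
#'
#' @param per_point data frame with columns `p_z`, `xi`, `nu`.
#' @return list `mean_dist`, `sd_dist`, `spearman_pos` (p_z > 0),
#'   `spearman_neg` (p_z <= 0).
#' @export
crossover_correlation <- function(per_point) {
  ok <- is.finite(per_point$xi) & is.finite(per_point$nu)
  d <- abs(per_point$xi[ok] - per_point$nu[ok])
  sp <- function(sel) {
    sel <- sel & ok
    if (sum(sel) < 3) return(NA_real_)
    stats::cor(per_point$xi[sel], per_point$nu[sel], method = "spearman")
  }
  list(mean_dist = mean(d), sd_dist = stats::sd(d),
       spearman_pos = sp(per_point$p_z > 0),
       spearman_neg = sp(per_point$p_z <= 0))
}

#' Segment composition of the geometric packing domains
#'
#' Fraction of atoms per segment label within the lag (`dist <= s`),
#' inflection (`s < dist <= o`) and asymptote (`dist > o`) domains around a
#' pore point.
#'
#' @param x an annotated `channel`.
#' @param p pore point (3-vector).
#' @param s lag-domain end (Angstrom).
#' @param o asymptote onset (Angstrom), `o > s`.
#' @return matrix of row-normalized fractions, rows `lag`, `inflection`,
#'   `asymptote`, columns the segment labels present.
#' @export
domain_composition <- function(x, p, s, o) {
  stopifnot(inherits(x, "channel"), o > s)
  d <- .dist_to_point(x, p)
  bin <- cut(d, c(-Inf, s, o, Inf), labels = c("lag", "inflection", "asymptote"))
  tab <- table(bin, x$atoms$segment)
  frac <- prop.table(tab, 1)
  frac[is.nan(frac)] <- 0
  as.matrix(unclass(frac))
}
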