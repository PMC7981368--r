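# End-to-end analysis: geometry profile -> radial traces -> per-point packing
# fits -> bi-phasic exponents -> scale-invariant regions, aggregates and
# energetics, plus report writers.

#' Full hydropathic-scaling analysis of a channel pore
#'
#' Runs the whole pipeline on a prepared (aligned, optionally annotated)
#' channel: pore-axis geometry profile, nested-sphere radial traces, per-point
#' sigmoid packing fits with AIC selection, per-point bi-phasic power-law fits
#' of the hydropathic imbalance, detection of scale-invariant regions,
#' inflection-vs-crossover correlation and cross-point aggregate traces.
#'
#' @param x an aligned `channel` (see [align_channel()]); segment annotation
#'   enables the crossover scale `nu`.
#' @param z_step,z_range pore-axis grid, see [pore_axis_points()].
#' @param k_alpha nested spheres per pore point (default 800).
#' @param pc_threshold Pearson threshold for region detection (default 0.97).
#' @param x_axis regression abscissa for the bi-phasic fits
#'   (`"alpha_index"` or `"physical_l"`).
#' @param use_noise use noise-perturbed hydropathic indices.
#' @param models candidate packing models for [select_packing()].
#' @return object of class `pore_scaling` with elements `profile`, `traces`,
#'   `per_point` (one row per pore point: geometry, packing parameters,
#'   bi-phasic exponents and PCs), `regions`, `crossover`, `aggregate_N`,
#'   `aggregate_I`, `aggregate_biphasic`, `config`.
#' @export
pore_scaling <- function(x, z_step = 0.5, z_range = NULL, k_alpha = 800,
                         pc_threshold = 0.97,
                         x_axis = c("alpha_index", "physical_l"),
                         use_noise = TRUE, models = .packing_models) {
  x_axis <- match.arg(x_axis)
  stopifnot(inherits(x, "channel"))
  has_vsd <- any(x$atoms$domain == "VSD")
  profile <- pore_axis_points(x, z_step = z_step, z_range = z_range,
                              crossover = if (has_vsd) "nearest" else "none")
  traces <- radial_traces(x, profile, k_alpha = k_alpha, use_noise = use_noise)

  can_fit <- k_alpha >= 8
  if (!can_fit)
    warning("k_alpha < 8: packing and bi-phasic fits skipped (degenerate run)")

  rows <- vector("list", nrow(profile))
  fits <- vector("list", nrow(profile))
  for (i in seq_len(nrow(profile))) {
    tr <- traces[[i]]
    row <- data.frame(p_z = profile$p_z[i], R = profile$R[i], D = profile$D[i],
                      L = profile$L[i], nu = profile$nu[i],
                      model = NA_character_, A = NA_real_, t = NA_real_,
                      s = NA_real_, q_tilde = NA_real_, q = NA_real_,
                      xi = NA_real_, o = NA_real_, os = NA_real_,
                      aic = NA_real_, mafe = NA_real_,
                      gamma_pre = NA_real_, gamma_post = NA_real_,
                      pc_pre = NA_real_, pc_post = NA_real_,
                      converged = FALSE, stringsAsFactors = FALSE)
    if (can_fit) {
      fit <- tryCatch(select_packing(tr$l, tr$N, models = models),
                      error = function(e) NULL)
      if (!is.null(fit) && isTRUE(fit$converged)) {
        fits[[i]] <- fit
        row$model <- fit$model
        row$A <- fit$par$A; row$t <- fit$par$t; row$s <- fit$par$s
        row$q_tilde <- fit$par$q_tilde %||% NA_real_
        row$q <- fit$q; row$xi <- fit$xi; row$o <- fit$o; row$os <- fit$os
        row$aic <- fit$aic; row$mafe <- fit$mafe
        row$converged <- TRUE
        bf <- tryCatch(fit_biphasic(tr, fit$s, fit$xi, x_axis = x_axis),
                       error = function(e) NULL)
        if (!is.null(bf)) {
          row$gamma_pre <- bf$gamma_pre; row$gamma_post <- bf$gamma_post
          row$pc_pre <- bf$pc_pre; row$pc_post <- bf$pc_post
        }
      }
    }
    rows[[i]] <- row
  }
  per_point <- do.call(rbind, rows)

  regions <- scale_invariant_regions(per_point, pc_threshold)
  crossover <- if (has_vsd && any(per_point$converged))
    crossover_correlation(per_point) else NULL
  boundaries <- per_point[, c("s", "xi", "nu", "o")]
  agg_N <- aggregate_traces(traces, "N", boundaries = boundaries)
  agg_I <- aggregate_traces(traces, "I", boundaries = boundaries)
  agg_bf <- NULL
  if (any(per_point$converged)) {
    s_bar <- mean(per_point$s, na.rm = TRUE)
    xi_bar <- mean(per_point$xi, na.rm = TRUE)
    pseudo <- data.frame(alpha = agg_I$alpha, l = agg_I$l_mean, I = agg_I$mean)
    agg_bf <- tryCatch(fit_biphasic(pseudo, s_bar, xi_bar, x_axis = "alpha_index"),
                       error = function(e) NULL)
  }

  structure(list(
    profile = profile, traces = traces, per_point = per_point,
    packing_fits = fits, regions = regions, crossover = crossover,
    aggregate_N = agg_N, aggregate_I = agg_I, aggregate_biphasic = agg_bf,
    config = list(z_step = z_step, z_range = z_range, k_alpha = k_alpha,
                  pc_threshold = pc_threshold, x_axis = x_axis,
                  use_noise = use_noise, n_atoms = x$n_atoms)
  ), class = "pore_scaling")
}

#' @export
print.pore_scaling <- function(x, ...) {
  pp <- x$per_point
  cat("Pore hydropathic-scaling analysis\n")
  cat(sprintf("  %d pore points (z in [%.2f, %.2f], step %.2f), k_alpha = %d\n",
              nrow(pp), min(pp$p_z), max(pp$p_z), x$config$z_step,
              x$config$k_alpha))
  cat(sprintf("  packing fits converged at %d/%d points; models: %s\n",
              sum(pp$converged), nrow(pp),
              paste(names(table(pp$model)), table(pp$model), sep = "=",
                    collapse = ", ")))
  if (!is.null(x$aggregate_biphasic))
    cat(sprintf("  aggregate exponents: gamma_pre = %+.2f, gamma_post = %+.2f (PC %+.2f / %+.2f)\n",
                x$aggregate_biphasic$gamma_pre, x$aggregate_biphasic$gamma_post,
                x$aggregate_biphasic$pc_pre, x$aggregate_biphasic$pc_post))
  if (nrow(x$regions))
    cat(sprintf("  scale-invariant region(s): %s\n",
                paste(sprintf("[%.2f, %.2f]", x$regions$z_min, x$regions$z_max),
                      collapse = ", ")))
  else cat("  no scale-invariant region at PC >=", x$config$pc_threshold, "\n")
  if (!is.null(x$crossover))
    cat(sprintf("  |xi - nu| = %.2f +/- %.2f A (Spearman %+0.2f / %+0.2f)\n",
                x$crossover$mean_dist, x$crossover$sd_dist,
                x$crossover$spearman_pos, x$crossover$spearman_neg))
  invisible(x)
}

#' Write the per-point fit table as TSV
#' @param ps a `pore_scaling` object.
#' @param path output file.
#' @export
write_fits_tsv <- function(ps, path) {
  utils::write.table(ps$per_point, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# md5 of a config list (for output provenance)
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Write a JSON analysis report
#'
#' Serializes the scaling analysis (exponents, PCs, regions, crossover
#' statistics, aggregate boundary indices) with the run configuration, its
#' hash and the package version embedded for provenance.
#'
#' @param ps a `pore_scaling` object.
#' @param path output file.
#' @export
write_report_json <- function(ps, path) {
  agg <- ps$aggregate_biphasic
  rep <- list(
    package = "porescale",
    version = as.character(utils::packageVersion("porescale")),
    config = ps$config,
    config_md5 = .config_hash(ps$config),
    n_pore_points = nrow(ps$per_point),
    converged_points = sum(ps$per_point$converged),
    aggregate = if (!is.null(agg)) list(
      gamma_pre = agg$gamma_pre, beta_pre = agg$beta_pre, pc_pre = agg$pc_pre,
      gamma_post = agg$gamma_post, beta_post = agg$beta_post,
      pc_post = agg$pc_post),
    boundary_indices = list(alpha_s = ps$aggregate_I$alpha_s,
                            alpha_xi = ps$aggregate_I$alpha_xi,
                            alpha_nu = ps$aggregate_I$alpha_nu,
                            alpha_o = ps$aggregate_I$alpha_o),
    regions = ps$regions,
    crossover = ps$crossover
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
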