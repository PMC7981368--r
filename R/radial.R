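# Nested-sphere radial sampling around pore points: atom-count trace N,
# cumulative hydropathic dipole field (CHDF) components, hydropathic
# imbalance I = |h_z|/N and atom-packing energy AE = |h_z|/l.

#' Nested sampling-sphere radii
#'
#' `l_alpha = D + alpha * (L - D) / K` for `alpha = 1..K`: `K` radii strictly
#' above the nearest-atom distance `D`, ending exactly at the outer-surface
#' radius `L`.
#'
#' @param D nearest-atom-center distance (Angstrom).
#' @param L outer-surface radius (Angstrom); must exceed `D`.
#' @param k_alpha number of spheres (>= 1).
#' @return numeric vector of length `k_alpha`.
#' @export
sampling_radii <- function(D, L, k_alpha) {
  if (!(L > D)) stop("L must exceed D")
  if (k_alpha < 1) stop("k_alpha must be >= 1")
  D + seq_len(k_alpha) * (L - D) / k_alpha
}

#' Radial sampling traces at a pore point
#'
#' Sorts atom-to-point distances once and computes, by cumulative sums, the
#' per-sphere traces: atom count `N` (atom centers, boundary-inclusive), the
#' signed axial CHDF component `h_z` and the in-plane components
#' (`h_x`, `h_y`, magnitude `h_xy`) of the hydropathic dipole field
#' `sum_i HI_i (c_i - p)` over atoms inside each sphere [kcal*A/mol], the
#' hydropathic imbalance `I = |h_z|/N` (NA where `N = 0`) and the atom-packing
#' energy `AE = |h_z|/l` [kcal/mol].
#'
#' @param x a `channel`.
#' @param p pore point (3-vector).
#' @param k_alpha number of nested spheres (default 800).
#' @param use_noise use the noise-perturbed hydropathic indices (`hi_noisy`)?
#' @return a `radial_trace` data frame with columns
#'   `alpha, l, N, h_x, h_y, h_z, h_xy, I, AE`; attributes `p` and `n_c`.
#' @export
radial_trace <- function(x, p, k_alpha = 800, use_noise = TRUE) {
  stopifnot(inherits(x, "channel"))
  if (x$n_atoms < 1) stop("empty structure")
  d <- .dist_to_point(x, p)
  vdw <- x$atoms$vdw
  D <- min(d); L <- max(d + vdw)
  l <- sampling_radii(D, L, k_alpha)

  o <- order(d)
  ds <- d[o]
  hi <- if (use_noise) x$atoms$hi_noisy[o] else x$atoms$hi[o]
  rx <- (x$atoms$x[o] - p[1]) * hi
  ry <- (x$atoms$y[o] - p[2]) * hi
  rz <- (x$atoms$z[o] - p[3]) * hi

  N <- findInterval(l, ds)            # boundary-inclusive: theta(0) = 1
  csx <- c(0, cumsum(rx)); csy <- c(0, cumsum(ry)); csz <- c(0, cumsum(rz))
  h_x <- csx[N + 1]; h_y <- csy[N + 1]; h_z <- csz[N + 1]
  h_xy <- sqrt(h_x^2 + h_y^2)
  I <- ifelse(N > 0, abs(h_z) / N, NA_real_)
  AE <- abs(h_z) / l

  out <- data.frame(alpha = seq_len(k_alpha), l = l, N = N,
                    h_x = h_x, h_y = h_y, h_z = h_z, h_xy = h_xy,
                    I = I, AE = AE)
  attr(out, "p") <- p
  attr(out, "n_c") <- x$n_atoms
  class(out) <- c("radial_trace", "data.frame")
  out
}

#' Radial traces for every point of a pore profile
#'
#' @param x a `channel`.
#' @param profile a `pore_profile` from [pore_axis_points()].
#' @param k_alpha number of nested spheres per point.
#' @param use_noise see [radial_trace()].
#' @return list of `radial_trace` objects (class `radial_traces`), one per
#'   pore point, in profile order.
#' @export
radial_traces <- function(x, profile, k_alpha = 800, use_noise = TRUE) {
  out <- lapply(profile$p_z, function(z)
    radial_trace(x, c(0, 0, z), k_alpha = k_alpha, use_noise = use_noise))
  names(out) <- sprintf("%.3f", profile$p_z)
  class(out) <- "radial_traces"
  out
}

#' Hydropathic imbalance and packing-energy traces from raw arrays
#'
#' Convenience for pre-computed arrays: `I = |h_z|/N` (entries with `N = 0`
#' masked as NA) and `AE = |h_z|/l`. Errors if no sphere contains any atom.
#'
#' @param N atom-count array.
#' @param h_z signed axial CHDF array.
#' @param l sampling radii.
#' @return list with components `I` and `AE`.
#' @export
hiis_ae <- function(N, h_z, l) {
  stopifnot(length(N) == length(h_z), length(N) == length(l))
  if (all(N == 0)) stop("no atoms sampled")
  list(I = ifelse(N > 0, abs(h_z) / N, NA_real_), AE = abs(h_z) / l)
}

#' Write radial traces as long-format TSV
#'
#' Columns: `p_z, alpha, l, N, h_z, h_xy, I, AE`.
#'
#' @param traces a `radial_traces` list.
#' @param path output file.
#' @export
write_traces_tsv <- function(traces, path) {
  long <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(p_z = attr(tr, "p")[3], alpha = tr$alpha, l = tr$l, N = tr$N,
               h_z = tr$h_z, h_xy = tr$h_xy, I = tr$I, AE = tr$AE)
  }))
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
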