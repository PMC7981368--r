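# Pore-axis geometry: per-point pore radius R, nearest-atom distance D,
# outer-surface radius L, and the PD-VSD geometrical crossover scale nu.

.atom_xyz <- function(x) cbind(x$atoms$x, x$atoms$y, x$atoms$z)

.dist_to_point <- function(x, p) {
  xyz <- .atom_xyz(x)
  sqrt((xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2)
}

#' Pore geometry at a point
#'
#' For a point `p` (usually on the pore axis) returns the pore radius
#' `R = min_i(||c_i - p|| - vdW_i)`, the nearest-atom-center distance
#' `D = min_i ||c_i - p||` and the outer-surface radius
#' `L = max_i(||c_i - p|| + vdW_i)`, all in Angstrom. `R` may be negative at
#' occluded points (an atom's van der Waals sphere covers `p`); it is
#' reported, not clamped.
#'
#' @param x a `channel`.
#' @param p numeric 3-vector.
#' @return named numeric vector `c(R =, D =, L =)`.
#' @export
pore_geometry <- function(x, p) {
  stopifnot(inherits(x, "channel"))
  if (x$n_atoms < 1) stop("empty structure")
  d <- .dist_to_point(x, p)
  c(R = min(d - x$atoms$vdw), D = min(d), L = max(d + x$atoms$vdw))
}

#' PD-VSD geometrical crossover scale
#'
#' Distance from `p` at which voltage-sensing-domain (VSD) structure begins.
#' The default (`mode = "nearest"`) is the distance from `p` to the nearest
#' VSD-labeled atom. The alternative `mode = "fraction"` returns the smallest
#' sampled distance at which VSD atoms make up at least a fraction `f` of all
#' atoms within that distance.
#'
#' @param x a `channel` with segments annotated (see [annotate_segments()]).
#' @param p numeric 3-vector.
#' @param mode `"nearest"` or `"fraction"`.
#' @param f VSD fraction threshold for `mode = "fraction"`.
#' @return crossover scale nu in Angstrom.
#' @export
crossover_scale <- function(x, p, mode = c("nearest", "fraction"), f = 0.1) {
  mode <- match.arg(mode)
  is_vsd <- x$atoms$domain == "VSD"
  if (!any(is_vsd)) stop("segment map required: no VSD-labeled atoms")
  d <- .dist_to_point(x, p)
  if (mode == "nearest") return(min(d[is_vsd]))
  o <- order(d)
  frac <- cumsum(is_vsd[o]) / seq_along(d)
  hit <- which(frac >= f)
  if (!length(hit)) stop("VSD fraction threshold never reached")
  d[o][hit[1]]
}

#' Build the pore-axis point set with its geometry profile
#'
#' Places points at (0, 0, z) on a uniform z-grid along the aligned pore axis
#' and evaluates [pore_geometry()] (and, when segments are annotated,
#' [crossover_scale()]) at each. The default z-range is the extent of the open
#' pore lumen, i.e. where the pore radius R is positive.
#'
#' @param x an aligned `channel`.
#' @param z_step grid spacing in Angstrom (default 0.5).
#' @param z_range length-2 numeric `c(z_min, z_max)`; default: the R > 0
#'   extent. A range outside the atomic z-extent triggers a warning.
#' @param crossover `"nearest"`, `"fraction"` or `"none"`; with `"none"` the
#'   `nu` column is `NA` (no segment map needed).
#' @param f fraction threshold, see [crossover_scale()].
#' @return a `pore_profile` data frame with columns `p_z, R, D, L, nu`.
#' @export
pore_axis_points <- function(x, z_step = 0.5, z_range = NULL,
                             crossover = c("nearest", "fraction", "none"),
                             f = 0.1) {
  stopifnot(inherits(x, "channel"))
  crossover <- match.arg(crossover)
  if (!x$aligned) warning("channel is not aligned; z-grid may not follow the pore axis")
  zext <- range(x$atoms$z)
  if (is.null(z_range)) {
    scan <- seq(zext[1], zext[2], by = z_step)
    rr <- vapply(scan, function(z) pore_geometry(x, c(0, 0, z))["R"], 0)
    open <- which(rr > 0)
    if (!length(open)) stop("no open lumen found (R <= 0 everywhere); supply z_range")
    z_range <- c(scan[min(open)], scan[max(open)])
  } else if (z_range[1] > zext[2] || z_range[2] < zext[1]) {
    warning("z_range lies outside the atomic z-extent")
  }
  zs <- seq(z_range[1], z_range[2], by = z_step)
  if (!length(zs)) stop("empty pore-axis grid")
  has_vsd <- any(x$atoms$domain == "VSD")
  rows <- lapply(zs, function(z) {
    g <- pore_geometry(x, c(0, 0, z))
    nu <- if (crossover != "none" && has_vsd)
      crossover_scale(x, c(0, 0, z), mode = crossover, f = f) else NA_real_
    data.frame(p_z = z, R = g[["R"]], D = g[["D"]], L = g[["L"]], nu = nu)
  })
  out <- do.call(rbind, rows)
  attr(out, "z_step") <- z_step
  class(out) <- c("pore_profile", "data.frame")
  out
}

#' Write a pore profile as TSV
#' @param profile a `pore_profile`.
#' @param path output file.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
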