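# Synthetic fixtures: noisy sigmoid packing traces, exact power-law imbalance
# traces, and toy protonated-like tetramer structures whose radial cumulative
# atom count around a designated axis point follows a prescribed sigmoid and
# whose axial hydropathic dipole follows a prescribed bi-phasic power law.
#
# The toy channel is built from spherical shells around the packing center.
# Base atoms are replicated by exact 4-fold rotation about z ((x,y) -> (-y,x),
# exact even after coordinates are rounded to PDB precision) and by inversion
# through the center, which makes the mass center, the z inertia eigenvector
# and the cancellation of the in-plane dipole component machine-exact.

#' Simulate a sigmoid packing trace
#'
#' Model curve plus iid Gaussian noise, optionally clipped to be
#' non-decreasing.
#'
#' @param model,par model and parameters, see [packing_curve()].
#' @param noise_sd Gaussian noise standard deviation (on the curve's scale).
#' @param k_alpha number of trace points.
#' @param l_range scale range covered by the trace.
#' @param seed RNG seed (local; global RNG state is restored).
#' @param monotone clip the noisy trace to a non-decreasing one.
#' @return data frame with columns `l`, `n`.
#' @export
sim_packing_trace <- function(model = "richards",
                              par = list(A = 1.05, t = 0.2, s = 18.02, q_tilde = 0.54),
                              noise_sd = 0, k_alpha = 800,
                              l_range = c(5, 45), seed = NULL,
                              monotone = FALSE) {
  l <- seq(l_range[1], l_range[2], length.out = k_alpha)
  n <- packing_curve(model, par, l)
  if (noise_sd > 0)
    n <- n + with_seed(seed, stats::rnorm(k_alpha, 0, noise_sd))
  if (monotone) n <- cummax(n)
  data.frame(l = l, n = n)
}

#' Simulate a power-law hydropathic-imbalance trace
#'
#' `I = exp(beta) * x^gamma * exp(eps)` with `eps ~ N(0, noise_sd^2)`.
#'
#' @param gamma exponent.
#' @param beta log-scale intercept.
#' @param x positive abscissa vector.
#' @param noise_sd multiplicative log-normal noise level.
#' @param seed RNG seed.
#' @return data frame with columns `x`, `I`.
#' @export
sim_powerlaw_hiis <- function(gamma, beta, x = 1:100, noise_sd = 0, seed = NULL) {
  stopifnot(all(x > 0))
  eps <- if (noise_sd > 0) with_seed(seed, stats::rnorm(length(x), 0, noise_sd)) else 0
  data.frame(x = x, I = exp(beta) * x^gamma * exp(eps))
}

# exact 4-fold rotation copies of (x, y): k = 0..3 applications of
# (x, y) -> (-y, x); exact under decimal rounding
.rot4 <- function(x, y) {
  list(cbind(x, y), cbind(-y, x), cbind(-x, -y), cbind(y, -x))
}

#' Generate a toy protonated-like tetramer channel
#'
#' Places atoms on spherical shells around the packing center (the origin) so
#' that the cumulative atom count within distance `l` follows the requested
#' sigmoid, keeps a cylindrical lumen of radius `lumen_radius` clear along z,
#' biases shell directions toward the poles (so the smallest-inertia axis is
#' z), and assigns per-atom hydropathic indices shell-by-shell so that the
#' axial dipole-field magnitude follows `|h_z|(l) = C N(l) l^gamma` with the
#' pre-inflection exponent below the packing inflection scale and the
#' post-inflection exponent above it (continuous at the inflection), with the
#' requested field orientation. A narrow 4-fold ring at `constriction_z`
#' provides the pore's narrowest point; a wide counter-ring mirrored in z
#' keeps the mass center exactly at the origin. A fraction of atoms are
#' hydrogens so the structure passes the protonation check.
#'
#' Per-atom indices are stored in the PDB B-factor column (3 decimals); load
#' the file with `read_channel(..., hi_source = "bfactor")`. Shells are
#' numbered as residues, so a segment map over residue (= shell) ranges can
#' label an inner pore-domain and an outer voltage-sensing region; the
#' returned `$segment_map` labels shells inside `pd_radius` as S6 (PD) and
#' the rest as S1 (VSD).
#'
#' @param n_atoms target cloud size (rounded to multiples of 8 per shell).
#' @param packing list with `model` and parameters of the planted sigmoid
#'   (on the normalized count scale, asymptote ~ 1).
#' @param gamma_pre,gamma_post planted pre-/post-inflection dipole exponents.
#' @param orientation sign of the planted axial field (-1 = "out" state).
#' @param l_range radial extent of the shells (Angstrom); the lower end must
#'   exceed `lumen_radius`.
#' @param shell_step shell spacing (Angstrom).
#' @param lumen_radius clear cylindrical lumen radius (Angstrom).
#' @param constriction_z,constriction_radius location and radius of the
#'   narrowest ring.
#' @param h_fraction fraction of shell atoms written as hydrogens.
#' @param hi_max largest per-atom index magnitude after scaling.
#' @param pd_radius shells within this radius are labeled pore-domain in the
#'   returned segment map.
#' @param seed RNG seed.
#' @param path optional output PDB path; when given the structure is written.
#' @return list of class `toy_channel`: `atoms` (data frame), `params`
#'   (planted truth: packing parameters, `xi`, `s`, `o`, exponents, scale
#'   `C`), `segment_map`, `path`.
#' @export
sim_channel <- function(n_atoms = 4000,
                        packing = list(model = "richards", A = 1, t = 0.2,
                                       s = 18.02, q_tilde = 0.54),
                        gamma_pre = 2.27, gamma_post = -4.36,
                        orientation = -1,
                        l_range = c(8, 27.5), shell_step = 0.25,
                        lumen_radius = 6,
                        constriction_z = -10, constriction_radius = 3,
                        h_fraction = 0.25, hi_max = 1.5,
                        pd_radius = 19, seed = 1, path = NULL) {
  stopifnot(l_range[1] > lumen_radius, n_atoms >= 200)
  model <- packing$model
  par <- packing[setdiff(names(packing), "model")]
  shells <- seq(l_range[1], l_range[2], by = shell_step)
  K <- length(shells)
  curve <- packing_curve(model, par, shells)
  if (any(diff(curve) < -1e-9))
    stop("infeasible fixture: planted packing curve must be non-decreasing")
  cum_target <- round(n_atoms * cummax(curve) / max(curve) / 8) * 8
  cum_target <- cummax(cum_target)
  n_shell <- diff(c(0, cum_target))

  atoms <- with_seed(seed, {
    rows <- vector("list", K)
    for (k in seq_len(K)) {
      nk <- n_shell[k]
      if (nk == 0) next
      m <- nk / 8                      # 4 rotations x inversion
      lk <- shells[k]
      u_max <- sqrt(1 - (lumen_radius / lk)^2)
      u <- u_max * stats::runif(m)^(1 / 3)      # pole-biased -> elongated in z
      phi <- stats::runif(m, 0, pi / 2)
      rho <- lk * sqrt(1 - u^2)
      bx <- round(rho * cos(phi), 3)
      by <- round(rho * sin(phi), 3)
      bz <- round(lk * u, 3)
      el <- ifelse(stats::runif(m) < h_fraction, "H", "C")
      rot <- .rot4(bx, by)
      xs <- unlist(lapply(rot, function(r) r[, 1]))
      ys <- unlist(lapply(rot, function(r) r[, 2]))
      zs <- rep(bz, 4)
      chain <- rep(c("A", "B", "C", "D"), each = m)
      elem <- rep(el, 4)
      # inversion partners
      rows[[k]] <- data.frame(
        element = c(elem, elem),
        chain = c(chain, chain),
        res_seq = k,
        x = c(xs, -xs), y = c(ys, -ys), z = c(zs, -zs),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })

  ring <- function(radius, z, res) {
    ang <- c(0.35, 1.15)
    bx <- round(radius * cos(ang), 3); by <- round(radius * sin(ang), 3)
    rot <- .rot4(bx, by)
    data.frame(element = "C", chain = rep(c("A", "B", "C", "D"), each = 2),
               res_seq = res,
               x = unlist(lapply(rot, function(r) r[, 1])),
               y = unlist(lapply(rot, function(r) r[, 2])),
               z = round(z, 3), stringsAsFactors = FALSE)
  }
  rings <- rbind(ring(constriction_radius, constriction_z, K + 1),
                 ring(3 * lumen_radius, -constriction_z, K + 2))
  atoms <- rbind(atoms, rings)

  # planted dipole: |h_z|(l) = C * N(l) * l^gamma, continuous at xi.
  # Evaluation radii sit just above the 1e-3 coordinate rounding slop so each
  # nominal shell is wholly inside its radius; dipole increments are assigned
  # to actual distance bands, carrying an increment forward when a band has
  # no usable atoms (e.g. a fully saturated stretch of the sigmoid).
  xi <- packing_inflection(model, par,
    method = if (model == "modified_gompertz") "numeric" else "closed")
  dist <- sqrt(atoms$x^2 + atoms$y^2 + atoms$z^2)
  r_eval <- shells + 0.005
  N_real <- vapply(r_eval, function(r) sum(dist <= r), 0L)
  h_unit <- ifelse(r_eval <= xi,
                   N_real * r_eval^gamma_pre,
                   N_real * xi^(gamma_pre - gamma_post) * r_eval^gamma_post)
  dh <- diff(c(0, h_unit))
  w <- rep(0, nrow(atoms))
  is_cloud <- atoms$res_seq <= K
  band <- findInterval(dist, r_eval, left.open = TRUE) + 1L  # dist <= r_eval[band]
  carry <- 0
  for (k in seq_len(K)) {
    idx <- which(is_cloud & band == k & atoms$z != 0)
    need <- dh[k] + carry
    if (!length(idx)) { carry <- need; next }
    zz2 <- sum(atoms$z[idx]^2)
    w[idx] <- need / zz2 * atoms$z[idx]
    carry <- 0
  }
  Cscale <- hi_max / max(abs(w))
  atoms$hi <- round(orientation * Cscale * w, 3)

  atoms$serial <- seq_len(nrow(atoms))
  atoms$res_name <- "TOY"
  cnt <- stats::ave(seq_len(nrow(atoms)), atoms$res_seq, atoms$chain,
                    FUN = seq_along)
  atoms$atom_name <- paste0(atoms$element, (cnt - 1) %% 99 + 1)

  seg_shells <- which(shells <= pd_radius)
  segment_map <- data.frame(
    chain = "*",
    res_start = c(1, max(seg_shells) + 1),
    res_end = c(max(seg_shells), K),   # rings (K+1, K+2) stay unmapped
    segment = c("S6", "S1"),
    stringsAsFactors = FALSE
  )

  out <- structure(list(
    atoms = atoms,
    params = list(model = model, par = par, xi = xi, s = par$s,
                  o = par$s + par$A / par$t,
                  gamma_pre = gamma_pre, gamma_post = gamma_post,
                  orientation = orientation, C = Cscale,
                  shells = shells, N_shell = N_real,
                  constriction_z = constriction_z,
                  lumen_radius = lumen_radius,
                  nu = shells[max(seg_shells) + 1]),
    segment_map = segment_map,
    path = path
  ), class = "toy_channel")
  if (!is.null(path)) write_pdb(atoms, path)
  out
}

#' Write atoms as a fixed-width PDB file
#'
#' Minimal strict-column PDB writer used for synthetic fixtures; per-atom
#' hydropathic indices (column `hi`, when present) go into the B-factor field
#' with 3 decimals.
#'
#' @param atoms data frame with `serial`, `atom_name`, `res_name`, `chain`,
#'   `res_seq`, `x`, `y`, `z`, `element` and optionally `hi`.
#' @param path output file.
#' @export
write_pdb <- function(atoms, path) {
  b <- if (!is.null(atoms$hi)) atoms$hi else 0
  name4 <- ifelse(nchar(atoms$atom_name) < 4,
                  sprintf(" %-3s", atoms$atom_name),
                  substr(atoms$atom_name, 1, 4))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.3f          %2s",
    atoms$serial %% 100000, name4, atoms$res_name, atoms$chain,
    atoms$res_seq %% 10000, atoms$x, atoms$y, atoms$z, 1.00, b,
    atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @export
print.toy_channel <- function(x, ...) {
  cat("Toy channel fixture:", nrow(x$atoms), "atoms,",
      length(x$params$shells), "shells\n")
  cat(sprintf("  planted %s packing (xi = %.2f A), exponents %+0.2f / %+0.2f\n",
              x$params$model, x$params$xi, x$params$gamma_pre,
              x$params$gamma_post))
  invisible(x)
}
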