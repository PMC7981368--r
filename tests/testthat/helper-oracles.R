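# Helpers: in-memory channel builder and independent brute-force oracles.

.vsd_labels <- c("S1", "S2", "S3", "S4", "S4S5_linker")
.pd_labels <- c("S5", "P_helix", "SF", "P2_helix", "S6")

# build a channel object directly (no PDB round trip) for unit tests
mk_channel <- function(xyz, mass = 12.011, vdw = 1.7, hi = 0.5,
                       element = "C", segment = "other",
                       res_seq = 1, chain = "A", aligned = TRUE) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  seg <- rep_len(segment, n)
  atoms <- data.frame(
    serial = seq_len(n), element = rep_len(element, n),
    atom_name = "C1", res_name = "TOY",
    res_seq = rep_len(res_seq, n), chain = rep_len(chain, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = rep_len(mass, n), vdw = rep_len(vdw, n),
    hi = rep_len(hi, n), hi_noisy = rep_len(hi, n),
    segment = seg,
    domain = ifelse(seg %in% .vsd_labels, "VSD",
                    ifelse(seg %in% .pd_labels, "PD", "other")),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, n_atoms = n, total_mass = sum(atoms$mass),
                 mass_center = c(0, 0, 0), rotation = diag(3),
                 aligned = aligned, source = "in-memory"),
            class = "channel")
}

rand_cloud <- function(n, seed, spread = c(10, 10, 25)) {
  set.seed(seed)
  cbind(rnorm(n, 0, spread[1]), rnorm(n, 0, spread[2]), rnorm(n, 0, spread[3]))
}

# exhaustive O(N) loop over atoms, one explicit min/max pass
brute_geometry <- function(ch, p) {
  R <- Inf; D <- Inf; L <- -Inf
  for (i in seq_len(nrow(ch$atoms))) {
    d <- sqrt((ch$atoms$x[i] - p[1])^2 + (ch$atoms$y[i] - p[2])^2 +
                (ch$atoms$z[i] - p[3])^2)
    R <- min(R, d - ch$atoms$vdw[i])
    D <- min(D, d)
    L <- max(L, d + ch$atoms$vdw[i])
  }
  c(R = R, D = D, L = L)
}

# independent per-sphere recount (distances recomputed for every sphere)
brute_trace <- function(ch, p, radii, use_noise = FALSE) {
  hi <- if (use_noise) ch$atoms$hi_noisy else ch$atoms$hi
  dx <- ch$atoms$x - p[1]; dy <- ch$atoms$y - p[2]; dz <- ch$atoms$z - p[3]
  N <- integer(length(radii))
  hx <- hy <- hz <- numeric(length(radii))
  for (a in seq_along(radii)) {
    d <- sqrt(dx^2 + dy^2 + dz^2)       # recompute per sphere on purpose
    sel <- d <= radii[a]
    N[a] <- sum(sel)
    hx[a] <- sum(hi[sel] * dx[sel])
    hy[a] <- sum(hi[sel] * dy[sel])
    hz[a] <- sum(hi[sel] * dz[sel])
  }
  list(N = N, h_x = hx, h_y = hy, h_z = hz)
}

# brute-force inertia tensor (explicit per-atom accumulation) -> smallest
# moment eigenvector
brute_principal_axis <- function(xyz, mass) {
  Iten <- matrix(0, 3, 3)
  for (i in seq_len(nrow(xyz))) {
    r <- xyz[i, ]
    Iten <- Iten + mass[i] * (sum(r^2) * diag(3) - tcrossprod(r))
  }
  ev <- eigen(Iten, symmetric = TRUE)
  ev$vectors[, 3]
}

# shared toy-channel fixture (generated once per test run)
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- file.path(tempdir(), "porescale_toy.pdb")
      cache <<- sim_channel(n_atoms = 2400, seed = 42, path = path)
    }
    cache
  }
})
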