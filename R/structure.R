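# Channel structure: parse a protonated PDB, attach chemistry, center on the
# molecular mass center, align the principal pore axis with z and annotate
# segments/domains.

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive an element symbol from a PDB atom name when the element column is
# blank (strip digits/primes; recognise two-letter symbols)
.element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", toupper(trimws(name)))
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "CU", "SE", "NA", "LI", "SI")
  el <- substr(nm, 1, 1)
  el2 <- substr(nm, 1, 2)
  ifelse(el2 %in% two, el2, el)
}

#' Read a protonated channel structure from a PDB file
#'
#' Parses ATOM records (HETATM optionally), resolves alternate locations to
#' the highest-occupancy conformer, attaches per-atom mass, van der Waals
#' radius and hydropathic index from the chemistry tables, and optionally adds
#' the weak Gaussian noise to the hydropathic indices that keeps the dipole
#' field non-degenerate at exactly symmetric configurations.
#'
#' @param path PDB file. Must contain hydrogens (a protonated structure).
#' @param chem `chemistry_tables()` object.
#' @param hi_source `"table"` looks indices up in `chem`; `"bfactor"` reads
#'   them from the B-factor column (used by the synthetic fixtures, which
#'   store their planted per-atom indices there).
#' @param include_het keep HETATM records (waters/ligands)? Default `FALSE`.
#' @param hi_noise add Gaussian noise to the hydropathic indices?
#' @param noise_sd standard deviation of the noise (default 0.001).
#' @param noise_seed RNG seed for the noise, applied once at load (default 0).
#' @return an object of class `channel`: a list with `atoms` (data frame with
#'   coordinates, `mass`, `vdw`, `hi`, `hi_noisy`, `segment`, `domain`),
#'   `n_atoms`, `total_mass`, plus centering/rotation metadata.
#' @export
read_channel <- function(path, chem = chemistry_tables(),
                         hi_source = c("table", "bfactor"),
                         include_het = FALSE,
                         hi_noise = TRUE, noise_sd = 0.001, noise_seed = 0) {
  hi_source <- match.arg(hi_source)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (!include_het) a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms parsed from ", path)

  # altLoc: keep the highest-occupancy conformer per (chain, residue, atom)
  alt <- trimws(ifelse(is.na(a$alt), "", a$alt))
  if (any(nzchar(alt))) {
    occ <- ifelse(is.na(a$o), 1, a$o)
    key <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert),
                 a$elety, sep = "|")
    ord <- order(-occ)
    first <- ord[!duplicated(key[ord])]
    a <- a[sort(first), , drop = FALSE]
  }

  element <- toupper(trimws(a$elesy %||% ""))
  blank <- is.na(element) | !nzchar(element)
  element[blank] <- .element_from_name(a$elety[blank])
  if (!any(element %in% c("H", "D")))
    stop("structure appears unprotonated: no hydrogen atoms found")

  serial <- a$eleno
  mass <- chem_mass(chem, element, serial)
  vdw  <- chem_vdw(chem, element, serial)
  hi <- if (hi_source == "bfactor") {
    as.numeric(a$b)
  } else {
    chem_hi(chem, a$resid, a$elety, element, serial)
  }
  if (anyNA(hi)) stop("hydropathic index missing for atom serial ",
                      serial[which(is.na(hi))[1]])

  hi_noisy <- if (hi_noise) {
    hi + with_seed(noise_seed, stats::rnorm(length(hi), 0, noise_sd))
  } else hi

  atoms <- data.frame(
    serial = serial, element = element,
    atom_name = trimws(a$elety), res_name = trimws(a$resid),
    res_seq = a$resno, chain = a$chain %||% "A",
    x = a$x, y = a$y, z = a$z,
    mass = mass, vdw = vdw, hi = hi, hi_noisy = hi_noisy,
    segment = "other", domain = "other",
    stringsAsFactors = FALSE
  )

  structure(list(
    atoms = atoms,
    n_atoms = nrow(atoms),
    total_mass = sum(mass),
    mass_center = c(0, 0, 0),
    rotation = diag(3),
    aligned = FALSE,
    source = path
  ), class = "channel")
}

# mass-weighted inertia tensor of a coordinate matrix (about the origin)
.inertia_tensor <- function(xyz, mass) {
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  Ixx <- sum(mass * (y^2 + z^2))
  Iyy <- sum(mass * (x^2 + z^2))
  Izz <- sum(mass * (x^2 + y^2))
  Ixy <- -sum(mass * x * y)
  Ixz <- -sum(mass * x * z)
  Iyz <- -sum(mass * y * z)
  matrix(c(Ixx, Ixy, Ixz, Ixy, Iyy, Iyz, Ixz, Iyz, Izz), 3, 3)
}

#' Center a channel on its mass center and align the pore axis with z
#'
#' Translates the structure so the mass-weighted centroid sits at the origin
#' and rotates the principal axis with the smallest moment of inertia (the
#' long axis of the tetramer, a proxy for the pore axis) onto the z-axis.
#' The z orientation (extracellular to intracellular) cannot be inferred from
#' coordinates alone; `flip = TRUE` rotates the structure by 180 degrees about
#' x so that z changes sign.
#'
#' @param x a `channel`.
#' @param axis optional explicit pore-axis 3-vector overriding the inertia
#'   eigenvector.
#' @param flip flip the z direction after alignment.
#' @return the centered/aligned `channel`, with the cumulative rotation in
#'   `$rotation` and the original mass center in `$mass_center`.
#' @export
align_channel <- function(x, axis = NULL, flip = FALSE) {
  stopifnot(inherits(x, "channel"))
  a <- x$atoms
  xyz <- cbind(a$x, a$y, a$z)
  com <- colSums(xyz * a$mass) / sum(a$mass)
  xyz <- sweep(xyz, 2, com)

  if (is.null(axis)) {
    Iten <- .inertia_tensor(xyz, a$mass)
    ev <- eigen(Iten, symmetric = TRUE)       # values descending
    vals <- rev(ev$values)                    # ascending
    if ((vals[2] - vals[1]) <= 1e-9 * max(abs(vals)))
      stop("degenerate inertia tensor: principal pore axis is ambiguous")
    offd <- max(abs(Iten[upper.tri(Iten)]))
    if (offd <= 1e-9 * max(abs(diag(Iten)))) {
      # already diagonal (symmetric fixture, or a second call): pick
      # coordinate axes directly so the operation is exactly idempotent
      v3 <- diag(3)[, which.min(diag(Iten))]
      v1 <- diag(3)[, which.max(diag(Iten))]
    } else {
      v3 <- ev$vectors[, 3]                   # smallest moment -> pore axis
      v1 <- ev$vectors[, 1]                   # largest moment
    }
  } else {
    v3 <- axis / sqrt(sum(axis^2))
    seed <- if (abs(v3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v1 <- seed - sum(seed * v3) * v3
    v1 <- v1 / sqrt(sum(v1^2))
  }
  # canonical signs, then a right-handed frame with v3 -> z
  if (v3[3] < 0 || (v3[3] == 0 && v3[1] < 0)) v3 <- -v3
  if (v1[1] < 0 || (v1[1] == 0 && v1[2] < 0)) v1 <- -v1
  v1 <- v1 - sum(v1 * v3) * v3
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(v3[2] * v1[3] - v3[3] * v1[2],
          v3[3] * v1[1] - v3[1] * v1[3],
          v3[1] * v1[2] - v3[2] * v1[1])
  R <- rbind(v1, v2, v3)
  xyz <- xyz %*% t(R)
  if (flip) {
    Rf <- diag(c(1, -1, -1))          # 180 deg about x: z -> -z
    xyz <- xyz %*% t(Rf)
    R <- Rf %*% R
  }
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  if (!x$aligned) x$mass_center <- com        # original-frame mass center
  x$rotation <- R %*% x$rotation
  x$aligned <- TRUE
  x
}

.vsd_segments <- c("S1", "S2", "S3", "S4", "S4S5_linker")
.pd_segments  <- c("S5", "P_helix", "SF", "P2_helix", "S6")

segment_domain <- function(segment) {
  ifelse(segment %in% .vsd_segments, "VSD",
         ifelse(segment %in% .pd_segments, "PD", "other"))
}

#' Read a segment-annotation map
#'
#' Tab-separated file with header `chain res_start res_end segment`; `chain`
#' may be `*` to match every chain. Segments are typically the transmembrane
#' labels S1..S6, S4S5_linker, P_helix, SF, P2_helix.
#'
#' @param path TSV file.
#' @return data frame usable by [annotate_segments()].
#' @export
read_segment_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chain", "res_start", "res_end", "segment")
  if (!all(need %in% names(m)))
    stop("segment map must have columns: ", paste(need, collapse = ", "))
  m
}

#' Annotate atoms with segment and domain labels
#'
#' Labels every atom whose residue number falls in a mapped range with the
#' range's segment; unmapped residues stay `"other"`. Segments S1-S4 and the
#' S4-S5 linker map to the voltage-sensing domain (VSD); S5, S6, the P-helices
#' and the selectivity filter map to the pore domain (PD).
#'
#' @param x a `channel`.
#' @param map data frame with columns `chain` (or `"*"`), `res_start`,
#'   `res_end`, `segment`. Overlapping ranges (on the same chain) are an
#'   error.
#' @return the annotated `channel`.
#' @export
annotate_segments <- function(x, map) {
  stopifnot(inherits(x, "channel"))
  if (nrow(map) == 0) {
    x$atoms$segment <- "other"
    x$atoms$domain <- "other"
    return(x)
  }
  # overlap check: two entries clash if their chains can match and ranges meet
  if (nrow(map) > 1) {
    for (i in seq_len(nrow(map) - 1)) for (j in (i + 1):nrow(map)) {
      chains_meet <- map$chain[i] == "*" || map$chain[j] == "*" ||
        map$chain[i] == map$chain[j]
      if (chains_meet &&
          map$res_start[i] <= map$res_end[j] &&
          map$res_start[j] <= map$res_end[i])
        stop("overlapping ranges in segment map (rows ", i, " and ", j, ")")
    }
  }
  seg <- rep("other", nrow(x$atoms))
  for (k in seq_len(nrow(map))) {
    hit <- x$atoms$res_seq >= map$res_start[k] &
      x$atoms$res_seq <= map$res_end[k] &
      (map$chain[k] == "*" | x$atoms$chain == map$chain[k])
    seg[hit] <- map$segment[k]
  }
  x$atoms$segment <- seg
  x$atoms$domain <- segment_domain(seg)
  x
}

#' @export
print.channel <- function(x, ...) {
  cat("Channel structure:", x$n_atoms, "atoms,",
      format(x$total_mass, digits = 6), "Da\n")
  cat("  aligned:", x$aligned)
  if (x$aligned)
    cat("  (mass center was [", paste(sprintf("%.2f", x$mass_center), collapse = ", "), "])")
  cat("\n")
  segs <- table(x$atoms$domain)
  cat("  domains:", paste(names(segs), segs, sep = "=", collapse = "  "), "\n")
  invisible(x)
}
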