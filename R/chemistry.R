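# Bundled chemistry: van der Waals radii, atomic masses and the per-atom
# hydropathic dichotomy. All three are plain lookup tables that the user can
# override per element or per (residue, atom name), either programmatically or
# from a YAML file.

# Bondi van der Waals radii [Angstrom]
.default_vdw <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  NA. = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.63,
  MN = 1.73, CU = 1.40, SE = 1.90, B = 1.92, SI = 2.10
)

# standard atomic weights [Da]
.default_mass <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  FE = 55.845, MN = 54.938, CU = 63.546, SE = 78.971, B = 10.81, SI = 28.085
)

# element-level hydropathic fallback: carbon/carbon-bound hydrogen apolar
# (+0.5), heteroatoms and everything ionizable polar (-0.5)
.default_hi_element <- c(
  C = 0.5, H = 0.5, D = 0.5,
  N = -0.5, O = -0.5, S = -0.5, P = -0.5,
  F = -0.5, CL = -0.5, BR = -0.5, I = -0.5,
  NA. = -0.5, K = -0.5, MG = -0.5, CA = -0.5, ZN = -0.5, FE = -0.5,
  MN = -0.5, CU = -0.5, SE = -0.5, B = 0.5, SI = 0.5
)

# carbons reclassified as polar: backbone carbonyl plus carboxylate / amide /
# guanidinium centres
.polar_carbons <- list(
  "*"   = "C",
  ASP   = "CG",  ASN = "CG",
  GLU   = "CD",  GLN = "CD",
  ARG   = "CZ"
)

# backbone amide hydrogens (several naming conventions)
.polar_h_backbone <- c("H", "HN", "H1", "H2", "H3", "HT1", "HT2", "HT3",
                       "1H", "2H", "3H", "HXT")

# side-chain hydrogens bound to N/O/S heavy atoms
.polar_h_side <- list(
  SER = c("HG", "HG1"),
  THR = "HG1",
  TYR = "HH",
  CYS = c("HG", "HG1", "HSG"),
  LYS = c("HZ1", "HZ2", "HZ3", "1HZ", "2HZ", "3HZ"),
  ARG = c("HE", "HH11", "HH12", "HH21", "HH22",
          "1HH1", "2HH1", "1HH2", "2HH2"),
  ASN = c("HD21", "HD22", "1HD2", "2HD2"),
  GLN = c("HE21", "HE22", "1HE2", "2HE2"),
  HIS = c("HD1", "HE2"),
  TRP = "HE1"
)

#' Chemistry lookup tables
#'
#' Builds the set of per-element / per-atom tables used to attach masses, van
#' der Waals radii and hydropathic indices to parsed atoms. Defaults are Bondi
#' radii, standard atomic weights and a rule-based atomic hydropathic
#' dichotomy (+0.5 apolar / -0.5 polar per atom): nitrogen, oxygen, sulfur,
#' phosphorus, ions and the hydrogens bound to them are polar; carbons and
#' carbon-bound hydrogens are apolar, except carbonyl, carboxylate, amide and
#' guanidinium carbons which are polar. Every value can be overridden.
#'
#' @param vdw named numeric vector/list of van der Waals radii by element
#'   symbol (Angstrom), merged over the defaults.
#' @param masses named numeric vector/list of atomic masses by element (Da).
#' @param hi_element named numeric vector/list, element-level hydropathic
#'   index fallback.
#' @param hi_atom named numeric vector/list of per-atom hydropathic indices,
#'   names of the form `"RES:ATOM"` (e.g. `"SER:OG"`); takes precedence over
#'   the rule and the element fallback.
#' @return an object of class `chemistry_tables`.
#' @examples
#' chem <- chemistry_tables(hi_atom = c("SER:OG" = -1))
#' @export
chemistry_tables <- function(vdw = NULL, masses = NULL,
                             hi_element = NULL, hi_atom = NULL) {
  merge_over <- function(base, extra) {
    if (is.null(extra) || length(extra) == 0) return(base)
    extra <- unlist(extra)
    base[names(extra)] <- extra
    base
  }
  tb <- list(
    vdw        = merge_over(.default_vdw, vdw),
    masses     = merge_over(.default_mass, masses),
    hi_element = merge_over(.default_hi_element, hi_element),
    hi_atom    = merge_over(numeric(0), hi_atom)
  )
  class(tb) <- "chemistry_tables"
  tb
}

#' Read chemistry-table overrides from a YAML file
#'
#' The file may contain any of the top-level keys `vdw`, `masses`,
#' `hi_element` (maps element -> value) and `hi_atom` (map `"RES:ATOM"` ->
#' value).
#'
#' @param path YAML file.
#' @return `chemistry_tables` object with the overrides applied.
#' @export
read_chemistry_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  chemistry_tables(vdw = cfg$vdw, masses = cfg$masses,
                   hi_element = cfg$hi_element, hi_atom = cfg$hi_atom)
}

# internal: element keyed lookup with a hard, atom-naming error
.chem_lookup <- function(table, element, serial, what) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  val <- unname(table[key])
  bad <- which(is.na(val) | !nzchar(element))
  if (length(bad)) {
    stop(sprintf("no %s for atom serial %s (element '%s')",
                 what, serial[bad[1]], element[bad[1]]), call. = FALSE)
  }
  val
}

chem_vdw  <- function(tb, element, serial) .chem_lookup(tb$vdw, element, serial, "van der Waals radius")
chem_mass <- function(tb, element, serial) .chem_lookup(tb$masses, element, serial, "atomic mass")

# per-atom hydropathic index: explicit (RES:ATOM) override > polarity rule >
# element fallback
chem_hi <- function(tb, res_name, atom_name, element, serial) {
  res  <- toupper(trimws(res_name))
  atom <- toupper(trimws(atom_name))
  el   <- toupper(trimws(element))
  n <- length(el)
  out <- rep(NA_real_, n)

  key <- paste0(res, ":", atom)
  hit <- key %in% names(tb$hi_atom)
  out[hit] <- unname(tb$hi_atom[key[hit]])

  todo <- which(!hit)
  if (length(todo)) {
    fall <- .chem_lookup(tb$hi_element, el[todo], serial[todo], "hydropathic index")
    # rule-based polar reclassification for C and H
    for (j in seq_along(todo)) {
      i <- todo[j]
      if (el[i] == "C") {
        pc <- c(.polar_carbons[["*"]], .polar_carbons[[res[i]]])
        if (atom[i] %in% pc) fall[j] <- -0.5
      } else if (el[i] %in% c("H", "D")) {
        ph <- c(.polar_h_backbone, .polar_h_side[[res[i]]])
        if (atom[i] %in% ph) fall[j] <- -0.5
      }
    }
    out[todo] <- fall
  }
  out
}

#' @export
print.chemistry_tables <- function(x, ...) {
  cat("Chemistry tables:",
      length(x$vdw), "vdW radii,",
      length(x$masses), "masses,",
      length(x$hi_element), "element HI entries,",
      length(x$hi_atom), "per-atom HI overrides\n")
  invisible(x)
}
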