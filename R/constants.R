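# Force-field constants.  All distances in Angstrom, energies in units of
# E_HB (the backbone hydrogen-bond well depth), masses in units of M_bead
# (one quarter of the alanine mass).

#' Force-field constants table
#'
#' Returns the single table of geometric and energetic constants used by the
#' four-bead model: covalent bond lengths, ideal backbone angles (from which
#' the next-neighbour pseudo-bond lengths are derived), square-well constraint
#' widths, hard-core diameters, the hydropathy well, and the backbone
#' hydrogen-bond specification.  Keeping every tunable in one place makes the
#' geometry recalibratable without touching the engine.
#'
#' Pseudo-bond rest lengths are computed from the law of cosines on the ideal
#' bond lengths and angles, so an ideal chain satisfies every constraint by
#' construction.
#'
#' @return A named list of constants.  Distances in Angstrom, energies in
#'   E_HB, masses in M_bead.
#' @export
ff_constants <- function() {
  bond <- c(n_ca = 1.46, ca_c = 1.51, c_n = 1.33, ca_cb = 1.53)
  angle <- c(n_ca_c = 111.0, ca_c_n = 116.0, c_n_ca = 122.0,
             n_ca_cb = 110.5, c_ca_cb = 110.1)  # degrees
  law_cos <- function(d1, d2, theta_deg) {
    sqrt(d1^2 + d2^2 - 2 * d1 * d2 * cos(theta_deg * pi / 180))
  }
  pseudo <- c(
    n_c    = law_cos(bond[["n_ca"]], bond[["ca_c"]], angle[["n_ca_c"]]),
    ca_n   = law_cos(bond[["ca_c"]], bond[["c_n"]], angle[["ca_c_n"]]),
    c_ca   = law_cos(bond[["c_n"]], bond[["n_ca"]], angle[["c_n_ca"]]),
    n_cb   = law_cos(bond[["n_ca"]], bond[["ca_cb"]], angle[["n_ca_cb"]]),
    c_cb   = law_cos(bond[["ca_c"]], bond[["ca_cb"]], angle[["c_ca_cb"]])
  )
  list(
    bond_lengths = bond,              # covalent rest lengths (A)
    bond_angles_deg = angle,
    pseudo_lengths = pseudo,          # next-neighbour pseudo-bonds (A)
    covalent_halfwidth = 0.02,        # +/- 2% square-well constraint
    pseudo_halfwidth = 0.025,         # +/- 2.5%
    core_diameter = c(backbone = 3.0, cb = 4.0),  # hard spheres (A)
    hp_cutoff = 7.5,                  # hydropathy square-well outer edge (A)
    hp_depth = 0.3,                   # E_HP, in E_HB
    hb_depth = 1.0,                   # backbone hydrogen bond, in E_HB
    hb_window = c(4.0, 5.0),          # N..C' bonded distance window (A)
    hb_flank_window = c(3.5, 7.0),    # auxiliary-bead windows at formation (A)
    bead_mass = 1.0,                  # all beads, in M_bead
    spatial_resolution = 0.1          # A; sets the simulation time unit
  )
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector over the 20 one-letter amino-acid codes.
#' @export
kyte_doolittle <- function() {
  c(I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
    E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
}

# One-letter alphabet used for validation.
aa_alphabet <- function() names(kyte_doolittle())

#' Write the force-field constants to a YAML file
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ff_constants <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to write the constants file")
  }
  cc <- ff_constants()
  cc <- lapply(cc, function(x) if (is.numeric(x)) as.list(x) else x)
  writeLines(yaml::as.yaml(cc), path)
  invisible(path)
}
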