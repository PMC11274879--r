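# Nonbonded interactions and the reduced unit system.
#
# The energy unit is E_HB, the depth of the backbone hydrogen-bond well.
# Simulated temperature is expressed in E_HB/kB; T = 0.13 corresponds to
# 310 K, which fixes E_HB ~= 4.6 kcal/mol.  The hydropathic well depth is
# E_HP = 0.3 E_HB.  The unit mass is one quarter of the alanine mass, and
# the simulation time unit is the time a bead takes to travel the spatial
# resolution (0.1 A) at the 1D thermal root-mean-square speed.

#' Reduced unit system of the force field
#'
#' @param T_sim Simulation temperature in E_HB/kB (default 0.13, i.e. 310 K).
#' @param E_HB_kcal Physical hydrogen-bond energy in kcal/mol (default 4.6).
#' @param m_kg Bead mass in kg (default 3e-26, one quarter of alanine).
#' @param spatial_resolution_A Spatial resolution in Angstrom (default 0.1).
#' @return Object of class `ff_units`: a list with the inputs plus
#'   `E_HP_kcal` (0.3 E_HB) and the derived time unit (see
#'   [derive_time_unit()]).
#' @export
ff_units <- function(T_sim = 0.13, E_HB_kcal = 4.6, m_kg = 3e-26,
                     spatial_resolution_A = 0.1) {
  if (T_sim <= 0 || E_HB_kcal <= 0 || m_kg <= 0 || spatial_resolution_A <= 0) {
    stop("all unit-system parameters must be positive")
  }
  u <- list(T_sim = T_sim, E_HB_kcal = E_HB_kcal, m_kg = m_kg,
            spatial_resolution_A = spatial_resolution_A,
            E_HP_kcal = 0.3 * E_HB_kcal)
  u <- c(u, derive_time_unit(u))
  structure(u, class = "ff_units")
}

#' Derive the physical time per simulation time unit
#'
#' Equipartition gives the 1D thermal speed `v_rms = sqrt(kB T / m)` with
#' `kB T = T_sim * E_HB` per molecule; one simulation time unit is the time
#' to travel the spatial resolution at that speed.
#'
#' @param units A list with `T_sim`, `E_HB_kcal`, `m_kg`,
#'   `spatial_resolution_A` (e.g. an `ff_units` object).
#' @return List with `v_rms_ms` (m/s), `dt_ps` (exact) and `dt_ps_1sf`
#'   (rounded to one significant figure, the conventional printed value).
#' @examples
#' derive_time_unit(ff_units())$dt_ps_1sf  # 0.03
#' @export
derive_time_unit <- function(units) {
  with(units, {
    if (T_sim <= 0 || E_HB_kcal <= 0 || m_kg <= 0 || spatial_resolution_A <= 0)
      stop("all unit-system parameters must be positive")
    kB_T_joule <- T_sim * E_HB_kcal * 4184 / 6.02214076e23
    v_rms <- sqrt(kB_T_joule / m_kg)                  # m/s, 1D
    dt_s <- spatial_resolution_A * 1e-10 / v_rms
    list(v_rms_ms = v_rms, dt_ps = dt_s * 1e12,
         dt_ps_1sf = signif(dt_s * 1e12, 1))
  })
}

# Conversion between the simulation time unit (tu) and the engine's internal
# reduced time t0 = A * sqrt(m / E_HB).  One tu is the time to travel the
# spatial resolution at the 1D rms speed of the production temperature.
time_unit_t0 <- function(T_production = 0.13,
                         spatial_resolution_A = ff_constants()$spatial_resolution) {
  spatial_resolution_A / sqrt(T_production)
}

#' Hydropathy step energy for a residue pair
#'
#' Square-well step energy (in E_HB) between the CB beads of two residues.
#' Hydrophobic pairs attract, with depth scaled by the geometric mean of
#' their Kyte-Doolittle values and anchored at the Ile-Ile minimum of
#' -0.3 E_HB; hydrophilic pairs repel with the analogous positive step;
#' mixed pairs and pairs involving a neutral residue do not interact.
#'
#' @param res_i,res_j One-letter amino-acid codes (vectorised).
#' @return Numeric step energy in E_HB (negative = attraction).
#' @examples
#' hydropathy_pair_energy("I", "I")  # -0.3
#' @export
hydropathy_pair_energy <- function(res_i, res_j) {
  ci <- classify_hydropathy(res_i)
  cj <- classify_hydropathy(res_j)
  kd <- kyte_doolittle()
  hi <- kd[toupper(res_i)]
  hj <- kd[toupper(res_j)]
  philic <- c("uncharged_hydrophilic", "charged_hydrophilic")
  scale <- ff_constants()$hp_depth / kd[["I"]]
  out <- numeric(length(ci))
  both_phobic <- ci == "hydrophobic" & cj == "hydrophobic"
  both_philic <- ci %in% philic & cj %in% philic
  out[both_phobic] <- -scale * sqrt(hi[both_phobic] * hj[both_phobic])
  out[both_philic] <- scale * sqrt(abs(hi[both_philic] * hj[both_philic]))
  unname(out)
}

#' Assemble the nonbonded interaction table for a multi-peptide system
#'
#' Concatenates the bead lists of the given peptide topologies and derives
#' everything the engine needs about nonbonded interactions: per-bead
#' hard-core diameters (backbone 3.0 A, CB 4.0 A, unlike pairs by
#' arithmetic mean), the CB-CB hydropathy square wells (cutoff 7.5 A, step
#' energies from [hydropathy_pair_energy()]), bonded-pair exclusions, and
#' the backbone hydrogen-bond entries (donor N with its flanking beads,
#' acceptor C with its flanking beads, well depth 1 E_HB over the
#' 4.0-5.0 A window).  Beads that share a bonded constraint have no
#' nonbonded entry.  N/C pairs in the same or adjacent peptide bond are not
#' hydrogen-bond candidates; the N-terminal N and C-terminal C lack a
#' flanking bead and are excluded as donor/acceptor.
#'
#' All bead pairs belonging to the same or adjacent residues of one peptide
#' are excluded from nonbonded interactions: their geometry is governed by
#' the covalent and pseudo-bond constraint network, and hard cores between
#' them would freeze the phi/psi-like backbone rotations the model keeps
#' free.
#'
#' @param topologies A `bead_topology` or list of them (one per peptide).
#' @param units An `ff_units` object.
#' @return Object of class `interaction_table`: list with `beads` (data
#'   frame over all peptides: `peptide`, `residue`, `role`, `aa`, `core`,
#'   `hp_active`), `eps` (20 x 20 named step-energy matrix, E_HB),
#'   `exclusions` (two-column matrix of global bead indices), `hb_donors` /
#'   `hb_acceptors` (data frames: `bead`, `flank1`, `flank2`), and `params`
#'   (the constants table plus `units`).
#' @export
build_interaction_table <- function(topologies, units = ff_units()) {
  if (inherits(topologies, "bead_topology")) topologies <- list(topologies)
  stopifnot(length(topologies) >= 1L,
            all(vapply(topologies, inherits, logical(1L), "bead_topology")))
  cc <- ff_constants()

  offset <- 0L
  beads_l <- list(); excl_l <- list()
  don_l <- list(); acc_l <- list()
  for (p in seq_along(topologies)) {
    tp <- topologies[[p]]
    b <- tp$beads
    hp_active <- b$role == "CB" & b$hydropathy != "neutral"
    beads_l[[p]] <- data.frame(
      peptide = p, residue = b$residue, role = b$role, aa = b$aa,
      core = ifelse(b$role == "CB", cc$core_diameter[["cb"]],
                    cc$core_diameter[["backbone"]]),
      hp_active = hp_active, stringsAsFactors = FALSE
    )
    # local exclusions: all pairs within the same or adjacent residues
    nb <- nrow(b)
    loc <- which(outer(b$residue, b$residue,
                       function(a, d) abs(a - d) <= 1L), arr.ind = TRUE)
    loc <- loc[loc[, 1L] < loc[, 2L], , drop = FALSE]
    excl_l[[p]] <- loc + offset

    bead_of <- function(res, r) {
      k <- which(b$residue == res & b$role == r)
      if (length(k) == 1L) k + offset else NA_integer_
    }
    L <- tp$spec$length
    don <- do.call(rbind, lapply(seq_len(L), function(i) {
      if (i == 1L) return(NULL)  # no preceding C: not a donor
      data.frame(bead = bead_of(i, "N"), residue = i, peptide = p,
                 flank1 = bead_of(i, "CA"), flank2 = bead_of(i - 1L, "C"))
    }))
    acc <- do.call(rbind, lapply(seq_len(L), function(i) {
      if (i == L) return(NULL)  # no following N: not an acceptor
      data.frame(bead = bead_of(i, "C"), residue = i, peptide = p,
                 flank1 = bead_of(i, "CA"), flank2 = bead_of(i + 1L, "N"))
    }))
    don_l[[p]] <- don; acc_l[[p]] <- acc
    offset <- offset + nrow(b)
  }

  aa <- aa_alphabet()
  eps <- outer(aa, aa, hydropathy_pair_energy)
  dimnames(eps) <- list(aa, aa)

  structure(list(
    beads = do.call(rbind, beads_l),
    eps = eps,
    exclusions = do.call(rbind, excl_l),
    hb_donors = do.call(rbind, don_l),
    hb_acceptors = do.call(rbind, acc_l),
    params = c(cc, list(units = units))
  ), class = "interaction_table")
}

#' Look up the nonbonded entry for one bead pair
#'
#' @param table An `interaction_table`.
#' @param i,j Global bead indices.
#' @return List with `kind` (`"excluded"`, `"hard_core"`, `"hydropathy_well"`
#'   or `"hydrogen_bond"`), `core` (pair hard-core diameter, A), and for
#'   wells `eps` (step energy, E_HB) and `cutoff` (A).
#' @export
interaction_entry <- function(table, i, j) {
  b <- table$beads
  core <- (b$core[i] + b$core[j]) / 2
  excl <- table$exclusions
  if (any((excl[, 1L] == i & excl[, 2L] == j) |
          (excl[, 1L] == j & excl[, 2L] == i))) {
    return(list(kind = "excluded"))
  }
  hb <- .hb_candidate(table, i, j)
  if (hb) {
    return(list(kind = "hydrogen_bond", core = core,
                eps = -table$params$hb_depth,
                cutoff = table$params$hb_window[2L]))
  }
  if (b$hp_active[i] && b$hp_active[j]) {
    e <- table$eps[b$aa[i], b$aa[j]]
    if (e != 0) {
      return(list(kind = "hydropathy_well", core = core, eps = e,
                  cutoff = table$params$hp_cutoff))
    }
  }
  list(kind = "hard_core", core = core)
}

# Is (i, j) a donor/acceptor hydrogen-bond candidate pair?
.hb_candidate <- function(table, i, j) {
  b <- table$beads
  chk <- function(n, c) {
    if (!(n %in% table$hb_donors$bead) || !(c %in% table$hb_acceptors$bead))
      return(FALSE)
    b$peptide[n] != b$peptide[c] || abs(b$residue[n] - b$residue[c]) >= 2L
  }
  chk(i, j) || chk(j, i)
}

#' Serialise an interaction table to JSON
#'
#' @param table An `interaction_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table_json <- function(table, path) {
  jsonlite::write_json(
    list(beads = table$beads,
         eps = list(alphabet = rownames(table$eps),
                    matrix = unclass(table$eps)),
         exclusions = unname(apply(table$exclusions, 1L, c, simplify = FALSE)),
         hb_donors = table$hb_donors, hb_acceptors = table$hb_acceptors),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
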