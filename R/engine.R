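# R-level interface to the event-driven DMD core.
#
# Coordinates are in Angstrom, energies in E_HB, masses in M_bead, and all
# user-facing times are in simulation time units (tu): one tu is the time a
# bead needs to travel the spatial resolution (0.1 A) at the 1D thermal rms
# speed of the production temperature.  The core integrates in reduced time
# t0 = A * sqrt(M_bead/E_HB); conversions happen only here.

#' Simulation configuration
#'
#' Bundles every knob of the two-stage protocol: a high-temperature
#' decorrelation stage with hydrogen bonding and hydropathy interactions
#' switched off (to produce independent unstructured monomeric starts),
#' followed by a production stage at physiological temperature under a
#' Berendsen-style velocity-rescaling thermostat.
#'
#' @param isoform_id Isoform or custom sequence, see [build_sequence()].
#' @param n_peptides Number of peptides (default 32).
#' @param box_nm Cubic box edge in nm (default 25; periodic boundaries).
#' @param T_decorrelation Decorrelation temperature in E_HB/kB (default 4).
#' @param T_production Production temperature in E_HB/kB (default 0.13).
#' @param total_time_tu Production duration in time units (default 4e7).
#' @param frame_interval_tu Frame output spacing in tu (default 1e5).
#' @param decorrelation_time_tu Decorrelation duration in tu (default 1e5).
#' @param thermo_interval_tu Thermostat coupling interval in tu (default 1e3).
#' @param thermo_tau_tu Thermostat relaxation time in tu (default 2e3; the
#'   coupling must outpace the heat released by hydrophobic collapse and
#'   hydrogen-bond formation or the kinetic temperature creeps above the
#'   target during the assembly phase).
#' @param seed Base random seed; replica r uses `seed + r - 1`.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(isoform_id = "Ab42", n_peptides = 32L,
                              box_nm = 25, T_decorrelation = 4,
                              T_production = 0.13, total_time_tu = 4e7,
                              frame_interval_tu = 1e5,
                              decorrelation_time_tu = 1e5,
                              thermo_interval_tu = 1e3,
                              thermo_tau_tu = 2e3, seed = 1L) {
  cc <- ff_constants()
  box_A <- box_nm * 10
  if (box_A <= 2 * cc$hp_cutoff) {
    stop("box edge must exceed twice the maximum interaction cutoff")
  }
  stopifnot(n_peptides >= 1L, total_time_tu > 0, frame_interval_tu > 0,
            decorrelation_time_tu > 0, T_decorrelation > 0, T_production > 0,
            thermo_interval_tu > 0, thermo_tau_tu > 0)
  structure(list(
    isoform_id = isoform_id, n_peptides = as.integer(n_peptides),
    box_nm = box_nm, box_A = box_A,
    T_decorrelation = T_decorrelation, T_production = T_production,
    total_time_tu = total_time_tu, frame_interval_tu = frame_interval_tu,
    decorrelation_time_tu = decorrelation_time_tu,
    thermo_interval_tu = thermo_interval_tu, thermo_tau_tu = thermo_tau_tu,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# tu -> reduced-time conversion factor for a config
.tu2t0 <- function(config) time_unit_t0(config$T_production)

# Maxwell-Boltzmann velocities (reduced units, kB = 1, per-component sd
# sqrt(T/m)) with the centre-of-mass drift removed.
.mb_velocities <- function(n, temperature, mass = rep(1, n)) {
  v <- matrix(stats::rnorm(3 * n, sd = sqrt(temperature / mass)), n, 3)
  drift <- colSums(v * mass) / sum(mass)
  sweep(v, 2L, drift)
}

# Flatten one-or-more topologies plus an interaction table into the list
# the C++ core consumes (0-based indices).
.flatten_system <- function(topologies, table) {
  if (inherits(topologies, "bead_topology")) topologies <- list(topologies)
  cc <- table$params
  b <- table$beads
  n <- nrow(b)
  bond_i <- integer(0); bond_j <- integer(0)
  dmin <- numeric(0); dmax <- numeric(0)
  off <- 0L
  for (tp in topologies) {
    bond_i <- c(bond_i, tp$bonds$i + off)
    bond_j <- c(bond_j, tp$bonds$j + off)
    dmin <- c(dmin, tp$bonds$dmin); dmax <- c(dmax, tp$bonds$dmax)
    off <- off + nrow(tp$beads)
  }
  welltype <- ifelse(b$hp_active, match(b$aa, rownames(table$eps)) - 1L, -1L)
  hb_role <- integer(n)
  hb_role[table$hb_donors$bead] <- 1L
  hb_role[table$hb_acceptors$bead] <- 2L
  fl1 <- rep(-1L, n); fl2 <- rep(-1L, n)
  fl1[table$hb_donors$bead] <- table$hb_donors$flank1 - 1L
  fl2[table$hb_donors$bead] <- table$hb_donors$flank2 - 1L
  fl1[table$hb_acceptors$bead] <- table$hb_acceptors$flank1 - 1L
  fl2[table$hb_acceptors$bead] <- table$hb_acceptors$flank2 - 1L
  list(
    mass = rep(cc$bead_mass, n),
    bond_i = bond_i - 1L, bond_j = bond_j - 1L,
    bond_dmin = dmin, bond_dmax = dmax,
    excl_i = as.integer(table$exclusions[, 1L] - 1L),
    excl_j = as.integer(table$exclusions[, 2L] - 1L),
    core = b$core, welltype = as.integer(welltype),
    eps = unclass(table$eps), hp_cutoff = cc$hp_cutoff,
    hb_role = hb_role, hb_flank1 = fl1, hb_flank2 = fl2,
    peptide = b$peptide - 1L, residue = b$residue,
    hb_depth = cc$hb_depth, hb_window = cc$hb_window,
    hb_flank_window = cc$hb_flank_window
  )
}

#' Place peptides on a cubic lattice in the periodic box
#'
#' Builds each peptide in a compact helical reference conformation (which
#' satisfies every bonded constraint exactly), centres the copies on a
#' cubic lattice, orients them along the cell body diagonal, and draws
#' Maxwell-Boltzmann velocities at the decorrelation temperature with zero
#' total momentum.
#'
#' @param config A `simulation_config`.
#' @param topology A `bead_topology` for one peptide (replicated
#'   `n_peptides` times).
#' @return Object of class `system_state`: list with `pos` (N x 3, A),
#'   `vel` (N x 3, A/t0), `box` (A), `topologies`, `table`, `hb_pairs`
#'   (0-row matrix), `time_tu` (0).
#' @export
initialize_lattice <- function(config, topology = build_topology(
                                 build_sequence(config$isoform_id))) {
  np <- config$n_peptides
  k <- ceiling(np^(1 / 3) - 1e-9)
  spacing <- config$box_A / k
  chain <- .build_chain(topology$spec$sequence,
                        phi = rep(-125, topology$spec$length),
                        psi = rep(-60, topology$spec$length))
  chain <- sweep(chain, 2L, colMeans(chain))
  # orient the long axis along the cell body diagonal
  ax <- svd(chain)$v[, 1L]
  diagdir <- c(1, 1, 1) / sqrt(3)
  v <- c(ax[2] * diagdir[3] - ax[3] * diagdir[2],
         ax[3] * diagdir[1] - ax[1] * diagdir[3],
         ax[1] * diagdir[2] - ax[2] * diagdir[1])
  cosA <- sum(ax * diagdir)
  if (.vnorm(v) > 1e-10) {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    R <- diag(3) + vx + vx %*% vx / (1 + cosA)
    chain <- chain %*% t(R)
  }
  extent <- max(sqrt(rowSums(chain^2)))
  if (2 * extent + 7.5 > sqrt(3) * spacing) {
    stop("box too small: ", np, " peptides do not fit a ", k, "^3 lattice ",
         "in a ", config$box_nm, " nm box without inter-peptide contact")
  }
  sites <- as.matrix(expand.grid(x = seq_len(k), y = seq_len(k),
                                 z = seq_len(k)))[seq_len(np), , drop = FALSE]
  centres <- (sites - 0.5) * spacing
  pos <- do.call(rbind, lapply(seq_len(np), function(p) {
    sweep(chain, 2L, centres[p, ], "+")
  }))
  topologies <- rep(list(topology), np)
  table <- build_interaction_table(topologies)
  vel <- .mb_velocities(nrow(pos), config$T_decorrelation)
  structure(list(pos = pos, vel = vel, box = config$box_A,
                 topologies = topologies, table = table,
                 hb_pairs = matrix(integer(0), 0, 2), time_tu = 0),
            class = "system_state")
}

# Internal: call the C++ core for a system_state.
.engine_call <- function(state, config, t_tu, frame_tu, interactions_on,
                         thermostat, T_target, max_events = 5e9) {
  f <- .tu2t0(config)
  sys <- c(list(pos = state$pos, vel = state$vel, box = state$box,
                hb_pairs = state$hb_pairs),
           .flatten_system(state$topologies, state$table))
  run <- list(interactions_on = interactions_on,
              t_end = t_tu * f,
              frame_dt = frame_tu * f,
              thermo_dt = if (thermostat) config$thermo_interval_tu * f else -1,
              thermo_tau = config$thermo_tau_tu * f,
              T_target = T_target,
              max_events = max_events)
  dmd_run_cpp(sys, run)
}

#' Decorrelate a freshly initialised system at high temperature
#'
#' Runs the system at the decorrelation temperature with hydrogen bonding
#' and hydropathy interactions switched off (hard cores and bonded
#' constraints only), so each seed yields an independent unstructured
#' monomeric starting conformation.
#'
#' @param state A `system_state` from [initialize_lattice()].
#' @param config A `simulation_config`.
#' @param seed Seed for the velocity draw (defaults to `config$seed`).
#' @return A new `system_state` at the end of the decorrelation stage (with
#'   an empty hydrogen-bond registry), carrying a `decorrelation`
#'   attribute with the stage's frame times and hydrogen-bond counts.
#' @export
decorrelate <- function(state, config, seed = config$seed) {
  set.seed(seed)
  state$vel <- .mb_velocities(nrow(state$pos), config$T_decorrelation)
  out <- .engine_call(state, config,
                      t_tu = config$decorrelation_time_tu,
                      frame_tu = config$decorrelation_time_tu / 10,
                      interactions_on = FALSE,
                      thermostat = TRUE, T_target = config$T_decorrelation)
  new_state <- state
  new_state$pos <- out$pos
  new_state$vel <- out$vel
  new_state$hb_pairs <- matrix(integer(0), 0, 2)
  attr(new_state, "decorrelation") <- list(
    frame_times_tu = out$frame_times / .tu2t0(config),
    frames = out$frames[, , seq_len(out$n_frames), drop = FALSE],
    n_hb = out$frame_hb[seq_len(out$n_frames)],
    n_events = out$n_events)
  new_state
}

#' Run the production stage and collect a trajectory
#'
#' Processes events in causal order through the priority queue, applying
#' Berendsen-style velocity rescaling toward the production temperature at
#' the configured coupling interval, and emits frames at the configured
#' spacing (including the initial state).
#'
#' @param state A `system_state` (normally after [decorrelate()]).
#' @param config A `simulation_config`.
#' @param seed Seed for the production velocity draw; `NULL` keeps the
#'   incoming velocities.
#' @param thermostat Logical; switch the thermostat off to check energy
#'   conservation.
#' @param total_time_tu,frame_interval_tu Optional overrides of the config.
#' @return Object of class `dmd_trajectory`: list with `frames`
#'   (N x 3 x F array, A), `times` (tu), `beads` (per-bead metadata),
#'   `box` (A), `energy` (data frame: time, kinetic, potential, n_hb),
#'   `hb_pairs`, `n_events`, `config`, `seed`, `engine_version`.
#' @export
run_dmd <- function(state, config, seed = NULL, thermostat = TRUE,
                    total_time_tu = config$total_time_tu,
                    frame_interval_tu = config$frame_interval_tu) {
  if (!is.null(seed)) {
    set.seed(seed)
    state$vel <- .mb_velocities(nrow(state$pos), config$T_production)
  }
  out <- .engine_call(state, config, t_tu = total_time_tu,
                      frame_tu = frame_interval_tu,
                      interactions_on = TRUE,
                      thermostat = thermostat,
                      T_target = config$T_production)
  nf <- out$n_frames
  structure(list(
    frames = out$frames[, , seq_len(nf), drop = FALSE],
    times = out$frame_times[seq_len(nf)] / .tu2t0(config),
    beads = state$table$beads,
    box = state$box,
    energy = data.frame(
      time = out$frame_times[seq_len(nf)] / .tu2t0(config),
      kinetic = out$frame_kinetic[seq_len(nf)],
      potential = out$frame_potential[seq_len(nf)],
      n_hb = out$frame_hb[seq_len(nf)]),
    hb_pairs = out$hb_pairs,
    topologies = state$topologies,
    final_state = list(pos = out$pos, vel = out$vel),
    n_events = out$n_events,
    config = config, seed = seed,
    engine_version = as.character(utils::packageVersion("abetadmd"))
  ), class = "dmd_trajectory")
}

#' @export
print.dmd_trajectory <- function(x, ...) {
  cat(sprintf(
    "<dmd_trajectory> %d beads, %d frames to t = %g tu (%.3g events)\n",
    nrow(x$beads), length(x$times), max(x$times), x$n_events))
  invisible(x)
}

#' Run the full two-stage replica protocol
#'
#' For each replica seed (`config$seed + replica - 1`): place peptides on
#' the lattice, decorrelate at high temperature, then run production at the
#' production temperature.  Production velocities are redrawn from the
#' Maxwell-Boltzmann distribution at the production temperature.
#'
#' @param config A `simulation_config`.
#' @param n_replicas Number of replica trajectories (default 32).
#' @return List of `dmd_trajectory` objects, one per replica, each carrying
#'   its replica id and seed.
#' @export
run_protocol <- function(config, n_replicas = 32L) {
  lapply(seq_len(n_replicas), function(r) {
    seed_r <- config$seed + r - 1L
    state <- tryCatch({
      set.seed(seed_r)
      st <- initialize_lattice(config)
      decorrelate(st, config, seed = seed_r)
    }, error = function(e) {
      stop("replica ", r, ": ", conditionMessage(e))
    })
    traj <- run_dmd(state, config, seed = seed_r)
    traj$replica <- r
    traj
  })
}

#' Predict the next pair event time
#'
#' Earliest positive root of `|r_ij + v_ij t| = d` under the minimum-image
#' convention: the reference algebra for collision prediction against a
#' distance discontinuity (hard core or well edge).
#'
#' @param r_i,r_j Positions (length-3, A).
#' @param v_i,v_j Velocities (length-3, A/tu or any consistent unit).
#' @param d Discontinuity distance (A).
#' @param box Periodic box edge (A); `Inf` for open boundaries.
#' @return Time to the crossing in the velocity's time unit, or `NA` if the
#'   pair never reaches the discontinuity.
#' @export
predict_pair_event <- function(r_i, r_j, v_i, v_j, d, box = Inf) {
  if (any(!is.finite(c(r_i, r_j, v_i, v_j)))) stop("non-finite coordinates")
  dr <- r_j - r_i
  if (is.finite(box)) dr <- .min_image(dr, box)
  dv <- v_j - v_i
  r2 <- sum(dr * dr); b <- sum(dr * dv); v2 <- sum(dv * dv)
  if (v2 == 0) return(NA_real_)
  d2 <- d * d
  disc <- b * b - v2 * (r2 - d2)
  if (r2 > d2) {            # approaching an inner discontinuity
    if (b >= 0 || disc <= 0) return(NA_real_)
    (-b - sqrt(disc)) / v2
  } else {                  # leaving through an outer discontinuity
    (-b + sqrt(disc)) / v2
  }
}

#' Resolve a square-well event for a bead pair
#'
#' Applies the standard discontinuous-potential collision rules along the
#' centre line: elastic reflection for hard walls, radial speed change
#' consuming or releasing the potential step for well crossings, and
#' reflection when the radial kinetic energy cannot pay for an uphill step.
#' Total momentum is conserved exactly.
#'
#' @param v_i,v_j Velocities (length-3).
#' @param n_hat Unit vector from i to j at the event.
#' @param du Potential step if the crossing succeeds (E_HB); 0 for a hard
#'   wall.
#' @param m_i,m_j Masses (default 1).
#' @return List with `v_i`, `v_j`, `crossed` (logical), `dKE` (kinetic
#'   energy change, equal to `-du` when crossed, else 0).
#' @export
resolve_pair_event <- function(v_i, v_j, n_hat, du = 0, m_i = 1, m_j = 1) {
  mu <- m_i * m_j / (m_i + m_j)
  s <- sum((v_j - v_i) * n_hat)
  if (du == 0 || s * s <= 2 * du / mu) {
    sp <- -s
    crossed <- FALSE
  } else {
    sp <- sign(s) * sqrt(s * s - 2 * du / mu)
    crossed <- TRUE
  }
  imp <- mu * (sp - s)
  list(v_i = v_i - imp * n_hat / m_i,
       v_j = v_j + imp * n_hat / m_j,
       crossed = crossed,
       dKE = 0.5 * mu * (sp^2 - s^2))
}

#' Low-level runner for arbitrary bead systems
#'
#' Direct access to the event-driven core for small validation systems
#' (isolated pairs in a well, ideal-gas beads, ...): no peptide topology
#' required.  Times are in reduced units t0 here.
#'
#' @param pos N x 3 positions (A).
#' @param vel N x 3 velocities (A/t0).
#' @param box Periodic box edge (A).
#' @param t_end Duration (t0).
#' @param frame_dt Frame spacing (t0); 0 suppresses periodic frames.
#' @param core Per-bead hard-core diameter (A), recycled.
#' @param bonds Optional data frame `i`, `j`, `dmin`, `dmax` (1-based).
#' @param welltype Per-bead integer well type (0-based row into `eps`),
#'   -1 for none.
#' @param eps Square step-energy matrix (E_HB) indexed by well type.
#' @param well_cutoff Outer well edge (A).
#' @param thermostat Optional list with `T`, `interval`, `tau` (t0).
#' @param mass Per-bead mass, recycled.
#' @param max_events Abort threshold.
#' @return The raw engine output list (frames, energies, events, ...).
#' @export
run_beads <- function(pos, vel, box, t_end, frame_dt = 0, core = 3.0,
                      bonds = NULL, welltype = NULL, eps = matrix(0, 1, 1),
                      well_cutoff = 7.5, thermostat = NULL, mass = 1,
                      max_events = 1e8) {
  n <- nrow(pos)
  if (is.null(welltype)) welltype <- rep(-1L, n)
  sys <- list(
    pos = pos, vel = vel, box = box,
    mass = rep_len(mass, n),
    bond_i = if (is.null(bonds)) integer(0) else as.integer(bonds$i - 1L),
    bond_j = if (is.null(bonds)) integer(0) else as.integer(bonds$j - 1L),
    bond_dmin = if (is.null(bonds)) numeric(0) else bonds$dmin,
    bond_dmax = if (is.null(bonds)) numeric(0) else bonds$dmax,
    excl_i = integer(0), excl_j = integer(0),
    core = rep_len(core, n), welltype = as.integer(rep_len(welltype, n)),
    eps = eps, hp_cutoff = well_cutoff,
    hb_role = rep(0L, n), hb_flank1 = rep(-1L, n), hb_flank2 = rep(-1L, n),
    peptide = seq_len(n) - 1L, residue = rep(1L, n),
    hb_depth = 1.0, hb_window = c(4.0, 5.0), hb_flank_window = c(3.5, 7.0),
    hb_pairs = matrix(integer(0), 0, 2)
  )
  run <- list(
    interactions_on = TRUE, t_end = t_end, frame_dt = frame_dt,
    thermo_dt = if (is.null(thermostat)) -1 else thermostat$interval,
    thermo_tau = if (is.null(thermostat)) 1 else thermostat$tau,
    T_target = if (is.null(thermostat)) 1 else thermostat$T,
    max_events = max_events,
    debug_check = getOption("abetadmd.debug_check", FALSE)
  )
  dmd_run_cpp(sys, run)
}
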