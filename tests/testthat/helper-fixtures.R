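# Shared fixture builders: trajectories assembled from explicit chain
# coordinates, bypassing the engine, so analysis code can be tested on
# conformations with known properties.

# Build an analysis-compatible trajectory from a list of frames, each a
# list of per-peptide coordinate matrices (one topology for all).
chains_traj <- function(frame_chains, topology, box = 500,
                        offsets = NULL, times = NULL) {
  np <- length(frame_chains[[1L]])
  if (is.null(offsets)) {
    offsets <- lapply(seq_len(np), function(p) c(100 * (p - 1L), 0, 0))
  }
  tab <- build_interaction_table(rep(list(topology), np))
  nb <- nrow(topology$beads)
  frames <- array(NA_real_, c(np * nb, 3L, length(frame_chains)))
  for (f in seq_along(frame_chains)) {
    for (p in seq_len(np)) {
      rows <- (p - 1L) * nb + seq_len(nb)
      q <- sweep(frame_chains[[f]][[p]], 2L, offsets[[p]] + box / 4, "+")
      frames[rows, , f] <- q %% box
    }
  }
  if (is.null(times)) times <- (seq_along(frame_chains) - 1L) * 1e5
  structure(list(frames = frames, times = times, beads = tab$beads,
                 box = box, topologies = rep(list(topology), np),
                 config = NULL, seed = NA),
            class = "dmd_trajectory")
}

# chain with an extended central block (residues 3..8 of 12) and the rest
# in a coil region: exactly half the residues classify as strand
half_strand_chain <- function() {
  L <- 12L
  phi <- rep(-160, L); psi <- rep(-60, L)
  phi[3:8] <- -120; psi[3:8] <- 120
  spec <- build_sequence(paste(rep("A", L), collapse = ""))
  list(pos = abetadmd:::.build_chain(spec$sequence, phi, psi),
       topology = build_topology(spec))
}
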