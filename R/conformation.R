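# Conformational analysis: backbone reconstruction, a dihedral/contact
# secondary-structure classifier, contact maps, hydrophobic SASA and
# terminus geometry.
#
# All functions operate on unwrapped coordinates; `unwrap_frame()` makes
# peptides whole across the periodic boundary and reassembles oligomers
# into contiguous coordinates.

# -- frame utilities ---------------------------------------------------------

#' Extract one frame of a trajectory
#'
#' @param traj A `dmd_trajectory`.
#' @param f Frame index.
#' @return N x 3 coordinate matrix (A).
#' @export
frame_coords <- function(traj, f) {
  traj$frames[, , f]
}

#' Unwrap a periodic frame
#'
#' Makes every peptide whole (each bead placed at its minimum image
#' relative to the previous bead of the chain) and, when a partition is
#' supplied, translates the peptides of each oligomer by box vectors so the
#' cluster is contiguous (each peptide placed at the minimum image relative
#' to an already-placed cluster member it touches).
#'
#' @param pos N x 3 coordinates (A), wrapped.
#' @param peptide Peptide id per bead.
#' @param box Box edge (A); `Inf` is a no-op.
#' @param partition Optional `oligomer_partition` for cluster reassembly.
#' @return N x 3 unwrapped coordinates.
#' @export
unwrap_frame <- function(pos, peptide, box, partition = NULL) {
  if (!is.finite(box)) return(pos)
  out <- pos
  ids <- sort(unique(peptide))
  for (p in ids) {
    k <- which(peptide == p)
    q <- pos[k, , drop = FALSE]
    for (r in seq_len(nrow(q))[-1L]) {
      q[r, ] <- q[r - 1L, ] + .min_image(q[r, ] - q[r - 1L, ], box)
    }
    out[k, ] <- q
  }
  if (!is.null(partition)) {
    for (cl in partition$clusters) {
      if (length(cl) < 2L) next
      edges <- partition$edges
      placed <- cl[1L]
      todo <- setdiff(cl, placed)
      while (length(todo) > 0L) {
        moved <- FALSE
        for (p in todo) {
          nb <- c(edges[edges[, 1L] == p, 2L], edges[edges[, 2L] == p, 1L])
          nb <- intersect(nb, placed)
          if (length(nb) == 0L) next
          a <- which(peptide == p); b <- which(peptide == nb[1L])
          ca <- colMeans(out[a, , drop = FALSE])
          cb <- colMeans(out[b, , drop = FALSE])
          shift <- .min_image(ca - cb, box) - (ca - cb)
          out[a, ] <- sweep(out[a, , drop = FALSE], 2L, shift, "+")
          placed <- c(placed, p)
          todo <- setdiff(todo, p)
          moved <- TRUE
        }
        if (!moved) break  # disconnected remainder; leave as is
      }
    }
  }
  out
}

# rows of the beads table for one peptide, as an index helper
.pep_rows <- function(beads, p) which(beads$peptide == p)

.bead_row <- function(beads, p, res, role) {
  k <- which(beads$peptide == p & beads$residue == res & beads$role == role)
  if (length(k) == 1L) k else NA_integer_
}

# -- backbone reconstruction -------------------------------------------------

#' Reconstruct amide hydrogens and carbonyl oxygens
#'
#' The four-bead model has no explicit H or O; their positions are inferred
#' from the neighbouring beads.  The amide H is placed 1.0 A from N along
#' the direction opposing the bisector of the N-CA and N-C'(prev) bonds;
#' the carbonyl O 1.24 A from C' opposing the bisector of C'-CA and
#' C'-N(next).  The N-terminal residue has no H and the C-terminal residue
#' no O (missing neighbour); those rows are `NA`.
#'
#' @param pos Unwrapped coordinates of one peptide (rows in topology
#'   order).
#' @param topology The peptide's `bead_topology`.
#' @return List with `H` and `O`, each an L x 3 matrix (A).
#' @export
reconstruct_backbone <- function(pos, topology) {
  b <- topology$beads
  L <- topology$spec$length
  stopifnot(nrow(pos) == nrow(b))
  at <- function(res, role) {
    k <- which(b$residue == res & b$role == role)
    if (length(k) == 1L) pos[k, ] else NULL
  }
  H <- matrix(NA_real_, L, 3L); O <- matrix(NA_real_, L, 3L)
  for (i in seq_len(L)) {
    if (i > 1L) {
      N <- at(i, "N"); CA <- at(i, "CA"); Cprev <- at(i - 1L, "C")
      u <- (CA - N) / .vnorm(CA - N) + (Cprev - N) / .vnorm(Cprev - N)
      H[i, ] <- N - u / .vnorm(u) * 1.0
    }
    if (i < L) {
      C <- at(i, "C"); CA <- at(i, "CA"); Nnext <- at(i + 1L, "N")
      u <- (CA - C) / .vnorm(CA - C) + (Nnext - C) / .vnorm(Nnext - C)
      O[i, ] <- C - u / .vnorm(u) * 1.24
    }
  }
  list(H = H, O = O)
}

#' Backbone pseudo-dihedrals of a four-bead peptide
#'
#' @param pos Unwrapped peptide coordinates.
#' @param topology The peptide's `bead_topology`.
#' @return Data frame with `residue`, `phi`, `psi` (degrees; `NA` at the
#'   chain ends).
#' @export
backbone_dihedrals <- function(pos, topology) {
  b <- topology$beads
  L <- topology$spec$length
  at <- function(res, role) {
    pos[which(b$residue == res & b$role == role), ]
  }
  phi <- rep(NA_real_, L); psi <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1L) {
      phi[i] <- .vdihedral(at(i - 1L, "C"), at(i, "N"), at(i, "CA"),
                           at(i, "C"))
    }
    if (i < L) {
      psi[i] <- .vdihedral(at(i, "N"), at(i, "CA"), at(i, "C"),
                           at(i + 1L, "N"))
    }
  }
  data.frame(residue = seq_len(L), phi = phi, psi = psi)
}

# classifier thresholds (degrees, Angstrom); kept in one place
.ss_rules <- function() {
  list(
    strand_phi = c(-180, -45), strand_psi = c(90, 180),
    strand_psi_wrap = c(-180, -150),   # psi just past +180
    helix_phi = c(-100, -30), helix_psi = c(-80, -5),
    strand_min_run = 2L, helix_min_run = 4L,
    turn_phi = c(-130, -20), turn_psi = c(-70, 50),
    turn_ca_dist = 7.0                 # CA(i)-CA(i+3) proximity
  )
}

#' Assign secondary structure to one peptide conformation
#'
#' A deterministic dihedral-plus-proximity classifier on the four-bead
#' backbone: residues with extended (phi, psi) in runs of at least two are
#' strand; helical (phi, psi) in runs of at least four are helix; residues
#' i+1 and i+2 of any i -> i+3 CA contact below 7 A become turn (unless
#' already strand or helix); everything else is coil.  Chains shorter than
#' three residues are entirely coil.  This is a surrogate for
#' full-atom secondary-structure algorithms and is validated on generated
#' conformations with known labels; comparisons with published propensity
#' curves are qualitative.
#'
#' @param pos Unwrapped peptide coordinates.
#' @param topology The peptide's `bead_topology`.
#' @return Character vector (length L) over
#'   `c("strand", "helix", "turn", "coil")`.
#' @export
assign_secondary_structure <- function(pos, topology) {
  L <- topology$spec$length
  if (L < 3L) return(rep("coil", L))
  r <- .ss_rules()
  dih <- backbone_dihedrals(pos, topology)
  in_rng <- function(x, rng) !is.na(x) & x >= rng[1L] & x <= rng[2L]
  ext <- in_rng(dih$phi, r$strand_phi) &
    (in_rng(dih$psi, r$strand_psi) | in_rng(dih$psi, r$strand_psi_wrap))
  hel <- in_rng(dih$phi, r$helix_phi) & in_rng(dih$psi, r$helix_psi)
  lab <- rep("coil", L)
  runs <- function(flag, minrun) {
    out <- logical(L)
    rl <- rle(flag)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in seq_along(rl$values)) {
      if (rl$values[k] && rl$lengths[k] >= minrun) {
        out[starts[k]:ends[k]] <- TRUE
      }
    }
    out
  }
  lab[runs(hel, r$helix_min_run)] <- "helix"
  lab[runs(ext, r$strand_min_run)] <- "strand"
  b <- topology$beads
  ca <- pos[b$role == "CA", , drop = FALSE]
  turnish <- in_rng(dih$phi, r$turn_phi) & in_rng(dih$psi, r$turn_psi)
  for (i in seq_len(L - 3L)) {
    if (turnish[i + 1L] && turnish[i + 2L] &&
        .vnorm(ca[i + 3L, ] - ca[i, ]) < r$turn_ca_dist) {
      for (j in (i + 1L):(i + 2L)) {
        if (lab[j] == "coil") lab[j] <- "turn"
      }
    }
  }
  lab
}

# labels for all peptides of one frame: matrix peptides x residues
.ss_labels_frame <- function(pos, beads, topologies, box) {
  u <- unwrap_frame(pos, beads$peptide, box)
  ids <- sort(unique(beads$peptide))
  t(vapply(seq_along(ids), function(k) {
    rows <- .pep_rows(beads, ids[k])
    assign_secondary_structure(u[rows, , drop = FALSE], topologies[[k]])
  }, character(topologies[[1L]]$spec$length)))
}

.ss_labels_all <- c("turn", "strand", "coil", "helix")

# -- propensity profiles -----------------------------------------------------

#' Per-residue secondary-structure propensity profile
#'
#' For each trajectory, per-residue label fractions are averaged over the
#' peptides of each frame and then over the frames in the window; the
#' ensemble mean and SEM are taken over trajectories.  With
#' `scope = "by_state"`, only peptides residing in oligomers of order
#' `order` enter the average; a trajectory without any such peptide
#' contributes a missing value (not a zero).
#'
#' @param trajectories List of `dmd_trajectory`.
#' @param window Time window `c(from, to)` in tu (`NULL`: all frames;
#'   frames with `from < t <= to` are used).
#' @param scope `"all"` or `"by_state"`.
#' @param order Oligomer order for `scope = "by_state"`.
#' @return Data frame: `residue`, `label`, `mean`, `sem`,
#'   `n_trajectories`.
#' @export
ss_propensity_profile <- function(trajectories, window = NULL,
                                  scope = c("all", "by_state"), order = 1L) {
  scope <- match.arg(scope)
  per_traj <- lapply(trajectories, function(tr) {
    fsel <- .window_frames(tr, window)
    L <- tr$topologies[[1L]]$spec$length
    acc <- array(0, c(length(.ss_labels_all), L))
    wsum <- 0
    for (f in fsel) {
      labs <- .ss_labels_frame(tr$frames[, , f], tr$beads, tr$topologies,
                               tr$box)
      if (scope == "by_state") {
        part <- partition_oligomers(tr$frames[, , f], tr$beads$peptide,
                                    tr$box)
        sel <- unlist(part$clusters[lengths(part$clusters) == order])
        if (length(sel) == 0L) next
        labs <- labs[sel, , drop = FALSE]
      }
      for (li in seq_along(.ss_labels_all)) {
        acc[li, ] <- acc[li, ] + colMeans(labs == .ss_labels_all[li])
      }
      wsum <- wsum + 1
    }
    if (wsum == 0) return(NULL)  # missing, not zero
    acc / wsum
  })
  ok <- !vapply(per_traj, is.null, logical(1L))
  if (!any(ok)) {
    stop("no frames matched the requested scope in any trajectory")
  }
  arr <- simplify2array(per_traj[ok])  # labels x residues x traj
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  L <- dim(arr)[2L]
  out <- expand.grid(residue = seq_len(L), label = .ss_labels_all,
                     stringsAsFactors = FALSE)
  out$mean <- as.vector(t(apply(arr, c(1L, 2L), mean)))
  out$sem <- as.vector(t(apply(arr, c(1L, 2L), stats::sd))) /
    sqrt(sum(ok))
  out$n_trajectories <- sum(ok)
  out
}

.window_frames <- function(tr, window) {
  if (is.null(window)) seq_along(tr$times)
  else which(tr$times > window[1L] & tr$times <= window[2L])
}

#' Mean secondary-structure content per peptide versus oligomer order
#'
#' The content of a peptide conformation is the fraction of its residues
#' carrying each label; contents are averaged over all peptides in
#' oligomers of each order (monomers up to `max_order`) and over frames,
#' then the SEM is taken over trajectories.
#'
#' @param trajectories List of `dmd_trajectory`.
#' @param window Time window in tu (`NULL`: all frames).
#' @param max_order Largest oligomer order reported (default 7).
#' @return Data frame: `order`, `label`, `mean`, `sem`, `n_trajectories`.
#' @export
ss_content_by_order <- function(trajectories, window = NULL, max_order = 7L) {
  per_traj <- lapply(trajectories, function(tr) {
    fsel <- .window_frames(tr, window)
    sums <- array(0, c(length(.ss_labels_all), max_order))
    cnt <- numeric(max_order)
    for (f in fsel) {
      labs <- .ss_labels_frame(tr$frames[, , f], tr$beads, tr$topologies,
                               tr$box)
      part <- partition_oligomers(tr$frames[, , f], tr$beads$peptide, tr$box)
      for (cl in part$clusters) {
        n <- length(cl)
        if (n > max_order) next
        for (p in cl) {
          for (li in seq_along(.ss_labels_all)) {
            sums[li, n] <- sums[li, n] +
              mean(labs[p, ] == .ss_labels_all[li])
          }
        }
        cnt[n] <- cnt[n] + n
      }
    }
    list(mean = sweep(sums, 2L, pmax(cnt, 1L), "/"), seen = cnt > 0)
  })
  out <- expand.grid(order = seq_len(max_order), label = .ss_labels_all,
                     stringsAsFactors = FALSE)
  out$mean <- NA_real_; out$sem <- NA_real_; out$n_trajectories <- 0L
  for (n in seq_len(max_order)) {
    seen <- vapply(per_traj, function(x) x$seen[n], logical(1L))
    if (!any(seen)) next
    vals <- vapply(per_traj[seen], function(x) x$mean[, n],
                   numeric(length(.ss_labels_all)))
    vals <- matrix(vals, nrow = length(.ss_labels_all))
    for (li in seq_along(.ss_labels_all)) {
      rows <- out$order == n & out$label == .ss_labels_all[li]
      out$mean[rows] <- mean(vals[li, ])
      out$sem[rows] <- if (sum(seen) > 1L) {
        stats::sd(vals[li, ]) / sqrt(sum(seen))
      } else NA_real_
      out$n_trajectories[rows] <- sum(seen)
    }
  }
  out
}

# -- contact maps ------------------------------------------------------------

# residue centres of mass (equal bead masses) for one peptide
.residue_com <- function(pos, beads, p) {
  rows <- .pep_rows(beads, p)
  res <- beads$residue[rows]
  out <- rowsum(pos[rows, , drop = FALSE], res) / as.vector(table(res))
  out <- out[order(as.integer(rownames(out))), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' Intra- and intermolecular residue contact maps
#'
#' Two residues are in contact when their centres of mass (equal-mass
#' average of the residue's beads) are at most 0.5 nm apart.  For each
#' oligomer of the requested order, contacts within one peptide
#' (excluding bonded neighbours, |i-j| <= 1) enter the intramolecular map,
#' averaged per peptide conformation; contacts between distinct peptides
#' enter the intermolecular map, averaged per ordered peptide pair.  Both
#' maps average over frames in the window and over trajectories.
#'
#' @param trajectories List of `dmd_trajectory`.
#' @param assembly_state Oligomer order n.
#' @param window Time window in tu (`NULL`: all frames).
#' @param threshold Contact distance (A), default 5.0, inclusive.
#' @return List with `intra` and `inter` (`contact_map` objects: fields
#'   `map`, `kind`, `state`, `isoform`, `n_conformations`), or `NULL`
#'   fields when the assembly state never occurs.
#' @export
contact_maps <- function(trajectories, assembly_state, window = NULL,
                         threshold = 5.0) {
  L <- trajectories[[1L]]$topologies[[1L]]$spec$length
  iso <- trajectories[[1L]]$topologies[[1L]]$spec$isoform_id
  intra <- matrix(0, L, L); inter <- matrix(0, L, L)
  n_intra <- 0L; n_inter <- 0L
  for (tr in trajectories) {
    for (f in .window_frames(tr, window)) {
      pos <- tr$frames[, , f]
      part <- partition_oligomers(pos, tr$beads$peptide, tr$box)
      sel <- part$clusters[lengths(part$clusters) == assembly_state]
      if (length(sel) == 0L) next
      u <- unwrap_frame(pos, tr$beads$peptide, tr$box, part)
      for (cl in sel) {
        coms <- lapply(cl, function(p) .residue_com(u, tr$beads, p))
        for (a in seq_along(cl)) {
          D <- as.matrix(stats::dist(coms[[a]]))
          m <- (D <= threshold) * 1
          dimnames(m) <- NULL
          m[abs(row(m) - col(m)) <= 1L] <- 0
          intra <- intra + m
          n_intra <- n_intra + 1L
          for (b in seq_along(cl)) {
            if (a == b) next
            DX <- outer(coms[[a]][, 1L], coms[[b]][, 1L], "-")
            DY <- outer(coms[[a]][, 2L], coms[[b]][, 2L], "-")
            DZ <- outer(coms[[a]][, 3L], coms[[b]][, 3L], "-")
            m2 <- (sqrt(DX^2 + DY^2 + DZ^2) <= threshold) * 1
            inter <- inter + (m2 + t(m2)) / 2
            n_inter <- n_inter + 1L
          }
        }
      }
    }
  }
  mk <- function(m, n, kind) {
    if (n == 0L) return(NULL)
    structure(list(map = m / n, kind = kind, state = assembly_state,
                   isoform = iso, n_conformations = n),
              class = "contact_map")
  }
  list(intra = mk(intra, n_intra, "intra"),
       inter = mk(inter, n_inter, "inter"))
}

#' Difference of two contact maps
#'
#' Elementwise `a - b` on the shared residue range `1..min(L_a, L_b)`;
#' the C-terminal overhang rows/columns of the longer map are returned
#' separately rather than silently dropped.
#'
#' @param map_a,map_b `contact_map` objects of the same kind.
#' @return List with `difference` (m x m signed matrix), `shared_range`,
#'   and `overhang` (the longer map's extra block, `NULL` when the maps
#'   have equal size).
#' @export
contact_map_difference <- function(map_a, map_b) {
  if (!identical(map_a$kind, map_b$kind)) {
    stop("cannot subtract maps of different kinds (",
         map_a$kind, " vs ", map_b$kind, ")")
  }
  La <- nrow(map_a$map); Lb <- nrow(map_b$map)
  m <- min(La, Lb)
  diffm <- map_a$map[seq_len(m), seq_len(m)] -
    map_b$map[seq_len(m), seq_len(m)]
  overhang <- NULL
  if (La != Lb) {
    longer <- if (La > Lb) map_a$map else map_b$map
    overhang <- longer[, (m + 1L):max(La, Lb), drop = FALSE]
  }
  list(difference = diffm, shared_range = c(1L, m), overhang = overhang)
}

# -- SASA and terminus geometry ---------------------------------------------

#' Hydrophobic solvent-accessible surface area
#'
#' Deterministic sphere-sampling SASA with a 1.4 A probe, restricted to
#' the beads of hydrophobic residues; beads of every residue class
#' occlude.  Van der Waals radii are the hard-core radii of the force
#' field.
#'
#' @param pos Unwrapped coordinates (any number of peptides; all beads
#'   occlude each other).
#' @param beads Bead metadata (`role`, `aa`, `core`, `peptide`) as in an
#'   `interaction_table` or trajectory.
#' @param probe Probe radius (A), default 1.4.
#' @param npoints Sphere sample points per bead (default 960).
#' @return Named numeric: total hydrophobic SASA (A^2) per peptide.
#' @export
hydrophobic_sasa <- function(pos, beads, probe = 1.4, npoints = 960L) {
  if (nrow(pos) == 0L) stop("no beads")
  hydrophobic <- classify_hydropathy(beads$aa) == "hydrophobic"
  a <- sasa_points_cpp(pos, beads$core / 2, hydrophobic, probe,
                       as.integer(npoints), .body_frame(pos))
  vapply(split(a, beads$peptide), sum, numeric(1L), na.rm = TRUE)
}

# canonical body frame from the coordinate covariance, with deterministic
# sign fixing, so the sphere sampling co-rotates with the structure and
# the measured area is invariant under rigid motions
.body_frame <- function(pos) {
  if (nrow(pos) < 3L) return(diag(3))
  cc <- stats::cov(pos)
  if (!all(is.finite(cc)) || sum(abs(cc)) < 1e-12) return(diag(3))
  ev <- eigen(cc, symmetric = TRUE)$vectors
  centred <- sweep(pos, 2L, colMeans(pos))
  for (k in 1:3) {
    # rotation-equivariant sign: third central moment along the axis
    proj <- centred %*% ev[, k]
    s <- sum(proj^3)
    if (abs(s) > 1e-9 * sum(abs(proj)^3 + 1e-30)) {
      if (s < 0) ev[, k] <- -ev[, k]
    } else if (ev[which.max(abs(ev[, k])), k] < 0) {
      ev[, k] <- -ev[, k]
    }
  }
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  ev
}

#' End-to-end (N-C) distance of a peptide
#'
#' Euclidean distance between the CA beads of the first and last residue,
#' on unwrapped coordinates.
#'
#' @param pos Unwrapped coordinates of one peptide.
#' @param topology The peptide's `bead_topology`.
#' @return Distance in A.
#' @export
nc_distance <- function(pos, topology) {
  b <- topology$beads
  L <- topology$spec$length
  .vnorm(pos[which(b$residue == L & b$role == "CA"), ] -
           pos[which(b$residue == 1L & b$role == "CA"), ])
}

#' Terminus to oligomer centre-of-mass distances
#'
#' For each peptide of an oligomer: the distance from its N-terminal CA
#' (NT) and C-terminal CA (CT) to the centre of mass of all beads of the
#' oligomer (equal masses).
#'
#' @param pos Unwrapped coordinates of the whole frame.
#' @param beads Bead metadata with `peptide`, `residue`, `role`.
#' @param members Peptide ids forming the oligomer.
#' @return Data frame: `peptide`, `nt_cm`, `ct_cm` (A).
#' @export
terminus_cm_distances <- function(pos, beads, members) {
  rows <- which(beads$peptide %in% members)
  cm <- colMeans(pos[rows, , drop = FALSE])
  do.call(rbind, lapply(members, function(p) {
    res <- beads$residue[.pep_rows(beads, p)]
    L <- max(res)
    nt <- pos[.bead_row(beads, p, 1L, "CA"), ]
    ct <- pos[.bead_row(beads, p, L, "CA"), ]
    data.frame(peptide = p, nt_cm = .vnorm(nt - cm), ct_cm = .vnorm(ct - cm))
  }))
}

#' Per-peptide geometry table of a trajectory
#'
#' The tidy table feeding the free-energy landscapes: for every frame in
#' the window and every peptide, the oligomer order it resides in, its
#' hydrophobic SASA, N-C distance, and NT/CT distances to its oligomer's
#' centre of mass.
#'
#' @param traj A `dmd_trajectory`.
#' @param window Time window in tu (`NULL`: all frames).
#' @param sasa_points Sphere points per bead for the SASA computation.
#' @return Data frame: `time`, `peptide`, `oligomer_size`, `oligomer_id`,
#'   `sasa`, `nc_dist`, `nt_cm`, `ct_cm`.
#' @export
peptide_geometry <- function(traj, window = NULL, sasa_points = 240L) {
  out <- list()
  for (f in .window_frames(traj, window)) {
    pos <- traj$frames[, , f]
    part <- partition_oligomers(pos, traj$beads$peptide, traj$box)
    u <- unwrap_frame(pos, traj$beads$peptide, traj$box, part)
    sasa <- hydrophobic_sasa(u, traj$beads, npoints = sasa_points)
    for (ci in seq_along(part$clusters)) {
      cl <- part$clusters[[ci]]
      tcd <- terminus_cm_distances(u, traj$beads, cl)
      for (p in cl) {
        rows <- .pep_rows(traj$beads, p)
        out[[length(out) + 1L]] <- data.frame(
          time = traj$times[f], peptide = p,
          oligomer_size = length(cl), oligomer_id = ci,
          sasa = unname(sasa[as.character(p)]),
          nc_dist = nc_distance(u[rows, , drop = FALSE],
                                traj$topologies[[p]]),
          nt_cm = tcd$nt_cm[tcd$peptide == p],
          ct_cm = tcd$ct_cm[tcd$peptide == p])
      }
    }
  }
  do.call(rbind, out)
}
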