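# Synthetic-data generators with known ground truth.  Every generator is
# deterministic given its seed and returns machine-readable truth labels
# alongside coordinates, so each analysis stage can be validated without
# running long simulations.

#' Synthetic frame realising a prescribed oligomer partition
#'
#' Places compact bead blobs ("peptides") so that the oligomer criterion
#' (inter-peptide bead distance below 5 A) recovers exactly the requested
#' cluster sizes: peptides within a cluster are chained with a linkage
#' distance below the threshold, clusters are separated by more than the
#' threshold plus a safety gap.
#'
#' @param sizes Integer vector of cluster sizes (sums to the peptide
#'   count).
#' @param box Box edge (A).
#' @param beads_per_peptide Beads per peptide blob (default 12).
#' @param blob_radius Blob radius (A, default 3).
#' @param linkage Surface gap between chained cluster members (A, default
#'   4 — below the 5 A criterion).
#' @param gap Extra clearance between clusters beyond the criterion (A,
#'   default 10).
#' @param seed Random seed.
#' @return List with `pos`, `peptide`, `box`, `truth` (list of peptide-id
#'   clusters), `beads` (minimal metadata table).
#' @export
make_partition_frame <- function(sizes, box = 250, beads_per_peptide = 12L,
                                 blob_radius = 3, linkage = 4, gap = 10,
                                 seed = 1L) {
  stopifnot(all(sizes >= 1L))
  set.seed(seed)
  n_pep <- sum(sizes)
  n_cl <- length(sizes)
  # cluster bounding radius: members are chained along a random walk with
  # step 2*blob_radius + linkage
  step <- 2 * blob_radius + linkage
  cl_rad <- (max(sizes) - 1) * step / 2 + blob_radius
  pitch <- 2 * cl_rad + 5 + gap
  k <- ceiling(n_cl^(1 / 3))
  if (k * pitch > box) {
    stop("infeasible packing: ", n_cl, " clusters of radius ", round(cl_rad),
         " A do not fit in a ", box, " A box")
  }
  sites <- as.matrix(expand.grid(x = seq_len(k), y = seq_len(k),
                                 z = seq_len(k)))[seq_len(n_cl), ,
                                                  drop = FALSE]
  centres <- (sites - 0.5) * (box / k)
  blob <- function() {
    u <- matrix(stats::rnorm(beads_per_peptide * 3L), ncol = 3L)
    u <- u / sqrt(rowSums(u^2)) *
      (stats::runif(beads_per_peptide)^(1 / 3) * blob_radius)
    u
  }
  stopifnot(beads_per_peptide >= 2L)
  pos <- NULL; peptide <- integer(0); truth <- list()
  pid <- 0L
  for (ci in seq_len(n_cl)) {
    members <- integer(0)
    at <- centres[ci, ]
    dir <- stats::rnorm(3L); dir <- dir / .vnorm(dir)
    for (m in seq_len(sizes[ci])) {
      pid <- pid + 1L
      members <- c(members, pid)
      centre_m <- at + ((m - 1L) - (sizes[ci] - 1L) / 2) * step * dir
      q <- sweep(blob(), 2L, centre_m, "+")
      # explicit bridge beads guarantee the linkage distance between
      # consecutive cluster members (and only between those)
      reach <- (step - linkage) / 2
      if (m > 1L) q[1L, ] <- centre_m - dir * reach
      if (m < sizes[ci]) q[2L, ] <- centre_m + dir * reach
      pos <- rbind(pos, q)
      peptide <- c(peptide, rep(pid, beads_per_peptide))
    }
    truth[[ci]] <- members
  }
  beads <- data.frame(peptide = peptide,
                      residue = rep(1L, length(peptide)),
                      role = rep("CA", length(peptide)))
  list(pos = pos, peptide = peptide, box = box, truth = truth,
       beads = beads)
}

#' Bead-cloud ensembles with known inertia scaling
#'
#' Samples bead clouds from uniform solids whose dimensions follow exact
#' power laws in the assembly order n, so the fitted inertia exponents
#' have closed-form targets: spheres of volume proportional to n
#' (`I1 = I2 = I3 ~ n^(5/3)`), rods of fixed thickness and length
#' proportional to n (`I1 = I2 ~ n^3`, `I3 ~ n`), ellipsoids of fixed
#' aspect ratio, and dumbbells (two spheres at fixed centre separation per
#' unit).  Analytic moments of the generating solid are attached as
#' ground truth.
#'
#' @param family `"sphere"`, `"rod"`, `"ellipsoid"` or `"dumbbell"`.
#' @param orders Integer vector of assembly orders n.
#' @param beads_per_unit Beads sampled per order unit (default 120).
#' @param replicates Independent clouds per order (default 8).
#' @param aspect Axis ratio c/a for ellipsoids (default 3).
#' @param r0 Base length scale (A, default 10).
#' @param seed Random seed.
#' @return List with `conformations` (list of `pos`/`n`, ready for
#'   [inertia_spectra()]) and `truth` (data frame of analytic moments per
#'   order, per unit sampling mass).
#' @export
make_shape_ensemble <- function(family = c("sphere", "rod", "ellipsoid",
                                           "dumbbell"),
                                orders = 1:10, beads_per_unit = 120L,
                                replicates = 8L, aspect = 3, r0 = 10,
                                seed = 1L) {
  family <- match.arg(family)
  set.seed(seed)
  sample_ball <- function(k, semi) {
    u <- matrix(stats::rnorm(k * 3L), ncol = 3L)
    u <- u / sqrt(rowSums(u^2)) * stats::runif(k)^(1 / 3)
    sweep(u, 2L, semi, "*")
  }
  conformations <- list(); truth <- list()
  for (n in orders) {
    k <- beads_per_unit * n
    M <- n  # sampling mass proportional to order
    if (family == "sphere") {
      R <- r0 * n^(1 / 3)
      gen <- function() sample_ball(k, c(R, R, R))
      I_true <- rep(2 / 5 * M * R^2, 3L)
    } else if (family == "rod") {
      len <- r0 * n; a <- r0 / 2
      gen <- function() {
        z <- stats::runif(k, -len / 2, len / 2)
        phi <- stats::runif(k, 0, 2 * pi)
        rr <- a * sqrt(stats::runif(k))
        cbind(rr * cos(phi), rr * sin(phi), z)
      }
      I_perp <- M * (len^2 / 12 + a^2 / 4)
      I_true <- c(I_perp, I_perp, M * a^2 / 2)
    } else if (family == "ellipsoid") {
      a <- r0 * n^(1 / 3); cax <- aspect * a
      gen <- function() sample_ball(k, c(a, a, cax))
      I_true <- c(M / 5 * (a^2 + cax^2), M / 5 * (a^2 + cax^2),
                  M / 5 * (2 * a^2))
    } else {  # dumbbell: two equal spheres, centres 3 R apart
      R <- r0 * n^(1 / 3); d <- 1.5 * R
      gen <- function() {
        half <- sample_ball(k, c(R, R, R))
        sgn <- rep_len(c(-1, 1), k)
        half[, 3L] <- half[, 3L] + sgn * d
        half
      }
      I_sph <- 2 / 5 * M * R^2
      I_true <- c(I_sph + M * d^2, I_sph + M * d^2, I_sph)
    }
    for (rep_i in seq_len(replicates)) {
      conformations[[length(conformations) + 1L]] <- list(pos = gen(), n = n)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      n = n, I1 = sort(I_true, decreasing = TRUE)[1L],
      I2 = sort(I_true, decreasing = TRUE)[2L],
      I3 = sort(I_true, decreasing = TRUE)[3L])
  }
  list(conformations = conformations, truth = do.call(rbind, truth),
       family = family)
}

#' Four-bead chains with known secondary-structure labels
#'
#' Builds ideal-dihedral chains for validating the structure classifier:
#' `"extended_strand"` (phi = -120, psi = +120 throughout),
#' `"turn"` (extended chain with a planted tight turn whose two central
#' residues are the truth turn positions), and `"random_coil"`
#' (dihedrals drawn uniformly away from the strand and helix regions).
#'
#' @param template `"extended_strand"`, `"turn"` or `"random_coil"`.
#' @param length Residue count (default 12).
#' @param sequence Optional sequence (default poly-A of `length`).
#' @param turn_at First residue of the planted turn motif (default middle).
#' @param seed Random seed (used by the coil template).
#' @return List with `pos`, `topology`, `truth` (per-residue labels), and
#'   the dihedral vectors `phi`, `psi`.
#' @export
make_ss_chain <- function(template = c("extended_strand", "turn",
                                       "random_coil"),
                          length = 12L, sequence = NULL,
                          turn_at = NULL, seed = 1L) {
  template <- match.arg(template)
  L <- as.integer(length)
  if (is.null(sequence)) sequence <- paste(rep("A", L), collapse = "")
  spec <- build_sequence(sequence)
  stopifnot(spec$length == L)
  topology <- build_topology(spec)
  set.seed(seed)
  if (template == "extended_strand") {
    phi <- rep(-120, L); psi <- rep(120, L)
    truth <- rep("strand", L)
  } else if (template == "turn") {
    if (is.null(turn_at)) turn_at <- max(2L, L %/% 2L - 1L)
    stopifnot(turn_at >= 2L, turn_at + 3L <= L)
    phi <- rep(-120, L); psi <- rep(120, L)
    # type-I-like tight turn at residues turn_at+1, turn_at+2
    phi[turn_at + 1L] <- -60; psi[turn_at + 1L] <- -30
    phi[turn_at + 2L] <- -90; psi[turn_at + 2L] <- 0
    truth <- rep("strand", L)
    truth[c(turn_at + 1L, turn_at + 2L)] <- "turn"
  } else {
    # coil: avoid the extended and helical bands
    phi <- stats::runif(L, -180, 180)
    psi <- numeric(L)
    for (i in seq_len(L)) {
      repeat {
        cand <- stats::runif(1L, -180, 180)
        extended <- phi[i] >= -180 && phi[i] <= -45 &&
          (cand >= 90 || cand <= -150)
        helical <- phi[i] >= -100 && phi[i] <= -30 &&
          cand >= -80 && cand <= -5
        if (!extended && !helical) break
      }
      psi[i] <- cand
    }
    truth <- rep("coil", L)
  }
  pos <- .build_chain(spec$sequence, phi, psi)
  list(pos = pos, topology = topology, truth = truth, phi = phi, psi = psi)
}

#' Mock trajectory interpolating monomeric to clustered states
#'
#' Builds a frame sequence whose ground-truth partitions follow a planted
#' monotone merging schedule (mean oligomer size non-decreasing), using
#' [make_partition_frame()] for each stage.  The result quacks like a
#' `dmd_trajectory` for the oligomer-statistics pipeline (frames, times,
#' beads, box).
#'
#' @param n_peptides Peptide count (default 8).
#' @param n_frames Frame count (default 21).
#' @param frame_interval_tu Frame spacing in tu (default 1e5).
#' @param final_sizes Cluster sizes of the last frame (default: all
#'   dimers).
#' @param box Box edge (A).
#' @param seed Random seed.
#' @return A list of class `dmd_trajectory` (analysis-compatible subset)
#'   plus `truth` (list of per-frame partitions).
#' @export
make_mock_trajectory <- function(n_peptides = 8L, n_frames = 21L,
                                 frame_interval_tu = 1e5,
                                 final_sizes = rep(2L, n_peptides %/% 2L),
                                 box = 250, seed = 1L) {
  stopifnot(sum(final_sizes) == n_peptides)
  # merging schedule: monomers -> final_sizes, interpolated by stages
  schedule <- list(rep(1L, n_peptides))
  current <- rep(1L, n_peptides)
  stage <- current
  repeat {
    # merge the two smallest groups that still undershoot the target
    target <- sort(final_sizes, decreasing = TRUE)
    stage <- sort(stage, decreasing = TRUE)
    if (identical(as.integer(stage), as.integer(target))) break
    o <- order(stage)
    stage <- c(stage[-o[1:2]], stage[o[1L]] + stage[o[2L]])
    schedule[[length(schedule) + 1L]] <- as.integer(stage)
  }
  frames_per_stage <- ceiling(n_frames / length(schedule))
  pos0 <- make_partition_frame(schedule[[1L]], box = box, seed = seed)
  nb <- nrow(pos0$pos)
  frames <- array(NA_real_, c(nb, 3L, n_frames))
  truth <- list()
  for (f in seq_len(n_frames)) {
    si <- min(length(schedule), 1L + (f - 1L) %/% frames_per_stage)
    if (f == n_frames) si <- length(schedule)
    fr <- make_partition_frame(schedule[[si]], box = box,
                               seed = seed + si)
    frames[, , f] <- fr$pos
    truth[[f]] <- fr$truth
  }
  structure(list(
    frames = frames,
    times = (seq_len(n_frames) - 1L) * frame_interval_tu,
    beads = pos0$beads, box = box, truth = truth,
    config = NULL, seed = seed
  ), class = "dmd_trajectory")
}
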