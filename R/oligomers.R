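# Oligomer identification and size distributions.
#
# Two peptides belong to the same oligomer when any inter-peptide bead pair
# is closer than 5 A (strictly less), distances taken with the
# minimum-image convention; oligomers are the connected components of the
# resulting peptide graph.

#' Partition the peptides of one frame into oligomers
#'
#' @param pos N x 3 bead coordinates (A).
#' @param peptide Integer vector (length N): peptide id per bead.
#' @param box Periodic box edge (A); `Inf` for open boundaries.
#' @param threshold Clustering distance (A); pairs strictly below it are
#'   linked (default 5).
#' @param time Optional frame time (tu), stored in the result.
#' @return Object of class `oligomer_partition`: list with `clusters` (list
#'   of integer vectors partitioning the peptide ids), `edges` (two-column
#'   matrix of directly linked peptide pairs), `n_peptides`, `time`.
#' @export
partition_oligomers <- function(pos, peptide, box = Inf, threshold = 5,
                                time = NA_real_) {
  stopifnot(nrow(pos) == length(peptide))
  ids <- sort(unique(peptide))
  np <- length(ids)
  idx <- lapply(ids, function(p) which(peptide == p))
  # prefilter peptide pairs by centroid distance minus spread
  cent <- t(vapply(idx, function(k) .wrapped_centroid(pos[k, , drop = FALSE],
                                                      box),
                   numeric(3L)))
  spread <- vapply(seq_len(np), function(k) {
    d <- .min_image(sweep(pos[idx[[k]], , drop = FALSE], 2L, cent[k, ]), box)
    max(sqrt(rowSums(d^2)))
  }, numeric(1L))
  ei <- integer(0); ej <- integer(0)
  if (np > 1L) {
    for (a in seq_len(np - 1L)) {
      for (b in (a + 1L):np) {
        dc <- .vnorm(.min_image(cent[b, ] - cent[a, ], box))
        if (dc - spread[a] - spread[b] >= threshold) next
        if (.min_cross_distance(pos[idx[[a]], , drop = FALSE],
                                pos[idx[[b]], , drop = FALSE],
                                box) < threshold) {
          ei <- c(ei, a); ej <- c(ej, b)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = np, directed = FALSE)
  if (length(ei) > 0L) g <- igraph::add_edges(g, rbind(ei, ej))
  comp <- igraph::components(g)$membership
  clusters <- unname(split(ids, comp))
  structure(list(clusters = clusters,
                 edges = cbind(ids[ei], ids[ej]),
                 n_peptides = np, time = time),
            class = "oligomer_partition")
}

# centroid that is robust to wrapping: take minimum images relative to the
# first bead, average, wrap back
.wrapped_centroid <- function(p, box) {
  ref <- p[1L, ]
  d <- .min_image(sweep(p, 2L, ref), box)
  out <- ref + colMeans(d)
  if (is.finite(box)) out <- out - box * floor(out / box)
  out
}

.min_cross_distance <- function(a, b, box) {
  m <- nrow(a); k <- nrow(b)
  dx <- .min_image(outer(b[, 1L], a[, 1L], "-"), box)
  dy <- .min_image(outer(b[, 2L], a[, 2L], "-"), box)
  dz <- .min_image(outer(b[, 3L], a[, 3L], "-"), box)
  sqrt(min(dx * dx + dy * dy + dz * dz))
}

#' Partition every frame of a trajectory
#'
#' @param traj A `dmd_trajectory` (or compatible list with `frames`,
#'   `times`, `beads$peptide`, `box`).
#' @param frames Optional integer subset of frame indices.
#' @return List of `oligomer_partition`, one per selected frame.
#' @export
partition_trajectory <- function(traj, frames = seq_along(traj$times)) {
  lapply(frames, function(f) {
    partition_oligomers(traj$frames[, , f], traj$beads$peptide, traj$box,
                        time = traj$times[f])
  })
}

#' Oligomer sizes of a partition
#'
#' @param partition An `oligomer_partition`.
#' @return Integer vector of cluster sizes.
#' @export
oligomer_sizes <- function(partition) {
  lengths(partition$clusters)
}

.distribution_one <- function(sizes, n_peptides, kind) {
  counts <- tabulate(sizes, nbins = n_peptides)
  if (kind == "molar") counts / sum(counts)
  else counts * seq_len(n_peptides) / n_peptides
}

.size_distribution <- function(partitions, kind) {
  if (length(partitions) == 0L) stop("no partitions supplied")
  np <- partitions[[1L]]$n_peptides
  per_frame <- t(vapply(partitions, function(p) {
    stopifnot(p$n_peptides == np)
    .distribution_one(oligomer_sizes(p), np, kind)
  }, numeric(np)))
  structure(list(
    kind = kind,
    propensity = colMeans(per_frame),
    per_frame = per_frame,
    times = vapply(partitions, function(p) p$time, numeric(1L)),
    n_peptides = np, sem = NULL, n_trajectories = 1L
  ), class = "size_distribution")
}

#' Molar oligomer size distribution
#'
#' For each frame, the number of oligomers of each size divided by the
#' total number of oligomers; `propensity` averages the supplied frames
#' (use a single frame for time-evolution snapshots, a window for
#' steady-state distributions).
#'
#' @param partitions List of `oligomer_partition` from one trajectory.
#' @return Object of class `size_distribution` with `propensity[n]`,
#'   `per_frame` (frames x sizes) and metadata.
#' @export
molar_distribution <- function(partitions) {
  .size_distribution(partitions, "molar")
}

#' Mass-weighted oligomer size distribution
#'
#' The count of size-n oligomers times n, divided by the number of
#' peptides: the probability that a peptide resides in an n-mer.
#'
#' @inheritParams molar_distribution
#' @return A `size_distribution`, as [molar_distribution()].
#' @export
mass_weighted_distribution <- function(partitions) {
  .size_distribution(partitions, "mass_weighted")
}

#' Ensemble average of per-trajectory size distributions
#'
#' @param distributions List of `size_distribution` objects (>= 2), one per
#'   replica trajectory, all of the same kind.
#' @return A `size_distribution` whose `propensity` is the mean over
#'   trajectories and whose `sem` is the standard error of the mean,
#'   `sd/sqrt(n_trajectories)`.
#' @export
ensemble_average <- function(distributions) {
  if (length(distributions) < 2L) {
    stop("the SEM is undefined for fewer than two trajectories")
  }
  kinds <- vapply(distributions, function(d) d$kind, character(1L))
  if (length(unique(kinds)) != 1L) stop("mixed distribution kinds")
  m <- t(vapply(distributions, function(d) d$propensity,
                numeric(length(distributions[[1L]]$propensity))))
  structure(list(
    kind = kinds[1L],
    propensity = colMeans(m),
    sem = apply(m, 2L, stats::sd) / sqrt(nrow(m)),
    per_trajectory = m,
    n_peptides = distributions[[1L]]$n_peptides,
    n_trajectories = nrow(m)
  ), class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> %s over %d peptides", x$kind,
              x$n_peptides))
  if (!is.null(x$n_trajectories) && x$n_trajectories > 1L) {
    cat(sprintf(", %d trajectories", x$n_trajectories))
  }
  cat("\n")
  occ <- which(x$propensity > 0)
  for (n in occ) {
    cat(sprintf("  n=%2d  P=%.4f%s\n", n, x$propensity[n],
                if (!is.null(x$sem)) sprintf(" +/- %.4f", x$sem[n]) else ""))
  }
  invisible(x)
}

#' Mean oligomer size of a distribution
#'
#' @param x A `size_distribution`.
#' @return `sum(n * P(n))` (number- or mass-averaged size depending on the
#'   kind).
#' @export
mean_oligomer_size <- function(x) {
  sum(seq_along(x$propensity) * x$propensity)
}

#' Export a size distribution as CSV
#'
#' Columns `size`, `propensity`, `sem` (NA when unavailable).
#'
#' @param x A `size_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_size_distribution <- function(x, path) {
  df <- data.frame(size = seq_along(x$propensity),
                   propensity = x$propensity,
                   sem = if (is.null(x$sem)) NA_real_ else x$sem)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
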