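# Free-energy (potential of mean force) surfaces over two reaction
# coordinates, and shape analysis via principal moments of inertia with
# fractal scaling exponents.

#' Potential of mean force over two reaction coordinates
#'
#' Bins the reaction coordinates (hydrophobic SASA as X1, N-C distance as
#' X2 in the standard pipeline), normalises the 2D histogram to a
#' probability P, and sets `W = W0 - ln P` on occupied bins with
#' `W0 = -ln(N + 1)` (N = number of conformations).  Unoccupied bins carry
#' `NA`, not infinities.  With `mode = "per_oligomer_average"` the
#' coordinates are first averaged over the peptides within each oligomer
#' (requiring `oligomer` ids), which smooths the landscape.
#'
#' Only differences of W are physically meaningful; the W0 offset makes
#' the absolute level depend on the sample size by construction.
#'
#' @param x1,x2 Reaction coordinate vectors (one entry per peptide
#'   conformation).
#' @param breaks1,breaks2 Bin edges; a single number is a bin width
#'   (defaults: 50 A^2 for X1, 2 A for X2) from which edges covering the
#'   data are built.
#' @param mode `"per_peptide"` or `"per_oligomer_average"`.
#' @param oligomer Oligomer id per entry (frame-unique), required for the
#'   averaged mode.
#' @return Object of class `free_energy_surface`: list with `W` (matrix,
#'   kB T), `W0`, `breaks1`, `breaks2`, `P`, `N`, `mode`.
#' @export
pmf_surface <- function(x1, x2, breaks1 = 50, breaks2 = 2,
                        mode = c("per_peptide", "per_oligomer_average"),
                        oligomer = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(x1) == length(x2), length(x1) >= 1L,
            all(is.finite(x1)), all(is.finite(x2)))
  if (mode == "per_oligomer_average") {
    if (is.null(oligomer)) stop("oligomer ids required for averaged mode")
    key <- as.character(oligomer)
    x1 <- vapply(split(x1, key), mean, numeric(1L))
    x2 <- vapply(split(x2, key), mean, numeric(1L))
  }
  edges <- function(x, br) {
    if (length(br) > 1L) return(br)
    if (br <= 0) stop("zero-width bins")
    lo <- floor(min(x) / br) * br
    hi <- ceiling(max(x) / br) * br
    if (hi <= lo) hi <- lo + br
    seq(lo, hi, by = br)
  }
  b1 <- edges(x1, breaks1); b2 <- edges(x2, breaks2)
  i1 <- findInterval(x1, b1, rightmost.closed = TRUE)
  i2 <- findInterval(x2, b2, rightmost.closed = TRUE)
  counts <- matrix(0, length(b1) - 1L, length(b2) - 1L)
  for (k in seq_along(i1)) {
    counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1
  }
  N <- length(x1)
  P <- counts / N
  W0 <- -log(N + 1)
  W <- matrix(NA_real_, nrow(P), ncol(P))
  occ <- P > 0
  W[occ] <- W0 - log(P[occ])
  structure(list(W = W, W0 = W0, breaks1 = b1, breaks2 = b2, P = P, N = N,
                 mode = mode),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  occ <- sum(!is.na(x$W))
  cat(sprintf(
    "<free_energy_surface> %d x %d bins (%d occupied), N = %d, W0 = %.3f\n",
    nrow(x$W), ncol(x$W), occ, x$N, x$W0))
  mn <- which(x$W == min(x$W, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  cat(sprintf("  minimum W = %.3f at X1 in [%g, %g], X2 in [%g, %g]\n",
              min(x$W, na.rm = TRUE),
              x$breaks1[mn[1L]], x$breaks1[mn[1L] + 1L],
              x$breaks2[mn[2L]], x$breaks2[mn[2L] + 1L]))
  invisible(x)
}

#' Export a PMF grid as CSV
#'
#' Columns `x1_lo`, `x1_hi`, `x2_lo`, `x2_hi`, `W` (occupied bins only).
#'
#' @param surface A `free_energy_surface`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmf_csv <- function(surface, path) {
  occ <- which(!is.na(surface$W), arr.ind = TRUE)
  df <- data.frame(
    x1_lo = surface$breaks1[occ[, 1L]],
    x1_hi = surface$breaks1[occ[, 1L] + 1L],
    x2_lo = surface$breaks2[occ[, 2L]],
    x2_hi = surface$breaks2[occ[, 2L] + 1L],
    W = surface$W[occ])
  utils::write.csv(df[order(df$x1_lo, df$x2_lo), ], path, row.names = FALSE)
  invisible(path)
}

#' Principal moments of inertia of a conformation
#'
#' Eigenvalues of the standard inertia tensor
#' `sum_k m_k (r_k^2 I - r_k r_k^T)` about the centre of mass with equal
#' bead masses, sorted `I1 >= I2 >= I3` and normalised by the monomer mass
#' `M0`.  Collinear geometries give `I3 = 0` with a flag.
#'
#' @param pos Unwrapped coordinates of the assembly.
#' @param n Oligomer order (stored in the result).
#' @param M0 Monomer mass in bead-mass units (e.g. bead count of one
#'   peptide).
#' @param mass Per-bead masses (default 1).
#' @return List with `n`, `I` (length 3, descending, units of
#'   mass * A^2 / M0), `degenerate` (TRUE when all beads are collinear).
#' @export
inertia_spectrum <- function(pos, n = 1L, M0 = 1, mass = 1) {
  stopifnot(nrow(pos) >= 1L)
  m <- rep_len(mass, nrow(pos))
  cm <- colSums(pos * m) / sum(m)
  q <- sweep(pos, 2L, cm)
  r2 <- rowSums(q^2)
  Tn <- diag(sum(m * r2), 3L) - t(q * m) %*% q
  ev <- sort(eigen(Tn, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0 & ev > -1e-9] <- 0
  degenerate <- ev[3L] <= 1e-9 * max(ev[1L], 1)
  list(n = n, I = ev / M0, degenerate = degenerate)
}

#' Collect inertia spectra into a data frame
#'
#' @param conformations List of lists with `pos` and `n` (e.g. from
#'   [make_shape_ensemble()] or oligomer extraction).
#' @param M0 Monomer mass.
#' @return Data frame: `n`, `I1`, `I2`, `I3`, `degenerate`.
#' @export
inertia_spectra <- function(conformations, M0 = 1) {
  do.call(rbind, lapply(conformations, function(cf) {
    s <- inertia_spectrum(cf$pos, n = cf$n, M0 = M0)
    data.frame(n = s$n, I1 = s$I[1L], I2 = s$I[2L], I3 = s$I[3L],
               degenerate = s$degenerate)
  }))
}

#' Fit fractal scaling exponents from inertia spectra
#'
#' Least-squares slope of `log Ii` versus `log n` using the per-order
#' ensemble means of each principal moment, on configurable order ranges
#' (defaults: orders 4-10 for I1 and I2, 1-6 for I3).  The derived
#' exponents follow from the slopes a1..a3: elongation
#' `alpha = (a1 + a2)/4 - 1/2`, thickness `beta = a3/2 - 1/2`, and volume
#' `gamma = (a1 + a2)/4 + a3 - 3/2` (from `I1 ~ I2 ~ M L^2`,
#' `I3 ~ M D^2`, `M = n M0`, `V ~ L D^2`).
#'
#' @param spectra Data frame from [inertia_spectra()].
#' @param range12 Order range for the I1 and I2 fits (default `c(4, 10)`).
#' @param range3 Order range for the I3 fit (default `c(1, 6)`).
#' @return Object of class `scaling_fit`: list with `exponents` (a1, a2,
#'   a3 with standard errors), `alpha`, `beta`, `gamma` (each with `se`),
#'   and the fit ranges.
#' @export
fit_scaling_exponents <- function(spectra, range12 = c(4, 10),
                                  range3 = c(1, 6)) {
  fit_one <- function(col, rng) {
    s <- spectra[spectra$n >= rng[1L] & spectra$n <= rng[2L], ]
    mu <- vapply(split(s[[col]], s$n), mean, numeric(1L))
    nn <- as.numeric(names(mu))
    if (length(nn) < 3L) {
      stop("need at least 3 distinct orders in the fit range for ", col)
    }
    if (any(mu <= 0)) stop("non-positive moments in the fit range")
    fm <- stats::lm(log(mu) ~ log(nn))
    c(slope = unname(stats::coef(fm)[2L]),
      se = summary(fm)$coefficients[2L, 2L])
  }
  a1 <- fit_one("I1", range12)
  a2 <- fit_one("I2", range12)
  a3 <- fit_one("I3", range3)
  prop <- function(w) sqrt(sum((w * c(a1["se"], a2["se"], a3["se"]))^2))
  structure(list(
    exponents = data.frame(
      moment = c("I1", "I2", "I3"),
      exponent = c(a1["slope"], a2["slope"], a3["slope"]),
      se = c(a1["se"], a2["se"], a3["se"])),
    alpha = c(value = unname((a1["slope"] + a2["slope"]) / 4 - 0.5),
              se = prop(c(0.25, 0.25, 0))),
    beta = c(value = unname(a3["slope"] / 2 - 0.5),
             se = prop(c(0, 0, 0.5))),
    gamma = c(value = unname((a1["slope"] + a2["slope"]) / 4 +
                               a3["slope"] - 1.5),
              se = prop(c(0.25, 0.25, 1))),
    range12 = range12, range3 = range3
  ), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("<scaling_fit>\n")
  for (k in seq_len(3L)) {
    cat(sprintf("  %s ~ n^%.3f (se %.3f)\n", x$exponents$moment[k],
                x$exponents$exponent[k], x$exponents$se[k]))
  }
  cat(sprintf("  alpha = %.3f +/- %.3f (elongation)\n",
              x$alpha["value"], x$alpha["se"]))
  cat(sprintf("  beta  = %.3f +/- %.3f (thickness)\n",
              x$beta["value"], x$beta["se"]))
  cat(sprintf("  gamma = %.3f +/- %.3f (volume)\n",
              x$gamma["value"], x$gamma["se"]))
  invisible(x)
}

#' Export a scaling fit as a JSON report
#'
#' @param fit A `scaling_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scaling_json <- function(fit, path) {
  jsonlite::write_json(
    list(exponents = fit$exponents,
         alpha = as.list(fit$alpha), beta = as.list(fit$beta),
         gamma = as.list(fit$gamma),
         range12 = fit$range12, range3 = fit$range3),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Shape ratios by oligomer order
#'
#' Per-order ensemble means of I3/I1 and I3/I2 with SEM; values near 1
#' mark quasi-spherical assemblies, small values elongated ones.
#'
#' @param spectra Data frame from [inertia_spectra()].
#' @return Data frame: `n`, `r31`, `r31_sem`, `r32`, `r32_sem`,
#'   `n_conformations`.
#' @export
shape_ratios <- function(spectra) {
  do.call(rbind, lapply(sort(unique(spectra$n)), function(n) {
    s <- spectra[spectra$n == n, ]
    r31 <- s$I3 / s$I1; r32 <- s$I3 / s$I2
    sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x))
                       else NA_real_
    data.frame(n = n, r31 = mean(r31), r31_sem = sem(r31),
               r32 = mean(r32), r32_sem = sem(r32),
               n_conformations = nrow(s))
  }))
}

#' Extract oligomer conformations from trajectories
#'
#' Pulls every oligomer of order `1..max_order` from the frames in the
#' window, as unwrapped coordinate sets ready for [inertia_spectra()].
#'
#' @param trajectories List of `dmd_trajectory`.
#' @param window Time window in tu (`NULL`: all frames).
#' @param max_order Largest order kept (default 10).
#' @return List of lists with `pos` and `n`.
#' @export
oligomer_conformations <- function(trajectories, window = NULL,
                                   max_order = 10L) {
  out <- list()
  for (tr in trajectories) {
    for (f in .window_frames(tr, window)) {
      pos <- tr$frames[, , f]
      part <- partition_oligomers(pos, tr$beads$peptide, tr$box)
      u <- unwrap_frame(pos, tr$beads$peptide, tr$box, part)
      for (cl in part$clusters) {
        if (length(cl) > max_order) next
        rows <- which(tr$beads$peptide %in% cl)
        out[[length(out) + 1L]] <- list(pos = u[rows, , drop = FALSE],
                                        n = length(cl))
      }
    }
  }
  out
}
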