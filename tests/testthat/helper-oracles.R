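# Independent oracles used across the suite.  These deliberately share no
# code with the implementation paths they check: the dynamics oracle is a
# synchronous all-pairs next-event search without heap, cells or
# counters; the clustering oracle is an O(P^2 B^2) scan plus union-find;
# the inertia oracle assembles the tensor element by element.

# minimum-image helper (scalar/vector)
mi <- function(d, box) if (is.finite(box)) d - box * round(d / box) else d

# --- synchronous square-well dynamics oracle -------------------------------
# beads: pos (n x 3), vel (n x 3), all masses 1.  Interactions:
#   core: hard-core diameter matrix (n x n; 0 = none)
#   well: list(depth matrix (negative = attraction), cutoff) or NULL
#   bonds: data.frame(i, j, dmin, dmax) or NULL
# Runs to t_end; returns positions at the sample times (synchronous).
oracle_dmd <- function(pos, vel, box, t_end, sample_times,
                       core, well = NULL, bonds = NULL) {
  n <- nrow(pos)
  eng <- function(i, j) {     # engaged well registry by current distance
    if (is.null(well)) return(FALSE)
    d <- sqrt(sum(mi(pos[j, ] - pos[i, ], box)^2))
    well$depth[i, j] != 0 && d < well$cutoff
  }
  bonded <- matrix(FALSE, n, n)
  bmin <- bmax <- matrix(0, n, n)
  if (!is.null(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds$i[k]; b <- bonds$j[k]
      bonded[a, b] <- bonded[b, a] <- TRUE
      bmin[a, b] <- bmin[b, a] <- bonds$dmin[k]
      bmax[a, b] <- bmax[b, a] <- bonds$dmax[k]
    }
  }
  inside <- matrix(FALSE, n, n)
  if (!is.null(well)) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      inside[i, j] <- inside[j, i] <- eng(i, j)
    }
  }
  t_cross <- function(i, j, d, from_outside) {
    dr <- mi(pos[j, ] - pos[i, ], box); dv <- vel[j, ] - vel[i, ]
    r2 <- sum(dr^2); b <- sum(dr * dv); v2 <- sum(dv^2)
    if (v2 == 0) return(Inf)
    disc <- b^2 - v2 * (r2 - d^2)
    if (from_outside) {
      if (b >= 0 || disc <= 0 || r2 <= d^2) return(Inf)
      (-b - sqrt(disc)) / v2
    } else {
      if (disc < 0) return(Inf)
      tt <- (-b + sqrt(disc)) / v2
      if (tt <= 0) Inf else tt
    }
  }
  t_now <- 0
  samples <- array(NA_real_, c(n, 3, length(sample_times)))
  si <- 1L
  repeat {
    # next event over all pairs
    best <- list(t = Inf)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      cand <- list()
      if (bonded[i, j]) {
        cand <- c(cand,
                  list(list(t = t_cross(i, j, bmin[i, j], TRUE), du = 0)),
                  list(list(t = t_cross(i, j, bmax[i, j], FALSE), du = 0)))
      } else {
        dc <- core[i, j]
        if (dc > 0) {
          cand <- c(cand, list(list(t = t_cross(i, j, dc, TRUE), du = 0)))
        }
        if (!is.null(well) && well$depth[i, j] != 0) {
          if (inside[i, j]) {
            cand <- c(cand, list(list(
              t = t_cross(i, j, well$cutoff, FALSE),
              du = -well$depth[i, j], out = TRUE)))
          } else {
            cand <- c(cand, list(list(
              t = t_cross(i, j, well$cutoff, TRUE),
              du = well$depth[i, j], out = FALSE)))
          }
        }
      }
      for (cd in cand) {
        if (cd$t < best$t) best <- c(cd, list(i = i, j = j))
      }
    }
    t_next <- t_now + best$t
    # emit samples that fall before the event
    while (si <= length(sample_times) && sample_times[si] <= min(t_next, t_end)) {
      dt <- sample_times[si] - t_now
      samples[, , si] <- pos + vel * dt
      si <- si + 1L
    }
    if (t_next > t_end) break
    pos <- pos + vel * best$t
    t_now <- t_next
    i <- best$i; j <- best$j
    dr <- mi(pos[j, ] - pos[i, ], box)
    nh <- dr / sqrt(sum(dr^2))
    s <- sum((vel[j, ] - vel[i, ]) * nh)
    mu <- 0.5
    du <- best$du
    if (du != 0 && s^2 > 2 * du / mu) {
      sp <- sign(s) * sqrt(s^2 - 2 * du / mu)
      if (!is.null(best$out) && best$out) inside[i, j] <- inside[j, i] <- FALSE
      else inside[i, j] <- inside[j, i] <- TRUE
    } else {
      sp <- -s
    }
    imp <- mu * (sp - s)
    vel[i, ] <- vel[i, ] - imp * nh
    vel[j, ] <- vel[j, ] + imp * nh
  }
  samples
}

# --- delta-t stepping crossing-time oracle ---------------------------------
# time at which |r_ij + v_ij t| first crosses distance d, by fine stepping
# plus bisection refinement
oracle_crossing_time <- function(r_i, r_j, v_i, v_j, d, t_max = 100,
                                 dt = 1e-3) {
  f <- function(t) sqrt(sum((r_j - r_i + (v_j - v_i) * t)^2)) - d
  s0 <- sign(f(0))
  t <- 0
  while (t < t_max) {
    t2 <- t + dt
    if (sign(f(t2)) != s0) {
      lo <- t; hi <- t2
      for (k in 1:60) {
        mid <- (lo + hi) / 2
        if (sign(f(mid)) == s0) lo <- mid else hi <- mid
      }
      return((lo + hi) / 2)
    }
    t <- t2
  }
  NA_real_
}

# --- brute-force clustering oracle -----------------------------------------
oracle_clusters <- function(pos, peptide, box, threshold = 5) {
  ids <- sort(unique(peptide))
  np <- length(ids)
  parent <- seq_len(np)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(np - 1)) for (b in (a + 1):np) {
    pa <- pos[peptide == ids[a], , drop = FALSE]
    pb <- pos[peptide == ids[b], , drop = FALSE]
    linked <- FALSE
    for (u in seq_len(nrow(pa))) {
      for (v in seq_len(nrow(pb))) {
        if (sqrt(sum(mi(pb[v, ] - pa[u, ], box)^2)) < threshold) {
          linked <- TRUE; break
        }
      }
      if (linked) break
    }
    if (linked) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(np), find, integer(1))
  unname(split(ids, roots))
}

# canonical form of a clustering for comparison
canon_clusters <- function(cl) {
  s <- lapply(cl, sort)
  s[order(vapply(s, min, numeric(1)))]
}

# --- element-wise inertia tensor oracle ------------------------------------
oracle_inertia <- function(pos, mass = 1) {
  m <- rep_len(mass, nrow(pos))
  cm <- colSums(pos * m) / sum(m)
  I <- matrix(0, 3, 3)
  for (k in seq_len(nrow(pos))) {
    r <- pos[k, ] - cm
    I <- I + m[k] * (sum(r^2) * diag(3) - outer(r, r))
  }
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

# random rigid motion
rigid_motion <- function(pos) {
  R <- abetadmd:::.random_rotation()
  shift <- stats::rnorm(3, sd = 10)
  sweep(pos %*% t(R), 2, shift, "+")
}
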