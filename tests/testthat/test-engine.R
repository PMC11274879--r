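# Event-driven core: collision prediction and resolution, conservation
# laws, oracle agreement, thermostat, and the two-stage protocol.

test_that("pair event prediction solves the crossing quadratic", {
  # head-on approach: gap of 6 A closed at 1 A per time unit
  expect_equal(predict_pair_event(c(10, 0, 0), c(20, 0, 0),
                                  c(0, 0, 0), c(-1, 0, 0), d = 4), 6)
  # receding pair never reaches an inner discontinuity
  expect_true(is.na(predict_pair_event(c(0, 0, 0), c(10, 0, 0),
                                       c(0, 0, 0), c(1, 0, 0), d = 4)))
  expect_error(predict_pair_event(c(NaN, 0, 0), c(1, 0, 0),
                                  c(0, 0, 0), c(1, 0, 0), d = 1),
               "non-finite")
  # oblique approaches against the fine-stepping oracle
  set.seed(42)
  for (k in 1:20) {
    r1 <- runif(3, 0, 5); r2 <- r1 + c(8, runif(2, -2, 2))
    v1 <- rnorm(3, sd = 0.3); v2 <- v1 + c(-1, rnorm(2, sd = 0.2))
    t_pred <- predict_pair_event(r1, r2, v1, v2, d = 4)
    t_orac <- oracle_crossing_time(r1, r2, v1, v2, d = 4)
    if (is.na(t_pred)) {
      expect_true(is.na(t_orac))
    } else {
      expect_equal(t_pred, t_orac, tolerance = 1e-9)
    }
  }
  # minimum image: the nearest periodic image defines the approach
  t_mi <- predict_pair_event(c(1, 0, 0), c(29, 0, 0),
                             c(-1, 0, 0), c(1, 0, 0), d = 1, box = 30)
  expect_equal(t_mi, 0.5)  # images 2 A apart closing at 2 A/tu
})

test_that("event resolution conserves momentum and books energy steps", {
  # equal-mass head-on core collision exchanges velocities
  r <- resolve_pair_event(c(1, 0, 0), c(-1, 0, 0), n_hat = c(1, 0, 0))
  expect_equal(r$v_i, c(-1, 0, 0))
  expect_equal(r$v_j, c(1, 0, 0))
  expect_equal(r$dKE, 0)
  # well capture releases the step depth into radial kinetic energy
  r2 <- resolve_pair_event(c(0.1, 0, 0), c(-0.1, 0, 0),
                           n_hat = c(1, 0, 0), du = -0.3)
  expect_true(r2$crossed)
  expect_equal(r2$dKE, 0.3)
  expect_equal(r2$v_i + r2$v_j, c(0, 0, 0))  # momentum
  # escape attempt with insufficient radial energy reflects
  r3 <- resolve_pair_event(c(-0.1, 0, 0), c(0.1, 0, 0),
                           n_hat = c(1, 0, 0), du = 0.3)
  expect_false(r3$crossed)
  expect_equal(r3$dKE, 0)
  expect_equal(sum((r3$v_j - r3$v_i) * c(1, 0, 0)), -0.2)  # sign flipped
})

test_that("energy and momentum are conserved over many events", {
  set.seed(7)
  n <- 12
  pos <- matrix(runif(3 * n, 2, 23), ncol = 3)
  # pull apart any initial core overlaps
  repeat {
    D <- as.matrix(dist(pos)); diag(D) <- Inf
    if (min(D) > 3.05) break
    w <- which(D == min(D), arr.ind = TRUE)[1, ]
    pos[w[1], ] <- pos[w[1], ] + runif(3, -2, 2)
    pos[w[1], ] <- pmin(pmax(pos[w[1], ], 1), 24)
  }
  vel <- matrix(rnorm(3 * n, sd = 0.6), ncol = 3)
  bonds <- data.frame(i = c(1, 3), j = c(2, 4),
                      dmin = 1.45, dmax = 1.55)
  pos[2, ] <- pos[1, ] + c(1.5, 0, 0)
  pos[4, ] <- pos[3, ] + c(1.5, 0, 0)
  out <- run_beads(pos, vel, box = 25, t_end = 1500, frame_dt = 25,
                   core = 3, bonds = bonds,
                   welltype = rep(0L, n), eps = matrix(-0.3, 1, 1),
                   well_cutoff = 7.5)
  expect_gt(out$n_events, 2e4)
  E <- out$frame_kinetic + out$frame_potential
  expect_lt(max(abs(E - E[1])), 1e-9 * out$n_events)
  # total momentum is conserved exactly up to floating point
  expect_equal(colSums(out$vel), colSums(vel), tolerance = 1e-10)
})

test_that("no emitted frame contains a hard-core overlap", {
  set.seed(11)
  n <- 10
  pos <- matrix(runif(3 * n, 1, 29), ncol = 3)
  repeat {
    D <- as.matrix(dist(pos)); diag(D) <- Inf
    if (min(D) > 3.05) break
    w <- which(D == min(D), arr.ind = TRUE)[1, ]
    pos[w[1], ] <- runif(3, 1, 29)
  }
  vel <- matrix(rnorm(3 * n, sd = 0.5), ncol = 3)
  out <- run_beads(pos, vel, box = 30, t_end = 300, frame_dt = 5,
                   core = 3, welltype = rep(0L, n),
                   eps = matrix(-0.2, 1, 1))
  for (f in seq_len(out$n_frames)) {
    p <- out$frames[, , f]
    dx <- mi(outer(p[, 1], p[, 1], "-"), 30)
    dy <- mi(outer(p[, 2], p[, 2], "-"), 30)
    dz <- mi(outer(p[, 3], p[, 3], "-"), 30)
    D <- sqrt(dx^2 + dy^2 + dz^2); diag(D) <- Inf
    expect_gt(min(D), 3 - 1e-8)
  }
})

test_that("the engine matches a synchronous all-pairs oracle", {
  set.seed(3)
  n <- 6
  pos <- matrix(c(5, 5, 5,  12, 5, 5,  5, 12, 5,  12, 12, 5,
                  5, 5, 12,  12, 12, 12), ncol = 3, byrow = TRUE)
  pos <- pos + matrix(runif(3 * n, -0.5, 0.5), ncol = 3)
  vel <- matrix(rnorm(3 * n, sd = 0.4), ncol = 3)
  box <- 24
  sample_times <- seq(2, 40, by = 2)
  out <- run_beads(pos, vel, box = box, t_end = 40, frame_dt = 2,
                   core = 3, welltype = rep(0L, n),
                   eps = matrix(-0.3, 1, 1), well_cutoff = 7.5)
  core_m <- matrix(3, n, n)
  orac <- oracle_dmd(pos, vel, box, t_end = 40,
                     sample_times = sample_times, core = core_m,
                     well = list(depth = matrix(-0.3, n, n), cutoff = 7.5))
  for (k in seq_along(sample_times)) {
    p_eng <- out$frames[, , k + 1L]  # frame 1 is t = 0
    p_ora <- orac[, , k]
    # compare via minimum-image displacement (engine wraps, oracle not)
    d <- mi(p_eng - p_ora, box)
    expect_lt(max(abs(d)), 1e-3)  # 1e-4 nm
  }
})

test_that("the engine is deterministic for identical inputs", {
  set.seed(5)
  pos <- matrix(runif(24, 2, 28), ncol = 3)
  vel <- matrix(rnorm(24, sd = 0.5), ncol = 3)
  o1 <- run_beads(pos, vel, box = 30, t_end = 100, frame_dt = 10,
                  core = 3, welltype = rep(0L, 8), eps = matrix(-0.3, 1, 1))
  o2 <- run_beads(pos, vel, box = 30, t_end = 100, frame_dt = 10,
                  core = 3, welltype = rep(0L, 8), eps = matrix(-0.3, 1, 1))
  expect_identical(o1$frames, o2$frames)
  expect_identical(o1$vel, o2$vel)
})

test_that("the thermostat holds an ideal gas at the target temperature", {
  set.seed(9)
  n <- 64
  pos <- matrix(runif(3 * n, 0, 40), ncol = 3)
  vel <- matrix(rnorm(3 * n, sd = sqrt(0.5)), ncol = 3)  # start hot
  T_target <- 0.13
  out <- run_beads(pos, vel, box = 40, t_end = 2000, frame_dt = 10,
                   core = 0.5,
                   thermostat = list(T = T_target, interval = 5, tau = 50))
  Tk <- 2 * out$frame_kinetic / (3 * n)
  # discard the equilibration third
  Tbar <- mean(Tk[-(1:70)])
  expect_lt(abs(Tbar - T_target) / T_target, 0.02)
})

test_that("the lattice initialiser separates and centres peptides", {
  cfg <- simulation_config("Ab42", n_peptides = 32L, box_nm = 25,
                           total_time_tu = 1e3, seed = 1)
  set.seed(1)
  st <- initialize_lattice(cfg)
  expect_identical(nrow(st$pos), 32L * 162L)
  # no two peptides within the interaction cutoff
  pep <- st$table$beads$peptide
  cent <- t(vapply(1:32, function(p) colMeans(st$pos[pep == p, ]),
                   numeric(3)))
  mind_all <- Inf
  for (a in 1:31) for (b in (a + 1):32) {
    dc <- sqrt(sum(mi(cent[b, ] - cent[a, ], 250)^2))
    if (dc > 80) next
    mind_all <- min(mind_all,
                    abetadmd:::.min_cross_distance(
                      st$pos[pep == a, ], st$pos[pep == b, ], 250))
  }
  expect_gt(mind_all, 7.5)
  # all bonded constraints hold at t = 0
  tp <- st$topologies[[1]]
  for (p in c(1L, 17L)) {
    q <- st$pos[pep == p, ]
    d <- sqrt(rowSums((q[tp$bonds$i, ] - q[tp$bonds$j, ])^2))
    expect_true(all(d > tp$bonds$dmin & d < tp$bonds$dmax))
  }
  # single peptide is centred in the box
  cfg1 <- simulation_config("Ab42", n_peptides = 1L, box_nm = 8,
                            total_time_tu = 1e3, seed = 1)
  st1 <- initialize_lattice(cfg1)
  expect_equal(colMeans(st1$pos), rep(40, 3), tolerance = 1)
  # velocities carry no net momentum
  expect_equal(colSums(st1$vel), c(0, 0, 0), tolerance = 1e-12)
  # capacity error
  expect_error(initialize_lattice(
    simulation_config("Ab42", n_peptides = 1e6L, box_nm = 25,
                      total_time_tu = 1)), "too small")
})

test_that("decorrelation produces independent unstructured starts", {
  cfg <- simulation_config("Ab38", n_peptides = 2L, box_nm = 12,
                           total_time_tu = 100, frame_interval_tu = 50,
                           decorrelation_time_tu = 60, seed = 1)
  set.seed(1)
  st <- initialize_lattice(cfg)
  s1 <- decorrelate(st, cfg, seed = 1)
  s2 <- decorrelate(st, cfg, seed = 2)
  # distinct seeds give distinct conformations
  expect_gt(sqrt(mean((s1$pos - s2$pos)^2)), 0.1)
  # no hydrogen bonds can form while interactions are off
  expect_identical(sum(attr(s1, "decorrelation")$n_hb), 0L)
  # bonded constraints survive the high-temperature stage
  tp <- st$topologies[[1]]
  pep <- st$table$beads$peptide
  for (p in 1:2) {
    q <- unwrap_frame(s1$pos, pep, cfg$box_A)[pep == p, ]
    d <- sqrt(rowSums((q[tp$bonds$i, ] - q[tp$bonds$j, ])^2))
    expect_true(all(d > tp$bonds$dmin - 1e-9 & d < tp$bonds$dmax + 1e-9))
  }
})

test_that("production runs emit evenly spaced frames deterministically", {
  cfg <- simulation_config("Ab38", n_peptides = 1L, box_nm = 8,
                           total_time_tu = 2000, frame_interval_tu = 100,
                           decorrelation_time_tu = 50, seed = 3)
  set.seed(3)
  st <- initialize_lattice(cfg)
  tr <- run_dmd(st, cfg, seed = 3)
  # frame interval 100 over 2000 tu: 20 frames beyond the initial one
  expect_identical(length(tr$times), 21L)
  expect_equal(diff(tr$times), rep(100, 20))
  expect_true(all(diff(tr$times) > 0))
  tr2 <- run_dmd(st, cfg, seed = 3)
  expect_identical(tr$frames, tr2$frames)  # bit-identical replay
})

test_that("the replica protocol records provenance per replica", {
  cfg <- simulation_config("Ab38", n_peptides = 2L, box_nm = 12,
                           total_time_tu = 200, frame_interval_tu = 100,
                           decorrelation_time_tu = 50, seed = 10)
  trajs <- run_protocol(cfg, n_replicas = 2L)
  expect_length(trajs, 2L)
  expect_identical(vapply(trajs, function(t) t$replica, integer(1)), 1:2)
  expect_identical(vapply(trajs, function(t) as.integer(t$seed),
                          integer(1)), c(10L, 11L))
  # replicas decorrelate to different conformations
  expect_gt(max(abs(trajs[[1]]$frames[, , 1] - trajs[[2]]$frames[, , 1])),
            0.1)
})
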