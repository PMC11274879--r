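# Backbone reconstruction, secondary-structure classification,
# propensity profiles, contact maps, SASA and terminus geometry.

test_that("backbone reconstruction places H and O deterministically", {
  ch <- make_ss_chain("extended_strand", length = 8)
  rec <- reconstruct_backbone(ch$pos, ch$topology)
  # boundary rule: no H on the N-terminal, no O on the C-terminal residue
  expect_true(all(is.na(rec$H[1, ])))
  expect_true(all(is.na(rec$O[8, ])))
  b <- ch$topology$beads
  for (i in 2:7) {
    N <- ch$pos[b$residue == i & b$role == "N", ]
    expect_equal(sqrt(sum((rec$H[i, ] - N)^2)), 1.0, tolerance = 1e-9)
    C <- ch$pos[b$residue == i & b$role == "C", ]
    expect_equal(sqrt(sum((rec$O[i, ] - C)^2)), 1.24, tolerance = 1e-9)
  }
  # equivariance: translating the input translates the reconstruction
  rec2 <- reconstruct_backbone(sweep(ch$pos, 2, c(10, 10, 10), "+"),
                               ch$topology)
  expect_equal(rec2$H[2:7, ], rec$H[2:7, ] + 10, tolerance = 1e-9)
  expect_equal(rec2$O[1:7, ], rec$O[1:7, ] + 10, tolerance = 1e-9)
})

test_that("the classifier recovers planted secondary structure", {
  # extended template: interior residues are strand (recall >= 0.75)
  ch <- make_ss_chain("extended_strand", length = 8)
  lab <- assign_secondary_structure(ch$pos, ch$topology)
  expect_gte(mean(lab[2:7] == "strand"), 0.75)
  # planted turn positions are detected
  ch2 <- make_ss_chain("turn", length = 12, turn_at = 5)
  lab2 <- assign_secondary_structure(ch2$pos, ch2$topology)
  expect_identical(lab2[ch2$truth == "turn"], c("turn", "turn"))
  # random chains: majority coil, strand false positives below 10%
  set.seed(21)
  frac_coil <- frac_strand <- numeric(100)
  for (s in 1:100) {
    cl <- make_ss_chain("random_coil", length = 12, seed = s)
    labs <- assign_secondary_structure(cl$pos, cl$topology)
    frac_coil[s] <- mean(labs == "coil")
    frac_strand[s] <- mean(labs == "strand")
  }
  expect_gt(mean(frac_coil), 0.5)
  expect_lte(mean(frac_strand), 0.1)
  # chains shorter than three residues are entirely coil
  sp2 <- build_sequence("AA")
  tp2 <- build_topology(sp2)
  ch3 <- abetadmd:::.build_chain("AA", c(-120, -120), c(120, 120))
  expect_identical(assign_secondary_structure(ch3, tp2), c("coil", "coil"))
})

test_that("propensity profiles average peptides, frames, trajectories", {
  ext <- make_ss_chain("extended_strand", length = 12)
  coil <- make_ss_chain("random_coil", length = 12, seed = 2)
  tp <- ext$topology
  mix_traj <- function(n_ext, n_coil) {
    frames <- c(replicate(n_ext, list(list(ext$pos)), simplify = FALSE),
                replicate(n_coil, list(list(coil$pos)), simplify = FALSE))
    frames <- lapply(frames, `[[`, 1L)
    chains_traj(frames, tp)
  }
  # all-coil frames: coil propensity 1 with zero SEM
  coil_only <- mix_traj(0, 3)
  labs <- assign_secondary_structure(coil$pos, tp)
  prof0 <- ss_propensity_profile(list(coil_only, coil_only))
  for (k in which(labs == "coil")) {
    row <- prof0[prof0$residue == k & prof0$label == "coil", ]
    expect_equal(row$mean, 1)
    expect_equal(row$sem, 0)
  }
  # two trajectories with strand propensity 0.4 and 0.6 at interior
  # residues: ensemble mean 0.5, two-point SEM 0.1
  prof <- ss_propensity_profile(list(mix_traj(2, 3), mix_traj(3, 2)))
  interior <- which(assign_secondary_structure(ext$pos, tp) == "strand" &
                      assign_secondary_structure(coil$pos, tp) != "strand")
  k <- interior[1]
  row <- prof[prof$residue == k & prof$label == "strand", ]
  expect_equal(row$mean, 0.5)
  expect_equal(row$sem, 0.1, tolerance = 1e-9)
})

test_that("content by assembly state recovers a uniform 50% strand", {
  hs <- half_strand_chain()
  tp <- hs$topology
  # two peptides in contact form a dimer; two far apart stay monomers
  tab <- build_interaction_table(rep(list(tp), 4L))
  traj <- chains_traj(list(list(hs$pos, hs$pos, hs$pos, hs$pos)), tp,
                      offsets = list(c(0, 0, 0), c(0, 0, 4.5),
                                     c(100, 0, 0), c(200, 0, 0)))
  cont <- ss_content_by_order(list(traj, traj), max_order = 3L)
  for (ord in 1:2) {
    row <- cont[cont$order == ord & cont$label == "strand", ]
    expect_equal(row$mean, 0.5, tolerance = 1e-9, info = paste("order", ord))
  }
  # contents are bounded and labels sum to at most one
  sums <- stats::aggregate(mean ~ order, cont[!is.na(cont$mean), ], sum)
  expect_true(all(sums$mean <= 1 + 1e-9))
  # an absent assembly state is reported as missing, not zero
  expect_true(all(is.na(cont$mean[cont$order == 3L])))
})

test_that("contact maps match a direct residue-COM computation", {
  hs <- half_strand_chain()
  tp <- hs$topology
  traj <- chains_traj(list(list(hs$pos, hs$pos)), tp,
                      offsets = list(c(0, 0, 0), c(0, 0, 4.5)))
  cm <- contact_maps(list(traj), assembly_state = 2L)
  expect_false(is.null(cm$inter))
  L <- tp$spec$length
  # independent recomputation from residue centres of mass
  pos <- traj$frames[, , 1]
  part <- partition_oligomers(pos, traj$beads$peptide, traj$box)
  u <- unwrap_frame(pos, traj$beads$peptide, traj$box, part)
  com <- function(p) {
    t(vapply(seq_len(L), function(r) {
      rows <- traj$beads$peptide == p & traj$beads$residue == r
      colMeans(u[rows, , drop = FALSE])
    }, numeric(3)))
  }
  c1 <- com(1); c2 <- com(2)
  inter_want <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    inter_want[i, j] <- (sqrt(sum((c1[i, ] - c2[j, ])^2)) <= 5) * 1
  }
  inter_want <- (inter_want + t(inter_want)) / 2
  expect_equal(cm$inter$map, inter_want, tolerance = 1e-12)
  intra_want <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    intra_want[i, j] <- (abs(i - j) > 1 &&
                           sqrt(sum((c1[i, ] - c1[j, ])^2)) <= 5) * 1
  }
  expect_equal(cm$intra$map, intra_want, tolerance = 1e-12)
  # symmetry and bonded-neighbour exclusion on every output
  expect_equal(cm$intra$map, t(cm$intra$map))
  expect_equal(cm$inter$map, t(cm$inter$map))
  expect_true(all(cm$intra$map[abs(row(inter_want) - col(inter_want)) <= 1]
                  == 0))
})

test_that("contact map differences align lengths and report overhangs", {
  mk <- function(L, kind, fill) {
    structure(list(map = matrix(fill, L, L), kind = kind, state = 2L,
                   isoform = "x", n_conformations = 1L),
              class = "contact_map")
  }
  a <- mk(42, "inter", 0.3); b <- mk(40, "inter", 0.1)
  d <- contact_map_difference(a, b)
  expect_equal(dim(d$difference), c(40L, 40L))
  expect_equal(d$difference[1, 1], 0.2)
  expect_equal(dim(d$overhang), c(42L, 2L))
  # a map minus itself vanishes; differences are antisymmetric
  expect_true(all(contact_map_difference(a, a)$difference == 0))
  d2 <- contact_map_difference(b, a)
  expect_equal(d2$difference, -d$difference)
  expect_error(contact_map_difference(a, mk(40, "intra", 0)), "kinds")
})

test_that("sphere-sampling SASA matches closed forms", {
  mkb <- function(n, aa = "I", core = 4) {
    data.frame(peptide = rep(1L, n), residue = seq_len(n),
               role = rep("CB", n), aa = rep(aa, n),
               core = rep(core, n))
  }
  # isolated bead: 4 pi (r + probe)^2 within 1%
  a1 <- hydrophobic_sasa(matrix(0, 1, 3), mkb(1))
  expect_lt(abs(a1 - 4 * pi * (2 + 1.4)^2) / (4 * pi * 3.4^2), 0.01)
  # two coincident identical beads count once
  a2 <- hydrophobic_sasa(matrix(0, 2, 3), mkb(2))
  expect_equal(unname(a2), unname(a1), tolerance = 1e-6)
  # probe-tangent beads: no occlusion, areas add (within 2%)
  pos3 <- rbind(c(0, 0, 0), c(4 + 2.8, 0, 0))
  a3 <- hydrophobic_sasa(pos3, mkb(2))
  expect_lt(abs(a3 - 2 * a1) / (2 * a1), 0.02)
  # occlusion monotonicity: adding a bead never increases the area
  set.seed(31)
  pos <- matrix(rnorm(15, sd = 3), 5, 3)
  base <- hydrophobic_sasa(pos, mkb(5))
  more <- hydrophobic_sasa(rbind(pos, c(1, 0, 0)), mkb(6))
  expect_lte(more, base + 1e-9)
  # neutral residues occlude but are not measured
  bb <- mkb(2); bb$aa[2] <- "G"
  a4 <- hydrophobic_sasa(rbind(c(0, 0, 0), c(3, 0, 0)), bb)
  expect_lt(a4, a1)
  expect_error(hydrophobic_sasa(matrix(0, 0, 3), mkb(0)), "no beads")
})

test_that("N-C and terminus-CM distances behave geometrically", {
  sp <- build_sequence("Ab40"); tp <- build_topology(sp)
  # canonical extended strand: close to the 3.5 A per residue contour
  ext <- abetadmd:::.build_chain(sp$sequence, rep(-139, 40), rep(135, 40))
  expect_lt(abs(nc_distance(ext, tp) - 39 * 3.5) / (39 * 3.5), 0.05)
  # a hairpin is much shorter than the extended chain
  hp_phi <- rep(-139, 40); hp_psi <- rep(135, 40)
  hp_phi[20:21] <- -60; hp_psi[20:21] <- -30
  hp <- abetadmd:::.build_chain(sp$sequence, hp_phi, hp_psi)
  expect_lt(nc_distance(hp, tp), nc_distance(ext, tp) / 2)
  # translation invariance
  expect_equal(nc_distance(sweep(ext, 2, c(5, -3, 9), "+"), tp),
               nc_distance(ext, tp), tolerance = 1e-9)
  # mirror-symmetric dimer: both peptides share the NT-CM distance
  tab <- build_interaction_table(list(tp, tp))
  mirror <- ext %*% diag(c(-1, 1, 1))
  mirror <- sweep(mirror, 2, c(100, 0, 0), "+")
  pos2 <- rbind(ext, mirror)
  tcd <- terminus_cm_distances(pos2, tab$beads, 1:2)
  expect_equal(tcd$nt_cm[1], tcd$nt_cm[2], tolerance = 1e-9)
  expect_equal(tcd$ct_cm[1], tcd$ct_cm[2], tolerance = 1e-9)
  # monomer: termini lie within the farthest-bead radius
  tcd1 <- terminus_cm_distances(ext, build_interaction_table(tp)$beads, 1)
  cm <- colMeans(ext)
  expect_lte(tcd1$nt_cm, max(sqrt(rowSums(sweep(ext, 2, cm)^2))))
})

test_that("geometric outputs are invariant under rigid motions", {
  set.seed(41)
  hs <- half_strand_chain()
  tp <- hs$topology
  tab <- build_interaction_table(tp)
  lab0 <- assign_secondary_structure(hs$pos, tp)
  s0 <- hydrophobic_sasa(hs$pos, tab$beads)
  nc0 <- nc_distance(hs$pos, tp)
  I0 <- inertia_spectrum(hs$pos)$I
  for (k in 1:5) {
    q <- rigid_motion(hs$pos)
    expect_identical(assign_secondary_structure(q, tp), lab0)
    expect_lt(abs(hydrophobic_sasa(q, tab$beads) - s0) / s0, 1e-6)
    expect_lt(abs(nc_distance(q, tp) - nc0) / nc0, 1e-9)
    expect_lt(max(abs(inertia_spectrum(q)$I - I0)) / I0[1], 1e-9)
  }
})

test_that("the per-peptide geometry table is assembled per oligomer", {
  hs <- half_strand_chain()
  tp <- hs$topology
  traj <- chains_traj(list(list(hs$pos, hs$pos, hs$pos)), tp,
                      offsets = list(c(0, 0, 0), c(0, 0, 4.5),
                                     c(120, 0, 0)))
  geo <- peptide_geometry(traj, sasa_points = 120)
  expect_identical(nrow(geo), 3L)
  expect_setequal(geo$oligomer_size[geo$peptide %in% 1:2], 2L)
  expect_identical(geo$oligomer_size[geo$peptide == 3], 1L)
  expect_true(all(c("sasa", "nc_dist", "nt_cm", "ct_cm") %in% names(geo)))
  expect_true(all(geo$sasa > 0))
  # dimer partners share an oligomer id and CM, so nt_cm differs from the
  # monomer value
  expect_identical(geo$oligomer_id[1], geo$oligomer_id[2])
})
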