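# Oligomer identification and molar / mass-weighted size distributions.

# two "peptides" of two beads each, at a controlled minimum distance
two_peptides_at <- function(d) {
  pos <- rbind(c(10, 10, 10), c(12, 10, 10),
               c(12 + d, 10, 10), c(14 + d, 10, 10))
  list(pos = pos, peptide = c(1L, 1L, 2L, 2L))
}

test_that("the 5 A criterion is strict and transitive", {
  f <- two_peptides_at(4.9)
  p <- partition_oligomers(f$pos, f$peptide, box = 100)
  expect_identical(sort(oligomer_sizes(p)), 2L)       # one dimer
  f2 <- two_peptides_at(5.1)
  p2 <- partition_oligomers(f2$pos, f2$peptide, box = 100)
  expect_identical(sort(oligomer_sizes(p2)), c(1L, 1L))
  # exactly at the threshold: strictly less than, so still separate
  f3 <- two_peptides_at(5.0)
  p3 <- partition_oligomers(f3$pos, f3$peptide, box = 100)
  expect_identical(sort(oligomer_sizes(p3)), c(1L, 1L))
  # transitive closure: A-B at 4, B-C at 4, A-C far
  pos <- rbind(c(10, 10, 10), c(14, 10, 10), c(18, 10, 10))
  p4 <- partition_oligomers(pos, c(1L, 2L, 3L), box = 100)
  expect_identical(oligomer_sizes(p4), 3L)
  # minimum image: peptides touching across the periodic boundary
  pos5 <- rbind(c(1, 10, 10), c(98, 10, 10))
  p5 <- partition_oligomers(pos5, c(1L, 2L), box = 100)
  expect_identical(oligomer_sizes(p5), 2L)            # 3 A through the wall
})

test_that("clustering equals the all-pairs connected-components oracle", {
  set.seed(101)
  for (rep in 1:100) {
    n_pep <- sample(3:8, 1)
    nb <- sample(2:5, 1)
    box <- 40
    pos <- matrix(runif(3 * n_pep * nb, 0, box), ncol = 3)
    peptide <- rep(seq_len(n_pep), each = nb)
    got <- partition_oligomers(pos, peptide, box)$clusters
    want <- oracle_clusters(pos, peptide, box)
    expect_identical(canon_clusters(got), canon_clusters(want))
  }
})

# build an oligomer_partition object directly from cluster sizes
fake_partition <- function(sizes, time = 0) {
  ids <- seq_len(sum(sizes))
  cl <- split(ids, rep(seq_along(sizes), sizes))
  structure(list(clusters = unname(cl), edges = cbind(integer(0), integer(0)),
                 n_peptides = sum(sizes), time = time),
            class = "oligomer_partition")
}

test_that("molar and mass-weighted distributions match the definitions", {
  # sixteen dimers
  d <- molar_distribution(list(fake_partition(rep(2L, 16))))
  expect_equal(d$propensity[2], 1)
  expect_equal(sum(d$propensity), 1)
  # two monomers and one dimer
  dm <- molar_distribution(list(fake_partition(c(1L, 1L, 2L))))
  expect_equal(dm$propensity[1], 2 / 3)
  expect_equal(dm$propensity[2], 1 / 3)
  dw <- mass_weighted_distribution(list(fake_partition(c(1L, 1L, 2L))))
  expect_equal(dw$propensity[1], 1 / 2)
  expect_equal(dw$propensity[2], 1 / 2)
  # all monomers (the initial frame of any run)
  d0 <- molar_distribution(list(fake_partition(rep(1L, 32))))
  expect_equal(d0$propensity[1], 1)
  expect_error(molar_distribution(list()), "no partitions")
})

test_that("distribution invariants hold on random partitions", {
  set.seed(13)
  rand_sizes <- function(np) {
    s <- integer(0)
    while (sum(s) < np) s <- c(s, sample(seq_len(np - sum(s)), 1))
    s
  }
  for (rep in 1:50) {
    sizes <- rand_sizes(32L)
    part <- fake_partition(sizes)
    mol <- molar_distribution(list(part))
    mas <- mass_weighted_distribution(list(part))
    expect_equal(sum(mol$propensity), 1, tolerance = 1e-12)
    expect_equal(sum(mas$propensity), 1, tolerance = 1e-12)
    expect_true(all(mol$propensity >= 0))
    # frame-by-frame identity: mass P(n) = n * count(n) / 32
    counts <- tabulate(sizes, 32)
    expect_equal(mas$propensity, counts * seq_len(32) / 32)
    # mass weighting never decreases the mean oligomer size
    expect_gte(mean_oligomer_size(mas), mean_oligomer_size(mol) - 1e-12)
  }
})

test_that("ensemble averaging reports the standard error of the mean", {
  p <- fake_partition(c(2L, 2L))
  d <- mass_weighted_distribution(list(p))
  avg <- ensemble_average(list(d, d, d))
  expect_equal(avg$sem, rep(0, 4))          # identical replicas
  expect_equal(avg$propensity, d$propensity)
  # two replicas with P(2) = 0 and 1
  d0 <- mass_weighted_distribution(list(fake_partition(c(1L, 1L, 1L, 1L))))
  d1 <- mass_weighted_distribution(list(fake_partition(c(4L))))
  avg2 <- ensemble_average(list(d0, d1))
  expect_equal(avg2$propensity[4], 0.5)
  expect_equal(avg2$sem[4], 0.5)
  expect_error(ensemble_average(list(d)), "fewer than two")
  expect_error(ensemble_average(list(d, molar_distribution(list(p)))),
               "mixed")
})

test_that("replica SEM agrees with the analytic multinomial spread", {
  # each replica: 16 independent peptide pairs dimerise with p = 0.4;
  # mass-weighted P(2) per replica is Binomial(16, p)/16, so the SEM of
  # the 32-replica mean is sqrt(p(1-p)/16)/sqrt(32)
  set.seed(77)
  p_dim <- 0.4
  reps <- lapply(1:32, function(r) {
    k <- stats::rbinom(1, 16, p_dim)
    sizes <- c(rep(2L, k), rep(1L, 2L * (16L - k)))
    mass_weighted_distribution(list(fake_partition(sizes)))
  })
  avg <- ensemble_average(reps)
  analytic <- sqrt(p_dim * (1 - p_dim) / 16) / sqrt(32)
  expect_lt(abs(avg$sem[2] - analytic) / analytic, 0.30)
})

test_that("size distributions export as CSV", {
  d <- mass_weighted_distribution(list(fake_partition(c(2L, 1L, 1L))))
  f <- tempfile(fileext = ".csv")
  write_size_distribution(d, f)
  back <- utils::read.csv(f)
  expect_equal(back$propensity, d$propensity)
  expect_identical(names(back), c("size", "propensity", "sem"))
})
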