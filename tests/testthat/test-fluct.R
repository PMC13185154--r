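test_that("superposition exactly recovers rigid-body motion", {
  s <- build_toy_protein(15, "helix", 1)
  frames <- lapply(seq(0.2, 1.8, length.out = 6), function(a)
    sweep(s$xyz %*% rot_z(a), 2, c(a, -2 * a, 5), "+"))
  trj <- traj_from_frames(s, frames)
  ca <- select_atoms(s, "alpha-carbon")
  al <- superpose(trj, ca, mode = "first-frame")
  rmsd <- vapply(seq_len(6), function(f)
    sqrt(mean(rowSums((al$coords[, , f] - al$coords[, , 1])^2))), 0)
  expect_lt(max(rmsd), 1e-8)
  # iterative-mean mode agrees for rigid motion
  al2 <- superpose(trj, ca, mode = "iterative-mean")
  expect_lt(max(abs(al2$coords[, , 2] - al2$coords[, , 5])), 1e-6)
})

test_that("superposition is idempotent on an aligned trajectory", {
  s <- build_toy_protein(12, "hairpin", 1)
  trj <- sample_gaussian_trajectory(s, ensemble_spec(12, "hairpin",
                                                     n_frames = 20, seed = 2))
  ca <- select_atoms(s, "alpha-carbon")
  once <- superpose(trj, ca, mode = "first-frame")
  twice <- superpose(once, ca, mode = "first-frame")
  expect_equal(twice$coords, once$coords, tolerance = 1e-10)
})

test_that("mirror images are fitted with proper rotations only", {
  s <- build_toy_protein(15, "helix", 1)  # chiral fold
  mirror <- s$xyz %*% diag(c(-1, 1, 1))
  trj <- traj_from_frames(s, list(s$xyz, mirror))
  al <- superpose(trj, select_atoms(s, "alpha-carbon"), mode = "first-frame")
  residual <- sqrt(mean(rowSums((al$coords[, , 2] - al$coords[, , 1])^2)))
  expect_gt(residual, 0.1)  # a reflection would have made this ~0
})

test_that("degenerate superposition masks are rejected", {
  line <- point_structure(cbind(3.8 * (0:9), 0, 0))
  trj <- traj_from_frames(line, list(line$xyz, line$xyz))
  expect_error(superpose(trj, select_atoms(line, "alpha-carbon")),
               "collinear")
  tiny <- point_structure(matrix(rnorm(6), 2, 3))
  trj2 <- traj_from_frames(tiny, list(tiny$xyz, tiny$xyz))
  expect_error(superpose(trj2, select_atoms(tiny, "alpha-carbon")), ">= 3")
})

test_that("RMSF matches hand-computable cases", {
  s <- build_toy_protein(5, "helix", 1)
  # identical frames -> zero
  trj <- traj_from_frames(s, list(s$xyz, s$xyz, s$xyz))
  expect_true(all(rmsf(trj)$rmsf == 0))
  # one atom alternating between (0,0,0) and (2,0,0) -> RMSF exactly 1 A
  a <- point_structure(matrix(0, 1, 3), residues = 1)
  alt <- traj_from_frames(a, rep(list(matrix(c(0, 0, 0), 1),
                                      matrix(c(2, 0, 0), 1)), 5))
  p <- rmsf(alt, select_atoms(a, "alpha-carbon"))
  expect_equal(p$rmsf, 1.0)
})

test_that("RMSF is invariant under a global rigid transform of all frames", {
  s <- build_toy_protein(10, "hairpin", 1)
  trj <- sample_gaussian_trajectory(s, ensemble_spec(10, "hairpin",
                                                     n_frames = 200, seed = 3))
  moved <- trj
  for (f in seq_len(n_frames(trj)))
    moved$coords[, , f] <- sweep(trj$coords[, , f] %*% rot_z(1.1), 2,
                                 c(10, -4, 2), "+")
  expect_equal(rmsf(moved)$rmsf, rmsf(trj)$rmsf, tolerance = 1e-10)
})

test_that("RMSF agrees with the bio3d reference implementation", {
  s <- build_toy_protein(14, "hairpin", 1)
  trj <- sample_gaussian_trajectory(s, ensemble_spec(14, "hairpin",
                                                     n_frames = 500, seed = 7))
  mine <- rmsf(trj)$rmsf
  flat <- t(apply(trj$coords, 3, function(m) as.numeric(t(m))))
  # bio3d divides by n-1 (sample variance); the time average divides by n
  theirs <- bio3d::rmsf(flat) * sqrt((500 - 1) / 500)
  expect_equal(mine, theirs, tolerance = 1e-6)
})

test_that("replica averaging is an unweighted mean, order-invariant, label-checked", {
  s <- build_toy_protein(8, "hairpin", 1)
  mk <- function(val, cond = "solution") {
    trj <- sample_gaussian_trajectory(s, ensemble_spec(8, "hairpin",
                                                       n_frames = 10, seed = 1))
    p <- rmsf(trj)
    p$rmsf <- rep(val, 8)
    m <- attr(p, "meta"); m$condition <- cond; attr(p, "meta") <- m
    p
  }
  same <- average_replicas(list(mk(2), mk(2), mk(2)))
  expect_equal(same$rmsf, rep(2, 8))
  expect_equal(profile_meta(same)$n_replicas, 3L)
  expect_equal(average_replicas(list(mk(1), mk(3)))$rmsf, rep(2, 8))
  # permuted residue order does not matter
  p1 <- mk(1); p3 <- mk(3)
  perm <- sample(nrow(p3))
  p3perm <- p3[perm, ]
  expect_equal(average_replicas(list(p1, p3perm))$rmsf, rep(2, 8))
  # mismatched residue sets and labels are errors
  short <- mk(1); short <- short[1:5, ]
  expect_error(average_replicas(list(p1, short)), "mismatched")
  expect_error(average_replicas(list(mk(1, "solution"), mk(1, "confined"))),
               "condition")
})

test_that("monomer pooling averages per-chain profiles position-wise", {
  base <- build_toy_protein(6, "hairpin", 1)
  at <- rbind(base$atom, base$atom)
  at$atom_index <- 1:12
  at$chain_id <- rep(c("A", "B"), each = 6)
  dimer <- cq_structure(at, rbind(base$xyz, base$xyz + 40))
  # chain A static, chain B's residue 3 alternates by +/-2 A in x
  fr <- function(dx) {
    m <- dimer$xyz
    m[9, 1] <- m[9, 1] + dx
    m
  }
  trj <- traj_from_frames(dimer, rep(list(fr(0), fr(2)), 8))
  pooled <- pool_monomers(trj, c("A", "B"), align = FALSE)
  expect_equal(pooled$rmsf[3], 0.5)  # mean of 0 (A) and 1.0 (B)
  expect_equal(pooled$rmsf[-3], rep(0, 5))
  expect_equal(profile_meta(pooled)$n_replicas, 2)
  # identical fluctuations in both chains -> pooled equals either chain
  trj2 <- traj_from_frames(dimer, lapply(1:6, function(i) {
    set.seed(i); n <- matrix(rnorm(18), 6); rbind(base$xyz + n, base$xyz + 40 + n)
  }))
  pooled2 <- pool_monomers(trj2, c("A", "B"), align = FALSE)
  solo <- rmsf(subset_trajectory(trj2, 1:6))
  expect_equal(pooled2$rmsf, solo$rmsf, tolerance = 1e-12)
  # unequal chain lengths are an error
  at3 <- at[1:11, ]
  trunc <- cq_structure(at3, rbind(base$xyz, base$xyz + 40)[1:11, ])
  trjt <- traj_from_frames(trunc, list(trunc$xyz, trunc$xyz))
  expect_error(pool_monomers(trjt, c("A", "B"), align = FALSE), "unequal")
})

test_that("pooling many copies equals the brute-force mean of monomer profiles", {
  base <- build_toy_protein(8, "hairpin", 1)
  n_copies <- 4
  at <- do.call(rbind, replicate(n_copies, base$atom, simplify = FALSE))
  at$atom_index <- seq_len(8 * n_copies)
  at$chain_id <- rep(LETTERS[1:n_copies], each = 8)
  multi <- cq_structure(at, do.call(rbind, lapply(1:n_copies,
                                                  function(k) base$xyz + 30 * k)))
  set.seed(99)
  trj <- traj_from_frames(multi, lapply(1:40, function(i)
    multi$xyz + matrix(rnorm(8 * n_copies * 3, sd = runif(1, 0.2, 1)),
                       8 * n_copies)))
  pooled <- pool_monomers(trj, LETTERS[1:n_copies])
  manual <- rowMeans(vapply(1:n_copies, function(k) {
    sub <- subset_trajectory(trj, which(at$chain_id == LETTERS[k]))
    sub <- superpose(sub, select_atoms(sub$topology, "alpha-carbon"))
    rmsf(sub)$rmsf
  }, numeric(8)))
  expect_equal(pooled$rmsf, manual, tolerance = 1e-10)
})

test_that("dRMSF is solution minus confined on the residue intersection", {
  mk <- function(vals, residues = seq_along(vals)) {
    p <- data.frame(residue = residues, rmsf = vals)
    attr(p, "meta") <- list(n_replicas = 1L)
    class(p) <- c("cq_rmsf_profile", "data.frame")
    p
  }
  d <- delta_rmsf(mk(c(3, 1, 2)), mk(c(1, 3.5, 2)))
  expect_equal(d$delta, c(2, -2.5, 0))
  expect_equal(delta_rmsf(mk(1:4), mk(1:4))$delta, rep(0, 4))
  d2 <- delta_rmsf(mk(c(5, 5), residues = 3:4), mk(c(1, 1), residues = 4:5))
  expect_equal(d2$residue, 4)
  expect_equal(d2$delta, 4)
  expect_error(delta_rmsf(mk(1, residues = 1), mk(1, residues = 9)),
               "no residues")
})

test_that("region detection finds maximal signed runs above threshold", {
  mk_delta <- function(vals, residues = seq_along(vals)) {
    d <- data.frame(residue = residues, delta = vals)
    class(d) <- c("cq_delta_profile", "data.frame")
    d
  }
  expect_equal(nrow(detect_regions(mk_delta(rep(0, 50)))), 0)

  v <- rep(0, 50); v[10:14] <- 3
  r <- detect_regions(mk_delta(v))
  expect_equal(r$start_residue, 10)
  expect_equal(r$end_residue, 14)
  expect_equal(r$sign, "positive")
  expect_equal(r$peak_value, 3)
  expect_equal(r$label, "I")

  v <- rep(0, 50); v[5:7] <- -2.5; v[40:45] <- 2.2
  r <- detect_regions(mk_delta(v))
  expect_equal(r$label, c("I", "II"))
  expect_equal(r$sign, c("negative", "positive"))
  expect_equal(r$start_residue, c(5, 40))
  expect_equal(r$end_residue, c(7, 45))

  # single-residue spikes are suppressed by min_length
  v <- rep(0, 20); v[9] <- 5
  expect_equal(nrow(detect_regions(mk_delta(v), min_length = 2)), 0)
  expect_equal(nrow(detect_regions(mk_delta(v), min_length = 1)), 1)

  # sign changes split runs
  v <- rep(0, 20); v[5:6] <- 3; v[7:8] <- -3
  r <- detect_regions(mk_delta(v))
  expect_equal(nrow(r), 2)

  # residue-number gaps split runs
  r <- detect_regions(mk_delta(c(3, 3, 3, 3), residues = c(1, 2, 10, 11)))
  expect_equal(r$start_residue, c(1, 10))
})

test_that("region detection matches a brute-force scan on random profiles", {
  for (seed in 1:15) {
    set.seed(seed)
    v <- round(rnorm(60, sd = 1.6), 2)
    res <- seq_len(60)
    d <- data.frame(residue = res, delta = v)
    class(d) <- c("cq_delta_profile", "data.frame")
    got <- detect_regions(d, threshold = 2, min_length = 2)
    want <- brute_force_regions(res, v, 2, 2)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$start_residue, want$start_residue)
      expect_equal(got$end_residue, want$end_residue)
    }
    # regions are disjoint and sorted
    if (nrow(got) > 1)
      expect_true(all(got$start_residue[-1] > got$end_residue[-nrow(got)]))
  }
})
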