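test_that("sphere radius conventions match their geometric definitions", {
  one <- point_structure(matrix(c(3, 4, 5), 1, 3))
  expect_equal(sphere_radius_estimate(one, "cargo", "max-extent"), 0)

  corners <- as.matrix(expand.grid(c(-5, 5), c(-5, 5), c(-5, 5)))
  cube <- point_structure(corners)
  expect_equal(sphere_radius_estimate(cube, "cargo", "max-extent"),
               5 * sqrt(3))

  # hollow spherical cage at radius 30, innermost-atom with zero probe -> 30
  # (antipodal pairs put the centroid exactly at the cage center)
  set.seed(1)
  half <- matrix(rnorm(150), 50, 3)
  dirs <- rbind(half, -half)
  cage <- point_structure(30 * dirs / sqrt(rowSums(dirs^2)))
  expect_equal(sphere_radius_estimate(cage, "shell-interior",
                                      "innermost-atom", probe_margin = 0), 30)
  expect_equal(sphere_radius_estimate(cage, "shell-interior",
                                      "innermost-atom", probe_margin = 1.4),
               28.6)

  # equal-volume: 500 residues at 134 A^3 each
  big <- point_structure(matrix(rnorm(1500) * 20, 500, 3))
  expect_equal(sphere_radius_estimate(big, "cargo", "equal-volume"),
               (3 * 500 * 134 / (4 * pi))^(1 / 3))

  expect_error(sphere_radius_estimate(one, "cargo", "innermost-atom"),
               "shell-interior convention")
  expect_error(sphere_radius_estimate(cage, "shell-interior", "max-extent"),
               "innermost-atom")
})

test_that("copy number is floor(phi (R/r)^3) with guarded inputs", {
  expect_equal(copy_number(0, 100, 25), 0L)
  expect_equal(copy_number(0.2, 100, 25), 12L)  # floor(0.2 * 64)
  expect_equal(copy_number(0.2, 90, 25.2), 9L)
  expect_error(copy_number(0.74, 100, 25), "phi")
  expect_error(copy_number(0.2, 25, 100), "smaller")
  # monotone in phi and R, non-increasing in r
  phis <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(vapply(phis, copy_number, 0L, 100, 20)) >= 0))
  Rs <- seq(50, 150, by = 10)
  expect_true(all(diff(vapply(Rs, function(R) copy_number(0.3, R, 20),
                              0L)) >= 0))
  rs <- seq(10, 40, by = 5)
  expect_true(all(diff(vapply(rs, function(r) copy_number(0.3, 100, r),
                              0L)) <= 0))
})

test_that("random sequential insertion honors both distance invariants", {
  expect_equal(place_copies(0, 90, 25)$n_copies, 0L)

  p1 <- place_copies(1, 90, 25, seed = 3)
  expect_lte(sqrt(sum(p1$placements[1, c("x", "y", "z")]^2)), 65)

  plan <- place_copies(9, 90, 27, seed = 7, max_attempts = 100000)
  cen <- as.matrix(plan$placements[, c("x", "y", "z")])
  # brute-force verification over all 36 pairs
  for (i in 1:8) for (j in (i + 1):9)
    expect_gte(sqrt(sum((cen[i, ] - cen[j, ])^2)), 2 * 27 - 1e-9)
  expect_true(all(sqrt(rowSums(cen^2)) <= 90 - 27 + 1e-9))
  # achieved volume fraction within one copy of the target
  expect_lt(abs(plan$phi_target - 9 * (27 / 90)^3), (27 / 90)^3 + 1e-12)
  # orientations are unit quaternions
  qn <- sqrt(rowSums(as.matrix(plan$placements[, c("qw", "qx", "qy",
                                                   "qz")])^2))
  expect_equal(qn, rep(1, 9), tolerance = 1e-12)
  # deterministic per seed
  expect_identical(place_copies(9, 90, 27, seed = 7,
                                max_attempts = 100000)$placements,
                   plan$placements)
})

test_that("infeasible packing requests fail loudly with progress reported", {
  expect_error(place_copies(50, 30, 10, seed = 1, max_attempts = 500),
               "placed [0-9]+ of 50")
})

test_that("invariants hold across a 100-seed sweep at moderate packing", {
  n <- copy_number(0.2, 90, 25.2)
  expect_equal(n, 9L)
  phi_achieved <- n * (25.2 / 90)^3
  expect_lte(phi_achieved, 0.2)
  violations <- 0
  for (seed in 1:100) {
    plan <- place_copies(n, 90, 25.2, seed = seed, max_attempts = 100000)
    cen <- as.matrix(plan$placements[, c("x", "y", "z")])
    d <- as.matrix(dist(cen))
    if (any(d[upper.tri(d)] < 2 * 25.2 - 1e-9)) violations <- violations + 1
    if (any(sqrt(rowSums(cen^2)) > 90 - 25.2 + 1e-9))
      violations <- violations + 1
    if (nrow(clash_screen(plan))) violations <- violations + 1
  }
  expect_equal(violations, 0)
})

test_that("sphere-level clash screening flags overlaps and wall contact", {
  plan <- place_copies(5, 90, 25, seed = 2, max_attempts = 100000)
  expect_equal(nrow(clash_screen(plan)), 0)
  # two copies overlapped by 1 A, both well inside the wall
  bad <- place_copies(2, 90, 25, seed = 2)
  bad$placements[1, c("x", "y", "z")] <- c(0, 0, 0)
  bad$placements[2, c("x", "y", "z")] <- c(2 * 25 - 1, 0, 0)
  hits <- clash_screen(bad)
  expect_setequal(hits$copy, c(1, 2))
  expect_equal(hits$distance, rep(2 * 25 - 1, 2), tolerance = 1e-9)
  # push a copy through the wall
  wall <- plan
  wall$placements[4, c("x", "y", "z")] <- c(0, 0, 89)
  hits <- clash_screen(wall)
  expect_equal(hits$copy, 4)
  expect_equal(hits$partner, "shell")
  # screening an already-clean plan twice changes nothing
  expect_identical(clash_screen(plan), clash_screen(plan))
})

test_that("atomic screening excludes exactly the perturbed copy; pooling then uses the rest", {
  cargo <- build_toy_protein(10, "compact", 4)
  plan <- place_copies(9, 60, 12, seed = 11, max_attempts = 100000)
  set.seed(1)
  dirs <- matrix(rnorm(600), 200, 3)
  shell <- point_structure(60 * dirs / sqrt(rowSums(dirs^2)))
  asm <- assemble_copies(plan, cargo, shell = shell)
  expect_equal(nrow(clash_screen(asm)), 0)
  # a shell protrusion ends up 0.5 A from one atom of copy 3 ("C")
  bad <- asm
  i3 <- which(bad$atom$chain_id == "C")
  extra <- bad$atom[nrow(bad$atom), , drop = FALSE]
  extra$atom_index <- extra$atom_index + 1L
  extra$residue_index <- extra$residue_index + 1L
  bad$atom <- rbind(bad$atom, extra)
  bad$xyz <- rbind(bad$xyz, bad$xyz[i3[1], ] + c(0.5, 0, 0))
  bad <- cq_structure(bad$atom, bad$xyz, bad$title)
  hits <- clash_screen(bad)
  expect_equal(unique(hits$copy), "C")
  expect_equal(unique(hits$partner), "shell")
  plan2 <- apply_exclusions(plan, hits)
  expect_equal(plan2$excluded$copy, 3)
  included <- setdiff(seq_len(plan2$n_copies), plan2$excluded$copy)
  expect_length(included, 8)
  expect_lt(plan2$phi_after_exclusion, plan2$phi_target)
  # pooled RMSF over the 8 surviving copies covers exactly those chains
  trj <- traj_from_frames(asm, list(asm$xyz,
                                    asm$xyz + matrix(rnorm(nrow(asm$xyz) * 3,
                                                           sd = 0.1),
                                                     nrow(asm$xyz))))
  pooled <- pool_monomers(trj, LETTERS[included], align = FALSE)
  expect_equal(profile_meta(pooled)$n_replicas, 8)
  expect_equal(nrow(pooled), 10)
})

test_that("assembled copies preserve cargo geometry and plan export is stable", {
  cargo <- build_toy_protein(8, "hairpin", 1)
  plan <- place_copies(3, 50, 10, seed = 5)
  asm <- assemble_copies(plan, cargo)
  expect_equal(nrow(asm$atom), 24)
  # rotation + translation preserve internal distances of each copy
  for (k in 1:3) {
    idx <- which(asm$atom$chain_id == LETTERS[k])
    expect_equal(as.numeric(dist(asm$xyz[idx, ])),
                 as.numeric(dist(cargo$xyz)), tolerance = 1e-9)
  }
  f <- withr::local_tempfile(fileext = ".tsv")
  export_plan_tsv(plan, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 3)
  expect_true(all(!tab$excluded))
})
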