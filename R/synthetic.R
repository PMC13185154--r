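# Synthetic conformational-ensemble generation. Two tiers:
#   * sample_gaussian_trajectory(): analytic Gaussian fluctuations with a
#     closed-form RMSF (sigma * sqrt(3)) -- the exact oracle tier.
#   * simulate_enm_langevin() (enm.R): an elastic-network model propagated with
#     overdamped Langevin dynamics -- the mechanistic tier where confinement
#     emerges from an actual wall and crowder spheres.

#' Specification of a synthetic conformational ensemble
#'
#' Encodes the study conditions the generator emulates: temperature-scaled
#' positional fluctuations around a native fold, suppression of those
#' fluctuations under confinement with crowders, localized planted flexible
#' regions, and (through the temperature scaling) gradual native-contact loss
#' in the unconfined condition.
#'
#' @param n_residues chain length.
#' @param fold `"helix"`, `"hairpin"` or `"compact"`.
#' @param temperature K.
#' @param n_frames number of frames to sample.
#' @param base_sigma per-coordinate fluctuation scale (A) at `t_ref`.
#' @param flexible_regions data.frame with columns `start`, `end`, `amp`
#'   (amplification factor applied to residues in \[start, end\]), or NULL.
#' @param confinement NULL, or list with `radius` (A), `n_crowders`,
#'   `crowder_radius` (A), `suppression` (0 < s <= 1; multiplies sigma).
#' @param seed integer RNG seed.
#' @param t_ref reference temperature (K) at which sigma equals `base_sigma`;
#'   sigma scales as sqrt(T / t_ref) (equipartition heuristic).
#' @return An object of class `cq_ensemble_spec`.
#' @export
ensemble_spec <- function(n_residues, fold = "hairpin", temperature = 298.15,
                          n_frames = 1000, base_sigma = 1.0,
                          flexible_regions = NULL, confinement = NULL,
                          seed = 1, t_ref = cq_constants$T_ref) {
  stopifnot(n_residues >= 4, n_frames >= 1, temperature > 0, t_ref > 0)
  if (base_sigma <= 0) stop("base_sigma must be > 0")
  fold <- match.arg(fold, c("helix", "hairpin", "compact"))
  if (!is.null(flexible_regions)) {
    stopifnot(is.data.frame(flexible_regions),
              all(c("start", "end", "amp") %in% names(flexible_regions)))
    if (any(flexible_regions$start < 1 | flexible_regions$end > n_residues |
            flexible_regions$start > flexible_regions$end))
      stop("flexible regions must lie within [1, n_residues]")
    if (any(flexible_regions$amp <= 0)) stop("amplification must be > 0")
  }
  if (!is.null(confinement)) {
    stopifnot(is.list(confinement))
    confinement <- modifyList(list(radius = 45, n_crowders = 0,
                                   crowder_radius = 10, suppression = 1),
                              confinement)
    if (confinement$suppression <= 0 || confinement$suppression > 1)
      stop("suppression must be in (0, 1]")
    if (confinement$radius <= 0) stop("confinement radius must be > 0")
  }
  structure(list(n_residues = as.integer(n_residues), fold = fold,
                 temperature = temperature, n_frames = as.integer(n_frames),
                 base_sigma = base_sigma, flexible_regions = flexible_regions,
                 confinement = confinement, seed = as.integer(seed),
                 t_ref = t_ref),
            class = "cq_ensemble_spec")
}

#' Per-residue fluctuation scale implied by an ensemble spec
#'
#' sigma_i = base_sigma * sqrt(T / T_ref) * amplification(i) * suppression,
#' so the expected RMSF of residue i in the Gaussian tier is sigma_i * sqrt(3).
#'
#' @param spec a `cq_ensemble_spec`.
#' @return numeric vector of per-coordinate standard deviations (A).
#' @export
spec_sigma <- function(spec) {
  stopifnot(inherits(spec, "cq_ensemble_spec"))
  amp <- rep(1, spec$n_residues)
  if (!is.null(spec$flexible_regions))
    for (r in seq_len(nrow(spec$flexible_regions))) {
      rg <- spec$flexible_regions[r, ]
      amp[rg$start:rg$end] <- rg$amp
    }
  sup <- if (is.null(spec$confinement)) 1 else spec$confinement$suppression
  spec$base_sigma * sqrt(spec$temperature / spec$t_ref) * amp * sup
}

# ---- Native-fold construction ------------------------------------------------

#' Build a C-alpha-only toy protein
#'
#' Consecutive C-alpha distances are 3.8 A (the virtual-bond length) within
#' 0.01 A. The hairpin fold pairs residues across two antiparallel strands
#' 3.8 A apart, guaranteeing native contacts with sequence separation > 3;
#' the compact fold is a seeded collapsed self-avoiding walk.
#'
#' @param n_residues >= 4.
#' @param fold `"helix"`, `"hairpin"` or `"compact"`.
#' @param seed integer; construction is deterministic per seed.
#' @return A `cq_structure` with one CA atom per residue, chain "A".
#' @export
build_toy_protein <- function(n_residues, fold = "hairpin", seed = 1) {
  if (n_residues < 4) stop("n_residues must be >= 4")
  fold <- match.arg(fold, c("helix", "hairpin", "compact"))
  b <- cq_constants$ca_spacing
  xyz <- switch(fold,
    helix = {
      rise <- 1.5; turn <- 100 * pi / 180
      rad <- sqrt((b^2 - rise^2) / (2 * (1 - cos(turn))))
      i <- seq_len(n_residues) - 1
      cbind(rad * cos(i * turn), rad * sin(i * turn), rise * i)
    },
    hairpin = {
      n1 <- ceiling(n_residues / 2)
      x1 <- cbind(b * (seq_len(n1) - 1), 0, 0)
      k <- seq_len(n_residues - n1)
      x2 <- cbind(b * (n1 - k), b, 0)
      rbind(x1, x2)
    },
    compact = .compact_walk(n_residues, b, seed))
  atom <- data.frame(atom_index = seq_len(n_residues), atom_name = "CA",
                     element = "C", residue_index = seq_len(n_residues),
                     chain_id = "A", bfactor = 0, stringsAsFactors = FALSE)
  cq_structure(atom, xyz, title = sprintf("toy %s n=%d seed=%d", fold,
                                          n_residues, seed))
}

# Collapsed random walk: fixed step length, inward bias beyond a target radius,
# candidate directions rejected within 3.4 A of earlier residues.
.compact_walk <- function(n, b, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  r_target <- b * (3 * n / (4 * pi * 4))^(1 / 3) * 1.6
  xyz <- matrix(0, n, 3)
  xyz[2, ] <- c(b, 0, 0)
  for (i in 3:n) {
    placed <- FALSE
    for (try in 1:300) {
      dir <- rnorm(3)
      cen <- colMeans(xyz[seq_len(i - 1), , drop = FALSE])
      pull <- cen - xyz[i - 1, ]
      np <- sqrt(sum(pull^2))
      if (np > r_target) dir <- dir + 1.5 * pull / np
      dir <- dir / sqrt(sum(dir^2))
      cand <- xyz[i - 1, ] + b * dir
      d2 <- rowSums(sweep(xyz[seq_len(i - 2), , drop = FALSE], 2, cand)^2)
      if (all(d2 > 3.4^2)) { xyz[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) xyz[i, ] <- xyz[i - 1, ] + b * dir  # rare; accept overlap
  }
  sweep(xyz, 2, colMeans(xyz))
}

# Save/restore the global RNG state so seeded generators do not perturb the
# caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# ---- Gaussian tier -----------------------------------------------------------

#' Sample an analytic Gaussian conformational ensemble
#'
#' Frame t = native coordinates + independent Gaussian noise with per-coordinate
#' standard deviation sigma_i from [spec_sigma()]. The expected per-residue
#' RMSF is exactly sigma_i * sqrt(3), which makes this tier the closed-form
#' oracle for every fluctuation statistic downstream.
#'
#' @param struct native `cq_structure` (one atom per residue).
#' @param spec a `cq_ensemble_spec` with `n_residues == n_atoms(struct)`.
#' @return A `cq_trajectory`; `meta` records the spec.
#' @export
sample_gaussian_trajectory <- function(struct, spec) {
  stopifnot(inherits(struct, "cq_structure"),
            inherits(spec, "cq_ensemble_spec"))
  n <- nrow(struct$atom)
  if (n != spec$n_residues)
    stop("spec n_residues (", spec$n_residues,
         ") does not match structure atom count (", n, ")")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  sig <- spec_sigma(spec)
  nf <- spec$n_frames
  noise <- array(rnorm(n * 3 * nf), c(n, 3, nf)) * sig  # sig recycles over atoms
  coords <- array(struct$xyz, c(n, 3, nf)) + noise
  cond <- if (is.null(spec$confinement)) "solution" else "confined"
  cq_trajectory(struct, coords,
                label = sprintf("%s_T%.2f", cond, spec$temperature),
                meta = list(spec = spec, condition = cond,
                            temperature = spec$temperature,
                            generator = "gaussian"))
}

# ---- Paired-condition datasets -----------------------------------------------

#' Generate a paired free-solution / confined dataset across temperatures
#'
#' Mirrors the paired simulation design: the same protein sampled in free
#' solution and under confinement at each requested temperature. The two specs
#' must agree on chain length, fold, frame count, fluctuation scale and
#' reference temperature; they may differ in confinement and in planted
#' flexible regions (so that both positive and negative dRMSF peaks can be
#' exercised).
#'
#' @param spec_free `cq_ensemble_spec` without confinement.
#' @param spec_confined `cq_ensemble_spec` with confinement.
#' @param temperatures vector of unique temperatures (K).
#' @return list with `structure`, `trajectories` (named
#'   `<condition>_<temperature>`), and a `manifest` data.frame of conditions,
#'   temperatures, seeds and sigma parameters.
#' @export
make_two_condition_dataset <- function(spec_free, spec_confined, temperatures) {
  stopifnot(inherits(spec_free, "cq_ensemble_spec"),
            inherits(spec_confined, "cq_ensemble_spec"))
  if (!is.null(spec_free$confinement))
    stop("spec_free must not be confined")
  if (is.null(spec_confined$confinement))
    stop("spec_confined must carry a confinement block")
  for (f in c("n_residues", "fold", "n_frames", "base_sigma", "t_ref"))
    if (!identical(spec_free[[f]], spec_confined[[f]]))
      stop("specs must agree on ", f)
  if (anyDuplicated(temperatures)) stop("duplicate temperature labels")
  struct <- build_toy_protein(spec_free$n_residues, spec_free$fold,
                              spec_free$seed)
  trajs <- list()
  manifest <- NULL
  for (ci in 1:2) {
    spec0 <- list(spec_free, spec_confined)[[ci]]
    cond <- c("solution", "confined")[ci]
    for (ti in seq_along(temperatures)) {
      sp <- spec0
      sp$temperature <- temperatures[ti]
      sp$seed <- .derive_seed(spec0$seed, ci, ti)
      trj <- sample_gaussian_trajectory(struct, sp)
      key <- sprintf("%s_%g", cond, temperatures[ti])
      trajs[[key]] <- trj
      manifest <- rbind(manifest, data.frame(
        key = key, condition = cond, temperature = temperatures[ti],
        seed = sp$seed, n_frames = sp$n_frames, base_sigma = sp$base_sigma,
        suppression = if (is.null(sp$confinement)) 1
                      else sp$confinement$suppression,
        stringsAsFactors = FALSE))
    }
  }
  list(structure = struct, trajectories = trajs, manifest = manifest)
}

# Deterministic sub-stream seed derivation, kept well below 2^31.
.derive_seed <- function(master, a, b = 0, c = 0) {
  as.integer((as.numeric(master) * 48271 + a * 100003 + b * 101 + c) %%
               2147483587)
}
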