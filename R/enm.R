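# Mechanistic synthetic tier: elastic-network model (ENM) propagated with
# overdamped (Brownian) Langevin dynamics. Confinement is explicit here -- a
# harmonic spherical wall plus repulsive crowder spheres propagated alongside
# the chain -- so fluctuation suppression emerges rather than being dialled in.

#' Parameters for the overdamped-Langevin elastic network model
#'
#' The Euler-Maruyama update is
#'   x <- x + (dt / friction) * F(x) + sqrt(2 kB T dt / friction) * xi,
#' with F the negative gradient of the harmonic network (plus optional tether,
#' wall and crowder terms). Stability of the discretization requires
#' dt * k_eff / friction to be small; construction rejects
#' dt * max(spring_constant, tether) / friction >= 0.25, and simulation
#' re-checks the bound against the realized network connectivity.
#'
#' @param spring_constant pairwise spring constant, kcal/(mol A^2).
#' @param contact_cutoff network cutoff (A); CA pairs closer than this in the
#'   native structure are connected.
#' @param friction Langevin friction, 1/ps.
#' @param dt time step, ps.
#' @param n_steps number of integration steps.
#' @param temperature K.
#' @param seed integer RNG seed.
#' @param tether optional harmonic restraint of every CA to its native
#'   position, kcal/(mol A^2); `tether > 0` with a single atom realizes an
#'   isotropic harmonic well (stationary per-coordinate variance kB T / tether).
#' @param save_every store every k-th step as a frame.
#' @return An object of class `cq_enm_params`.
#' @export
enm_params <- function(spring_constant = 1, contact_cutoff = 10, friction = 1,
                       dt = 0.01, n_steps = 10000, temperature = 300, seed = 1,
                       tether = 0, save_every = 1) {
  stopifnot(spring_constant >= 0, contact_cutoff > 0, friction > 0, dt > 0,
            n_steps >= 1, temperature >= 0, tether >= 0, save_every >= 1)
  a <- dt * max(spring_constant, tether) / friction
  if (a >= 0.25)
    stop("unstable discretization: dt * k / friction = ", signif(a, 3),
         " >= 0.25; reduce dt or spring constants")
  structure(list(spring_constant = spring_constant,
                 contact_cutoff = contact_cutoff, friction = friction,
                 dt = dt, n_steps = as.integer(n_steps),
                 temperature = temperature, seed = as.integer(seed),
                 tether = tether, save_every = as.integer(save_every)),
            class = "cq_enm_params")
}

#' Simulate an elastic-network ensemble with overdamped Langevin dynamics
#'
#' Springs connect CA pairs within `contact_cutoff` in the native structure,
#' each at its native length. With a confinement spec, a harmonic wall of
#' stiffness `wall_k` confines all CA radial positions to the stated radius,
#' and `n_crowders` repulsive spheres are propagated alongside the chain
#' (crowder-CA and crowder-crowder overlaps penalized harmonically); crowders
#' are discarded from the returned trajectory, which covers chain atoms only.
#'
#' @param struct CA-only native `cq_structure` (the ENM energy minimum).
#' @param params a `cq_enm_params`.
#' @param confinement NULL, or list with `radius` (A), `n_crowders`,
#'   `crowder_radius` (A); see [ensemble_spec()].
#' @param wall_k wall and crowder-repulsion stiffness, kcal/(mol A^2).
#' @return A `cq_trajectory` of the saved frames; deterministic per seed.
#' @export
simulate_enm_langevin <- function(struct, params, confinement = NULL,
                                  wall_k = 10) {
  stopifnot(inherits(struct, "cq_structure"),
            inherits(params, "cq_enm_params"))
  if (!all(struct$atom$atom_name == "CA"))
    stop("ENM requires a CA-only structure")
  n <- nrow(struct$atom)
  x0 <- struct$xyz
  # network springs
  pairs <- NULL
  if (n >= 2 && params$spring_constant > 0) {
    dm <- as.matrix(stats::dist(x0))
    sel <- which(upper.tri(dm) & dm < params$contact_cutoff, arr.ind = TRUE)
    if (nrow(sel))
      pairs <- list(i = sel[, 1], j = sel[, 2], r0 = dm[sel])
  }
  # runtime stability refinement: effective stiffness ~ k * max coordination
  if (!is.null(pairs)) {
    coord_n <- tabulate(c(pairs$i, pairs$j), nbins = n)
    a_eff <- params$dt * (params$spring_constant * max(coord_n) +
                            params$tether) / params$friction
    if (a_eff >= 0.5)
      stop("unstable discretization for this network: dt * k_eff / friction = ",
           signif(a_eff, 3), " >= 0.5; reduce dt")
    B <- Matrix::sparseMatrix(i = c(pairs$i, pairs$j),
                              j = rep(seq_along(pairs$i), 2),
                              x = rep(c(1, -1), each = length(pairs$i)),
                              dims = c(n, length(pairs$i)))
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(params$seed)
  kBT <- cq_constants$kB * params$temperature
  mob <- params$dt / params$friction
  noise_sd <- sqrt(2 * kBT * mob)
  x <- x0
  crowd <- NULL
  if (!is.null(confinement)) {
    R <- confinement$radius
    nc <- if (is.null(confinement$n_crowders)) 0 else confinement$n_crowders
    rc <- if (is.null(confinement$crowder_radius)) 0
          else confinement$crowder_radius
    if (nc > 0) {
      # uniform initial crowder centers in the allowed ball
      u <- runif(nc)^(1 / 3) * max(R - rc, 0)
      d <- matrix(rnorm(3 * nc), nc, 3)
      crowd <- d / sqrt(rowSums(d^2)) * u
    }
  }
  n_save <- params$n_steps %/% params$save_every
  frames <- array(NA_real_, c(n, 3, n_save))
  fi <- 0L
  for (step in seq_len(params$n_steps)) {
    F <- matrix(0, n, 3)
    if (!is.null(pairs)) {
      D <- x[pairs$i, , drop = FALSE] - x[pairs$j, , drop = FALSE]
      r <- sqrt(rowSums(D^2))
      fmag <- -params$spring_constant * (r - pairs$r0) / pmax(r, 1e-12)
      F <- F + as.matrix(B %*% (D * fmag))
    }
    if (params$tether > 0) F <- F - params$tether * (x - x0)
    if (!is.null(confinement)) {
      rr <- sqrt(rowSums(x^2))
      out <- rr > R
      if (any(out))
        F[out, ] <- F[out, ] - wall_k * (rr[out] - R) * x[out, ] / rr[out]
      if (!is.null(crowd)) {
        Fc <- matrix(0, nrow(crowd), 3)
        # crowder-CA repulsion (CA treated as points inside crowder radius rc)
        for (ic in seq_len(nrow(crowd))) {
          dv <- sweep(x, 2, crowd[ic, ])
          dd <- sqrt(rowSums(dv^2))
          ov <- dd < rc
          if (any(ov)) {
            f <- wall_k * (rc - dd[ov]) * dv[ov, , drop = FALSE] /
              pmax(dd[ov], 1e-12)
            F[ov, ] <- F[ov, ] + f
            Fc[ic, ] <- Fc[ic, ] - colSums(f)
          }
        }
        # crowder-crowder repulsion
        if (nrow(crowd) > 1) {
          cd <- as.matrix(stats::dist(crowd))
          ovp <- which(upper.tri(cd) & cd < 2 * rc, arr.ind = TRUE)
          for (kk in seq_len(nrow(ovp))) {
            ii <- ovp[kk, 1]; jj <- ovp[kk, 2]
            dv <- crowd[ii, ] - crowd[jj, ]
            dd <- max(sqrt(sum(dv^2)), 1e-12)
            f <- wall_k * (2 * rc - dd) * dv / dd
            Fc[ii, ] <- Fc[ii, ] + f
            Fc[jj, ] <- Fc[jj, ] - f
          }
        }
        # crowder wall
        cr <- sqrt(rowSums(crowd^2))
        cout <- cr > (R - rc)
        if (any(cout))
          Fc[cout, ] <- Fc[cout, ] - wall_k * (cr[cout] - (R - rc)) *
            crowd[cout, ] / cr[cout]
        crowd <- crowd + mob * Fc +
          noise_sd * matrix(rnorm(3 * nrow(crowd)), nrow(crowd), 3)
      }
    }
    x <- x + mob * F + noise_sd * matrix(rnorm(3 * n), n, 3)
    if (step %% params$save_every == 0L) {
      fi <- fi + 1L
      frames[, , fi] <- x
    }
  }
  cq_trajectory(struct, frames[, , seq_len(fi), drop = FALSE],
                frame_times = seq_len(fi) * params$save_every * params$dt,
                label = sprintf("enm_T%.1f%s", params$temperature,
                                if (is.null(confinement)) "" else "_confined"),
                meta = list(params = params, confinement = confinement,
                            generator = "enm"))
}
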