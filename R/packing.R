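# Crowded-shell design: copy number from a target volume fraction under
# spherical assumptions, seeded random-sequential-insertion placement inside
# the shell interior, and post-hoc steric-clash screening with exclusion of
# offending copies from downstream pooled analyses.

#' Estimate a sphere radius for a structure under a named convention
#'
#' The shell interior and the cargo are treated as spheres; because different
#' radius conventions change the copy count, the convention is explicit:
#' \describe{
#'   \item{cargo / equal-volume}{radius of the sphere whose volume equals the
#'     summed residue volumes (mean residue volume
#'     `cq_constants$residue_volume` = 134 A^3 when residue identity is
#'     unknown, as in CA-only models).}
#'   \item{cargo / max-extent}{maximum centroid-to-atom distance.}
#'   \item{shell-interior / innermost-atom}{minimum centroid-to-shell-atom
#'     distance minus `probe_margin` (default 0 A).}
#' }
#'
#' @param struct a `cq_structure`.
#' @param role `"cargo"` or `"shell-interior"`.
#' @param convention `"equal-volume"`, `"max-extent"` or `"innermost-atom"`.
#' @param probe_margin subtracted from the innermost-atom radius, A.
#' @param residue_volume per-residue volume for equal-volume, A^3.
#' @return radius in A.
#' @export
sphere_radius_estimate <- function(struct,
                                   role = c("cargo", "shell-interior"),
                                   convention = c("equal-volume", "max-extent",
                                                  "innermost-atom"),
                                   probe_margin = 0,
                                   residue_volume = cq_constants$residue_volume) {
  stopifnot(inherits(struct, "cq_structure"), nrow(struct$atom) >= 1)
  role <- match.arg(role)
  convention <- match.arg(convention)
  cen <- colMeans(struct$xyz)
  d <- sqrt(rowSums(sweep(struct$xyz, 2, cen)^2))
  if (role == "cargo") {
    if (convention == "innermost-atom")
      stop("innermost-atom is a shell-interior convention")
    if (convention == "equal-volume") {
      n_res <- length(unique(paste(struct$atom$chain_id,
                                   struct$atom$residue_index)))
      return((3 * n_res * residue_volume / (4 * pi))^(1 / 3))
    }
    return(max(d))
  }
  if (convention != "innermost-atom")
    stop("shell-interior role supports the innermost-atom convention only")
  min(d) - probe_margin
}

#' Cargo copy number from a target volume fraction
#'
#' Under the spherical assumption the number of cargo copies occupying volume
#' fraction `phi` of the shell interior is
#' N = floor( phi * (shell_interior_radius / cargo_radius)^3 )
#' (floor, not round: N copies must not exceed the capacity at the stated
#' fraction).
#'
#' @param phi target volume fraction, 0 <= phi < 0.74 (random sphere packings
#'   cannot reach the FCC close-packing bound).
#' @param shell_interior_radius A.
#' @param cargo_radius A, < shell_interior_radius.
#' @return integer N.
#' @export
copy_number <- function(phi, shell_interior_radius, cargo_radius) {
  if (phi < 0 || phi >= 0.74)
    stop("phi must be in [0, 0.74): got ", phi)
  stopifnot(shell_interior_radius > 0, cargo_radius > 0)
  if (cargo_radius >= shell_interior_radius)
    stop("cargo_radius must be smaller than shell_interior_radius")
  as.integer(floor(phi * (shell_interior_radius / cargo_radius)^3))
}

#' Clash-free placement of cargo copies by random sequential insertion
#'
#' Candidate centers are drawn uniformly in the allowed ball of radius
#' (shell_interior_radius - cargo_radius) and accepted only when at least
#' 2 * cargo_radius from every accepted center; orientations are uniform
#' random proper rotations (unit quaternions). Deterministic per seed; fails
#' loudly, reporting how many copies were placed, once `max_attempts`
#' candidate draws are exhausted.
#'
#' @param n number of copies (>= 0).
#' @param shell_interior_radius A.
#' @param cargo_radius A.
#' @param seed integer.
#' @param max_attempts total candidate-draw budget (default 10000).
#' @return A `cq_packing_plan`: list with radii, `phi_target` = achieved
#'   n (r/R)^3, `n_copies`, `placements` (data.frame copy, x, y, z, qw, qx,
#'   qy, qz), `excluded` (empty data.frame), `seed`.
#' @export
place_copies <- function(n, shell_interior_radius, cargo_radius, seed = 1,
                         max_attempts = 10000) {
  stopifnot(n >= 0, shell_interior_radius > 0, cargo_radius > 0)
  if (n > 0 && cargo_radius >= shell_interior_radius)
    stop("cargo does not fit: cargo_radius >= shell_interior_radius")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  allowed <- shell_interior_radius - cargo_radius
  centers <- matrix(numeric(0), 0, 3)
  quats <- matrix(numeric(0), 0, 4)
  attempts <- 0
  while (nrow(centers) < n) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("placement infeasible: placed ", nrow(centers), " of ", n,
           " copies within ", max_attempts, " attempts")
    u <- runif(1)^(1 / 3) * allowed
    dir <- rnorm(3)
    cand <- dir / sqrt(sum(dir^2)) * u
    if (nrow(centers)) {
      d2 <- rowSums(sweep(centers, 2, cand)^2)
      if (any(d2 < (2 * cargo_radius)^2)) next
    }
    q <- rnorm(4)
    q <- q / sqrt(sum(q^2))
    if (q[1] < 0) q <- -q
    centers <- rbind(centers, cand)
    quats <- rbind(quats, q)
  }
  placements <- data.frame(copy = seq_len(n),
                           x = centers[, 1][seq_len(n)],
                           y = centers[, 2][seq_len(n)],
                           z = centers[, 3][seq_len(n)],
                           qw = quats[, 1][seq_len(n)],
                           qx = quats[, 2][seq_len(n)],
                           qy = quats[, 3][seq_len(n)],
                           qz = quats[, 4][seq_len(n)])
  structure(list(shell_interior_radius = shell_interior_radius,
                 cargo_radius = cargo_radius,
                 phi_target = n * (cargo_radius / shell_interior_radius)^3,
                 n_copies = as.integer(n), placements = placements,
                 excluded = data.frame(copy = integer(), reason = character()),
                 seed = as.integer(seed)),
            class = "cq_packing_plan")
}

#' @export
print.cq_packing_plan <- function(x, ...) {
  cat(sprintf(paste0("cq_packing_plan: %d copies (r = %.1f A) in shell ",
                     "R = %.1f A, phi = %.3f, %d excluded\n"),
              x$n_copies, x$cargo_radius, x$shell_interior_radius,
              x$phi_target, nrow(x$excluded)))
  invisible(x)
}

.quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Assemble atomic cargo copies (and optionally a shell) from a packing plan
#'
#' Cargo coordinates are centered, rotated by each placement's quaternion and
#' translated to its center. Copies get chain ids "A", "B", ...; an optional
#' shell structure is appended with chain id "z".
#'
#' @param plan a `cq_packing_plan`.
#' @param cargo a `cq_structure` (one copy's atoms).
#' @param shell optional `cq_structure` of the shell.
#' @return A `cq_structure` of all copies (plus shell).
#' @export
assemble_copies <- function(plan, cargo, shell = NULL) {
  stopifnot(inherits(plan, "cq_packing_plan"), inherits(cargo, "cq_structure"))
  if (plan$n_copies > 25) stop("chain-id scheme supports at most 25 copies")
  xyz0 <- sweep(cargo$xyz, 2, colMeans(cargo$xyz))
  atoms <- NULL; coords <- NULL
  next_idx <- 1
  for (k in seq_len(plan$n_copies)) {
    p <- plan$placements[k, ]
    R <- .quat_to_rot(c(p$qw, p$qx, p$qy, p$qz))
    xyz <- sweep(xyz0 %*% t(R), 2, c(p$x, p$y, p$z), "+")
    at <- cargo$atom
    at$chain_id <- LETTERS[k]
    at$atom_index <- seq(next_idx, length.out = nrow(at))
    next_idx <- next_idx + nrow(at)
    atoms <- rbind(atoms, at)
    coords <- rbind(coords, xyz)
  }
  if (!is.null(shell)) {
    at <- shell$atom
    at$chain_id <- "z"
    at$atom_index <- seq(next_idx, length.out = nrow(at))
    atoms <- rbind(atoms, at)
    coords <- rbind(coords, shell$xyz)
  }
  cq_structure(atoms, coords,
               title = sprintf("assembly of %d copies", plan$n_copies))
}

#' Screen for steric clashes
#'
#' Generic. On a `cq_packing_plan`, the spheres themselves are screened: a
#' pair of copies clashes when their center distance is below
#' 2 * cargo_radius, and a copy clashes with the shell when its center is
#' farther than shell_interior_radius - cargo_radius from the origin. On an
#' assembled atomic `cq_structure` (chain id = copy, shell chain `"z"`), any
#' copy with an interatomic distance below `min_distance` to another copy or
#' to the shell is flagged. Flagged copies are meant to populate
#' `plan$excluded` (see [apply_exclusions()]) and be dropped from pooled
#' analyses.
#'
#' @param x a `cq_packing_plan` or assembled `cq_structure`.
#' @param min_distance heavy-atom clash criterion for atomic screening, A
#'   (default 2.0).
#' @param ... unused.
#' @return data.frame (copy, partner, distance); zero rows when clash-free.
#' @export
clash_screen <- function(x, min_distance = 2.0, ...) UseMethod("clash_screen")

#' @rdname clash_screen
#' @export
clash_screen.cq_packing_plan <- function(x, min_distance = 2.0, ...) {
  out <- data.frame(copy = integer(), partner = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  n <- x$n_copies
  if (n == 0) return(out)
  cen <- as.matrix(x$placements[, c("x", "y", "z")])
  eps <- 1e-9
  if (n > 1) {
    dm <- as.matrix(stats::dist(cen))
    hit <- which(upper.tri(dm) & dm < 2 * x$cargo_radius - eps,
                 arr.ind = TRUE)
    for (k in seq_len(nrow(hit)))
      out <- rbind(out,
                   data.frame(copy = c(hit[k, 1], hit[k, 2]),
                              partner = paste0("copy ", c(hit[k, 2],
                                                          hit[k, 1])),
                              distance = dm[hit[k, 1], hit[k, 2]],
                              stringsAsFactors = FALSE))
  }
  rad <- sqrt(rowSums(cen^2))
  wall <- which(rad > x$shell_interior_radius - x$cargo_radius + eps)
  for (k in wall)
    out <- rbind(out, data.frame(copy = k, partner = "shell",
                                 distance = x$shell_interior_radius - rad[k],
                                 stringsAsFactors = FALSE))
  out[order(out$copy), , drop = FALSE]
}

#' @rdname clash_screen
#' @export
clash_screen.cq_structure <- function(x, min_distance = 2.0, ...) {
  at <- x$atom
  chains <- setdiff(unique(at$chain_id), "z")
  out <- data.frame(copy = character(), partner = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  groups <- c(chains, if ("z" %in% at$chain_id) "z")
  for (a in seq_along(chains)) {
    ia <- which(at$chain_id == chains[a])
    for (b in seq_along(groups)) {
      if (groups[b] == chains[a] || (groups[b] != "z" && b <= a)) next
      ib <- which(at$chain_id == groups[b])
      # min cross distance between the two atom groups
      d2 <- outer(rowSums(x$xyz[ia, , drop = FALSE]^2),
                  rowSums(x$xyz[ib, , drop = FALSE]^2), "+") -
        2 * x$xyz[ia, , drop = FALSE] %*% t(x$xyz[ib, , drop = FALSE])
      mind <- sqrt(max(min(d2), 0))
      if (mind < min_distance) {
        pb <- if (groups[b] == "z") "shell" else paste0("copy ", groups[b])
        out <- rbind(out,
                     data.frame(copy = chains[a], partner = pb,
                                distance = mind, stringsAsFactors = FALSE))
        if (groups[b] != "z")
          out <- rbind(out,
                       data.frame(copy = groups[b],
                                  partner = paste0("copy ", chains[a]),
                                  distance = mind, stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$copy), , drop = FALSE]
}

#' Record clash exclusions in a packing plan
#'
#' @param plan a `cq_packing_plan`.
#' @param clashes data.frame from [clash_screen()] (`copy` may be a copy
#'   number or a chain letter from an assembled structure).
#' @return The plan with `excluded` populated (unique copies, with reasons);
#'   `phi_after_exclusion` records the achieved volume fraction both before
#'   and after exclusion.
#' @export
apply_exclusions <- function(plan, clashes) {
  stopifnot(inherits(plan, "cq_packing_plan"))
  if (nrow(clashes)) {
    cp <- clashes$copy
    if (is.character(cp)) cp <- match(cp, LETTERS)
    keep <- !duplicated(cp)
    plan$excluded <- data.frame(copy = as.integer(cp[keep]),
                                reason = paste("clash with",
                                               clashes$partner[keep]),
                                stringsAsFactors = FALSE)
  }
  n_eff <- plan$n_copies - nrow(plan$excluded)
  plan$phi_after_exclusion <-
    n_eff * (plan$cargo_radius / plan$shell_interior_radius)^3
  plan
}

#' Export a packing plan as TSV
#' @param plan a `cq_packing_plan`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
export_plan_tsv <- function(plan, path) {
  df <- plan$placements
  df$excluded <- df$copy %in% plan$excluded$copy
  num <- vapply(df, is.numeric, TRUE) & names(df) != "copy"
  df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
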