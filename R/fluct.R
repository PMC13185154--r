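# Per-residue fluctuation analysis: Kabsch superposition, RMSF, replica
# averaging, homodimer monomer pooling, dRMSF and thresholded region detection.

# ---- Kabsch superposition ----------------------------------------------------

# Proper (det = +1) least-squares rotation R such that X %*% R best matches Y
# (X, Y centered coordinate matrices, one point per row).
.kabsch_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

.apply_fit <- function(frame, fit_idx, ref) {
  mx <- colMeans(frame[fit_idx, , drop = FALSE])
  my <- colMeans(ref)
  R <- .kabsch_rotation(sweep(frame[fit_idx, , drop = FALSE], 2, mx),
                        sweep(ref, 2, my))
  sweep(sweep(frame, 2, mx) %*% R, 2, my, "+")
}

.check_fit_mask <- function(refcoords) {
  if (nrow(refcoords) < 3) stop("superposition mask needs >= 3 atoms")
  sv <- svd(sweep(refcoords, 2, colMeans(refcoords)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("superposition mask is collinear or degenerate")
}

#' Rigid-body superposition of a trajectory
#'
#' Each frame is least-squares fitted (proper rotation only, determinant +1)
#' on the mask atoms, either onto the first frame or onto the iterated mean
#' structure (re-fitting until the mean shifts by less than `tol`). The whole
#' frame is transformed; only mask atoms define the fit.
#'
#' @param trajectory a `cq_trajectory`.
#' @param mask a `cq_mask` with >= 3 non-collinear atoms.
#' @param mode `"iterative-mean"` (default) or `"first-frame"`.
#' @param tol convergence threshold on the mean-structure shift (A).
#' @param max_iter iteration cap for the iterative mode.
#' @return The aligned `cq_trajectory`; `meta$aligned` records the mode.
#' @export
superpose <- function(trajectory, mask, mode = c("iterative-mean",
                                                 "first-frame"),
                      tol = 1e-6, max_iter = 50) {
  stopifnot(inherits(trajectory, "cq_trajectory"), inherits(mask, "cq_mask"))
  mode <- match.arg(mode)
  idx <- mask$atom_indices
  nf <- n_frames(trajectory)
  coords <- trajectory$coords
  ref <- coords[idx, , 1, drop = TRUE]
  if (length(idx) == 1) ref <- matrix(ref, 1, 3)
  .check_fit_mask(ref)
  for (f in seq_len(nf)) coords[, , f] <- .apply_fit(coords[, , f], idx, ref)
  if (mode == "iterative-mean") {
    prev_mean <- NULL
    for (it in seq_len(max_iter)) {
      m <- rowMeans(coords[idx, , , drop = FALSE], dims = 2)
      if (!is.null(prev_mean) &&
          max(abs(m - prev_mean)) < tol) break
      prev_mean <- m
      for (f in seq_len(nf)) coords[, , f] <- .apply_fit(coords[, , f], idx, m)
    }
  }
  out <- trajectory
  out$coords <- coords
  out$meta$aligned <- mode
  out$meta$fit_mask <- mask$descriptor
  out
}

# ---- RMSF --------------------------------------------------------------------

.new_profile <- function(residues, values, meta, class = "cq_rmsf_profile",
                         value_col = "rmsf") {
  df <- data.frame(residue = residues, v = values)
  names(df)[2] <- value_col
  attr(df, "meta") <- meta
  class(df) <- c(class, "data.frame")
  df
}

#' Profile metadata
#' @param profile an RMSF or dRMSF profile.
#' @return the `meta` attribute (named list).
#' @export
profile_meta <- function(profile) attr(profile, "meta")

#' Per-residue root-mean-square fluctuation
#'
#' RMSF(i) = sqrt( <  || r_i(t) - <r_i> ||^2  >_t ), with the time average over
#' all retained frames and one mask atom (normally CA) per residue. The caller
#' is responsible for prior superposition; whether the trajectory was aligned
#' is recorded in the profile metadata.
#'
#' @param trajectory a `cq_trajectory`.
#' @param mask `cq_mask` selecting one atom per residue (default: alpha-carbon
#'   selection of the topology).
#' @param discard_fraction fraction of initial frames discarded as
#'   equilibration (default 0: the entire run is used).
#' @return A `cq_rmsf_profile`: data.frame (residue, rmsf) with metadata
#'   (label, temperature, n_replicas = 1, n_frames, alignment mode).
#' @export
rmsf <- function(trajectory, mask = NULL, discard_fraction = 0) {
  stopifnot(inherits(trajectory, "cq_trajectory"),
            discard_fraction >= 0, discard_fraction < 1)
  if (is.null(mask)) mask <- select_atoms(trajectory$topology, "alpha-carbon")
  idx <- mask$atom_indices
  nf <- n_frames(trajectory)
  first <- floor(discard_fraction * nf) + 1
  keep <- seq(first, nf)
  sub <- trajectory$coords[idx, , keep, drop = FALSE]
  meta <- list(label = trajectory$label,
               temperature = trajectory$meta$temperature,
               condition = trajectory$meta$condition,
               n_replicas = 1L, n_frames = length(keep),
               aligned = trajectory$meta$aligned,
               single_frame = length(keep) < 2)
  res <- trajectory$topology$atom$residue_index[idx]
  if (length(keep) < 2) {
    warning("single-frame trajectory: RMSF is identically zero")
    return(.new_profile(res, rep(0, length(idx)), meta))
  }
  mu <- rowMeans(sub, dims = 2)
  msf <- rowSums((sub - as.vector(mu))^2, dims = 1) / length(keep)
  .new_profile(res, sqrt(msf), meta)
}

#' Average RMSF profiles over independent replicas
#'
#' Unweighted per-residue arithmetic mean (replicas are equal-length by
#' design); the result's `n_replicas` is the sum over inputs. Inputs must
#' cover identical residue sets and share a condition label.
#'
#' @param profiles list of `cq_rmsf_profile`s.
#' @return A `cq_rmsf_profile`.
#' @export
average_replicas <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  profiles <- lapply(profiles, function(p) p[order(p$residue), ])
  res <- profiles[[1]]$residue
  for (p in profiles[-1])
    if (!identical(p$residue, res))
      stop("replica profiles have mismatched residue sets")
  conds <- unique(vapply(profiles, function(p) {
    cm <- profile_meta(p)$condition
    if (is.null(cm)) NA_character_ else cm
  }, ""))
  conds <- conds[!is.na(conds)]
  if (length(conds) > 1)
    stop("replica profiles carry different condition labels: ",
         paste(conds, collapse = ", "))
  vals <- rowMeans(vapply(profiles, function(p) p$rmsf,
                          numeric(length(res))))
  meta <- profile_meta(profiles[[1]])
  meta$n_replicas <- sum(vapply(profiles,
                                function(p) profile_meta(p)$n_replicas, 1L))
  .new_profile(res, vals, meta)
}

# ---- Monomer pooling ---------------------------------------------------------

#' Extract a sub-trajectory for a set of atom indices
#' @param trajectory a `cq_trajectory`.
#' @param indices atom row positions to keep.
#' @return A `cq_trajectory` over the subset (topology subset accordingly).
#' @export
subset_trajectory <- function(trajectory, indices) {
  stopifnot(inherits(trajectory, "cq_trajectory"))
  topo <- trajectory$topology
  sub <- cq_structure(topo$atom[indices, , drop = FALSE],
                      topo$xyz[indices, , drop = FALSE], topo$title)
  cq_trajectory(sub, trajectory$coords[indices, , , drop = FALSE],
                frame_times = trajectory$frame_times,
                label = trajectory$label, meta = trajectory$meta)
}

#' Pool RMSF over the monomers of a homomeric assembly
#'
#' Each chain is superposed independently (copies tumble inside a shell, so a
#' global fit would inflate RMSF), its per-residue RMSF computed on CA atoms,
#' and the profiles averaged position-wise across chains. Residues are
#' re-indexed to 1..L (position within the chain) so chains with different
#' author numbering still pool.
#'
#' @param trajectory a `cq_trajectory` containing all chains.
#' @param chains chain ids to pool (all must have equal residue counts).
#' @param mask optional `cq_mask` restricting the atoms considered (defaults
#'   to alpha-carbon).
#' @param align superpose each chain before RMSF (default TRUE).
#' @return A `cq_rmsf_profile` over positions 1..L; `n_replicas` = n chains.
#' @export
pool_monomers <- function(trajectory, chains, mask = NULL, align = TRUE) {
  stopifnot(inherits(trajectory, "cq_trajectory"), length(chains) >= 1)
  if (is.null(mask)) mask <- select_atoms(trajectory$topology, "alpha-carbon")
  at <- trajectory$topology$atom
  profiles <- vector("list", length(chains))
  L <- NULL
  for (k in seq_along(chains)) {
    idx <- intersect(mask$atom_indices, which(at$chain_id == chains[k]))
    if (!length(idx)) stop("chain ", chains[k], " matches no masked atoms")
    if (is.null(L)) L <- length(idx)
    else if (length(idx) != L)
      stop("chains have unequal lengths: chain ", chains[k], " has ",
           length(idx), " residues, expected ", L)
    sub <- subset_trajectory(trajectory, idx)
    if (align && n_frames(sub) > 1)
      sub <- superpose(sub, select_atoms(sub$topology, "alpha-carbon"),
                       mode = "iterative-mean")
    p <- rmsf(sub)
    p$residue <- seq_len(L)  # positional numbering
    profiles[[k]] <- p
  }
  vals <- rowMeans(vapply(profiles, function(p) p$rmsf, numeric(L)))
  meta <- profile_meta(profiles[[1]])
  meta$n_replicas <- length(chains)
  meta$pooled_chains <- chains
  .new_profile(seq_len(L), vals, meta)
}

# ---- dRMSF and region detection ----------------------------------------------

#' Difference RMSF profile (solution minus confined)
#'
#' Positive values mark residues more flexible in free solution than under
#' confinement; negative values mark residues whose flexibility is enhanced by
#' the crowded environment. Defined on the residue intersection of the inputs.
#'
#' @param solution,confined `cq_rmsf_profile`s.
#' @return A `cq_delta_profile`: data.frame (residue, delta).
#' @export
delta_rmsf <- function(solution, confined) {
  common <- intersect(solution$residue, confined$residue)
  if (!length(common)) stop("profiles share no residues")
  common <- sort(common)
  s <- solution$rmsf[match(common, solution$residue)]
  c_ <- confined$rmsf[match(common, confined$residue)]
  .new_profile(common, s - c_,
               meta = list(solution = profile_meta(solution),
                           confined = profile_meta(confined)),
               class = "cq_delta_profile", value_col = "delta")
}

#' Detect contiguous regions of large |dRMSF|
#'
#' Maximal runs of consecutive residues with |delta| >= threshold and uniform
#' sign, at least `min_length` residues long. The threshold is applied to the
#' magnitude with the sign recorded, so suppressed (positive) and enhanced
#' (negative) regions are both reported. Regions are labelled I, II, ... in
#' residue order; `peak_value` is the signed extreme within the run.
#'
#' @param delta a `cq_delta_profile`.
#' @param threshold A (default 2.0).
#' @param min_length minimum run length in residues (default 2).
#' @return data.frame (label, start_residue, end_residue, sign, peak_value);
#'   zero rows if nothing crosses the threshold.
#' @export
detect_regions <- function(delta, threshold = 2.0, min_length = 2) {
  stopifnot(threshold > 0, min_length >= 1)
  ord <- order(delta$residue)
  res <- delta$residue[ord]
  d <- delta$delta[ord]
  state <- ifelse(abs(d) >= threshold, sign(d), 0)
  out <- NULL
  i <- 1
  n <- length(res)
  while (i <= n) {
    if (state[i] != 0) {
      j <- i
      while (j < n && state[j + 1] == state[i] && res[j + 1] == res[j] + 1)
        j <- j + 1
      if (j - i + 1 >= min_length) {
        seg <- d[i:j]
        out <- rbind(out, data.frame(
          start_residue = res[i], end_residue = res[j],
          sign = if (state[i] > 0) "positive" else "negative",
          peak_value = seg[which.max(abs(seg))],
          stringsAsFactors = FALSE))
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out))
    return(data.frame(label = character(), start_residue = integer(),
                      end_residue = integer(), sign = character(),
                      peak_value = numeric(), stringsAsFactors = FALSE))
  cbind(data.frame(label = as.character(as.roman(seq_len(nrow(out)))),
                   stringsAsFactors = FALSE), out)
}

#' Export RMSF / dRMSF profiles and region annotations as TSV
#'
#' @param profiles named list of `cq_rmsf_profile`s (columns become
#'   `rmsf_<name>`).
#' @param delta optional `cq_delta_profile`.
#' @param regions optional region table from [detect_regions()].
#' @param path output TSV path.
#' @return invisibly, the exported data.frame.
#' @export
export_profiles_tsv <- function(profiles, delta = NULL, regions = NULL, path) {
  stopifnot(length(profiles) >= 1)
  res <- sort(unique(unlist(lapply(profiles, function(p) p$residue))))
  df <- data.frame(residue = res)
  for (nm in names(profiles))
    df[[paste0("rmsf_", nm)]] <-
      profiles[[nm]]$rmsf[match(res, profiles[[nm]]$residue)]
  if (!is.null(delta))
    df$delta_rmsf <- delta$delta[match(res, delta$residue)]
  if (!is.null(regions)) {
    df$region <- ""
    if (nrow(regions))
      for (r in seq_len(nrow(regions))) {
        inr <- df$residue >= regions$start_residue[r] &
          df$residue <= regions$end_residue[r]
        df$region[inr] <- regions$label[r]
      }
  }
  num <- vapply(df, is.numeric, TRUE) & names(df) != "residue"
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
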