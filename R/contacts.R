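# Soft fraction-of-native-contacts analysis. A native contact is an atom pair
# closer than `cutoff` in the reference structure with residue separation
# |i - j| > min_separation (excluding trivial local contacts); the per-frame
# order parameter is
#   Q(X) = (1/N) sum_(i,j) 1 / (1 + exp[ beta * ( r_ij(X) - lambda * r_ij0 ) ])
# with r_ij0 the reference-structure distance of the same pair, beta the
# switching sharpness (1/A) and lambda the tolerance for thermal fluctuation.

#' Native-contact parameters
#'
#' @param beta switching sharpness, 1/A (default 5).
#' @param lambda contact-formation tolerance, dimensionless (default 1.8).
#' @param cutoff reference-distance cutoff, A (default 4.5).
#' @param min_separation residue-separation exclusion: pairs with
#'   |i - j| <= min_separation are never contacts (default 3).
#' @param mode `"alpha-carbon"` (one contact per CA pair; default) or
#'   `"heavy-atom"` (one contact per heavy-atom pair; N counts atom pairs).
#' @return An object of class `cq_contact_params`.
#' @export
contact_params <- function(beta = 5, lambda = 1.8, cutoff = 4.5,
                           min_separation = 3,
                           mode = c("alpha-carbon", "heavy-atom")) {
  stopifnot(beta > 0, lambda > 0, cutoff >= 0, min_separation >= 0)
  structure(list(beta = beta, lambda = lambda, cutoff = cutoff,
                 min_separation = as.integer(min_separation),
                 mode = match.arg(mode)),
            class = "cq_contact_params")
}

#' Build the reference native-contact set
#'
#' Only intra-chain pairs are considered (interfacial contacts are out of
#' scope; homodimer analyses run per monomer). An empty result is returned
#' with a warning rather than failing, so degenerate geometries surface
#' explicitly downstream.
#'
#' @param struct reference `cq_structure`.
#' @param params a `cq_contact_params`.
#' @param chain restrict to one chain id (default: first chain in the
#'   structure when several are present).
#' @return A `cq_contact_set`: list with `pairs` (data.frame i_atom, j_atom,
#'   i_res, j_res, r0), `params`, `reference`, `chain`, and `n` = nrow(pairs).
#' @export
reference_contacts <- function(struct, params = contact_params(),
                               chain = NULL) {
  stopifnot(inherits(struct, "cq_structure"),
            inherits(params, "cq_contact_params"))
  at <- struct$atom
  if (is.null(chain)) chain <- at$chain_id[1]
  sel <- which(at$chain_id == chain &
                 (if (params$mode == "alpha-carbon") at$atom_name == "CA"
                  else toupper(at$element) != "H"))
  if (length(unique(at$residue_index[sel])) < params$min_separation + 2)
    stop("structure has too few residues for the separation rule")
  pairs <- data.frame(i_atom = integer(), j_atom = integer(),
                      i_res = integer(), j_res = integer(), r0 = numeric())
  if (length(sel) >= 2 && params$cutoff > 0) {
    dm <- as.matrix(stats::dist(struct$xyz[sel, , drop = FALSE]))
    ri <- at$residue_index[sel]
    sep <- abs(outer(ri, ri, "-"))
    hit <- which(upper.tri(dm) & dm < params$cutoff &
                   sep > params$min_separation, arr.ind = TRUE)
    if (nrow(hit)) {
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      pairs <- data.frame(i_atom = sel[hit[, 1]], j_atom = sel[hit[, 2]],
                          i_res = ri[hit[, 1]], j_res = ri[hit[, 2]],
                          r0 = dm[hit])
    }
  }
  if (!nrow(pairs))
    warning("empty native-contact set (cutoff = ", params$cutoff, " A, mode ",
            params$mode, ")")
  structure(list(pairs = pairs, params = params, reference = struct$title,
                 chain = chain, n = nrow(pairs)),
            class = "cq_contact_set")
}

#' @export
print.cq_contact_set <- function(x, ...) {
  cat(sprintf("cq_contact_set: %d contacts (%s, cutoff %.2f A, |i-j| > %d)\n",
              x$n, x$params$mode, x$params$cutoff, x$params$min_separation))
  invisible(x)
}

# Saturating logistic switching term; arguments clipped at +/-500 before
# exponentiation (the term is already 0/1 to machine precision there).
.q_switch <- function(r, r0, beta, lambda) {
  arg <- pmin(pmax(beta * (r - lambda * r0), -500), 500)
  1 / (1 + exp(arg))
}

#' Soft fraction of native contacts for one frame
#'
#' @param frame n_atoms x 3 coordinate matrix covering every atom index named
#'   in the contact set.
#' @param contacts a `cq_contact_set` with N > 0.
#' @return Q in (0, 1).
#' @export
q_fraction <- function(frame, contacts) {
  stopifnot(inherits(contacts, "cq_contact_set"))
  if (contacts$n == 0) stop("Q is undefined for an empty contact set")
  frame <- as.matrix(frame)
  p <- contacts$pairs
  if (max(p$i_atom, p$j_atom) > nrow(frame))
    stop("frame does not cover all contact atoms")
  D <- frame[p$i_atom, , drop = FALSE] - frame[p$j_atom, , drop = FALSE]
  r <- sqrt(rowSums(D^2))
  mean(.q_switch(r, p$r0, contacts$params$beta, contacts$params$lambda))
}

# Map a contact set defined on its reference chain onto another chain of a
# homomeric topology, by residue position within the chain (CA mode).
.map_contacts_to_chain <- function(contacts, topology, chain) {
  at <- topology$atom
  ref_ca <- which(at$chain_id == contacts$chain & at$atom_name == "CA")
  tgt_ca <- which(at$chain_id == chain & at$atom_name == "CA")
  if (length(ref_ca) != length(tgt_ca))
    stop("chain ", chain, " length differs from reference chain ",
         contacts$chain)
  out <- contacts
  out$pairs$i_atom <- tgt_ca[match(contacts$pairs$i_atom, ref_ca)]
  out$pairs$j_atom <- tgt_ca[match(contacts$pairs$j_atom, ref_ca)]
  if (anyNA(out$pairs$i_atom) || anyNA(out$pairs$j_atom))
    stop("contact set is not CA-resolved on chain ", contacts$chain,
         "; per-monomer mapping requires alpha-carbon mode")
  out$chain <- chain
  out
}

#' Per-frame Q series, per monomer
#'
#' Evaluates Q for every frame. For homomeric systems, pass the chain ids in
#' `monomers`: the contact set (built on its reference chain, alpha-carbon
#' mode) is mapped onto each chain by residue position and one series per
#' monomer is produced, concatenated with monomer labels.
#'
#' @param trajectory a `cq_trajectory` sharing the contact set's topology.
#' @param contacts a `cq_contact_set`.
#' @param monomers optional vector of chain ids (default: the contact set's
#'   own chain only).
#' @return A `cq_q_series`: data.frame (frame, monomer, q) with metadata
#'   (condition, temperature, contact-set reference).
#' @export
q_series <- function(trajectory, contacts, monomers = NULL) {
  stopifnot(inherits(trajectory, "cq_trajectory"),
            inherits(contacts, "cq_contact_set"))
  if (contacts$n == 0) stop("Q is undefined for an empty contact set")
  if (is.null(monomers)) monomers <- contacts$chain
  nf <- n_frames(trajectory)
  out <- NULL
  for (ch in monomers) {
    cs <- if (identical(ch, contacts$chain)) contacts
          else .map_contacts_to_chain(contacts, trajectory$topology, ch)
    p <- cs$pairs
    # vectorized over frames: (n_pairs x n_frames) distance matrix
    Di <- trajectory$coords[p$i_atom, , , drop = FALSE] -
      trajectory$coords[p$j_atom, , , drop = FALSE]
    r <- sqrt(colSums(aperm(Di, c(2, 1, 3))^2))  # n_pairs x n_frames
    if (is.null(dim(r))) r <- matrix(r, ncol = nf)
    terms <- .q_switch(r, p$r0, cs$params$beta, cs$params$lambda)
    qv <- colMeans(matrix(terms, ncol = nf))
    out <- rbind(out, data.frame(frame = seq_len(nf), monomer = ch, q = qv,
                                 stringsAsFactors = FALSE))
  }
  attr(out, "meta") <- list(condition = trajectory$meta$condition,
                            temperature = trajectory$meta$temperature,
                            label = trajectory$label,
                            contacts = contacts$reference,
                            mode = contacts$params$mode)
  class(out) <- c("cq_q_series", "data.frame")
  out
}

#' Summary statistics of pooled Q values by condition and temperature
#'
#' @param series list of `cq_q_series` objects (each carries condition and
#'   temperature metadata), or a single one.
#' @return data.frame with one row per (condition, temperature): n, median,
#'   mean, iqr, q05, q95.
#' @export
q_summary <- function(series) {
  if (inherits(series, "cq_q_series")) series <- list(series)
  stopifnot(is.list(series), length(series) >= 1)
  pooled <- do.call(rbind, lapply(series, function(s) {
    m <- attr(s, "meta")
    data.frame(condition = if (is.null(m$condition)) "unknown" else m$condition,
               temperature = if (is.null(m$temperature)) NA_real_
                             else m$temperature,
               q = s$q, stringsAsFactors = FALSE)
  }))
  if (!nrow(pooled)) stop("no Q values to summarize")
  groups <- unique(pooled[c("condition", "temperature")])
  groups <- groups[order(groups$condition, groups$temperature), , drop = FALSE]
  out <- NULL
  for (g in seq_len(nrow(groups))) {
    qs <- pooled$q[pooled$condition == groups$condition[g] &
                     (pooled$temperature %in% groups$temperature[g] |
                        (is.na(groups$temperature[g]) &
                           is.na(pooled$temperature)))]
    out <- rbind(out, data.frame(
      condition = groups$condition[g], temperature = groups$temperature[g],
      n = length(qs), median = median(qs), mean = mean(qs),
      iqr = unname(quantile(qs, 0.75) - quantile(qs, 0.25)),
      q05 = unname(quantile(qs, 0.05)), q95 = unname(quantile(qs, 0.95)),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Export a contact list or Q series as TSV
#' @param x a `cq_contact_set`, `cq_q_series`, or the data.frame from
#'   [q_summary()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
export_contacts_tsv <- function(x, path) {
  df <- if (inherits(x, "cq_contact_set")) x$pairs else as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE) &
    !names(df) %in% c("frame", "i_atom", "j_atom", "i_res", "j_res", "n")
  df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
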