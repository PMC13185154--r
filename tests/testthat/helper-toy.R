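# Shared fixtures, all built in code.

# Handcrafted PDB ATOM line with fixed-width fields.
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          b = 0, record = "ATOM") {
  sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), resid, chain, resno, x, y, z,
          1, b, substr(name, 1, 1))
}

# A 3-atom single-model PDB with known coordinates.
toy_pdb_text <- function() {
  c(pdb_atom_line(1, "CA", "ALA", "A", 1, 1.000, 2.000, 3.000, b = 0.5),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 4.500, 5.250, 6.125),
    pdb_atom_line(3, "CA", "ALA", "A", 3, -1.000, 0.000, 2.500),
    "END")
}

# Build a CA-only structure directly from a coordinate matrix.
point_structure <- function(xyz, chain = "A", residues = seq_len(nrow(xyz))) {
  xyz <- as.matrix(xyz)
  cq_structure(
    data.frame(atom_index = seq_len(nrow(xyz)), atom_name = "CA",
               element = "C", residue_index = residues, chain_id = chain,
               bfactor = 0, stringsAsFactors = FALSE),
    xyz)
}

# Proper rotation about z by angle a.
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1),
                            3, 3)

# Trajectory whose frames are explicit coordinate matrices.
traj_from_frames <- function(struct, frames, ...) {
  coords <- array(NA_real_, c(nrow(struct$xyz), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  cq_trajectory(struct, coords, ...)
}

# Independent brute-force Q: double loop over contacts, no vectorization.
brute_force_q <- function(frame, contacts) {
  p <- contacts$pairs
  beta <- contacts$params$beta
  lam <- contacts$params$lambda
  tot <- 0
  for (k in seq_len(nrow(p))) {
    d <- sqrt(sum((frame[p$i_atom[k], ] - frame[p$j_atom[k], ])^2))
    a <- beta * (d - lam * p$r0[k])
    a <- min(max(a, -500), 500)
    tot <- tot + 1 / (1 + exp(a))
  }
  tot / nrow(p)
}

# Independent brute-force region scan used as the detect_regions oracle.
brute_force_regions <- function(residues, delta, threshold, min_length) {
  hits <- which(abs(delta) >= threshold)
  out <- NULL
  while (length(hits)) {
    run <- hits[1]
    hits <- hits[-1]
    while (length(hits) && hits[1] == run[length(run)] + 1 &&
           residues[hits[1]] == residues[run[length(run)]] + 1 &&
           sign(delta[hits[1]]) == sign(delta[run[1]])) {
      run <- c(run, hits[1]); hits <- hits[-1]
    }
    if (length(run) >= min_length)
      out <- rbind(out, data.frame(start_residue = residues[run[1]],
                                   end_residue = residues[run[length(run)]]))
  }
  out
}

# Default paired dataset at the package's study conditions (shared across
# the trend and region-recovery checks).
study_dataset <- function(n_frames = 5000, seed = 11) {
  temps <- c(25, 50, 65, 80) + 273.15
  sf <- ensemble_spec(64, "hairpin", n_frames = n_frames, base_sigma = 1,
                      flexible_regions = data.frame(start = 40, end = 48,
                                                    amp = 3),
                      seed = seed)
  sc <- ensemble_spec(64, "hairpin", n_frames = n_frames, base_sigma = 1,
                      flexible_regions = data.frame(start = 20, end = 24,
                                                    amp = 5),
                      confinement = list(radius = 45, suppression = 0.6),
                      seed = seed)
  make_two_condition_dataset(sf, sc, temps)
}
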