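#' @importFrom stats rnorm runif sd median quantile IQR setNames
#' @importFrom utils write.table read.table as.roman head tail
NULL

# ---- Structure container -----------------------------------------------------

#' Construct a Structure object
#'
#' A Structure is the frame of reference for every downstream stage: an ordered
#' atom table plus an n x 3 coordinate matrix in Angstrom.
#'
#' @param atom data.frame with columns `atom_index` (strictly increasing
#'   integers), `atom_name`, `element`, `residue_index` (>= 1, non-decreasing
#'   within a chain), `chain_id`, `bfactor`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in A.
#' @param title character scalar.
#' @return An object of class `cq_structure`.
#' @export
cq_structure <- function(atom, xyz, title = "") {
  xyz <- as.matrix(xyz)
  stopifnot(is.data.frame(atom), ncol(xyz) == 3, nrow(xyz) == nrow(atom))
  needed <- c("atom_index", "atom_name", "element", "residue_index",
              "chain_id", "bfactor")
  missing_cols <- setdiff(needed, names(atom))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atom) > 1 && any(diff(atom$atom_index) <= 0))
    stop("atom_index must be strictly increasing")
  for (ch in unique(atom$chain_id)) {
    ri <- atom$residue_index[atom$chain_id == ch]
    if (length(ri) > 1 && any(diff(ri) < 0))
      stop("residue_index must be non-decreasing within chain ", ch)
  }
  if (any(atom$residue_index < 1)) stop("residue_index must be >= 1")
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  dimnames(xyz) <- NULL
  rownames(atom) <- NULL
  structure(list(atom = atom, xyz = xyz, title = as.character(title)[1]),
            class = "cq_structure")
}

#' @export
print.cq_structure <- function(x, ...) {
  cat(sprintf("cq_structure: %d atoms, %d residues, chains [%s]%s\n",
              nrow(x$atom), length(unique(paste(x$atom$chain_id,
                                                x$atom$residue_index))),
              paste(unique(x$atom$chain_id), collapse = ","),
              if (nzchar(x$title)) paste0(" -- ", x$title) else ""))
  invisible(x)
}

#' Number of atoms in a Structure or Trajectory
#' @param x a `cq_structure` or `cq_trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "cq_structure")) nrow(x$atom)
  else if (inherits(x, "cq_trajectory")) nrow(x$topology$atom)
  else stop("unsupported type")
}

# ---- Trajectory container ----------------------------------------------------

#' Construct a Trajectory object
#'
#' @param topology a `cq_structure` giving the fixed atom set.
#' @param coords numeric array of dimension (n_atoms, 3, n_frames), A.
#' @param frame_times optional numeric vector of times (ps).
#' @param label condition/temperature label.
#' @param meta optional named list of provenance metadata.
#' @return An object of class `cq_trajectory`.
#' @export
cq_trajectory <- function(topology, coords, frame_times = NULL, label = "",
                          meta = list()) {
  stopifnot(inherits(topology, "cq_structure"))
  coords <- as.array(coords)
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an (n_atoms, 3, n_frames) array")
  if (dim(coords)[1] != nrow(topology$atom))
    stop("coords atom count (", dim(coords)[1],
         ") does not match topology (", nrow(topology$atom), ")")
  if (!is.null(frame_times) && length(frame_times) != dim(coords)[3])
    stop("frame_times length must equal the number of frames")
  structure(list(topology = topology, coords = coords,
                 frame_times = frame_times, label = as.character(label)[1],
                 meta = meta),
            class = "cq_trajectory")
}

#' @export
print.cq_trajectory <- function(x, ...) {
  cat(sprintf("cq_trajectory: %d frames x %d atoms%s\n", n_frames(x),
              n_atoms(x), if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param trajectory a `cq_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Extract one frame as a coordinate matrix
#' @param trajectory a `cq_trajectory`.
#' @param i frame index.
#' @return n_atoms x 3 matrix.
#' @export
frame_coords <- function(trajectory, i) {
  if (i < 1 || i > n_frames(trajectory)) stop("frame index out of range")
  trajectory$coords[, , i, drop = TRUE]
}

# ---- PDB reading -------------------------------------------------------------

# Pre-validate the ATOM/HETATM records of a PDB file so parse failures can be
# reported with a line number; bio3d does the actual parsing afterwards.
.validate_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (k in which(is_atom)) {
    ln <- lines[k]
    if (nchar(ln) < 54)
      stop("malformed ATOM record at line ", k, " of '", path,
           "': record shorter than coordinate fields")
    flds <- c(serial = substr(ln, 7, 11), x = substr(ln, 31, 38),
              y = substr(ln, 39, 46), z = substr(ln, 47, 54))
    num <- suppressWarnings(as.numeric(flds))
    if (any(is.na(num)))
      stop("malformed ATOM record at line ", k, " of '", path,
           "': non-numeric field (", paste(names(flds)[is.na(num)],
                                           collapse = ", "), ")")
  }
  invisible(is_atom)
}

# Indices of ATOM lines grouped by MODEL block (single block if no MODEL).
.pdb_model_blocks <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_at <- which(rec == "MODEL ")
  if (!length(model_at)) {
    if (!any(is_atom)) return(list())
    return(list(which(is_atom)))
  }
  endm_at <- which(substr(lines, 1, 6) == "ENDMDL")
  blocks <- vector("list", length(model_at))
  for (b in seq_along(model_at)) {
    lo <- model_at[b]
    hi <- endm_at[endm_at > lo]
    hi <- if (length(hi)) hi[1] else length(lines)
    blocks[[b]] <- intersect(which(is_atom), seq(lo, hi))
  }
  blocks[vapply(blocks, length, 1L) > 0]
}

.water_resids <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "SPC")

# Convert a bio3d pdb atom table + one xyz model row into a cq_structure.
.bio3d_to_structure <- function(pdb, keep, model_xyz, title) {
  at <- pdb$atom[keep, , drop = FALSE]
  ele <- at$elesy
  ele[is.na(ele) | !nzchar(trimws(ele))] <-
    substr(trimws(at$elety[is.na(ele) | !nzchar(trimws(ele))]), 1, 1)
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  xyz <- matrix(model_xyz, ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
  cq_structure(
    atom = data.frame(atom_index = at$eleno, atom_name = trimws(at$elety),
                      element = trimws(ele), residue_index = at$resno,
                      chain_id = chain,
                      bfactor = ifelse(is.na(at$b), 0, at$b),
                      stringsAsFactors = FALSE),
    xyz = xyz, title = title)
}

#' Read a protein structure from a PDB file
#'
#' Heteroatoms and water molecules are excluded by default; all downstream
#' analyses in this package are protein-only. Coordinates are in A and residue
#' numbering is the file's own (1-based PDB numbering), which matters because
#' the native-contact sequence-separation rule |i - j| > 3 is residue-number
#' arithmetic.
#'
#' @param path PDB file path.
#' @param model_index which MODEL to read (1-based; files without MODEL records
#'   count as a single model).
#' @param keep_hetero keep HETATM records (waters are still dropped unless
#'   `keep_water` is TRUE).
#' @param keep_water keep water residues.
#' @return A `cq_structure`.
#' @export
read_structure <- function(path, model_index = 1, keep_hetero = FALSE,
                           keep_water = FALSE) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines, path)
  blocks <- .pdb_model_blocks(lines)
  if (!length(blocks)) stop("no ATOM records found in '", path, "'")
  if (model_index < 1 || model_index > length(blocks))
    stop("model_index ", model_index, " absent: '", path, "' has ",
         length(blocks), " model(s)")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nmod <- nrow(pdb$xyz)
  if (nmod < length(blocks)) {
    # bio3d collapsed models (it requires equal atom counts); fall back to a
    # single-model re-read of the requested block written to a temp file.
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c(lines[blocks[[model_index]]], "END"), tmp)
    pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
    model_row <- 1
  } else model_row <- model_index
  keep <- rep(TRUE, nrow(pdb$atom))
  if (!keep_hetero) keep <- keep & pdb$atom$type == "ATOM"
  if (!keep_water) keep <- keep & !(trimws(pdb$atom$resid) %in% .water_resids)
  if (!any(keep)) stop("no atoms left after heteroatom/water filtering in '",
                       path, "'")
  .bio3d_to_structure(pdb, keep, pdb$xyz[model_row, ], basename(path))
}

# ---- Trajectory reading ------------------------------------------------------

.is_dcd <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", n = 8)
  length(hdr) == 8 && rawToChar(hdr[5:8]) == "CORD"
}

#' Read a conformational ensemble (multi-model PDB or DCD)
#'
#' @param path trajectory file (multi-model PDB, or CHARMM-style DCD).
#' @param topology `cq_structure` defining the atom set; every frame must have
#'   exactly this atom count.
#' @return A `cq_trajectory` with frames in file order.
#' @export
read_trajectory <- function(path, topology) {
  stopifnot(inherits(topology, "cq_structure"))
  if (!file.exists(path)) stop("file not found: '", path, "'")
  nat <- nrow(topology$atom)
  if (.is_dcd(path)) {
    xyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                    error = function(e) stop("truncated or unreadable DCD '",
                                             path, "': ", conditionMessage(e)))
    if (ncol(xyz) != 3 * nat)
      stop("atom-count mismatch: DCD has ", ncol(xyz) / 3,
           " atoms, topology has ", nat)
    nf <- nrow(xyz)
    coords <- array(NA_real_, c(nat, 3, nf))
    for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3,
                                                   byrow = TRUE)
    return(cq_trajectory(topology, coords, label = basename(path)))
  }
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines, path)
  blocks <- .pdb_model_blocks(lines)
  if (!length(blocks)) stop("empty trajectory: no ATOM records in '", path, "'")
  counts <- vapply(blocks, length, 1L)
  bad <- which(counts != nat)
  if (length(bad))
    stop("atom-count mismatch in frame ", bad[1], " of '", path, "': has ",
         counts[bad[1]], " atoms, topology has ", nat)
  nf <- length(blocks)
  coords <- array(NA_real_, c(nat, 3, nf))
  for (f in seq_len(nf)) {
    ln <- lines[blocks[[f]]]
    coords[, 1, f] <- as.numeric(substr(ln, 31, 38))
    coords[, 2, f] <- as.numeric(substr(ln, 39, 46))
    coords[, 3, f] <- as.numeric(substr(ln, 47, 54))
  }
  cq_trajectory(topology, coords, label = basename(path))
}

# ---- Writing -----------------------------------------------------------------

.as_bio3d_pdb <- function(struct) {
  at <- struct$atom
  n <- nrow(at)
  atom <- data.frame(
    type = rep("ATOM", n), eleno = at$atom_index, elety = at$atom_name,
    alt = rep(NA, n), resid = rep("ALA", n), chain = at$chain_id,
    resno = at$residue_index, insert = rep(NA, n), o = rep(1, n),
    b = at$bfactor, segid = rep(NA, n), elesy = at$element,
    charge = rep(NA, n), stringsAsFactors = FALSE)
  pdb <- list(atom = atom, xyz = bio3d::as.xyz(matrix(t(struct$xyz), nrow = 1)),
              calpha = at$atom_name == "CA")
  class(pdb) <- "pdb"
  pdb
}

#' Write a Structure to a PDB file
#' @param struct a `cq_structure`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_structure <- function(struct, path) {
  stopifnot(inherits(struct, "cq_structure"))
  pdb <- .as_bio3d_pdb(struct)
  bio3d::write.pdb(pdb = pdb, file = path)
  invisible(path)
}

.write_dcd <- function(coords, path) {
  nat <- dim(coords)[1]; nf <- dim(coords)[3]
  con <- file(path, "wb"); on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header block: 'CORD' + 20 control integers (CHARMM version 24, no cell)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1; icntrl[3] <- 1; icntrl[4] <- nf
  icntrl[20] <- 24
  wint(84); writeBin(charToRaw("CORD"), con); wint(icntrl); wint(84)
  title <- sprintf("%-80s", "crowdq trajectory")
  wint(4 + 80); wint(1); writeBin(charToRaw(title), con); wint(4 + 80)
  wint(4); wint(nat); wint(4)
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      wint(4 * nat)
      writeBin(as.numeric(coords[, d, f]), con, size = 4, endian = "little")
      wint(4 * nat)
    }
  }
}

#' Write a Trajectory to multi-model PDB or DCD
#'
#' Multi-model PDB round trips losslessly at the format's 3-decimal coordinate
#' precision; DCD stores single-precision floats.
#'
#' @param trajectory a `cq_trajectory`.
#' @param path output path.
#' @param format `"pdb"` or `"dcd"`; default inferred from the file extension.
#' @return invisibly, the path.
#' @export
write_trajectory <- function(trajectory, path,
                             format = c("auto", "pdb", "dcd")) {
  stopifnot(inherits(trajectory, "cq_trajectory"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  if (format == "dcd") {
    .write_dcd(trajectory$coords, path)
    return(invisible(path))
  }
  pdb <- .as_bio3d_pdb(trajectory$topology)
  nf <- n_frames(trajectory)
  xyz <- matrix(NA_real_, nf, 3 * n_atoms(trajectory))
  for (f in seq_len(nf)) xyz[f, ] <- as.numeric(t(trajectory$coords[, , f]))
  bio3d::write.pdb(pdb = pdb, xyz = bio3d::as.xyz(xyz), file = path)
  invisible(path)
}

# ---- Atom selection ----------------------------------------------------------

#' Select atoms from a Structure
#'
#' Selector terms: `"alpha-carbon"` (one CA per amino-acid residue),
#' `"heavy-atom"` (element != H), `"chain=<id>"`, `"residues=<a>..<b>"`.
#' Terms may be conjoined with `" and "` or `"&"`; conjunction is set
#' intersection. An empty selection is an error, never a silent empty mask.
#'
#' @param struct a `cq_structure`.
#' @param selector selection expression (see Details).
#' @return A `cq_mask`: list with sorted unique `atom_indices` (row positions
#'   into the structure's atom table) and a `descriptor`.
#' @export
select_atoms <- function(struct, selector) {
  stopifnot(inherits(struct, "cq_structure"), is.character(selector))
  terms <- trimws(strsplit(selector, "\\s+and\\s+|&")[[1]])
  terms <- terms[nzchar(terms)]
  if (!length(terms)) stop("empty selector expression")
  at <- struct$atom
  keep <- rep(TRUE, nrow(at))
  for (tm in terms) {
    keep <- keep & switch(
      sub("=.*", "", tm),
      "alpha-carbon" = at$atom_name == "CA",
      "heavy-atom"   = toupper(at$element) != "H",
      "chain"        = at$chain_id == sub("^chain=", "", tm),
      "residues"     = {
        rng <- suppressWarnings(as.integer(
          strsplit(sub("^residues=", "", tm), "\\.\\.")[[1]]))
        if (length(rng) != 2 || any(is.na(rng)))
          stop("bad residue range in selector term '", tm, "'")
        at$residue_index >= rng[1] & at$residue_index <= rng[2]
      },
      stop("unknown selector term '", tm, "'"))
  }
  idx <- which(keep)
  if (!length(idx))
    stop("selection '", selector, "' matched no atoms")
  structure(list(atom_indices = idx, descriptor = selector),
            class = "cq_mask")
}

#' Intersect two selection masks
#' @param a,b `cq_mask` objects on the same structure.
#' @return A `cq_mask` with the index intersection.
#' @export
mask_intersect <- function(a, b) {
  idx <- intersect(a$atom_indices, b$atom_indices)
  if (!length(idx)) stop("mask intersection is empty")
  structure(list(atom_indices = sort(idx),
                 descriptor = paste(a$descriptor, "and", b$descriptor)),
            class = "cq_mask")
}

# ---- B-factor mapping --------------------------------------------------------

#' Write per-residue values into a PDB B-factor column
#'
#' Used to paint dRMSF (or any per-residue scalar) onto a structure for
#' visualization; every atom of a residue carries the residue's value rounded
#' to the PDB field's 2 decimals. Residues missing from the map are written
#' as 0.00.
#'
#' @param struct a `cq_structure`.
#' @param per_residue_values named numeric vector (names = residue indices) or
#'   data.frame with columns `residue`, `value`.
#' @param path output PDB path.
#' @return invisibly, the path.
#' @export
write_bfactor_map <- function(struct, per_residue_values, path) {
  stopifnot(inherits(struct, "cq_structure"))
  if (is.data.frame(per_residue_values)) {
    vals <- setNames(per_residue_values$value,
                     as.character(per_residue_values$residue))
  } else vals <- per_residue_values
  if (is.null(names(vals))) stop("per-residue values must be named by residue")
  v <- vals[as.character(struct$atom$residue_index)]
  v[is.na(v)] <- 0
  if (any(v >= 1000 | v <= -100))
    stop("B-factor value out of PDB field width (must fit %6.2f)")
  out <- struct
  out$atom$bfactor <- round(as.numeric(v), 2)
  write_structure(out, path)
}

#' Extract the per-residue B-factor map from a Structure
#' @param struct a `cq_structure`.
#' @return named numeric vector, one value per residue (first atom's value).
#' @export
read_bfactor_map <- function(struct) {
  first <- !duplicated(paste(struct$atom$chain_id, struct$atom$residue_index))
  setNames(struct$atom$bfactor[first],
           as.character(struct$atom$residue_index[first]))
}
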