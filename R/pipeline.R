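# End-to-end orchestration: generate paired ensembles -> superpose -> RMSF /
# dRMSF / regions -> Q series and summaries -> packing plan, with a manifest
# that makes every output table recomputable from recorded parameters alone.

#' @importFrom utils modifyList
NULL

.config_schema <- function() {
  # key = list(default, parse, check, message)
  num <- function(x) suppressWarnings(as.numeric(x))
  int <- function(x) suppressWarnings(as.integer(x))
  list(
    temperatures_c   = list(d = c(25, 50, 65, 80),
                            p = function(x) num(strsplit(x, ",")[[1]]),
                            c = function(v) length(v) >= 1 && !anyNA(v) &&
                              !anyDuplicated(v),
                            m = "comma-separated unique temperatures in C"),
    n_residues       = list(d = 64L, p = int,
                            c = function(v) !is.na(v) && v >= 4,
                            m = "integer >= 4"),
    fold             = list(d = "hairpin", p = identity,
                            c = function(v) v %in% c("helix", "hairpin",
                                                     "compact"),
                            m = "helix|hairpin|compact"),
    n_frames         = list(d = 1000L, p = int,
                            c = function(v) !is.na(v) && v >= 2,
                            m = "integer >= 2"),
    base_sigma       = list(d = 1.0, p = num,
                            c = function(v) !is.na(v) && v > 0, m = "> 0"),
    t_ref_c          = list(d = 25, p = num,
                            c = function(v) !is.na(v) && v > -273.15,
                            m = "temperature in C"),
    suppression      = list(d = 0.6, p = num,
                            c = function(v) !is.na(v) && v > 0 && v <= 1,
                            m = "in (0, 1]"),
    confinement_radius = list(d = 45, p = num,
                            c = function(v) !is.na(v) && v > 0, m = "> 0"),
    n_crowders       = list(d = 0L, p = int,
                            c = function(v) !is.na(v) && v >= 0, m = ">= 0"),
    crowder_radius   = list(d = 10, p = num,
                            c = function(v) !is.na(v) && v > 0, m = "> 0"),
    regions_solution = list(d = "40:48:3", p = identity,
                            c = function(v) is.character(v), m = "a:b:amp;..."),
    regions_confined = list(d = "20:24:5", p = identity,
                            c = function(v) is.character(v), m = "a:b:amp;..."),
    delta_threshold  = list(d = 2.0, p = num,
                            c = function(v) !is.na(v) && v > 0, m = "> 0"),
    min_region_length = list(d = 2L, p = int,
                            c = function(v) !is.na(v) && v >= 1, m = ">= 1"),
    beta             = list(d = 5, p = num,
                            c = function(v) !is.na(v) && v > 0, m = "> 0"),
    lambda           = list(d = 1.8, p = num,
                            c = function(v) !is.na(v) && v > 0, m = "> 0"),
    contact_cutoff   = list(d = 4.5, p = num,
                            c = function(v) !is.na(v) && v > 0, m = "> 0"),
    min_separation   = list(d = 3L, p = int,
                            c = function(v) !is.na(v) && v >= 0, m = ">= 0"),
    contact_mode     = list(d = "alpha-carbon", p = identity,
                            c = function(v) v %in% c("alpha-carbon",
                                                     "heavy-atom"),
                            m = "alpha-carbon|heavy-atom"),
    n_replicas       = list(d = 3L, p = int,
                            c = function(v) !is.na(v) && v >= 1, m = ">= 1"),
    phi              = list(d = 0.2, p = num,
                            c = function(v) !is.na(v) && v >= 0 && v < 0.74,
                            m = "in [0, 0.74)"),
    shell_radius     = list(d = 90, p = num,
                            c = function(v) !is.na(v) && v > 0, m = "> 0"),
    cargo_radius     = list(d = 25.2, p = num,
                            c = function(v) !is.na(v) && v > 0, m = "> 0"),
    clash_min_distance = list(d = 2.0, p = num,
                            c = function(v) !is.na(v) && v > 0, m = "> 0"),
    stride           = list(d = 1L, p = int,
                            c = function(v) !is.na(v) && v >= 1, m = ">= 1"),
    discard_fraction = list(d = 0, p = num,
                            c = function(v) !is.na(v) && v >= 0 && v < 1,
                            m = "in [0, 1)"),
    seed             = list(d = 1L, p = int,
                            c = function(v) !is.na(v), m = "integer")
  )
}

.parse_regions <- function(txt) {
  if (!nzchar(trimws(txt))) return(NULL)
  parts <- strsplit(trimws(txt), ";")[[1]]
  out <- NULL
  for (p in parts) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(p), ":")[[1]]))
    if (length(f) != 3 || anyNA(f))
      stop("bad region spec '", p, "': expected start:end:amplification")
    out <- rbind(out, data.frame(start = as.integer(f[1]),
                                 end = as.integer(f[2]), amp = f[3]))
  }
  out
}

#' Validate a run configuration
#'
#' Reads a flat `key = value` configuration file (lines starting with `#` and
#' blank lines ignored), applies documented defaults for absent keys (each
#' applied default is reported via `message`), and collects all problems —
#' unknown keys, out-of-range values — into a single error. With `path =
#' NULL`, returns the all-defaults configuration. Temperatures are accepted in
#' Celsius (`temperatures_c`, `t_ref_c`) and stored in Kelvin.
#'
#' @param path configuration file, or NULL for defaults.
#' @param quiet suppress default-application messages.
#' @return An object of class `cq_config` (named list).
#' @export
validate_config <- function(path = NULL, quiet = FALSE) {
  schema <- .config_schema()
  supplied <- list()
  errors <- character()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: '", path, "'")
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE)) {
        errors <- c(errors, paste0("line not of form key = value: '", ln, "'"))
        next
      }
      key <- trimws(sub("=.*", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% names(schema)) {
        errors <- c(errors, paste0("unknown key '", key, "'"))
        next
      }
      parsed <- tryCatch(schema[[key]]$p(val), error = function(e) NA)
      if (length(parsed) == 0 ||
          (!is.character(parsed) && all(is.na(parsed))) ||
          !isTRUE(schema[[key]]$c(parsed))) {
        errors <- c(errors, paste0("key '", key, "' = '", val,
                                   "' invalid (expected ", schema[[key]]$m,
                                   ")"))
        next
      }
      supplied[[key]] <- parsed
    }
  }
  cfg <- lapply(schema, `[[`, "d")
  defaults_applied <- setdiff(names(schema), names(supplied))
  cfg[names(supplied)] <- supplied
  for (rk in c("regions_solution", "regions_confined")) {
    cfg[[paste0(rk, "_parsed")]] <-
      tryCatch(.parse_regions(cfg[[rk]]),
               error = function(e) {
                 errors <<- c(errors, conditionMessage(e)); NULL
               })
  }
  if (!is.null(cfg$regions_solution_parsed) &&
      any(cfg$regions_solution_parsed$end > cfg$n_residues))
    errors <- c(errors, "regions_solution extends past n_residues")
  if (!is.null(cfg$regions_confined_parsed) &&
      any(cfg$regions_confined_parsed$end > cfg$n_residues))
    errors <- c(errors, "regions_confined extends past n_residues")
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  cfg$temperatures <- cfg$temperatures_c + 273.15
  cfg$t_ref <- cfg$t_ref_c + 273.15
  if (!quiet && length(defaults_applied))
    message("defaults applied for: ", paste(defaults_applied, collapse = ", "))
  structure(cfg, class = "cq_config")
}

#' Thin a trajectory by a frame stride
#' @param trajectory a `cq_trajectory`.
#' @param stride keep every `stride`-th frame (from the first).
#' @return A `cq_trajectory`.
#' @export
thin_trajectory <- function(trajectory, stride) {
  if (stride <= 1) return(trajectory)
  keep <- seq(1, n_frames(trajectory), by = stride)
  out <- trajectory
  out$coords <- trajectory$coords[, , keep, drop = FALSE]
  if (!is.null(out$frame_times)) out$frame_times <- out$frame_times[keep]
  out
}

.log_line <- function(con, msg) {
  writeLines(msg, con)
  message(msg)
}

#' Run the full confinement-analysis pipeline on synthetic ensembles
#'
#' Stages: packing design (copy number at the configured volume fraction,
#' seeded clash-free placement, clash screening with exclusion) -> paired
#' ensemble generation per condition and temperature (free solution: replicas;
#' confined: one ensemble per non-excluded cargo copy) -> superposition and
#' per-residue RMSF with replica/copy averaging -> dRMSF and thresholded
#' region detection -> native-contact Q series and summaries. Re-running with
#' the same configuration produces byte-identical tables.
#'
#' @param config a `cq_config` from [validate_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a report bundle: list with `config`, `plan`, `profiles`,
#'   `deltas`, `regions` (per temperature), `q_summary`, and `files` (all
#'   written paths).
#' @export
run_pipeline <- function(config = validate_config(quiet = TRUE), out_dir) {
  stopifnot(inherits(config, "cq_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  con <- file(logf, "w"); on.exit(close(con))
  files <- character()
  stage <- function(name, expr) {
    .log_line(con, paste0("[stage] ", name))
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  # -- packing design
  plan <- stage("packing", {
    n <- copy_number(config$phi, config$shell_radius, config$cargo_radius)
    pl <- place_copies(n, config$shell_radius, config$cargo_radius,
                       seed = .derive_seed(config$seed, 9, 0))
    apply_exclusions(pl, clash_screen(pl))
  })
  included <- setdiff(seq_len(plan$n_copies), plan$excluded$copy)
  f <- file.path(out_dir, "packing_plan.tsv")
  export_plan_tsv(plan, f); files <- c(files, f)

  # -- native structure and contact set
  struct <- stage("native structure",
                  build_toy_protein(config$n_residues, config$fold,
                                    config$seed))
  cpar <- contact_params(beta = config$beta, lambda = config$lambda,
                         cutoff = config$contact_cutoff,
                         min_separation = config$min_separation,
                         mode = config$contact_mode)
  contacts <- stage("reference contacts", reference_contacts(struct, cpar))
  f <- file.path(out_dir, "contacts.tsv")
  export_contacts_tsv(contacts, f); files <- c(files, f)

  spec_of <- function(condition, temperature, seed) {
    ensemble_spec(
      n_residues = config$n_residues, fold = config$fold,
      temperature = temperature, n_frames = config$n_frames,
      base_sigma = config$base_sigma,
      flexible_regions = if (condition == "solution")
        config$regions_solution_parsed else config$regions_confined_parsed,
      confinement = if (condition == "confined")
        list(radius = config$confinement_radius,
             n_crowders = config$n_crowders,
             crowder_radius = config$crowder_radius,
             suppression = config$suppression) else NULL,
      seed = seed, t_ref = config$t_ref)
  }

  ca <- select_atoms(struct, "alpha-carbon")
  profiles <- list(); deltas <- list(); regions <- list()
  all_series <- list()
  manifest_rows <- NULL
  for (ti in seq_along(config$temperatures)) {
    TK <- config$temperatures[ti]
    tc <- config$temperatures_c[ti]
    per_cond <- list()
    for (cond in c("solution", "confined")) {
      reps <- if (cond == "solution") seq_len(config$n_replicas) else included
      if (!length(reps)) stop("no confined copies left after exclusion")
      rep_profiles <- list(); cond_series <- list()
      for (k in seq_along(reps)) {
        sd <- .derive_seed(config$seed, if (cond == "solution") 1 else 2,
                           ti, reps[k])
        trj <- stage(sprintf("generate %s T=%gC rep %d", cond, tc, reps[k]),
                     sample_gaussian_trajectory(struct,
                                                spec_of(cond, TK, sd)))
        trj <- thin_trajectory(trj, config$stride)
        altrj <- stage("superpose", superpose(trj, ca, "iterative-mean"))
        rep_profiles[[k]] <- rmsf(altrj, ca,
                                  discard_fraction = config$discard_fraction)
        cond_series[[k]] <- q_series(trj, contacts)
        manifest_rows <- rbind(manifest_rows, data.frame(
          condition = cond, temperature_c = tc, replica = reps[k], seed = sd,
          n_frames = config$n_frames, stringsAsFactors = FALSE))
      }
      per_cond[[cond]] <- average_replicas(rep_profiles)
      all_series <- c(all_series, cond_series)
      f <- file.path(out_dir, sprintf("q_series_%s_%gC.tsv", cond, tc))
      export_contacts_tsv(do.call(rbind, lapply(seq_along(cond_series),
        function(i) cbind(replica = reps[i],
                          as.data.frame(cond_series[[i]])))), f)
      files <- c(files, f)
    }
    key <- sprintf("%gC", tc)
    profiles[[key]] <- per_cond
    deltas[[key]] <- delta_rmsf(per_cond$solution, per_cond$confined)
    regions[[key]] <- detect_regions(deltas[[key]],
                                     threshold = config$delta_threshold,
                                     min_length = config$min_region_length)
    f <- file.path(out_dir, sprintf("rmsf_delta_%s.tsv", key))
    export_profiles_tsv(list(solution = per_cond$solution,
                             confined = per_cond$confined),
                        delta = deltas[[key]], regions = regions[[key]],
                        path = f)
    files <- c(files, f)
    f <- file.path(out_dir, sprintf("regions_%s.tsv", key))
    write.table(within(regions[[key]],
                       peak_value <- sprintf("%.6f", peak_value)),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, sprintf("delta_bfactor_%s.pdb", key))
    stage("b-factor map",
          write_bfactor_map(struct,
                            data.frame(residue = deltas[[key]]$residue,
                                       value = deltas[[key]]$delta), f))
    files <- c(files, f)
  }

  qsum <- stage("q summary", q_summary(all_series))
  qsum$temperature_c <- qsum$temperature - 273.15
  f <- file.path(out_dir, "q_summary.tsv")
  export_contacts_tsv(qsum, f); files <- c(files, f)

  manifest <- list(config = unclass(config)[!vapply(unclass(config), is.data.frame, TRUE)],
                   packing = list(n_copies = plan$n_copies,
                                  excluded = plan$excluded$copy,
                                  phi_target = plan$phi_target,
                                  phi_after_exclusion =
                                    plan$phi_after_exclusion,
                                  seed = plan$seed),
                   ensembles = manifest_rows,
                   n_contacts = contacts$n,
                   files = basename(files))
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  .log_line(con, "[stage] done")

  invisible(list(config = config, plan = plan, profiles = profiles,
                 deltas = deltas, regions = regions, q_summary = qsum,
                 files = files))
}
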