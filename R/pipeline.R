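# End-to-end pipeline: synthesize (or read) an ensemble, reduce it to
# representatives, map every representative, and profile residues across the
# ensemble, with reproducible seeding and a consolidated report.

#' Pipeline configuration
#'
#' Bundles the stage configurations with a single global seed. Stage seeds
#' are derived as fixed offsets of the global seed so one knob reproduces the
#' whole run.
#'
#' @param synthetic a [synthetic_spec()] (used when no input ensemble is
#'   given); its seed is overridden by `seed`.
#' @param reduction list with `cutoff` (Angstrom, default 1.5) and `top_k`
#'   (default 15) and optional `selection` (selection expression for the
#'   superposition atoms; default the ensemble's own alignment selection).
#' @param mapping a [mapping_config()].
#' @param profiling a [profiling_config()].
#' @param seed integer global seed.
#' @return object of class `ensmap_pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_spec(),
                            reduction = list(cutoff = 1.5, top_k = 15L,
                                             selection = NULL),
                            mapping = mapping_config(),
                            profiling = profiling_config(),
                            seed = 1L) {
  if (is.null(reduction$cutoff)) reduction$cutoff <- 1.5
  if (is.null(reduction$top_k)) reduction$top_k <- 15L
  stopifnot(reduction$cutoff > 0, reduction$top_k >= 1)
  red <- list(cutoff = as.numeric(reduction$cutoff),
              top_k = as.integer(reduction$top_k))
  if (!is.null(reduction$selection)) red$selection <- reduction$selection
  reduction <- red
  synthetic$seed <- as.integer(seed)
  mapping$seed <- as.integer(seed + 1000L)
  structure(list(synthetic = synthetic, reduction = reduction,
                 mapping = mapping, profiling = profiling,
                 seed = as.integer(seed)),
            class = "ensmap_pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' YAML round-trip: `write_pipeline_config()` then `read_pipeline_config()`
#' restores an equal configuration (hash-stable, see [config_hash()]).
#'
#' @param config an `ensmap_pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_config` returns the restored config;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- list(
    synthetic = unclass(config$synthetic),
    reduction = config$reduction[!vapply(config$reduction, is.null, logical(1))],
    mapping = unclass(config$mapping),
    profiling = unclass(config$profiling),
    seed = config$seed
  )
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    synthetic = do.call(synthetic_spec, y$synthetic),
    reduction = y$reduction,
    mapping = do.call(mapping_config, y$mapping),
    profiling = do.call(profiling_config, y$profiling),
    seed = y$seed
  )
  cfg
}

#' Stable hash of a pipeline configuration
#' @param config an `ensmap_pipeline_config`.
#' @return md5 hex string of the canonical JSON serialization.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(list(synthetic = unclass(config$synthetic),
                            reduction = config$reduction,
                            mapping = unclass(config$mapping),
                            profiling = unclass(config$profiling),
                            seed = config$seed),
                       tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Number of saved frames in a trajectory
#'
#' @param total_duration_ns total simulation time in nanoseconds.
#' @param interval_ps frame-saving interval in picoseconds.
#' @return integer frame count `total/interval`; a non-integer ratio is
#'   floored with a warning.
#' @export
frame_count <- function(total_duration_ns, interval_ps) {
  if (total_duration_ns <= 0 || interval_ps <= 0) {
    stop("duration and interval must be positive")
  }
  ratio <- total_duration_ns * 1000 / interval_ps
  n <- floor(ratio + 1e-9)
  if (abs(ratio - round(ratio)) > 1e-9) {
    warning("duration is not an integer multiple of the interval; flooring")
  }
  as.integer(n)
}

#' Run the full ensemble-mapping pipeline
#'
#' Stages: (1) generate the synthetic ensemble (or read `input_pdb`),
#' (2) reduce to representative structures, (3) map every representative,
#' (4) profile residues across the mapped ensemble. When `out_dir` is given,
#' stage outputs are written there: `ensemble.pdb`, `ligand.pdb`,
#' `ground_truth.json`, `representatives.pdb`, `reduction.tsv`,
#' `mapping_rep<i>.pdb`, `cs_rep<i>.tsv`, `residue_table.tsv`, `sites.tsv`
#' and `run.json` (provenance: config echo, hash, seed).
#'
#' @param config an `ensmap_pipeline_config`.
#' @param input_pdb optional multi-model PDB path replacing the synthetic
#'   stage; requires `ligand_pdb` for orthosteric classification.
#' @param ligand_pdb optional ligand PDB path.
#' @param out_dir optional output directory (created if needed).
#' @param verbose print stage progress.
#' @return run report (class `ensmap_run_report`): list with `reduction`
#'   report, `mappings`, `profiles`, `top`, `sites`, `truth` (synthetic runs
#'   only), `config`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), input_pdb = NULL,
                         ligand_pdb = NULL, out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  truth <- NULL
  ligand <- NULL
  if (is.null(input_pdb)) {
    say("stage synth: generating ensemble (seed %d)", config$seed)
    gen <- generate_ensemble(config$synthetic)
    ens <- gen$ensemble
    truth <- gen$truth
    ligand <- gen$ligand
    if (!is.null(out_dir)) {
      write_pdb_models(ens, file.path(out_dir, "ensemble.pdb"))
      write_pdb_models(gen$ligand, file.path(out_dir, "ligand.pdb"))
      jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                           auto_unbox = FALSE, digits = NA)
    }
  } else {
    say("stage input: reading %s", input_pdb)
    ens <- read_pdb_models(input_pdb)
    if (!is.null(ligand_pdb)) {
      ligand <- read_pdb_models(ligand_pdb)$models[[1]]
    }
  }
  if (!is.null(config$reduction$selection)) {
    ens$alignment_selection <- select_atoms(ens$models[[1]],
                                            config$reduction$selection)
  }

  say("stage reduce: clustering %d models at %.2f A", n_models(ens),
      config$reduction$cutoff)
  if (n_models(ens) < config$reduction$top_k) {
    warning(sprintf("ensemble has %d models < top_k = %d; using all clusters",
                    n_models(ens), config$reduction$top_k))
  }
  red <- reduce_ensemble(ens, cutoff = config$reduction$cutoff,
                         k = config$reduction$top_k)
  reps <- red$representatives
  if (!is.null(out_dir)) {
    write_pdb_models(reps, file.path(out_dir, "representatives.pdb"))
    write.table(red$report$clusters, file.path(out_dir, "reduction.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  mappings <- vector("list", n_models(reps))
  probes <- default_probe_library()
  for (i in seq_len(n_models(reps))) {
    say("stage map: representative %d / %d", i, n_models(reps))
    mappings[[i]] <- map_structure(reps$models[[i]], config$mapping, probes)
    if (!is.null(out_dir)) {
      write_pdb_with_probes(reps$models[[i]], mappings[[i]]$sites,
                            file.path(out_dir, sprintf("mapping_rep%d.pdb", i)),
                            probes)
      write.table(consensus_site_table(mappings[[i]]),
                  file.path(out_dir, sprintf("cs_rep%d.tsv", i)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  say("stage profile: aggregating %d structures", length(mappings))
  if (is.null(input_pdb)) {
    # synthetic runs classify and group against the generator's base
    # structure (the analogue of an experimental reference), rigidly moved
    # into the representatives' frame together with its ligand
    base <- generate_receptor(config$synthetic)$structure
    fit <- kabsch_superpose(coords(base), coords(reps$models[[1]]),
                            ens$alignment_selection)
    reference <- set_coords(base, fit$coords)
    if (!is.null(ligand)) {
      ligand <- set_coords(ligand, sweep(coords(ligand) %*% t(fit$rotation), 2,
                                         fit$translation, "+"))
    }
  } else {
    # external runs fall back to the first representative
    reference <- reps$models[[1]]
  }
  prof <- profile_ensemble(reps$models, mappings, reference, ligand,
                           config$profiling, probes)
  report <- structure(list(
    reduction = red$report,
    representatives = reps,
    mappings = mappings,
    profiles = prof$profiles,
    top = prof$top,
    sites = prof$sites,
    truth = truth,
    ligand = ligand,
    config = config,
    config_hash = config_hash(config)
  ), class = "ensmap_run_report")
  if (!is.null(out_dir)) {
    write_residue_table(report, file.path(out_dir, "residue_table.tsv"))
    write_site_table(report, file.path(out_dir, "sites.tsv"))
    jsonlite::write_json(list(seed = config$seed,
                              config_hash = report$config_hash,
                              n_models = n_models(ens),
                              n_representatives = n_models(reps),
                              occupancy = red$report$occupancy),
                         file.path(out_dir, "run.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  report
}

#' @export
print.ensmap_run_report <- function(x, ...) {
  cat(sprintf("<ensmap run> %d representatives (occupancy %.1f%%), %d top residues, %d site groups\n",
              nrow(x$reduction$clusters), x$reduction$occupancy,
              nrow(x$top), length(x$sites)))
  invisible(x)
}

#' Write the ranked residue table of a run
#'
#' Machine-readable per-residue table: rank, residue key, raw contact count,
#' percentage of all ensemble contacts, orthosteric flag and site id (NA for
#' orthosteric or ungrouped residues).
#'
#' @param report an `ensmap_run_report`.
#' @param path output TSV path.
#' @return invisibly, the written data.frame.
#' @export
write_residue_table <- function(report, path) {
  top <- report$top
  site_of <- rep(NA_integer_, nrow(top))
  for (s in report$sites) {
    site_of[top$key %in% s$residues] <- s$site_id
  }
  out <- data.frame(rank = top$rank, residue = top$key,
                    raw_count = top$raw_count,
                    percentage = sprintf("%.4f", top$percentage),
                    orthosteric = top$orthosteric, site_id = site_of,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write the site-group summary of a run
#' @param report an `ensmap_run_report`.
#' @param path output TSV path.
#' @return invisibly, the written data.frame.
#' @export
write_site_table <- function(report, path) {
  out <- if (length(report$sites)) {
    do.call(rbind, lapply(report$sites, function(s) {
      data.frame(site_id = s$site_id, percentage = sprintf("%.4f", s$percentage),
                 n_residues = length(s$residues),
                 residues = paste(s$residues, collapse = ","),
                 n_poses = length(s$pose_idx), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(site_id = integer(0), percentage = character(0),
               n_residues = integer(0), residues = character(0),
               n_poses = integer(0))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
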