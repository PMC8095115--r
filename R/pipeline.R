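#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML (or already-parsed list) describing the
#' analysis conditions and thresholds. Fields:
#' \describe{
#'   \item{conditions}{list of named conditions, each with `ensemble` (path
#'     to a multi-model PDB), `ligand` (path to a ligand YAML) and
#'     optionally `reference_map` (OpenDX path).}
#'   \item{selectivity_pairs}{list of two-element condition-name vectors to
#'     compare.}
#'   \item{thresholds}{optional overrides: `cutoff` (5.0 A),
#'     `selectivity_threshold` (0.5), `water_cutoff` (6.0 A), `d_bridge`
#'     (3.5 A), `resolution` (0.5 A), `atom_size` (1.0 A).}
#'   \item{bridge_residue}{optional residue_seq for the water-bridge and
#'     water-occupancy stages.}
#'   \item{density_stride}{frame stride for the density stage (default 10).}
#'   \item{outdir}{output directory.}
#'   \item{seed}{integer seed echoed into the summary (the analyses
#'     themselves are deterministic).}
#' }
#' All referenced files must exist at validation time.
#'
#' @param config a YAML file path or a list with the fields above.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$conditions) || length(cfg$conditions) == 0)
    stop("pipeline config: no conditions")
  if (is.null(names(cfg$conditions)) || any(names(cfg$conditions) == ""))
    stop("pipeline config: conditions must be named")
  for (nm in names(cfg$conditions)) {
    cond <- cfg$conditions[[nm]]
    for (field in c("ensemble", "ligand")) {
      if (is.null(cond[[field]]))
        stop(sprintf("pipeline config: condition '%s' lacks '%s'", nm, field))
      if (!file.exists(cond[[field]]))
        stop(sprintf("pipeline config: condition '%s': file not found: %s",
                     nm, cond[[field]]))
    }
    if (!is.null(cond$reference_map) && !file.exists(cond$reference_map))
      stop(sprintf("pipeline config: condition '%s': file not found: %s",
                   nm, cond$reference_map))
  }
  th_default <- list(cutoff = 5.0, selectivity_threshold = 0.5,
                     water_cutoff = 6.0, d_bridge = 3.5, resolution = 0.5,
                     atom_size = 1.0)
  th <- utils::modifyList(th_default, as.list(cfg$thresholds))
  pairs <- lapply(cfg$selectivity_pairs, function(p) {
    p <- unlist(p)
    if (length(p) != 2 || !all(p %in% names(cfg$conditions)))
      stop("pipeline config: selectivity pair must name two conditions")
    p
  })
  structure(list(conditions = cfg$conditions, selectivity_pairs = pairs,
                 thresholds = th,
                 bridge_residue = cfg$bridge_residue,
                 density_stride = if (is.null(cfg$density_stride)) 10L
                                  else as.integer(cfg$density_stride),
                 outdir = if (is.null(cfg$outdir)) "pipeline_out" else cfg$outdir,
                 seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
                 ligand_rules = cfg$ligand_rules),
            class = "pipeline_config")
}

#' Run the full binding-site analysis pipeline
#'
#' Executes, per condition: contact profiling, ligand RMSD versus the
#' initial configuration, an atomic density map of the ligand, and (when a
#' reference map is configured) map correlation; per selectivity pair:
#' selectivity classification, shared-contact extraction and
#' minimum-distance series of the qualifying residues; and, when a bridge
#' residue is configured, water-bridge occupancy and the water occupancy
#' map. Every stage's outputs, thresholds and wall time are recorded in
#' `summary.txt`. Outputs are a pure function of the configuration and the
#' input files; any stage error aborts the run naming the stage.
#'
#' @param config a [pipeline_config()], YAML path or list.
#' @return invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  th <- cfg$thresholds
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("pipeline run, seed %d", cfg$seed),
                 "thresholds:",
                 sprintf("  %s = %.6g", names(th), unlist(th)),
                 sprintf("  density_stride = %d", cfg$density_stride))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %-28s %8.2f s", name,
                                       proc.time()[["elapsed"]] - t0))
    out
  }
  rules <- if (is.null(cfg$ligand_rules)) NULL else
    classify_rules(ligand_residues = unlist(cfg$ligand_rules))
  results <- list()

  loaded <- list()
  for (nm in names(cfg$conditions)) {
    cond <- cfg$conditions[[nm]]
    loaded[[nm]] <- stage(paste0("load:", nm), {
      lig <- read_ligand_spec(cond$ligand)
      r <- if (is.null(rules))
        classify_rules(ligand_residues = unique(c(paste0("LG", substr(lig$label, 1, 1)))))
      else rules
      list(ens = read_structure_ensemble(cond$ensemble, rules = r), lig = lig)
    })
  }

  profiles <- list()
  for (nm in names(loaded)) {
    profiles[[nm]] <- stage(paste0("contacts:", nm), {
      prof <- contact_frequencies(loaded[[nm]]$ens, loaded[[nm]]$lig,
                                  cutoff = th$cutoff)
      write_contact_profile(prof, file.path(cfg$outdir, paste0("contacts_", nm, ".tsv")))
      prof
    })
  }
  results$profiles <- profiles

  for (nm in names(loaded)) {
    results$rmsd[[nm]] <- stage(paste0("rmsd:", nm), {
      rs <- rmsd_series(loaded[[nm]]$ens, loaded[[nm]]$lig)
      write_series_tsv(rs$values, file.path(cfg$outdir, paste0("rmsd_", nm, ".tsv")))
      write_series_tsv(rs$values, file.path(cfg$outdir, paste0("rmsd_", nm, ".xvg")),
                       format = "xvg", ylab = "RMSD (A)")
      rs
    })
  }

  for (pair in cfg$selectivity_pairs) {
    key <- paste(pair, collapse = "_vs_")
    results$selectivity[[key]] <- stage(paste0("selectivity:", key), {
      selrep <- classify_selectivity(profiles[[pair[1]]], profiles[[pair[2]]],
                                     threshold = th$selectivity_threshold)
      write_selectivity_report(selrep, file.path(cfg$outdir,
                                                 paste0("selectivity_", key, ".tsv")))
      selrep
    })
    results$mindist[[key]] <- stage(paste0("mindist:", key), {
      selrep <- results$selectivity[[key]]
      resids <- selrep$residues$residue_seq[selrep$residues$class != "neither"]
      lead <- loaded[[pair[1]]]
      ser <- min_distance_series(lead$ens, resids, lead$lig)
      msr <- mean_separation_report(ser, margin = 4)
      write.table(format(msr, digits = 6), file.path(cfg$outdir,
                                                     paste0("mean_separation_", key, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      for (r in names(ser$series))
        write_series_tsv(ser$series[[r]]$d,
                         file.path(cfg$outdir, sprintf("mindist_%s_res%s.tsv", key, r)))
      list(series = ser, report = msr)
    })
  }

  for (nm in names(loaded)) {
    results$density[[nm]] <- stage(paste0("density:", nm), {
      frames <- seq(1, n_frames(loaded[[nm]]$ens), by = cfg$density_stride)
      dm <- atomic_density_map(loaded[[nm]]$ens, loaded[[nm]]$lig,
                               resolution = th$resolution,
                               atom_size = th$atom_size, frames = frames)
      write_density_map(dm, file.path(cfg$outdir, paste0("density_", nm, ".dx")))
      dm
    })
    ref_path <- cfg$conditions[[nm]]$reference_map
    if (!is.null(ref_path)) {
      results$map_correlation[[nm]] <- stage(paste0("overlap:", nm), {
        cmp <- map_correlation(results$density[[nm]], read_density_map(ref_path))
        cmp
      })
    }
  }
  if (length(results$map_correlation) > 0) {
    mc <- results$map_correlation
    writeLines(c("condition\tcorrelation\tn_voxels",
                 sprintf("%s\t%.6f\t%d", names(mc),
                         vapply(mc, `[[`, numeric(1), "correlation"),
                         vapply(mc, `[[`, integer(1), "n_voxels_compared"))),
               file.path(cfg$outdir, "map_correlation.tsv"))
  }

  if (!is.null(cfg$bridge_residue)) {
    for (nm in names(loaded)) {
      results$bridge[[nm]] <- stage(paste0("waterbridge:", nm), {
        br <- water_bridge_frequency(loaded[[nm]]$ens, cfg$bridge_residue,
                                     loaded[[nm]]$lig, d_bridge = th$d_bridge)
        br
      })
      results$water_map[[nm]] <- stage(paste0("wateroccupancy:", nm), {
        wm <- water_occupancy_map(loaded[[nm]]$ens, cfg$bridge_residue,
                                  loaded[[nm]]$lig, cutoff = th$water_cutoff,
                                  resolution = th$resolution,
                                  atom_size = th$atom_size)
        write_density_map(wm, file.path(cfg$outdir, paste0("water_occupancy_", nm, ".dx")))
        wm
      })
    }
    br <- results$bridge
    writeLines(c("condition\tresidue\tligand\td_bridge\tbridge_frequency",
                 sprintf("%s\t%s%d\t%s\t%.2f\t%.6f", names(br),
                         vapply(br, `[[`, character(1), "residue_name"),
                         vapply(br, `[[`, numeric(1), "residue_seq"),
                         vapply(br, `[[`, character(1), "ligand_label"),
                         vapply(br, `[[`, numeric(1), "d_bridge"),
                         vapply(br, `[[`, numeric(1), "bridge_frequency"))),
               file.path(cfg$outdir, "water_bridge.tsv"))
  }

  writeLines(log_lines, file.path(cfg$outdir, "summary.txt"))
  results$outdir <- cfg$outdir
  invisible(results)
}
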