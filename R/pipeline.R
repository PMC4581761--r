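#' @include AllClasses.R AllGenerics.R energetics.R saltbridges.R
#' @include fluctuation.R sasa.R synthetic-data.R
NULL

#' Validate a pipeline run configuration
#'
#' Structural validation of the YAML-derived configuration list:
#' required fields, positive thresholds, and a baseline system present
#' among the systems. Runs before any compute so misconfiguration
#' aborts early.
#'
#' @param config Configuration list (see [runPipeline()]).
#' @return The config, invisibly, with defaults filled in.
#' @export
validateRunConfig <- function(config) {
  req <- c("baseline", "systems")
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop("config validation: missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  labels <- vapply(config$systems, `[[`, character(1), "label")
  if (!config$baseline %in% labels)
    stop("config validation: baseline '", config$baseline,
         "' is not among the systems (", paste(labels, collapse = ", "),
         ")", call. = FALSE)
  defaults <- list(
    thresholds = list(shift_A = 1.5, rmsf_diff_A = 0.5,
                      bridge_cutoff_A = 3.5, sasa_diff_A2 = 40,
                      contact_A = 4.5),
    window = list(skip_fraction = 0.125, stride = 1L),
    energy = list(gb_model = "HCT", snapshot_interval_ps = 1000,
                  sasa_points = 960L),
    frame_spacing_ps = 100, seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (sub in names(defaults[[nm]]))
        if (is.null(config[[nm]][[sub]]))
          config[[nm]][[sub]] <- defaults[[nm]][[sub]]
  }
  th <- unlist(config$thresholds)
  if (any(th <= 0))
    stop("config validation: thresholds must be positive", call. = FALSE)
  for (s in config$systems)
    for (f in c("structure", "trajectory", "parameters"))
      if (!file.exists(s[[f]]))
        stop("config validation: missing ", f, " file for system '",
             s$label, "': ", s[[f]], call. = FALSE)
  invisible(config)
}

.log_line <- function(logfile, stage, msg, t0 = NULL) {
  elapsed <- if (is.null(t0)) "" else
    sprintf(" [%.2fs]", as.numeric(proc.time()["elapsed"]) - t0)
  line <- sprintf("[%s] %s: %s%s", format(Sys.time(), "%H:%M:%S"),
                  stage, msg, elapsed)
  message(line)
  cat(line, "\n", file = logfile, append = TRUE)
}

.fmt3 <- function(x) formatC(x, digits = 3L, format = "f")

#' Run the full glycoform-comparison pipeline
#'
#' From one configuration (YAML path or list), for each system: RMSD
#' series, per-residue shift classification, RMSF profile with
#' flexibility bands, salt-bridge statistics, trajectory-averaged SASA
#' and an MM-GBSA summary; then cross-system difference reports (RMSF
#' and SASA deltas, energy comparison) against the named baseline
#' system, a human-readable summary, a log and a reproducibility
#' manifest (config hash + per-output checksums). Re-running an
#' unchanged config reproduces identical checksums.
#'
#' Config fields: `baseline` (label), `systems` (list of `label`,
#' `structure`, `trajectory`, `parameters`, `chain_roles`),
#' `thresholds` (`shift_A`, `rmsf_diff_A`, `bridge_cutoff_A`,
#' `sasa_diff_A2`, `contact_A`), `window` (`skip_fraction`, `stride`),
#' `energy` (`gb_model`, `snapshot_interval_ps`, `sasa_points`),
#' `frame_spacing_ps`, `seed`, `outdir`.
#'
#' @param config YAML file path or configuration list.
#' @param outdir Output directory (overrides `config$outdir`).
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validateRunConfig(config)
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("no output directory given", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  cat("", file = logfile)
  th <- config$thresholds
  outputs <- character(0)
  profiles_rmsf <- list()
  profiles_sasa <- list()
  summaries <- list()
  stage_times <- list()
  econf <- energyModelConfig(gbModel = config$energy$gb_model)
  for (s in config$systems) {
    t0 <- as.numeric(proc.time()["elapsed"])
    lab <- s$label
    stage <- paste0("system:", lab)
    res <- tryCatch({
      roles <- unlist(s$chain_roles)
      model <- readPDB(s$structure, chainRoles = roles)
      traj <- readTrajectory(s$trajectory, model,
                             config$frame_spacing_ps)
      ff <- readForceField(s$parameters, model)
      lig_chains <- names(roles)[startsWith(roles, "ligand")]
      rec_chains <- names(roles)[roles == "receptor"]
      sel_bb_lig <- makeSelection(model, paste0(
        "backbone and chain ", paste(lig_chains, collapse = ",")))
      sel_ca_lig <- makeSelection(model, paste0(
        "calpha and chain ", paste(lig_chains, collapse = ",")))
      sel_rec <- makeSelection(model, paste0(
        "heavy and chain ", paste(rec_chains, collapse = ",")))
      nfr <- nFrames(traj)
      window <- seq(floor(config$window$skip_fraction * nfr) + 1L, nfr,
                    by = config$window$stride)

      rmsd <- rmsdSeries(traj, sel_bb_lig, reference = NULL)
      utils::write.csv(as.data.frame(rmsd),
                       fp <- file.path(outdir, paste0(lab, "_rmsd.csv")),
                       row.names = FALSE)
      outputs <- c(outputs, fp)

      shifts <- classifyResidueShifts(traj, NULL, sel_bb_lig, sel_rec,
                                      shiftThreshold = th$shift_A,
                                      contactCutoff = th$contact_A)
      utils::write.csv(shifts,
                       fp <- file.path(outdir, paste0(lab, "_shifts.csv")),
                       row.names = FALSE)
      outputs <- c(outputs, fp)

      rp <- rmsfProfile(traj, sel_ca_lig, window = window, label = lab)
      profiles_rmsf[[lab]] <- rp
      bands <- flexibilityBands(rp)
      utils::write.csv(bands,
                       fp <- file.path(outdir, paste0(lab, "_rmsf.csv")),
                       row.names = FALSE)
      outputs <- c(outputs, fp)

      bridges <- findSaltBridges(model)
      stride <- defaultBridgeStride(traj)
      btab <- do.call(rbind, lapply(seq_len(nrow(bridges)), function(b) {
        ser <- bridgeDistanceSeries(traj, bridges[b, ], stride = stride)
        st <- bridgeStatistics(ser, cutoff = th$bridge_cutoff_A)
        cbind(bridges[b, c("cation_chain", "cation_resseq",
                           "cation_resname", "anion_chain",
                           "anion_resseq", "anion_resname")], st)
      }))
      if (is.null(btab))
        btab <- data.frame(note = "no interface salt bridges detected")
      utils::write.csv(btab,
                       fp <- file.path(outdir, paste0(lab, "_bridges.csv")),
                       row.names = FALSE)
      outputs <- c(outputs, fp)

      sp <- sasaTrajectory(traj,
                           skipFraction = config$window$skip_fraction,
                           stride = max(1L, nfr %/% 20L),
                           nPoints = config$energy$sasa_points,
                           label = lab)
      profiles_sasa[[lab]] <- sp
      utils::write.csv(as.data.frame(sp),
                       fp <- file.path(outdir, paste0(lab, "_sasa.csv")),
                       row.names = FALSE)
      outputs <- c(outputs, fp)

      es <- mmgbsaSummary(traj, ff, econf,
                          snapshotIntervalPs =
                            config$energy$snapshot_interval_ps,
                          mode = "absolute", label = lab,
                          nPoints = config$energy$sasa_points)
      summaries[[lab]] <- es
      etab <- data.frame(component = c("INT", "ELE", "VDW", "GBSOL",
                                       "GBTOT"),
                         mean = es@means[c("internal", "electrostatic",
                                           "vdw", "gbsol", "gbtot")],
                         sd = es@sds[c("internal", "electrostatic",
                                       "vdw", "gbsol", "gbtot")])
      utils::write.csv(etab,
                       fp <- file.path(outdir, paste0(lab, "_energy.csv")),
                       row.names = FALSE)
      outputs <- c(outputs, fp)
      TRUE
    }, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage_times[[stage]] <-
      as.numeric(proc.time()["elapsed"]) - t0
    .log_line(logfile, stage, "done", t0)
  }

  base <- config$baseline
  t0 <- as.numeric(proc.time()["elapsed"])
  for (lab in setdiff(names(profiles_rmsf), base)) {
    rd <- rmsfDifference(profiles_rmsf[[lab]], profiles_rmsf[[base]],
                         threshold = th$rmsf_diff_A)
    utils::write.csv(rd, fp <- file.path(
      outdir, paste0(lab, "_vs_", base, "_rmsf_diff.csv")),
      row.names = FALSE)
    outputs <- c(outputs, fp)
    sd_ <- sasaDifference(profiles_sasa[[lab]], profiles_sasa[[base]],
                          cutoff = th$sasa_diff_A2)
    utils::write.csv(sd_, fp <- file.path(
      outdir, paste0(lab, "_vs_", base, "_sasa_diff.csv")),
      row.names = FALSE)
    outputs <- c(outputs, fp)
  }
  cmp <- compareEnergies(summaries)
  utils::write.csv(cmp, fp <- file.path(outdir, "energy_comparison.csv"),
                   row.names = FALSE)
  outputs <- c(outputs, fp)
  stage_times[["differences"]] <-
    as.numeric(proc.time()["elapsed"]) - t0
  .log_line(logfile, "differences", "done", t0)

  summary_path <- file.path(outdir, "summary.txt")
  con <- file(summary_path, "w")
  cat("Glycoform comparison summary\n============================\n",
      file = con)
  for (lab in names(profiles_rmsf))
    cat(sprintf("%s: mean RMSF %s A; total SASA %s A^2\n", lab,
                .fmt3(meanRmsf(profiles_rmsf[[lab]])),
                .fmt3(totalSasa(profiles_sasa[[lab]]))), file = con)
  cat("\nEnergies (kcal/mol, mean (sd)):\n", file = con)
  for (lab in names(summaries)) {
    es <- summaries[[lab]]
    cat(sprintf("%s: GBTOT %.2f (%.2f)\n", lab, es@means[["gbtot"]],
                es@sds[["gbtot"]]), file = con)
  }
  close(con)
  outputs <- c(outputs, summary_path)

  cfg_norm <- jsonlite::toJSON(config, auto_unbox = TRUE)
  cfg_file <- tempfile()
  writeLines(cfg_norm, cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("gfdyn")),
    outputs = as.list(tools::md5sum(outputs)),
    stage_seconds = stage_times)
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .log_line(logfile, "pipeline", "complete")
  invisible(manifest)
}

#' Pairwise total-energy comparison
#'
#' Pairwise differences in mean GBTOT between systems, with the spread
#' propagated as the square root of the summed variances (the snapshot
#' sets are treated as independent).
#'
#' @param summaries A named list of [EnergySummary-class] objects, or an
#'   energy table `data.frame(component, system, mean, sd)` as read by
#'   [readEnergyTable()] (rows with `component == "GBTOT"` are used).
#' @param labels Optional subset/order of system labels.
#' @return `data.frame(system_a, system_b, delta_gbtot, sd,
#'   delta_rounded)`, one row per unordered pair, `delta = a - b`.
#' @export
compareEnergies <- function(summaries, labels = NULL) {
  if (is.data.frame(summaries)) {
    gb <- summaries[summaries$component == "GBTOT", , drop = FALSE]
    means <- stats::setNames(gb$mean, gb$system)
    sds <- stats::setNames(gb$sd, gb$system)
  } else {
    means <- vapply(summaries, function(s) s@means[["gbtot"]],
                    numeric(1))
    sds <- vapply(summaries, function(s) s@sds[["gbtot"]], numeric(1))
  }
  if (is.null(labels)) labels <- names(means)
  if (length(labels) < 2L) stop("need at least two systems",
                                call. = FALSE)
  pairs <- utils::combn(labels, 2L)
  out <- data.frame(
    system_a = pairs[1L, ], system_b = pairs[2L, ],
    delta_gbtot = means[pairs[1L, ]] - means[pairs[2L, ]],
    sd = sqrt(sds[pairs[1L, ]]^2 + sds[pairs[2L, ]]^2))
  out$delta_rounded <- round(out$delta_gbtot)
  rownames(out) <- NULL
  out
}

#' Read a long-format energy table
#'
#' @param path CSV with columns `component` (INT, ELE, VDW, GBSOL,
#'   GBTOT), `system`, `mean`, `sd`.
#' @return The table as a `data.frame`.
#' @export
readEnergyTable <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE)

#' Check the component ledger of an energy table
#'
#' For each system asserts `GBTOT = INT + ELE + VDW + GBSOL` within
#' `tol` (default 0.02 kcal/mol, absorbing printed rounding).
#'
#' @param table Long-format energy table (see [readEnergyTable()]).
#' @param tol Permitted absolute residual, kcal/mol.
#' @return `data.frame(system, residual, pass)`; attribute `"pass"` is
#'   TRUE when every system passes.
#' @export
validateEnergyTable <- function(table, tol = 0.02) {
  systems <- unique(table$system)
  res <- vapply(systems, function(s) {
    sub <- table[table$system == s, ]
    get <- function(cmp) sub$mean[sub$component == cmp]
    get("GBTOT") - (get("INT") + get("ELE") + get("VDW") + get("GBSOL"))
  }, numeric(1))
  out <- data.frame(system = systems, residual = res,
                    pass = abs(res) <= tol)
  attr(out, "pass") <- all(out$pass)
  if (!all(out$pass))
    warning("ledger violation in system(s): ",
            paste(systems[!out$pass], collapse = ", "),
            " (max residual ", signif(max(abs(res)), 3L), ")")
  out
}
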