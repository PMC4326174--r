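# Run configuration and pipeline assembly.  A run config is a single
# YAML file naming input paths, the named atom selections, the analysis
# thresholds and the cutoff scheme; commands consume it and write CSV
# results, a JSON summary and a JSON manifest (inputs, config hash,
# package version, seed) so a run can be reproduced byte for byte.

.default_thresholds <- list(stateRmsd = 4.0, zeroTol = 0.5,
                            persistence = 5L, minDwell = 5L)

.units_table <- c(time_ns = "ns", angle_deg = "deg",
                  rmsd = "Angstrom", extension_A = "Angstrom",
                  separation_A = "Angstrom", distance_A = "Angstrom",
                  vdw = "kcal/mol", elec = "kcal/mol",
                  total = "kcal/mol", force_pN = "pN")

.series_units <- function(tab) {
  nm <- names(tab)
  u <- vapply(nm, function(x) {
    if (x %in% names(.units_table)) return(.units_table[[x]])
    if (grepl("^rmsd_", x)) return("Angstrom")
    ""
  }, character(1))
  u[nzchar(u)]
}

#' Read and validate a run configuration
#'
#' Reads a YAML run config and validates it, reporting every schema
#' violation at once rather than failing on the first.  Required keys:
#' `trajectory` (path), `references` (named map label -> path),
#' `params` (path), `selections` (named map of selection expressions).
#' Optional keys with defaults: `timeStep` (0.1 ns), `thresholds`
#' (`stateRmsd` 4.0 A, `zeroTol` 0.5 kcal/mol, `persistence` 5,
#' `minDwell` 5), `cutoff` (`rOn` 10, `rOff` 12 A), `pulling`
#' (mode/force/velocity/spring), `forceLog` (path, cv runs).
#'
#' @param path YAML file path.
#' @return validated config list (paths resolved relative to the
#'   config file's directory).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || grepl("^/", p)) p else
    file.path(base, p)
  errs <- character(0)
  need <- function(key) {
    if (is.null(cfg[[key]]))
      errs <<- c(errs, sprintf("missing required key '%s'", key))
  }
  need("trajectory"); need("references"); need("params")
  need("selections")
  cfg$trajectory <- rel(cfg$trajectory)
  cfg$params <- rel(cfg$params)
  cfg$forceLog <- rel(cfg$forceLog)
  if (!is.null(cfg$references))
    cfg$references <- lapply(cfg$references, rel)
  for (key in c("trajectory", "params", "forceLog")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p))
      errs <- c(errs, sprintf("'%s' file does not exist: %s", key, p))
  }
  for (lab in names(cfg$references)) {
    if (!file.exists(cfg$references[[lab]]))
      errs <- c(errs, sprintf("reference '%s' file does not exist: %s",
                              lab, cfg$references[[lab]]))
  }
  thr <- utils::modifyList(.default_thresholds,
                           if (is.null(cfg$thresholds)) list()
                           else cfg$thresholds)
  for (k in names(thr)) {
    if (!is.numeric(thr[[k]]) || thr[[k]] <= 0)
      errs <- c(errs, sprintf("threshold '%s' must be positive", k))
  }
  cfg$thresholds <- thr
  cut <- utils::modifyList(list(rOn = 10, rOff = 12),
                           if (is.null(cfg$cutoff)) list()
                           else cfg$cutoff)
  if (!(cut$rOn > 0 && cut$rOff > cut$rOn))
    errs <- c(errs, "cutoff must satisfy 0 < rOn < rOff")
  cfg$cutoff <- cut
  if (is.null(cfg$timeStep)) cfg$timeStep <- 0.1
  if (length(errs))
    stop("invalid run config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  cfg$configPath <- normalizePath(path)
  cfg
}

.write_manifest <- function(outDir, command, cfg, seed, outputs) {
  inputs <- c(trajectory = cfg$trajectory, params = cfg$params,
              forceLog = cfg$forceLog, unlist(cfg$references))
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- list(
    command = command,
    package = "AllosTraj",
    version = as.character(utils::packageVersion("AllosTraj")),
    seed = seed,
    config = cfg$configPath,
    config_md5 = unname(tools::md5sum(cfg$configPath)),
    inputs = as.list(unname(tools::md5sum(unlist(inputs)))),
    input_paths = as.list(unlist(inputs)),
    units = list(length = "Angstrom", time = "ns", energy = "kcal/mol",
                 force = "pN", angle = "deg"),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest,
                       file.path(outDir, paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.load_run_inputs <- function(cfg) {
  refs_struct <- lapply(cfg$references, readStructure)
  topo <- refs_struct[[1L]]
  traj <- readTrajectory(cfg$trajectory, topo, timeStep = cfg$timeStep)
  sel <- cfg$selections
  refs <- lapply(names(refs_struct), function(lab) {
    ReferenceState(lab, refs_struct[[lab]],
                   alignSel = sel$lecRigid, loopSel = sel$loop)
  })
  names(refs) <- names(refs_struct)
  list(traj = traj, refs = refs, refs_struct = refs_struct, sel = sel)
}

.cmd_orient <- function(cfg, outDir) {
  inp <- .load_run_inputs(cfg)
  sel <- inp$sel
  outputs <- character(0)
  for (lab in names(inp$refs_struct)) {
    odef <- OrientationDefinition(sel$hingeLecEgf, sel$egfBody,
                                  sel$lecRigid, inp$refs_struct[[lab]])
    ser <- orientationSeries(inp$traj, odef)
    f <- file.path(outDir, sprintf("orient_egf_%s.csv", lab))
    writeSeries(ser, f, units = .series_units(ser))
    outputs <- c(outputs, f)
  }
  # CR1 orientation relative to the first reference, aligned on EGF
  odef_cr <- OrientationDefinition(sel$hingeEgfCr1, sel$cr1Body,
                                   sel$egfDomain, inp$refs_struct[[1L]])
  ser <- orientationSeries(inp$traj, odef_cr)
  f <- file.path(outDir, "orient_cr1.csv")
  writeSeries(ser, f, units = .series_units(ser))
  c(outputs, f)
}

.cmd_classify <- function(cfg, outDir) {
  inp <- .load_run_inputs(cfg)
  series <- loopRmsdSeries(inp$traj, inp$refs)
  calls <- classifyFrames(series[, grep("^rmsd_", names(series))],
                          threshold = cfg$thresholds$stateRmsd)
  tab <- cbind(series, call = calls$call)
  f1 <- file.path(outDir, "classify_frames.csv")
  writeSeries(tab, f1, units = .series_units(tab))
  stats <- stateStatistics(calls)
  trans <- transitionDetect(calls, minDwell = cfg$thresholds$minDwell)
  summary <- list(
    n_frames = nFrames(inp$traj),
    threshold_A = cfg$thresholds$stateRmsd,
    state_fractions = stats::setNames(as.list(stats$fraction),
                                      stats$state),
    transitions = trans)
  f2 <- file.path(outDir, "classify_summary.json")
  jsonlite::write_json(summary, f2, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  c(f1, f2)
}

.cmd_energy <- function(cfg, outDir) {
  inp <- .load_run_inputs(cfg)
  params <- readNonbondParams(cfg$params)
  scheme <- CutoffScheme(cfg$cutoff$rOn, cfg$cutoff$rOff)
  prof <- groupEnergySeries(inp$traj, inp$sel$receptor, inp$sel$ligand,
                            params, scheme)
  tab <- as.data.frame(prof)
  f1 <- file.path(outDir, "energy_receptor_ligand.csv")
  writeSeries(tab, f1, units = .series_units(tab))
  doms <- list(lec = inp$sel$lecDomain, egf = inp$sel$egfDomain,
               cr1 = inp$sel$cr1Body, cr2 = inp$sel$cr2Body)
  doms <- doms[!vapply(doms, is.null, logical(1))]
  f2 <- NULL
  if (length(doms) >= 2L) {
    hinge <- hingeEnergyTable(list(inp$traj), doms, params, scheme)
    f2 <- file.path(outDir, "energy_hinges.csv")
    writeSeries(hinge, f2,
                units = c(mean_kcal = "kcal/mol", sd_kcal = "kcal/mol"))
  }
  c(f1, f2)
}

.cmd_unbind <- function(cfg, outDir) {
  inp <- .load_run_inputs(cfg)
  sel <- inp$sel
  params <- readNonbondParams(cfg$params)
  scheme <- CutoffScheme(cfg$cutoff$rOn, cfg$cutoff$rOff)
  pull <- cfg$pulling
  setup <- PullingSetup(sel$fixedEnd, sel$pulled,
                        mode = if (is.null(pull$mode)) "cv" else pull$mode)
  ext <- extensionSeries(inp$traj, setup)
  axis <- forceAxis(setup, inp$traj)
  sep <- separationSeries(inp$traj, sel$lecDomain, sel$ligand, axis)
  mark <- if (!is.null(sel$markerFuc) && !is.null(sel$markerCal))
    markerDistanceSeries(inp$traj, sel$markerFuc, sel$markerCal)$distance_A
  else rep(NA_real_, nFrames(inp$traj))
  prof <- groupEnergySeries(inp$traj, sel$receptor, sel$ligand, params,
                            scheme)
  tab <- data.frame(time_ns = inp$traj@times,
                    extension_A = ext$extension_A,
                    separation_A = sep$separation_A,
                    marker_A = mark,
                    vdw = prof@vdw, elec = prof@elec, total = prof@total)
  f1 <- file.path(outDir, "unbind_series.csv")
  writeSeries(tab, f1, units = .series_units(tab))
  ev <- unbindingSummary(prof, ext, sep,
                         zeroTol = cfg$thresholds$zeroTol,
                         persistence = cfg$thresholds$persistence)
  summary <- list(event = if (is.null(ev)) NULL else ev)
  if (!is.null(cfg$forceLog)) {
    fl <- readSeries(cfg$forceLog)
    feat <- forceProfileFeatures(fl$force_pN, ext$extension_A)
    summary$peak <- as.list(feat)
  }
  f2 <- file.path(outDir, "unbind_summary.json")
  jsonlite::write_json(summary, f2, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  c(f1, f2)
}

.cmd_synth <- function(outDir, seed, mode = "equilibration") {
  toy <- buildToy(seed = seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  refs_paths <- list()
  for (lab in names(toy$references)) {
    p <- file.path(outDir, sprintf("ref_%s.pdb", lab))
    writeStructure(toy$references[[lab]]@structure, p)
    refs_paths[[lab]] <- basename(p)
  }
  ppath <- file.path(outDir, "params.csv")
  writeNonbondParams(toy$params, ppath)
  spec <- syntheticSpec(mode, seed = seed)
  if (mode == "equilibration") {
    run <- generateEquilibration(toy, spec)
    forceRel <- NULL
  } else {
    run <- generateDissociation(toy, spec)
    forceRel <- "force.csv"
    writeSeries(run$forceLog, file.path(outDir, forceRel),
                units = c(time_ns = "ns", force_pN = "pN"))
  }
  tpath <- file.path(outDir, "trajectory.pdb")
  writeTrajectory(run$trajectory, tpath)
  writeGroundTruth(run$truth, file.path(outDir, "ground_truth.json"))
  sel <- as.list(toy$selections)
  cfg <- list(trajectory = "trajectory.pdb",
              references = refs_paths,
              params = "params.csv",
              forceLog = forceRel,
              timeStep = spec$timeStep,
              selections = sel,
              thresholds = .default_thresholds,
              cutoff = list(rOn = 10, rOff = 12),
              pulling = list(mode = if (mode == "cv") "cv" else "cf",
                             forcePN = spec$forcePN,
                             velocityAps = 0.01,
                             springPNperA = spec$springPNperA))
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  cpath <- file.path(outDir, "run_config.yaml")
  yaml::write_yaml(cfg, cpath)
  c(tpath, ppath, cpath)
}

.cmd_report <- function(summaryPaths, outDir) {
  vals <- list()
  for (p in summaryPaths) {
    j <- jsonlite::read_json(p, simplifyVector = TRUE)
    flat <- unlist(j)
    num <- suppressWarnings(as.numeric(flat))
    names(num) <- names(flat)
    keep <- !is.na(num)
    for (k in names(flat)[keep]) vals[[k]] <- c(vals[[k]], num[[k]])
  }
  rows <- lapply(names(vals), function(k) {
    st <- replicateStatistics(vals[[k]])
    data.frame(quantity = k, n = st[["n"]], mean = st[["mean"]],
               sd = st[["sd"]])
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(quantity = character(0), n = integer(0),
               mean = numeric(0), sd = numeric(0))
  f <- file.path(outDir, "report.csv")
  writeSeries(tab, f)
  f
}

#' Run one pipeline command
#'
#' Dispatches the named pipeline stage against a run configuration and
#' writes its artifacts plus a JSON manifest into `outDir`.  Commands:
#' `"synth"` (generate a synthetic run and a ready-to-use config),
#' `"orient"` (EGF orientation per reference + CR1 orientation),
#' `"classify"` (loop RMSD series, state calls, fractions,
#' transitions), `"energy"` (receptor-ligand profile and hinge table),
#' `"unbind"` (extension/separation/marker/energy series and event
#' summary), `"report"` (merge JSON summaries into a mean +/- SD
#' table).  Outputs are deterministic for deterministic inputs.
#'
#' @param config path to a YAML run config, or a validated config list
#'   (not used by `synth`/`report`).
#' @param command one of `synth`, `orient`, `classify`, `energy`,
#'   `unbind`, `report`.
#' @param outDir output directory, created if needed.
#' @param seed integer seed (used by `synth`).
#' @param mode synthetic mode for `synth`: `"equilibration"`, `"cf"`
#'   or `"cv"`.
#' @param summaryPaths character vector of JSON summary paths
#'   (`report` only).
#' @return character vector of written artifact paths, invisibly.
#' @export
runPipeline <- function(config = NULL,
                        command = c("orient", "classify", "energy",
                                    "unbind", "synth", "report"),
                        outDir = ".", seed = 1L,
                        mode = "equilibration", summaryPaths = NULL) {
  command <- match.arg(command)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (command == "synth") {
    out <- .cmd_synth(outDir, seed, mode)
    return(invisible(out))
  }
  if (command == "report") {
    if (is.null(summaryPaths)) stop("report requires summaryPaths")
    return(invisible(.cmd_report(summaryPaths, outDir)))
  }
  cfg <- if (is.character(config)) readRunConfig(config) else config
  if (is.null(cfg)) stop(command, " requires a run config")
  out <- switch(command,
                orient = .cmd_orient(cfg, outDir),
                classify = .cmd_classify(cfg, outDir),
                energy = .cmd_energy(cfg, outDir),
                unbind = .cmd_unbind(cfg, outDir))
  .write_manifest(outDir, command, cfg, seed, basename(out))
  invisible(out)
}
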