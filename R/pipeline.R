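#' Read and validate a pipeline run configuration
#'
#' Configurations are nested key-value YAML.  Either a `synthetic` block
#' (replicated encounter generation with planted truth) or an `inputs` list
#' (structure + trajectory paths per replicate) provides the trajectories;
#' `stages` selects which analyses run.  Referenced paths are checked at
#' validation time, before any compute.
#'
#' @param config path to a YAML file, or an equivalent named list
#' @return validated config list (class `run_config`)
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$stages <- unlist(cfg$stages %||% c("distances", "contacts", "landscape"))
  known <- c("distances", "contacts", "landscape", "dimer", "rmsf")
  bad <- setdiff(cfg$stages, known)
  if (length(bad))
    stop("run config: unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$synthetic) && is.null(cfg$inputs))
    stop("run config: need a 'synthetic' block or an 'inputs' list")
  for (inp in cfg$inputs) {
    if (!file.exists(inp$structure))
      stop("run config: missing structure file: ", inp$structure)
    if (!is.null(inp$trajectory) && !file.exists(inp$trajectory))
      stop("run config: missing trajectory file: ", inp$trajectory)
  }
  cfg$output <- cfg$output %||% "membind_out"
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order (load, distances + fits,
#' contacts, reference + landscape, dimer, RMSF), writes CSV/JSON outputs
#' under the configured output directory, and returns the result bundle.
#' Stage parameters and timings are logged to stderr.  If a stage fails the
#' bundle is marked partial, downstream stages that depend on it are
#' skipped, and the error is recorded.
#'
#' @param config path to YAML or config list, see [read_run_config()]
#' @return list (class `report_bundle`) with per-stage results and a
#'   `provenance` block (config, seed, package version)
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$output, recursive = TRUE, showWarnings = FALSE)
  bundle <- list(provenance = list(
    config = unclass(cfg), seed = cfg$seed,
    package_version = as.character(utils::packageVersion("membind")),
    timestamp = NA), partial = FALSE, errors = list())

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message("[membind] stage ", name, " ...")
    out <- tryCatch(expr, error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(out, "error")) {
      message("[membind] stage ", name, " FAILED: ", conditionMessage(out))
      bundle$partial <<- TRUE
      bundle$errors[[name]] <<- conditionMessage(out)
      return(NULL)
    }
    message(sprintf("[membind] stage %s done (%.1f s)", name, dt))
    out
  }

  trajs <- stage("load", load_stage(cfg))
  if (is.null(trajs)) {
    class(bundle) <- "report_bundle"
    return(bundle)
  }
  bundle$truths <- attr(trajs, "truths")

  if ("distances" %in% cfg$stages) {
    bundle$distances <- stage("distances", distances_stage(cfg, trajs))
  }
  if ("contacts" %in% cfg$stages) {
    bundle$contacts <- stage("contacts", contacts_stage(cfg, trajs))
  }
  if ("landscape" %in% cfg$stages) {
    bundle$landscape <- stage("landscape", landscape_stage(cfg, trajs))
  }
  if ("dimer" %in% cfg$stages) {
    bundle$dimer <- stage("dimer", dimer_stage(cfg, trajs))
  }
  if ("rmsf" %in% cfg$stages) {
    bundle$rmsf <- stage("rmsf", rmsf_stage(cfg, trajs))
  }
  jsonlite::write_json(bundle$provenance,
                       file.path(cfg$output, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(bundle) <- "report_bundle"
  bundle
}

load_stage <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    s <- cfg$synthetic
    bspec <- do.call(bilayer_spec, s$bilayer %||% list())
    bil <- build_bilayer(bspec, seed = cfg$seed)
    pargs <- s$protein %||% list()
    pargs$seed <- cfg$seed
    prot <- do.call(build_protein_model, pargs)
    eargs <- s$params %||% list()
    eargs$seed <- cfg$seed
    params <- do.call(encounter_params, eargs)
    runs <- simulate_ensemble(prot, bil, params,
                              n_replicates = s$n_replicates %||% 3)
    trajs <- lapply(runs, `[[`, "trajectory")
    attr(trajs, "truths") <- lapply(runs, `[[`, "truth")
    return(trajs)
  }
  trajs <- lapply(cfg$inputs, function(inp) {
    st <- load_structure(inp$structure,
                         mass_model = cfg$mass_model %||% "cg")
    if (is.null(inp$trajectory))
      trajectory(st$topology, st$frame$time, st$frame$coords, st$frame$box)
    else load_trajectory(inp$trajectory, st$topology,
                         dt = cfg$dt %||% 0.5)
  })
  trajs
}

distances_stage <- function(cfg, trajs) {
  d <- cfg$distances %||% list()
  series <- lapply(trajs, com_distance_series,
                   protein_sel = d$protein %||% "protein",
                   membrane_sel = d$membrane %||% "lipid",
                   metric = d$metric %||% "z_component")
  mean_series <- ensemble_mean(series)
  fit <- fit_binding_curve(mean_series)
  for (i in seq_along(series))
    write_series_csv(series[[i]],
                     file.path(cfg$output, sprintf("distance_rep%02d.csv", i)))
  write_series_csv(mean_series, file.path(cfg$output, "distance_mean.csv"))
  jsonlite::write_json(unclass(fit), file.path(cfg$output, "binding_fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(series = series, mean = mean_series, fit = fit)
}

contacts_stage <- function(cfg, trajs) {
  cc <- cfg$contacts %||% list()
  profs <- lapply(trajs, residue_contact_profile,
                  lipid_target_sel = cc$target %||% "species PI4P and headgroup",
                  cutoff = cc$cutoff %||% 0.7,
                  mode = cc$mode %||% "min_particle")
  # pooled profile: sum raw counts across replicates, renormalise
  pooled <- profs[[1]]
  if (length(profs) > 1) {
    for (p in profs[-1]) pooled$raw <- pooled$raw + p$raw
    pooled <- normalize_profile(pooled)
  }
  write_contact_profile(pooled, file.path(cfg$output, "contact_profile.csv"))
  list(replicates = profs, pooled = pooled)
}

landscape_stage <- function(cfg, trajs) {
  ls <- cfg$landscape %||% list()
  ref <- pick_reference(trajs,
                        site_residues = unlist(ls$site_residues %||% 180:184),
                        lipid_target_sel = ls$target %||%
                          "species PI4P and headgroup",
                        cutoff = ls$cutoff %||% 0.7)
  dists <- lapply(trajs, com_distance_series, metric = "z_component")
  ors <- lapply(trajs, orientation_series, reference = ref)
  map <- distance_orientation_map(dists, ors,
                                  n_bins_d = ls$n_bins_d %||% 50,
                                  n_bins_r = ls$n_bins_r %||% 50)
  modes <- find_modes(map, k = ls$k %||% 2)
  write_density_map(map, file.path(cfg$output, "density_map.csv"))
  jsonlite::write_json(modes, file.path(cfg$output, "modes.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(ls$png)) {
    grDevices::png(file.path(cfg$output, "density_map.png"), 640, 480)
    plot_density_map(map)
    grDevices::dev.off()
  }
  list(reference = ref, map = map, modes = modes)
}

dimer_stage <- function(cfg, trajs) {
  dm <- cfg$dimer %||% list()
  res <- lapply(trajs, function(traj) {
    ang <- hinge_angle_series(traj,
                              dm$armA %||% "subunit A and resid 182",
                              dm$vertex %||% "subunit A and resid 29",
                              dm$armB %||% "subunit B and resid 182")
    dA <- subunit_distance_series(traj, dm$siteA %||%
                                    "subunit A and resid 182")
    dB <- subunit_distance_series(traj, dm$siteB %||%
                                    "subunit B and resid 182")
    list(angle = ang, distance_A = dA, distance_B = dB)
  })
  ang <- res[[1]]$angle
  utils::write.csv(data.frame(time_ns = ang$times, theta_deg = ang$theta,
                              dist_A_nm = res[[1]]$distance_A$values,
                              dist_B_nm = res[[1]]$distance_B$values),
                   file.path(cfg$output, "dimer_series.csv"),
                   row.names = FALSE)
  res
}

rmsf_stage <- function(cfg, trajs) {
  rs <- cfg$rmsf %||% list()
  out <- lapply(trajs, rmsf, selection = rs$selection %||% "protein")
  utils::write.csv(out[[1]], file.path(cfg$output, "rmsf.csv"),
                   row.names = FALSE)
  out
}

write_series_csv <- function(series, path) {
  utils::write.csv(data.frame(time_ns = series$times,
                              value_nm = series$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Command-line dispatcher
#'
#' Thin argv-level wrapper over the package functions, used by the
#' `inst/scripts/membind` Rscript.  Subcommands: `synth` (generate a system,
#' trajectory and truth record), `run` (full pipeline from a config), and
#' `bind` / `contacts` / `landscape` / `dimer` / `rmsf` (single-stage runs of
#' the same config).  Returns the process exit code rather than quitting, so
#' it is testable.
#'
#' @param argv character vector of command-line arguments
#' @return integer exit code (0 ok, 1 runtime failure, 2 usage error)
#' @export
membind_cli <- function(argv = character()) {
  usage <- paste(
    "usage: membind <subcommand> [options]",
    "  synth     --out DIR [--seed N] [--n-frames N] [--preset monomer]",
    "  run       --config FILE [--seed N]",
    "  bind|contacts|landscape|dimer|rmsf  --config FILE [--seed N]",
    sep = "\n")
  if (!length(argv)) { message(usage); return(2L) }
  cmd <- argv[1]
  opts <- tryCatch(parse_cli_flags(argv[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts), "\n", usage)
    return(2L)
  }
  run_cfg_stage <- function(stages) {
    if (is.null(opts$config)) { message("--config required\n", usage); return(2L) }
    cfg <- read_run_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (!is.null(stages)) cfg$stages <- stages
    bundle <- run_pipeline(cfg)
    if (bundle$partial) 1L else 0L
  }
  switch(cmd,
    synth = {
      out <- opts$out %||% "."
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      seed <- as.integer(opts$seed %||% 1L)
      bil <- build_bilayer(bilayer_spec(), seed = seed)
      prot <- build_protein_model(seed = seed)
      params <- encounter_params(
        n_frames = as.integer(opts[["n-frames"]] %||% 400L), seed = seed)
      run <- simulate_encounter(prot, bil, params)
      write_gro(run$trajectory$topology, get_frame(run$trajectory, 1),
                file.path(out, "system.gro"))
      write_gro_trajectory(run$trajectory, file.path(out, "trajectory.gro"))
      write_truth(run$truth, file.path(out, "truth.json"))
      message("[membind] wrote system.gro, trajectory.gro, truth.json to ", out)
      0L
    },
    run = run_cfg_stage(NULL),
    bind = run_cfg_stage("distances"),
    contacts = run_cfg_stage("contacts"),
    landscape = run_cfg_stage("landscape"),
    dimer = run_cfg_stage("dimer"),
    rmsf = run_cfg_stage("rmsf"),
    { message("unknown subcommand: ", cmd, "\n", usage); 2L })
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unknown argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("flag --", key, " needs a value")
    opts[[key]] <- args[i + 1]
    i <- i + 2L
  }
  known <- c("config", "seed", "out", "n-frames", "preset", "json")
  bad <- setdiff(names(opts), known)
  if (length(bad)) stop("unknown flag: --", bad[1])
  opts
}
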