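#' Default stage parameters
#'
#' The defaults every run configuration starts from: 6 A adsorption
#' criterion, 4.5 A side-chain contact cutoff, interaction-strength
#' cutoff 3, correlation filter 0.3, surface tension 0.0072 kcal/mol/A^2,
#' dielectrics 1/80, 0.5 A grid over a 150 A box, 1.4 A probe. All are
#' echoed to the run manifest.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    dt = 1,
    cutoff = 6.0,
    distance_cutoff = 4.5,
    Imin = 3.0,
    occupancy_min = 0.5,
    corr_min = 0.3,
    gamma = 0.0072,
    eps_in = 1,
    eps_out = 80,
    probe_radius = 1.4,
    n_points = 960,
    grid_spacing = 0.5,
    grid_box = 150,
    bin_width = 1.0,
    stride = 1L,
    fraction = 1/3,
    seed = 1L
  )
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys override \code{\link{default_config}}.
#' @return named list (class \code{run_config}).
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  structure(cfg, class = c("run_config", "list"))
}

config_error <- function(...) {
  stop(structure(class = c("usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stage_names <- c("simulate", "adsorption", "rmsd", "dccm", "psn-path",
                 "energy", "pocket", "hydration", "screen-stats")

load_stage_trajectory <- function(config) {
  if (is.null(config$input))
    config_error("config key 'input' (PDB path) is required for this stage")
  if (!file.exists(config$input))
    stop("input not found: ", config$input)
  traj <- read_pdb(config$input, dt = config$dt)
  if (!is.null(config$parameters)) {
    pt <- read_parameter_table(config$parameters)
    traj$system <- apply_parameters(traj$system, pt)
  }
  traj
}

write_manifest <- function(out_dir, stage, config, inputs = character(0)) {
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  input_hashes <- if (length(inputs) > 0)
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  manifest <- list(
    package = "cntmd",
    version = as.character(utils::packageVersion("cntmd")),
    stage = stage,
    config = config,
    config_md5 = unname(tools::md5sum(cfg_file)),
    input_md5 = input_hashes,
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run one analysis stage
#'
#' Thin staged front-end over the package's analysis functions. Every
#' stage writes plain-text outputs plus a \code{manifest.json} recording
#' the package version, full configuration, config hash, input hashes
#' and seed into the output directory.
#'
#' Stages: \code{simulate} (run a named generator and write its data and
#' truth), \code{adsorption}, \code{rmsd}, \code{dccm}, \code{psn-path},
#' \code{energy}, \code{pocket}, \code{hydration}, \code{screen-stats}.
#'
#' @param stage stage name.
#' @param config a \code{run_config} list (or path to a YAML file).
#' @param out_dir output directory (created if missing; default
#'   \code{config$output_dir} or "."). No stage writes outside it.
#' @return invisible list of written file paths.
#' @export
run_stage <- function(stage, config, out_dir = NULL) {
  if (!stage %in% stage_names)
    config_error("unknown stage '", stage, "'; expected one of: ",
                 paste(stage_names, collapse = ", "))
  if (is.character(config) && length(config) == 1) config <- read_run_config(config)
  config <- utils::modifyList(default_config(), config)
  out_dir <- out_dir %||% config$output_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pathto <- function(f) file.path(out_dir, f)
  written <- character(0)
  inputs <- c(config$input, config$parameters, config$odor_table)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]

  if (stage == "simulate") {
    kind <- config$generator %||% config_error("simulate: config key 'generator' required")
    seed <- config$seed
    if (kind == "correlated_traj") {
      n_res <- config$n_residues %||% 10
      half <- max(1L, floor(n_res / 2))
      g <- gen_correlated_trajectory(
        n_residues = n_res,
        correlation = config$correlation %||%
          list(kind = "blocks", blocks = list(c(1, half), c(half + 1, n_res)),
               rho = 0.6),
        amplitude = config$amplitude %||% 0.3,
        n_frames = config$n_frames %||% 1000, seed = seed)
      write_pdb(g$trajectory, pathto("trajectory.pdb"))
      write_truth(g$truth, pathto("truth.yaml"))
      written <- c(pathto("trajectory.pdb"), pathto("truth.yaml"))
    } else if (kind == "adsorption_traj") {
      sched <- as.data.frame(config$schedule %||% data.frame(
        from = c(1, 11, 21), to = c(10, 20, 30), separation = c(12, 5, 1)))
      g <- gen_adsorption_trajectory(sched, jitter = config$jitter %||% 0,
                                     cutoff = config$cutoff, seed = seed)
      write_pdb(g$trajectory, pathto("trajectory.pdb"))
      write_truth(g$truth, pathto("truth.yaml"))
      written <- c(pathto("trajectory.pdb"), pathto("truth.yaml"))
    } else if (kind == "water_box") {
      prof <- as.data.frame(config$axial_profile %||% data.frame(
        z_min = c(0, 10, 20), z_max = c(10, 20, 30), weight = c(1, 0.2, 1)))
      g <- gen_water_box(config$n_waters %||% 200, prof,
                         box = config$box %||% c(30, 30, 30),
                         n_frames = config$n_frames %||% 10, seed = seed)
      write_xyz_trajectory(g$trajectory, pathto("waters.xyz"))
      write_truth(g$truth, pathto("truth.yaml"))
      written <- c(pathto("waters.xyz"), pathto("truth.yaml"))
    } else if (kind == "toy_complex") {
      g <- gen_toy_complex(seed = seed)
      tr <- trajectory(g$system, array(g$coords, dim = c(nrow(g$coords), 3, 1)))
      write_pdb(tr, pathto("complex.pdb"))
      write_parameter_table(data.frame(
        atom_name = g$system$atoms$name, residue_name = "*",
        radius = g$system$atoms$radius, charge = g$system$atoms$charge,
        epsilon = g$system$atoms$epsilon, sigma = g$system$atoms$sigma),
        pathto("parameters.tsv"))
      write_truth(g$truth, pathto("truth.yaml"))
      written <- pathto(c("complex.pdb", "parameters.tsv", "truth.yaml"))
    } else if (kind == "odor_table") {
      g <- gen_odor_table(n = config[["n"]] %||% 132,
                          score_model = config$score_model %||% "turnover",
                          noise_sd = config$noise_sd %||% 0.5, seed = seed)
      utils::write.table(g$records, pathto("odors.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_truth(g$truth, pathto("truth.yaml"))
      written <- pathto(c("odors.tsv", "truth.yaml"))
    } else config_error("simulate: unknown generator '", kind, "'")
  }

  if (stage == "adsorption") {
    traj <- load_stage_trajectory(config)
    rec <- select_atoms(traj$system, config$rec_selection %||% "group:receptor and heavy")
    tube <- select_atoms(traj$system, config$tube_selection %||% "group:tube")
    ser <- adsorption_series(traj, rec, tube, cutoff = config$cutoff,
                             stride = config$stride,
                             with_contact_area = !isFALSE(config$contact_area),
                             probe_radius = config$probe_radius,
                             n_points = config$n_points)
    utils::write.table(ser, pathto("adsorption.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- pathto("adsorption.tsv")
  }

  if (stage == "rmsd") {
    traj <- load_stage_trajectory(config)
    fit <- select_atoms(traj$system, config$fit_selection %||% "backbone")
    mea <- select_atoms(traj$system, config$measure_selection %||%
                          config$fit_selection %||% "backbone")
    ref <- frame_coords(traj, config$reference_frame %||% 1)
    ser <- rmsd_series(traj, ref, fit, mea)
    utils::write.table(ser, pathto("rmsd.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- pathto("rmsd.tsv")
  }

  if (stage == "dccm") {
    traj <- load_stage_trajectory(config)
    ca <- select_atoms(traj$system, config$ca_selection %||% "name:CA")
    M <- dccm(traj, ca)
    write_dccm(M, pathto("dccm.tsv"))
    written <- pathto("dccm.tsv")
  }

  if (stage == "psn-path") {
    traj <- load_stage_trajectory(config)
    fm <- psn_frames(traj, distance_cutoff = config$distance_cutoff)
    net <- build_network(fm, Imin = config$Imin,
                         occupancy_min = config$occupancy_min)
    write_network(net, pathto("network.tsv"))
    written <- pathto("network.tsv")
    if (!is.null(config$sources) && !is.null(config$sinks)) {
      ca <- select_atoms(traj$system, config$ca_selection %||% "name:CA")
      M <- dccm(traj, ca)
      pw <- shortest_paths(net, M, as.integer(config$sources),
                           as.integer(config$sinks),
                           corr_min = config$corr_min)
      pw <- score_path_frequencies(pw, fm, Imin = config$Imin)
      write_pathways(pw, pathto("pathways.tsv"))
      written <- c(written, pathto("pathways.tsv"))
    }
  }

  if (stage == "energy") {
    traj <- load_stage_trajectory(config)
    rec <- select_atoms(traj$system, config$rec_selection %||% "group:receptor")
    lig <- select_atoms(traj$system, config$lig_selection %||%
                          "group:ligand or group:tube")
    be <- binding_energy(traj, rec, lig, gamma = config$gamma,
                         polar_model = config$polar_model %||% "born",
                         eps_in = config$eps_in, eps_out = config$eps_out,
                         probe_radius = config$probe_radius,
                         n_points = config$n_points)
    comp <- data.frame(
      component = c("ele", "vdw", "gas", "npsolv", "psolv", "solv", "binding"),
      value = c(be$ele, be$vdw, be$gas, be$npsolv, be$psolv, be$solv, be$binding),
      se = unname(be$se[c("ele", "vdw", "gas", "npsolv", "psolv", "solv", "binding")]))
    utils::write.table(comp, pathto("energy_components.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- pathto("energy_components.tsv")
  }

  if (stage == "pocket") {
    traj <- load_stage_trajectory(config)
    if (is.null(config$pocket_resids))
      config_error("pocket: config key 'pocket_resids' required")
    pk <- pocket_definition(unlist(config$pocket_resids),
                            spacing = config$grid_spacing,
                            probe_radius = config$probe_radius)
    vol <- pocket_volume(frame_coords(traj, config$frame %||% 1),
                         traj$system, pk)
    utils::write.table(
      data.frame(frame = config$frame %||% 1, volume = as.numeric(vol)),
      pathto("pocket_volume.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    written <- pathto("pocket_volume.tsv")
  }

  if (stage == "hydration") {
    traj <- load_stage_trajectory(config)
    wat <- select_atoms(traj$system, config$water_selection %||%
                          "group:solvent and element:O")
    prof <- z_profile(traj, wat, bin_width = config$bin_width)
    utils::write.table(prof, pathto("z_profile.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- pathto("z_profile.tsv")
  }

  if (stage == "screen-stats") {
    if (is.null(config$odor_table))
      config_error("screen-stats: config key 'odor_table' required")
    rec <- load_odor_table(config$odor_table)
    desc <- config$descriptor %||% "volume"
    top <- top_fraction_subset(rec, desc, fraction = config$fraction)
    roc <- roc_auc(rec, top)
    tr <- descriptor_trend(rec, desc, n_bins = config$n_bins %||% 6)
    utils::write.table(roc$points, pathto("roc_points.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(tr$bins, pathto("descriptor_bins.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary <- data.frame(metric = c("auc", "spearman_rho", "n_top"),
                          value = c(roc$auc, tr$spearman_rho, length(top)))
    utils::write.table(summary, pathto("screen_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- pathto(c("roc_points.tsv", "descriptor_bins.tsv",
                        "screen_summary.tsv"))
  }

  write_manifest(out_dir, stage, config, inputs)
  invisible(c(written, file.path(out_dir, "manifest.json")))
}
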