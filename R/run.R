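#' @include AllClasses.R synthetic-data.R dose-response.R bias.R hbonds.R geometry.R
NULL

# Resolve a run configuration: accept a YAML path or a list, fill defaults,
# reject unknown keys. The fully resolved config is embedded in every report.
.resolve_config <- function(config, defaults, required = character()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  resolved <- utils::modifyList(defaults, config)
  missing <- required[vapply(resolved[required], is.null, logical(1))]
  if (length(missing))
    stop("config must set: ", paste(missing, collapse = ", "))
  resolved
}

.write_report <- function(payload, out_dir, name) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  payload$package_version <-
    as.character(utils::packageVersion("ChemokineBias"))
  path <- file.path(out_dir, name)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

#' Simulate a dose-response panel to disk
#'
#' @param config list or YAML path with keys \code{preset},
#'   \code{pathways}, \code{grid_min}, \code{grid_max}, \code{grid_step}
#'   (log10 molar), \code{n_experiments}, \code{noise_sd}, \code{seed},
#'   \code{out} (output directory).
#' @return paths of the files written, invisibly.
#' @export
runSimulate <- function(config) {
  cfg <- .resolve_config(config, defaults = list(
    preset = "ccl15_truncations",
    pathways = c("gi_dissociation", "arrestin_recruitment"),
    grid_min = -13, grid_max = -6, grid_step = 0.5,
    n_experiments = 8L, noise_sd = 5, seed = 1L, out = "."),
    required = "out")
  sim <- SimulationConfig(seq(cfg$grid_min, cfg$grid_max, by = cfg$grid_step),
                          cfg$n_experiments, cfg$noise_sd, cfg$seed)
  panel <- simulatePanel(generatePanel(cfg$preset),
                         pathways = unlist(cfg$pathways), config = sim)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(cfg$out, "panel.tsv")
  writePanel(panel, tsv)
  rpt <- .write_report(list(command = "simulate", config = cfg,
                            n_records = nrow(records(panel))),
                       cfg$out, "simulate_report.json")
  invisible(c(panel = tsv, report = rpt))
}

#' Run the pharmacology arm: normalization, fits, bias factors, comparisons
#'
#' Reads a long-format dose-response file, normalizes it, fits combined and
#' per-experiment curves, computes per-experiment bias factors of every
#' ligand against the reference, and performs the many-vs-one comparison.
#' Any failed (non-converged or degenerate) fit aborts the run unless
#' \code{allow_partial} is set, in which case the affected ligand is dropped
#' and listed in the report.
#'
#' @param config list or YAML path with keys \code{input} (panel TSV),
#'   \code{reference}, \code{pathway_pair} (2 pathway ids),
#'   \code{normalization} (mode or \code{"none"}), \code{model},
#'   \code{allow_partial}, \code{out}.
#' @return paths of the files written, invisibly.
#' @export
runBias <- function(config) {
  cfg <- .resolve_config(config, defaults = list(
    input = NULL, reference = NULL,
    pathway_pair = c("gi_dissociation", "arrestin_recruitment"),
    normalization = "reference_max_100", model = "hill_fixed_1",
    allow_partial = FALSE, out = "."),
    required = c("input", "reference", "out"))
  panel <- readPanel(cfg$input)
  if (!nrow(records(panel))) stop("input panel is empty")
  if (cfg$normalization != "none")
    panel <- normalizePanel(panel, cfg$normalization,
                            reference = cfg$reference)
  pair <- unlist(cfg$pathway_pair)
  fits <- fitDoseResponse(panel, model = cfg$model,
                          pooling = "per_experiment")
  tab <- fitTable(fits)
  bad <- unique(tab$ligand[!tab$converged | tab$degenerate])
  if (length(bad)) {
    if (cfg$reference %in% bad || !cfg$allow_partial)
      stop("failed fits for ligand(s): ", paste(bad, collapse = ", "),
           if (!cfg$allow_partial) " (set allow_partial to drop them)")
  }
  ligands <- setdiff(unique(tab$ligand), bad)
  others <- setdiff(ligands, cfg$reference)
  bias <- lapply(c(cfg$reference, others), function(lig)
    perExperimentBias(fits, lig, cfg$reference, pair = pair))
  names(bias) <- c(cfg$reference, others)
  cmp <- compareVsReference(bias, cfg$reference)
  btab <- biasTable(bias, cmp)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  fit_path <- file.path(cfg$out, "fit_table.tsv")
  bias_path <- file.path(cfg$out, "bias_table.tsv")
  utils::write.table(tab, fit_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(btab, bias_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rpt <- .write_report(list(
    command = "bias", config = cfg, dropped_ligands = as.list(bad),
    anova_F = cmp@statistic, p_adjusted = as.list(cmp@p_values),
    bias = lapply(bias, function(b) list(
      mean = b@mean, sem = b@sem, n = length(b@per_experiment_betas),
      classification = b@classification))),
    cfg$out, "bias_report.json")
  invisible(c(fit_table = fit_path, bias_table = bias_path, report = rpt))
}

#' Run the structural arm: CRS areas, hydrogen bonds, polar-network state
#'
#' @param config list or YAML path with keys \code{structure} (coordinate
#'   file), \code{format}, \code{chain_roles} (named list chain -> role;
#'   required), \code{bw_map} (path to a two-column map, or \code{"ccr1"}),
#'   \code{probe}, \code{n_points}, \code{hbond_dist}, \code{hbond_angle},
#'   \code{site_config} (named overrides for \code{\link{crsConfig}}),
#'   \code{out}.
#' @return paths of the files written, invisibly.
#' @export
runCrs <- function(config) {
  cfg <- .resolve_config(config, defaults = list(
    structure = NULL, format = "guess", chain_roles = NULL, bw_map = "ccr1",
    probe = 1.4, n_points = 960L, hbond_dist = 3.5, hbond_angle = 120,
    site_config = list(), out = "."),
    required = c("structure", "chain_roles", "out"))
  roles <- unlist(cfg$chain_roles)
  if (!"receptor" %in% roles || !"chemokine" %in% roles)
    stop("chain_roles must assign a receptor and a chemokine chain")
  model <- readStructure(cfg$structure, format = cfg$format,
                         chain_roles = roles)
  map <- if (identical(cfg$bw_map, "ccr1")) ccr1Numbering()
         else readBWMap(cfg$bw_map)
  anchors <- if (identical(cfg$bw_map, "ccr1")) ccr1Anchors() else NULL
  model <- assignNumbering(model, map, anchors = anchors)
  site_cfg <- do.call(crsConfig, cfg$site_config)
  partition <- defineSites(model, site_cfg)
  report <- crsReport(model, partition, probe = cfg$probe,
                      n_points = cfg$n_points, hbond_dist = cfg$hbond_dist,
                      hbond_angle = cfg$hbond_angle)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  dsasa_path <- file.path(cfg$out, "residue_dsasa.tsv")
  hb_path <- file.path(cfg$out, "hbonds.tsv")
  sites_path <- file.path(cfg$out, "sites.json")
  utils::write.table(report@residue_dsasa, dsasa_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report@hbonds, hb_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeSites(partition, sites_path)
  rpt <- .write_report(list(
    command = "crs", config = cfg,
    total_buried_area = report@total_buried_area,
    total_delta_sasa = report@total_delta_sasa,
    site_buried_area = as.list(report@site_buried_area),
    n_hbonds = nrow(report@hbonds),
    network_state = report@network_state),
    cfg$out, "crs_report.json")
  invisible(c(residue_dsasa = dsasa_path, hbonds = hb_path,
              sites = sites_path, report = rpt))
}

#' Run the angle arm: interdomain rotation and side-chain sway
#'
#' @param config list or YAML path with keys \code{structure_a},
#'   \code{structure_b}, \code{format}, \code{chain_roles_a},
#'   \code{chain_roles_b}, \code{sway_residues} (receptor residue numbers to
#'   measure; optional), \code{interdomain} (logical: measure the
#'   chemokine-core rotation in the receptor frame), \code{out}.
#' @return paths of the files written, invisibly.
#' @export
runAngles <- function(config) {
  cfg <- .resolve_config(config, defaults = list(
    structure_a = NULL, structure_b = NULL, format = "guess",
    chain_roles_a = NULL, chain_roles_b = NULL, sway_residues = integer(),
    interdomain = TRUE, out = "."),
    required = c("structure_a", "structure_b", "chain_roles_a",
                 "chain_roles_b", "out"))
  A <- readStructure(cfg$structure_a, format = cfg$format,
                     chain_roles = unlist(cfg$chain_roles_a))
  B <- readStructure(cfg$structure_b, format = cfg$format,
                     chain_roles = unlist(cfg$chain_roles_b))
  out <- list(command = "angles", config = cfg)
  if (isTRUE(cfg$interdomain)) {
    recCa <- function(m) {
      roles <- chainRoles(m)
      ch <- names(roles)[roles == "receptor"]
      a <- atoms(m)
      idx <- which(a$chain %in% ch & a$name == "CA" & !a$het)
      stats::setNames(idx, a$resno[idx])
    }
    ca_a <- recCa(A); ca_b <- recCa(B)
    common <- intersect(names(ca_a), names(ca_b))
    corr <- chemokineCoreCorrespondence(A, B)
    out$interdomain_rotation_deg <- interdomainRotation(
      A, B, align_a = unname(ca_a[common]), align_b = unname(ca_b[common]),
      measure_a = corr$a, measure_b = corr$b)
  }
  if (length(cfg$sway_residues)) {
    out$sway_deg <- lapply(stats::setNames(
      as.integer(cfg$sway_residues), cfg$sway_residues),
      function(rn) sidechainOrientationChange(A, B, rn))
  }
  rpt <- .write_report(out, cfg$out, "angles_report.json")
  invisible(c(report = rpt))
}
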