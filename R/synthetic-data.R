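#' @include AllClasses.R
NULL

#' Four-parameter logistic (sigmoidal) dose-response curve
#'
#' Response at a given log10 molar concentration under the standard
#' pharmacological 4PL model. At \code{logc == log10_ec50} the response is
#' exactly midway between baseline and emax.
#'
#' @param logc log10 molar concentration(s).
#' @param baseline bottom asymptote (\%).
#' @param emax top asymptote (\%).
#' @param log10_ec50 log10 molar half-maximal concentration.
#' @param hill Hill slope (> 0).
#' @return numeric response(s) on the same scale as \code{emax}.
#' @export
fourPL <- function(logc, baseline, emax, log10_ec50, hill = 1) {
  baseline + (emax - baseline) / (1 + 10^(hill * (log10_ec50 - logc)))
}

#' Construct a LigandProfile
#'
#' @param name ligand label.
#' @param pathways named list of named numeric vectors
#'   (\code{emax}, \code{baseline}, \code{log10_ec50}, \code{hill}).
#' @return a \linkS4class{LigandProfile}
#' @export
LigandProfile <- function(name, pathways) {
  new("LigandProfile", name = name, pathways = pathways)
}

#' Construct a SimulationConfig
#'
#' Defaults emulate the assay design: 15 half-log concentration steps from
#' 1e-13 to 1e-6 M, 8 independent experiments, additive Gaussian noise with
#' s.d. 5 on the normalized percent scale.
#'
#' @param concentration_grid strictly increasing log10 molar values.
#' @param n_experiments number of independent experiments.
#' @param noise_sd Gaussian noise s.d. (percent units, >= 0).
#' @param seed integer RNG seed.
#' @return a \linkS4class{SimulationConfig}
#' @export
SimulationConfig <- function(concentration_grid = seq(-13, -6, by = 0.5),
                             n_experiments = 8L, noise_sd = 5, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  new("SimulationConfig", concentration_grid = as.numeric(concentration_grid),
      n_experiments = as.integer(n_experiments), noise_sd = noise_sd,
      seed = as.integer(seed))
}

# True-parameter tables for the shipped presets. The values are illustrative
# package constants with the qualitative structure of the CCL15 truncation
# panel: near-constant G-protein potency across truncations, arrestin Emax
# declining with shorter N terminus with a pronounced drop between the
# (27-92) and (28-92) forms.
.ligand_presets <- list(
  ccl15_truncations = list(
    #                gi: emax  lec50      arr: emax  lec50
    `CCL15(26-92)` = c(95,  -8.9,  105, -8.8),
    `CCL15(27-92)` = c(100, -9.0,  100, -8.7),
    `CCL15(28-92)` = c(100, -9.1,   55, -8.6),
    `CCL15(29-92)` = c(98,  -9.2,   40, -8.7),
    `CCL15(30-92)` = c(97,  -9.0,   30, -8.6),
    `CCL15(31-92)` = c(95,  -8.8,   22, -8.5)
  )
)

#' Generate a panel of ligand profiles from a named preset
#'
#' The \code{"ccl15_truncations"} preset returns six N-terminal truncations
#' of the chemokine CCL15 (labels \code{CCL15(26-92)} through
#' \code{CCL15(31-92)}) with true parameters for two pathways
#' (\code{gi_dissociation}, \code{arrestin_recruitment}). By construction the
#' G-protein log10 EC50 values lie within 0.5 log units of one another while
#' the arrestin Emax declines monotonically with shorter N terminus, dropping
#' sharply between the (27-92) and (28-92) forms. The magnitudes are
#' illustrative constants, not measured values.
#'
#' @param preset preset name; currently \code{"ccl15_truncations"}.
#' @return list of \linkS4class{LigandProfile} objects, in truncation order.
#' @export
generatePanel <- function(preset = "ccl15_truncations") {
  if (!preset %in% names(.ligand_presets))
    stop("unknown preset '", preset, "'; available: ",
         paste(names(.ligand_presets), collapse = ", "))
  tab <- .ligand_presets[[preset]]
  lapply(names(tab), function(nm) {
    p <- tab[[nm]]
    LigandProfile(nm, list(
      gi_dissociation = c(emax = p[1], baseline = 0,
                          log10_ec50 = p[2], hill = 1),
      arrestin_recruitment = c(emax = p[3], baseline = 0,
                               log10_ec50 = p[4], hill = 1)))
  })
}

#' Simulate one replicated dose-response experiment
#'
#' Draws one response per (concentration, experiment): the 4PL curve value at
#' the profile's true parameters plus additive homoscedastic Gaussian noise.
#' Reproducible under the config seed.
#'
#' @param profile a \linkS4class{LigandProfile}.
#' @param pathway pathway id defined in the profile.
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{DoseResponsePanel} for this ligand/pathway.
#' @export
simulateExperiment <- function(profile, pathway, config = SimulationConfig()) {
  if (!pathway %in% names(profile@pathways))
    stop("pathway '", pathway, "' not defined in profile '",
         profile@name, "'")
  p <- profile@pathways[[pathway]]
  grid <- config@concentration_grid
  n <- config@n_experiments
  set.seed(config@seed)
  df <- expand.grid(concentration_M = 10^grid, experiment = seq_len(n),
                    KEEP.OUT.ATTRS = FALSE)
  mu <- fourPL(log10(df$concentration_M), p[["baseline"]], p[["emax"]],
               p[["log10_ec50"]], p[["hill"]])
  df$response <- mu + rnorm(nrow(df), 0, config@noise_sd)
  new("DoseResponsePanel",
      records = data.frame(ligand = profile@name, pathway = pathway,
                           experiment = as.character(df$experiment),
                           concentration_M = df$concentration_M,
                           response = df$response,
                           stringsAsFactors = FALSE),
      normalization = "raw")
}

#' Simulate a full ligand x pathway panel
#'
#' Runs \code{\link{simulateExperiment}} for every profile and pathway,
#' drawing all noise from a single seeded stream so that the whole panel is
#' reproducible from one seed.
#'
#' @param profiles list of \linkS4class{LigandProfile} objects.
#' @param pathways pathway ids to simulate (must exist in every profile).
#' @param config a \linkS4class{SimulationConfig}; its seed governs the panel.
#' @return a combined \linkS4class{DoseResponsePanel}.
#' @export
simulatePanel <- function(profiles,
                          pathways = c("gi_dissociation",
                                       "arrestin_recruitment"),
                          config = SimulationConfig()) {
  set.seed(config@seed)
  grid <- config@concentration_grid
  n <- config@n_experiments
  out <- list()
  for (prof in profiles) {
    for (pw in pathways) {
      if (!pw %in% names(prof@pathways))
        stop("pathway '", pw, "' not defined in profile '", prof@name, "'")
      p <- prof@pathways[[pw]]
      df <- expand.grid(concentration_M = 10^grid,
                        experiment = seq_len(n), KEEP.OUT.ATTRS = FALSE)
      mu <- fourPL(log10(df$concentration_M), p[["baseline"]], p[["emax"]],
                   p[["log10_ec50"]], p[["hill"]])
      df$response <- mu + rnorm(nrow(df), 0, config@noise_sd)
      out[[length(out) + 1L]] <- data.frame(
        ligand = prof@name, pathway = pw,
        experiment = as.character(df$experiment),
        concentration_M = df$concentration_M, response = df$response,
        stringsAsFactors = FALSE)
    }
  }
  new("DoseResponsePanel", records = do.call(rbind, out),
      normalization = "raw")
}

#' Write / read a dose-response panel as tab-delimited text
#'
#' Long format with columns \code{ligand}, \code{pathway}, \code{experiment},
#' \code{concentration_M}, \code{response}.
#'
#' @param panel a \linkS4class{DoseResponsePanel}.
#' @param file path to a delimited text file.
#' @return \code{writePanel} returns \code{file} invisibly; \code{readPanel}
#'   returns a \linkS4class{DoseResponsePanel}.
#' @export
writePanel <- function(panel, file) {
  utils::write.table(records(panel), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writePanel
#' @param normalization provenance note to attach on read.
#' @export
readPanel <- function(file, normalization = "raw") {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(ligand = "character",
                                         pathway = "character",
                                         experiment = "character"))
  new("DoseResponsePanel", records = df, normalization = normalization)
}

# ---- toy structures with analytically / numerically known surface truths ----

#' Numerical-integration SASA oracle for small sphere sets
#'
#' Independent reference for the production Shrake-Rupley engine: integrates
#' the exposed area of each expanded sphere (radius + probe) over a fine
#' latitude-longitude quadrature grid. Intended for toy fixtures only
#' (cost grows as atoms x grid).
#'
#' @param xyz n x 3 matrix of sphere centers (A).
#' @param radii per-sphere van der Waals radii (A).
#' @param probe probe radius (A), default 1.4.
#' @param n_theta,n_phi quadrature resolution (polar x azimuthal).
#' @return per-sphere exposed areas (A^2).
#' @export
sasaOracle <- function(xyz, radii, probe = 1.4, n_theta = 360L,
                       n_phi = 720L) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  R <- radii + probe
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  st <- sin(theta)
  # unit directions for the full grid
  dirs <- cbind(rep(st, times = n_phi) * rep(cos(phi), each = n_theta),
                rep(st, times = n_phi) * rep(sin(phi), each = n_theta),
                rep(cos(theta), times = n_phi))
  w <- rep(st, times = n_phi) * (pi / n_theta) * (2 * pi / n_phi)
  vapply(seq_len(n), function(i) {
    pts <- sweep(dirs * R[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, nrow(pts))
    for (j in seq_len(n)[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > R[j]^2
    }
    R[i]^2 * sum(w[exposed])
  }, numeric(1))
}

#' Build a toy multi-chain structure with known surface-area truths
#'
#' Creates a minimal \linkS4class{StructureModel} from an explicit atom
#' specification and computes ground truth with the independent
#' \code{\link{sasaOracle}}: isolated-atom SASA (exact analytic spheres),
#' per-chain-group SASA, and the pairwise buried interface area between the
#' two chain groups. Optionally writes the fixture as a minimal PDB file.
#'
#' @param spec data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{chain}; optional \code{radius} to override the element
#'   radius table.
#' @param probe probe radius (A).
#' @param file optional path; when given the model is written as PDB.
#' @return list with elements \code{model} (a StructureModel) and
#'   \code{truth} (list: \code{sasa_isolated}, \code{sasa_complex},
#'   \code{buried_area} between the first two chains).
#' @export
makeToyInterface <- function(spec, probe = 1.4, file = NULL) {
  need <- c("element", "x", "y", "z", "chain")
  if (!all(need %in% names(spec)))
    stop("spec must have columns: ", paste(need, collapse = ", "))
  key <- paste(spec$chain, round(spec$x, 6), round(spec$y, 6),
               round(spec$z, 6))
  if (anyDuplicated(key))
    stop("overlapping identical atoms within one chain")
  radii <- if ("radius" %in% names(spec)) spec$radius
           else atomRadii(toupper(spec$element))
  n <- nrow(spec)
  atoms <- data.frame(
    serial = seq_len(n),
    name = toupper(spec$element),
    element = toupper(spec$element),
    resid = "TOY", resno = seq_len(n), insert = "",
    chain = as.character(spec$chain),
    x = spec$x, y = spec$y, z = spec$z,
    o = 1, alt = "", b = 0, het = FALSE,
    stringsAsFactors = FALSE)
  model <- new("StructureModel", atoms = atoms,
               chain_roles = stats::setNames(
                 rep("other", length(unique(atoms$chain))),
                 unique(atoms$chain)))
  xyz <- as.matrix(spec[, c("x", "y", "z")])
  chains <- unique(atoms$chain)
  sasa_iso <- 4 * pi * (radii + probe)^2
  truth <- list(sasa_isolated = sasa_iso,
                sasa_complex = sasaOracle(xyz, radii, probe))
  if (length(chains) >= 2L) {
    a <- atoms$chain == chains[1]
    b <- atoms$chain == chains[2]
    sasa_a <- sum(sasaOracle(xyz[a, , drop = FALSE], radii[a], probe))
    sasa_b <- sum(sasaOracle(xyz[b, , drop = FALSE], radii[b], probe))
    sasa_ab <- sum(sasaOracle(xyz[a | b, , drop = FALSE],
                              radii[a | b], probe))
    truth$buried_area <- (sasa_a + sasa_b - sasa_ab) / 2
  }
  if (!is.null(file)) writeStructure(model, file)
  list(model = model, truth = truth)
}
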