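#' @import methods
NULL

PATHWAYS <- c("gi_dissociation", "arrestin_recruitment", "camp", "endocytosis")

#' True generating parameters for one ligand across signaling pathways
#'
#' A \code{LigandProfile} stores, for one ligand, the true four-parameter
#' logistic (4PL) parameters per pathway: \code{emax} (\% of the reference
#' ligand's maximum), \code{baseline} (\%), \code{log10_ec50} (log10 molar)
#' and \code{hill} (unitless slope). These are the generating truths used by
#' the simulator; downstream fitting treats them as unknowns.
#'
#' @slot name ligand label, e.g. \code{"CCL15(27-92)"}.
#' @slot pathways named list; one element per pathway id, each a named
#'   numeric vector with entries \code{emax}, \code{baseline},
#'   \code{log10_ec50}, \code{hill}.
#'
#' @export
setClass("LigandProfile",
  representation(name = "character", pathways = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a single non-empty string")
    for (pw in names(object@pathways)) {
      p <- object@pathways[[pw]]
      need <- c("emax", "baseline", "log10_ec50", "hill")
      if (!all(need %in% names(p))) {
        msg <- c(msg, sprintf("pathway '%s' must define %s", pw,
                              paste(need, collapse = ", ")))
        next
      }
      if (!is.finite(p[["log10_ec50"]]))
        msg <- c(msg, sprintf("pathway '%s': log10_ec50 must be finite", pw))
      if (!(p[["emax"]] >= p[["baseline"]] && p[["baseline"]] >= 0))
        msg <- c(msg, sprintf("pathway '%s': need emax >= baseline >= 0", pw))
      if (!(p[["hill"]] > 0))
        msg <- c(msg, sprintf("pathway '%s': hill must be > 0", pw))
    }
    if (length(msg)) msg else TRUE
  })

#' Simulation design for replicated dose-response experiments
#'
#' Mirrors the assay design: a log10-molar concentration grid (default 15
#' half-log steps spanning 1e-13 to 1e-6 M), a number of independent
#' experiments, and a homoscedastic Gaussian noise s.d. on the normalized
#' percent-response scale.
#'
#' @slot concentration_grid strictly increasing log10 molar values.
#' @slot n_experiments number of independent experiments (>= 1).
#' @slot noise_sd Gaussian noise standard deviation, percent units (>= 0).
#' @slot seed integer RNG seed.
#'
#' @export
setClass("SimulationConfig",
  representation(concentration_grid = "numeric", n_experiments = "integer",
                 noise_sd = "numeric", seed = "integer"),
  prototype(concentration_grid = seq(-13, -6, by = 0.5),
            n_experiments = 8L, noise_sd = 5, seed = 1L),
  validity = function(object) {
    msg <- character()
    g <- object@concentration_grid
    if (length(g) < 2L || any(diff(g) <= 0))
      msg <- c(msg, "concentration_grid must be strictly increasing")
    if (object@n_experiments < 1L)
      msg <- c(msg, "n_experiments must be >= 1")
    if (object@noise_sd < 0)
      msg <- c(msg, "noise_sd must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Replicated dose-response measurements for ligand/pathway combinations
#'
#' Long-format container: one row per (ligand, pathway, experiment,
#' concentration). Responses are on a normalized percent scale; the
#' \code{normalization} slot records which convention produced them.
#'
#' @slot records data.frame with columns \code{ligand}, \code{pathway},
#'   \code{experiment}, \code{concentration_M} (molar, > 0), \code{response}.
#' @slot normalization provenance note, e.g. \code{"reference_max_100"}.
#'
#' @export
setClass("DoseResponsePanel",
  representation(records = "data.frame", normalization = "character"),
  prototype(normalization = "raw"),
  validity = function(object) {
    msg <- character()
    need <- c("ligand", "pathway", "experiment", "concentration_M", "response")
    if (!all(need %in% names(object@records)))
      msg <- c(msg, paste("records must have columns:",
                          paste(need, collapse = ", ")))
    else {
      if (any(object@records$concentration_M <= 0))
        msg <- c(msg, "concentrations must be > 0")
      if (any(!is.finite(object@records$response)))
        msg <- c(msg, "responses must be finite")
    }
    if (length(msg)) msg else TRUE
  })

#' Sigmoidal dose-response fit result
#'
#' Estimates of the 4PL parameters for one ligand/pathway (one experiment or
#' the combined data), with standard errors and convergence diagnostics.
#' Non-converged or degenerate fits are flagged, never silently reused:
#' bias computation refuses them.
#'
#' @slot ligand,pathway identifiers of the fitted trace.
#' @slot experiment experiment id for per-experiment fits; \code{NA} for a
#'   combined fit.
#' @slot estimates named numeric: \code{baseline}, \code{emax},
#'   \code{log10_ec50}, \code{hill}.
#' @slot se standard errors for the estimated parameters (NA where fixed).
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag.
#' @slot degenerate logical; TRUE when the data were too flat to support a fit.
#' @slot n_experiments_used count of experiments in the fitted data.
#' @slot model \code{"hill_fixed_1"} or \code{"hill_free"}.
#'
#' @export
setClass("FitResult",
  representation(ligand = "character", pathway = "character",
                 experiment = "character", estimates = "numeric",
                 se = "numeric", rss = "numeric", converged = "logical",
                 degenerate = "logical", n_experiments_used = "integer",
                 model = "character"),
  prototype(experiment = NA_character_, rss = NA_real_, converged = FALSE,
            degenerate = FALSE, n_experiments_used = 0L,
            model = "hill_fixed_1"))

#' Bias factor (beta value) for one ligand against a reference
#'
#' The beta value is the delta-delta-log(Emax/EC50) statistic comparing a
#' ligand's pathway-1 vs pathway-2 transduction against a reference ligand.
#' beta > 0 denotes bias toward pathway 1 (G-protein dissociation by
#' convention), beta < 0 toward pathway 2 (beta-arrestin recruitment).
#'
#' @slot ligand,reference ligand labels.
#' @slot pathway_pair character(2): pathway 1 then pathway 2.
#' @slot beta point estimate (log10 units) from the combined fits, or the
#'   per-experiment mean when computed per experiment.
#' @slot per_experiment_betas one beta per matched experiment (may be empty).
#' @slot mean,sem mean and standard error over experiments.
#' @slot classification \code{"gi_biased"}, \code{"arrestin_biased"} or
#'   \code{"balanced"}.
#'
#' @export
setClass("BiasResult",
  representation(ligand = "character", reference = "character",
                 pathway_pair = "character", beta = "numeric",
                 per_experiment_betas = "numeric", mean = "numeric",
                 sem = "numeric", classification = "character"),
  prototype(per_experiment_betas = numeric(), mean = NA_real_,
            sem = NA_real_, classification = "balanced"),
  validity = function(object) {
    msg <- character()
    if (!is.finite(object@beta)) msg <- c(msg, "beta must be finite")
    if (length(object@pathway_pair) != 2L ||
        object@pathway_pair[1] == object@pathway_pair[2])
      msg <- c(msg, "pathway_pair must name two distinct pathways")
    ok <- c("gi_biased", "arrestin_biased", "balanced")
    if (!object@classification %in% ok)
      msg <- c(msg, paste("classification must be one of",
                          paste(ok, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Statistical comparison of bias factors across ligands
#'
#' Either a one-way ANOVA with Dunnett-style many-vs-one adjusted p-values
#' against the reference ligand, or a two-tailed two-sample Student's t-test.
#'
#' @slot test \code{"anova_dunnett"} or \code{"t_test_two_tailed"}.
#' @slot statistic F statistic (ANOVA) or t statistic.
#' @slot p_values named per-ligand p-values (Dunnett-adjusted for ANOVA).
#' @slot reference reference ligand id.
#'
#' @export
setClass("BiasComparison",
  representation(test = "character", statistic = "numeric",
                 p_values = "numeric", reference = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@test %in% c("anova_dunnett", "t_test_two_tailed"))
      msg <- c(msg, "unknown test type")
    if (any(object@p_values < 0 | object@p_values > 1, na.rm = TRUE))
      msg <- c(msg, "p_values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Annotated atomic coordinates of a receptor-chemokine complex
#'
#' Container for parsed PDB/mmCIF coordinates with chain-role assignments
#' (receptor, chemokine, other) and, after \code{\link{assignNumbering}},
#' per-residue segment labels and Ballesteros-Weinstein numbers on the
#' receptor chain.
#'
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resid} (residue name), \code{resno},
#'   \code{insert}, \code{chain}, \code{x}, \code{y}, \code{z}, \code{o}
#'   (occupancy), \code{alt} (altloc), \code{b}, \code{het} (logical,
#'   water/ligand/detergent flag).
#' @slot chain_roles named character: chain id -> role in
#'   \code{c("receptor", "chemokine", "other")}.
#' @slot numbering data.frame (possibly empty) with columns \code{resno},
#'   \code{bw} (Ballesteros-Weinstein label or NA) and \code{segment}
#'   for the receptor chain.
#'
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", chain_roles = "character",
                 numbering = "data.frame"),
  prototype(chain_roles = character(),
            numbering = data.frame(resno = integer(), bw = character(),
                                   segment = character())),
  validity = function(object) {
    msg <- character()
    a <- object@atoms
    need <- c("serial", "name", "element", "resid", "resno", "insert",
              "chain", "x", "y", "z", "o", "alt", "b", "het")
    if (!all(need %in% names(a)))
      msg <- c(msg, paste("atoms must have columns:",
                          paste(setdiff(need, names(a)), collapse = ", ")))
    else if (nrow(a)) {
      if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
        msg <- c(msg, "coordinates must be finite")
      key <- paste(a$chain, a$resno, a$insert, a$name, a$alt)
      if (anyDuplicated(key))
        msg <- c(msg, "duplicate (chain, residue, atom name, altloc) entries")
    }
    bad <- setdiff(object@chain_roles, c("receptor", "chemokine", "other"))
    if (length(bad))
      msg <- c(msg, paste("unknown chain roles:", paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Chemokine recognition site (CRS) partition of an interface
#'
#' Maps each site (CRS1, CRS1.5, CRS2, CRS3) to the receptor and chemokine
#' residue numbers it comprises. Receptor residue sets are pairwise disjoint;
#' the sites need not tile the whole interface.
#'
#' @slot sites named list; each element a list with integer vectors
#'   \code{receptor} and \code{chemokine}.
#'
#' @export
setClass("SitePartition",
  representation(sites = "list"),
  validity = function(object) {
    msg <- character()
    rec <- lapply(object@sites, `[[`, "receptor")
    all_rec <- unlist(rec, use.names = FALSE)
    if (anyDuplicated(all_rec))
      msg <- c(msg, "receptor residue sets must be pairwise disjoint")
    if (length(msg)) msg else TRUE
  })

#' Interface analysis report
#'
#' Buried surface areas (total and per CRS site, PISA-style halved
#' convention, with the un-halved total also recorded), per-residue
#' delta-SASA, the hydrogen-bond list, and the Y7.43 polar-network state.
#'
#' @slot total_buried_area interface area in A^2 (delta-SASA / 2).
#' @slot total_delta_sasa un-halved total delta-SASA in A^2.
#' @slot site_buried_area named numeric, A^2 per site.
#' @slot residue_dsasa data.frame: chain, resno, resid, dsasa.
#' @slot hbonds data.frame: donor/acceptor atom descriptors, distance, angle.
#' @slot network_state one of \code{"tm2_engaged"}, \code{"tm3_tm6_engaged"},
#'   \code{"mixed"}, \code{"undetermined"}.
#'
#' @export
setClass("InterfaceReport",
  representation(total_buried_area = "numeric", total_delta_sasa = "numeric",
                 site_buried_area = "numeric", residue_dsasa = "data.frame",
                 hbonds = "data.frame", network_state = "character"),
  prototype(network_state = "undetermined"),
  validity = function(object) {
    msg <- character()
    if (length(object@total_buried_area) &&
        is.finite(object@total_buried_area) && object@total_buried_area < -1e-6)
      msg <- c(msg, "total buried area must be >= 0")
    if (any(object@site_buried_area < -1e-6, na.rm = TRUE))
      msg <- c(msg, "site buried areas must be >= 0")
    ok <- c("tm2_engaged", "tm3_tm6_engaged", "mixed", "undetermined")
    if (!object@network_state %in% ok)
      msg <- c(msg, "invalid network_state")
    if (length(msg)) msg else TRUE
  })

#' Rigid-body superposition result
#'
#' Least-squares optimal proper rotation (Kabsch; reflections excluded) and
#' translation mapping a mobile atom selection onto a reference, with the
#' residual RMSD over the correspondence used.
#'
#' @slot rotation 3x3 orthonormal matrix with det = +1.
#' @slot translation length-3 vector in Angstrom.
#' @slot rmsd root-mean-square deviation after superposition (A).
#' @slot n_pairs number of corresponding atom pairs used.
#'
#' @export
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", n_pairs = "integer"),
  validity = function(object) {
    msg <- character()
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L)))
      msg <- c(msg, "rotation must be 3x3")
    else {
      if (max(abs(crossprod(R) - diag(3))) > 1e-6)
        msg <- c(msg, "rotation must be orthonormal")
      if (abs(det(R) - 1) > 1e-6)
        msg <- c(msg, "rotation must be proper (det = +1)")
    }
    if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
    if (length(msg)) msg else TRUE
  })
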