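#' @include AllClasses.R
NULL

#' Atom table of a structure
#' @param x a \linkS4class{StructureModel}
#' @return data.frame of atoms
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Chain role map of a structure
#' @param x a \linkS4class{StructureModel}
#' @return named character vector (chain id -> role)
#' @export
setGeneric("chainRoles", function(x) standardGeneric("chainRoles"))

#' Replace the chain role map
#' @param x a \linkS4class{StructureModel}
#' @param value named character vector (chain id -> role)
#' @export
setGeneric("chainRoles<-", function(x, value) standardGeneric("chainRoles<-"))

#' Residue numbering annotation of a structure
#' @param x a \linkS4class{StructureModel}
#' @return data.frame with resno, bw, segment
#' @export
setGeneric("numbering", function(x) standardGeneric("numbering"))

#' Long-format records of a dose-response panel
#' @param x a \linkS4class{DoseResponsePanel}
#' @return data.frame
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Parameter estimates of a fit
#' @param x a \linkS4class{FitResult}
#' @return named numeric vector
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' Convergence flag of a fit
#' @param x a \linkS4class{FitResult}
#' @return logical
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' Bias factor point estimate
#' @param x a \linkS4class{BiasResult}
#' @return numeric beta (log10 units)
#' @export
setGeneric("betaValue", function(x) standardGeneric("betaValue"))

#' @rdname atoms
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname chainRoles
#' @export
setMethod("chainRoles", "StructureModel", function(x) x@chain_roles)

#' @rdname chainRoles-set
#' @export
setMethod("chainRoles<-", "StructureModel", function(x, value) {
  x@chain_roles <- value
  validObject(x)
  x
})

#' @rdname numbering
#' @export
setMethod("numbering", "StructureModel", function(x) x@numbering)

#' @rdname records
#' @export
setMethod("records", "DoseResponsePanel", function(x) x@records)

#' @rdname estimates
#' @export
setMethod("estimates", "FitResult", function(x) x@estimates)

#' @rdname converged
#' @export
setMethod("converged", "FitResult", function(x) x@converged)

#' @rdname betaValue
#' @export
setMethod("betaValue", "BiasResult", function(x) x@beta)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel:", nrow(a), "atoms,",
      length(unique(a$chain)), "chain(s)\n")
  if (length(object@chain_roles)) {
    cat("  roles:",
        paste(sprintf("%s=%s", names(object@chain_roles),
                      object@chain_roles), collapse = ", "), "\n")
  }
  if (nrow(object@numbering))
    cat("  numbering:", sum(!is.na(object@numbering$bw)),
        "BW-labelled residues\n")
})

setMethod("show", "DoseResponsePanel", function(object) {
  r <- object@records
  cat("DoseResponsePanel:", nrow(r), "records |",
      length(unique(r$ligand)), "ligand(s) x",
      length(unique(r$pathway)), "pathway(s),",
      length(unique(r$experiment)), "experiment(s)\n")
  cat("  normalization:", object@normalization, "\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s / %s%s] %s\n", object@ligand, object@pathway,
              if (is.na(object@experiment)) " / combined"
              else paste0(" / expt ", object@experiment),
              object@model))
  if (object@degenerate) {
    cat("  degenerate fit (flat data); no parameters reported\n")
  } else {
    e <- object@estimates; s <- object@se
    for (p in names(e))
      cat(sprintf("  %-10s %9.4f (se %s)\n", p, e[[p]],
                  if (is.na(s[[p]])) "fixed/NA" else sprintf("%.4f", s[[p]])))
    cat("  converged:", object@converged, " rss:",
        format(object@rss, digits = 5), "\n")
  }
})

setMethod("show", "BiasResult", function(object) {
  cat(sprintf("BiasResult: %s vs %s [%s | %s]\n", object@ligand,
              object@reference, object@pathway_pair[1], object@pathway_pair[2]))
  cat(sprintf("  beta = %.4f", object@beta))
  if (length(object@per_experiment_betas))
    cat(sprintf("  (mean %.4f +/- %.4f s.e.m., n = %d)",
                object@mean, object@sem, length(object@per_experiment_betas)))
  cat("\n  classification:", object@classification, "\n")
})

setMethod("show", "BiasComparison", function(object) {
  cat("BiasComparison:", object@test, "vs", object@reference, "\n")
  cat("  statistic:", format(object@statistic, digits = 5), "\n")
  for (lig in names(object@p_values))
    cat(sprintf("  %-20s p = %.4g\n", lig, object@p_values[[lig]]))
})

setMethod("show", "InterfaceReport", function(object) {
  cat("InterfaceReport\n")
  cat(sprintf("  total buried area: %.1f A^2 (delta-SASA %.1f A^2)\n",
              object@total_buried_area, object@total_delta_sasa))
  for (s in names(object@site_buried_area))
    cat(sprintf("  %-7s %.1f A^2\n", s, object@site_buried_area[[s]]))
  cat("  hydrogen bonds:", nrow(object@hbonds), "\n")
  cat("  polar-network state:", object@network_state, "\n")
})

setMethod("show", "Superposition", function(object) {
  cat(sprintf("Superposition over %d atom pairs, rmsd = %.4f A\n",
              object@n_pairs, object@rmsd))
})
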