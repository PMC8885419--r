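#' @include AllClasses.R numbering.R
NULL

#' Default chemokine-recognition-site boundaries for CCL15-bound CCR1
#'
#' Residue-level boundaries of the four recognition sites. The published
#' description fixes the receptor N-terminal stretch (D17..K26), the
#' CRS1.5 cysteine region around C24, the chemokine 30s loop (50-57,
#' FETSSECS) and the identity of the most N-terminal chemokine residue
#' (F26); the remaining boundaries (N-loop, beta strands, first core
#' cysteine, TM tips) are conventional defaults and overridable.
#'
#' @param nt_end last receptor N-terminus residue in CRS1 (default 26).
#' @param crs15_receptor receptor residues of the CRS1.5 PC-motif region.
#' @param first_cysteine chemokine residue number of the first core cysteine;
#'   chemokine residues before it form the CRS2 chemokine set.
#' @param n_loop,beta3 chemokine residue ranges forming the CRS1 groove.
#' @param core_disulfide chemokine residues of the CRS1.5 disulfide region.
#' @param loop30s chemokine 30s-loop residues (CRS3).
#' @param beta1_beta2 chemokine beta1-beta2 residues (CRS3).
#' @param tm5_tip_from,tm6_tip_from BW position (helix-internal number) from
#'   which TM5/TM6 residues count as extracellular tips for CRS3.
#' @param crs2_cutoff heavy-atom distance (A) defining the CRS2 receptor
#'   pocket around the chemokine N terminus.
#' @return named list of boundary settings.
#' @export
crsConfig <- function(nt_end = 26L, crs15_receptor = 23:25,
                      first_cysteine = 33L, n_loop = 34:44, beta3 = 73:79,
                      core_disulfide = 31:35, loop30s = 50:57,
                      beta1_beta2 = c(45:49, 58:65),
                      tm5_tip_from = 60L, tm6_tip_from = 55L,
                      crs2_cutoff = 4.5) {
  list(nt_end = as.integer(nt_end), crs15_receptor = as.integer(crs15_receptor),
       first_cysteine = as.integer(first_cysteine),
       n_loop = as.integer(n_loop), beta3 = as.integer(beta3),
       core_disulfide = as.integer(core_disulfide),
       loop30s = as.integer(loop30s), beta1_beta2 = as.integer(beta1_beta2),
       tm5_tip_from = as.integer(tm5_tip_from),
       tm6_tip_from = as.integer(tm6_tip_from), crs2_cutoff = crs2_cutoff)
}

#' Partition the receptor-chemokine interface into CRS sites
#'
#' Builds the CRS1 / CRS1.5 / CRS2 / CRS3 partition from an annotated model:
#' \itemize{
#'   \item CRS1: resolved receptor N-terminal stretch (through
#'     \code{nt_end}, excluding the CRS1.5 region) against the chemokine
#'     N-loop and beta3 strand;
#'   \item CRS1.5: the receptor PC-motif region (residues 23-25 by default)
#'     against the chemokine core-disulfide region;
#'   \item CRS2: chemokine residues preceding the first core cysteine against
#'     the receptor 7TM pocket, defined geometrically as receptor residues
#'     with any heavy atom within \code{crs2_cutoff} A of that chemokine
#'     segment;
#'   \item CRS3: the chemokine 30s loop plus beta1-beta2 strands against
#'     ECL2, ECL3 and the extracellular tips of TM5/TM6.
#' }
#' Receptor residue sets are made pairwise disjoint by removing, from CRS3
#' and then CRS2, residues already claimed by an earlier site.
#'
#' @param model an annotated \linkS4class{StructureModel} (run
#'   \code{\link{assignNumbering}} first) with receptor and chemokine roles.
#' @param config boundary settings from \code{\link{crsConfig}}.
#' @return a \linkS4class{SitePartition}
#' @export
defineSites <- function(model, config = crsConfig()) {
  num <- numbering(model)
  if (!nrow(num)) stop("model is not annotated; run assignNumbering() first")
  roles <- chainRoles(model)
  rec_chains <- names(roles)[roles == "receptor"]
  chem_chains <- names(roles)[roles == "chemokine"]
  if (!length(rec_chains) || !length(chem_chains))
    stop("model must have receptor and chemokine chain roles")
  a <- atoms(model)
  rec_res <- sort(unique(a$resno[a$chain %in% rec_chains & !a$het]))
  chem_res <- sort(unique(a$resno[a$chain %in% chem_chains & !a$het]))

  .require <- function(wanted, present, what) {
    missing <- setdiff(wanted, present)
    if (length(missing) == length(wanted))
      stop("site definition references absent ", what, " residues: ",
           paste(missing, collapse = ", "))
    intersect(wanted, present)
  }

  crs15_rec <- .require(config$crs15_receptor, rec_res, "receptor")
  crs1_rec <- setdiff(rec_res[rec_res <= config$nt_end &
                                rec_res %in%
                                num$resno[num$segment == "NT"]],
                      crs15_rec)
  if (!length(crs1_rec))
    stop("no resolved receptor N-terminus residues for CRS1")
  crs1_chem <- c(.require(config$n_loop, chem_res, "chemokine N-loop"),
                 .require(config$beta3, chem_res, "chemokine beta3"))
  crs15_chem <- .require(config$core_disulfide, chem_res, "chemokine")
  crs3_chem <- c(.require(config$loop30s, chem_res, "chemokine 30s-loop"),
                 .require(config$beta1_beta2, chem_res,
                          "chemokine beta1-beta2"))

  # CRS3 receptor side: ECL2/ECL3 plus TM5/TM6 extracellular tips
  bw_pos <- suppressWarnings(
    as.integer(sub("^[0-9]+\\.", "", num$bw)))
  crs3_rec <- num$resno[
    num$segment %in% c("ECL2", "ECL3") |
      (num$segment == "TM5" & !is.na(bw_pos) & bw_pos >= config$tm5_tip_from) |
      (num$segment == "TM6" & !is.na(bw_pos) & bw_pos >= config$tm6_tip_from)]
  crs3_rec <- setdiff(intersect(crs3_rec, rec_res),
                      c(crs1_rec, crs15_rec))

  # CRS2: geometric pocket around the chemokine N-terminal segment
  crs2_chem <- chem_res[chem_res < config$first_cysteine]
  nterm_idx <- selectAtoms(model, chain = chem_chains, resno = crs2_chem)
  rec_idx <- selectAtoms(model, chain = rec_chains)
  crs2_rec <- integer()
  if (length(nterm_idx) && length(rec_idx)) {
    xyz_n <- coords(model, nterm_idx)
    xyz_r <- coords(model, rec_idx)
    d2 <- outer(rowSums(xyz_r^2), rowSums(xyz_n^2), `+`) -
      2 * xyz_r %*% t(xyz_n)
    near <- apply(d2, 1, function(v) any(v <= config$crs2_cutoff^2))
    crs2_rec <- sort(unique(a$resno[rec_idx][near]))
    crs2_rec <- setdiff(crs2_rec, c(crs1_rec, crs15_rec, crs3_rec))
  }

  part <- new("SitePartition", sites = list(
    CRS1 = list(receptor = sort(crs1_rec), chemokine = sort(crs1_chem)),
    CRS1.5 = list(receptor = sort(crs15_rec), chemokine = sort(crs15_chem)),
    CRS2 = list(receptor = sort(crs2_rec), chemokine = sort(crs2_chem)),
    CRS3 = list(receptor = sort(crs3_rec), chemokine = sort(crs3_chem))))
  validObject(part)
  part
}

#' Site accessor
#' @param partition a \linkS4class{SitePartition}.
#' @param site site name, e.g. \code{"CRS3"}.
#' @return list with integer vectors \code{receptor} and \code{chemokine}.
#' @export
siteResidues <- function(partition, site) {
  if (!site %in% names(partition@sites))
    stop("unknown site '", site, "'; available: ",
         paste(names(partition@sites), collapse = ", "))
  partition@sites[[site]]
}

#' Serialize / restore a site partition
#'
#' @param partition a \linkS4class{SitePartition}.
#' @param file path to a JSON file.
#' @return \code{writeSites} returns \code{file} invisibly;
#'   \code{readSites} a \linkS4class{SitePartition}.
#' @export
writeSites <- function(partition, file) {
  jsonlite::write_json(partition@sites, file, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname writeSites
#' @export
readSites <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  sites <- lapply(raw, function(s)
    list(receptor = as.integer(s$receptor),
         chemokine = as.integer(s$chemokine)))
  new("SitePartition", sites = sites)
}

setMethod("show", "SitePartition", function(object) {
  cat("SitePartition:\n")
  for (nm in names(object@sites)) {
    s <- object@sites[[nm]]
    cat(sprintf("  %-7s receptor: %d residue(s); chemokine: %d residue(s)\n",
                nm, length(s$receptor), length(s$chemokine)))
  }
})
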