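#' @include AllClasses.R structure-io.R
NULL

# van der Waals radii (A), Lee-Richards/Bondi-style values. Overridable via
# the radii argument of the SASA routines.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
                D = 1.20, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
                I = 1.98, FE = 1.61, ZN = 1.39, MG = 1.73, "NA" = 2.27,
                K = 2.75, CA = 2.31, MN = 1.61, CU = 1.40, CO = 1.52,
                NI = 1.63)

#' Van der Waals radii for elements
#'
#' @param elements character vector of element symbols.
#' @param overrides optional named numeric vector of radius overrides (A).
#' @return numeric radii (A); unknown elements without an override are an
#'   error.
#' @export
atomRadii <- function(elements, overrides = NULL) {
  tab <- .vdw_radii
  if (!is.null(overrides)) tab[toupper(names(overrides))] <- overrides
  r <- tab[toupper(elements)]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "),
         "; supply an override")
  unname(r)
}

# Deterministic quasi-uniform sphere points (golden-spiral construction).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Shrake-Rupley engine on bare coordinates: per-sphere exposed area.
.sasa_engine <- function(xyz, radii, probe = 1.4, n_points = 960L) {
  n <- nrow(xyz)
  if (n == 0L) return(numeric(0))
  R <- radii + probe
  pts <- .sphere_points(n_points)
  out <- numeric(n)
  # pairwise neighbor lists via squared distances
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    if (!length(nb)) {
      out[i] <- 4 * pi * R[i]^2
      next
    }
    sp <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 > R[j]^2
      if (!any(exposed)) break
    }
    out[i] <- 4 * pi * R[i]^2 * sum(exposed) / n_points
  }
  out
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals surface by testing a
#' deterministic quasi-uniform point set on each atom's expanded sphere
#' against all neighboring expanded spheres. Hydrogens are ignored; flagged
#' heteroatoms (waters, detergents) are excluded unless \code{het = TRUE}.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param probe probe radius in A (default 1.4, water).
#' @param n_points sphere test points per atom (>= 92; default 960).
#' @param chains restrict to these chain ids (default: all).
#' @param radii named radius overrides passed to \code{\link{atomRadii}}.
#' @param het include flagged heteroatoms.
#' @return data.frame with the selected atoms' chain, resno, resid, name and
#'   \code{sasa} (A^2).
#' @export
computeSasa <- function(model, probe = 1.4, n_points = 960L, chains = NULL,
                        radii = NULL, het = FALSE) {
  if (probe < 0) stop("probe radius must be >= 0")
  if (n_points < 92L) stop("n_points must be >= 92")
  idx <- selectAtoms(model, chain = chains, het = het)
  a <- atoms(model)[idx, , drop = FALSE]
  keep <- !a$element %in% c("H", "D")
  a <- a[keep, , drop = FALSE]
  if (!nrow(a)) stop("no atoms selected for SASA")
  r <- atomRadii(a$element, overrides = radii)
  sasa <- .sasa_engine(as.matrix(a[, c("x", "y", "z")]), r, probe,
                       as.integer(n_points))
  data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
             name = a$name, sasa = sasa, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Buried surface area between two chain groups
#'
#' BSA = (SASA(A alone) + SASA(B alone) - SASA(A and B together)) / 2,
#' the PISA-style halved interface-area convention; the un-halved
#' delta-SASA is returned alongside. With a site filter, the per-atom
#' delta-SASA is summed only over the filter's receptor residues (group A)
#' and chemokine residues (group B) before halving.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param chains_a,chains_b disjoint, non-empty chain-id groups. When a CRS
#'   site filter is used, group A is the receptor side.
#' @param site optional residue filter: a list with integer vectors
#'   \code{receptor} and \code{chemokine} (e.g. one element of a
#'   \linkS4class{SitePartition}).
#' @param probe,n_points,radii as in \code{\link{computeSasa}}.
#' @param detail return per-residue delta-SASA alongside the totals.
#' @return with \code{detail = FALSE}, a named numeric vector
#'   (\code{buried_area}, \code{delta_sasa}); with \code{detail = TRUE}, a
#'   list also carrying the per-residue table.
#' @export
buriedArea <- function(model, chains_a, chains_b, site = NULL, probe = 1.4,
                       n_points = 960L, radii = NULL, detail = FALSE) {
  if (!length(chains_a) || !length(chains_b))
    stop("both chain groups must be non-empty")
  if (length(intersect(chains_a, chains_b)))
    stop("chain groups must be disjoint")
  a <- atoms(model)
  grab <- function(ch) {
    idx <- selectAtoms(model, chain = ch)
    sub <- a[idx, , drop = FALSE]
    sub[!sub$element %in% c("H", "D"), , drop = FALSE]
  }
  A <- grab(chains_a)
  B <- grab(chains_b)
  if (!nrow(A) || !nrow(B)) stop("a chain group selected no atoms")
  rA <- atomRadii(A$element, overrides = radii)
  rB <- atomRadii(B$element, overrides = radii)
  xyzA <- as.matrix(A[, c("x", "y", "z")])
  xyzB <- as.matrix(B[, c("x", "y", "z")])
  sA <- .sasa_engine(xyzA, rA, probe, n_points)
  sB <- .sasa_engine(xyzB, rB, probe, n_points)
  sAB <- .sasa_engine(rbind(xyzA, xyzB), c(rA, rB), probe, n_points)
  dA <- sA - sAB[seq_len(nrow(A))]
  dB <- sB - sAB[nrow(A) + seq_len(nrow(B))]
  if (!is.null(site)) {
    if (!all(c("receptor", "chemokine") %in% names(site)))
      stop("site filter must have 'receptor' and 'chemokine' residue sets")
    out_a <- setdiff(site$receptor, A$resno)
    out_b <- setdiff(site$chemokine, B$resno)
    if (length(out_a) || length(out_b))
      stop("site filter references residues outside the groups: ",
           paste(c(out_a, out_b), collapse = ", "))
    dA[!A$resno %in% site$receptor] <- 0
    dB[!B$resno %in% site$chemokine] <- 0
  }
  dsasa <- sum(dA) + sum(dB)
  totals <- c(buried_area = dsasa / 2, delta_sasa = dsasa)
  if (!detail) return(totals)
  res <- rbind(
    data.frame(chain = A$chain, resno = A$resno, resid = A$resid,
               dsasa = dA, stringsAsFactors = FALSE),
    data.frame(chain = B$chain, resno = B$resno, resid = B$resid,
               dsasa = dB, stringsAsFactors = FALSE))
  per_res <- stats::aggregate(dsasa ~ chain + resno + resid, data = res, sum)
  per_res <- per_res[order(per_res$chain, per_res$resno), ]
  rownames(per_res) <- NULL
  list(totals = totals, residue_dsasa = per_res)
}
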