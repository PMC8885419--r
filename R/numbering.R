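#' @include AllClasses.R structure-io.R
NULL

# Helix spans and x.50 anchor residues for human CCR1 (author numbering of
# the depositions). The TM2/TM3/TM6/TM7 anchors are pinned by the published
# assignments T86=2.56, W90=2.60, Y113=3.32, Y255=6.51, D280=7.32,
# E287=7.39, Y291=7.43; the remaining spans follow class-A / CC-receptor
# homology conventions and are approximate (overridable via a user map).
.ccr1_spans <- list(
  TM1 = list(start = 33L, end = 63L, anchor50 = 53L),
  TM2 = list(start = 68L, end = 96L, anchor50 = 80L),
  TM3 = list(start = 103L, end = 136L, anchor50 = 131L),
  TM4 = list(start = 147L, end = 171L, anchor50 = 158L),
  TM5 = list(start = 196L, end = 229L, anchor50 = 211L),
  TM6 = list(start = 234L, end = 265L, anchor50 = 254L),
  TM7 = list(start = 278L, end = 304L, anchor50 = 298L),
  H8  = list(start = 305L, end = 315L, anchor50 = 308L)
)
.ccr1_loops <- list(NT = c(1L, 32L), ICL1 = c(64L, 67L), ECL1 = c(97L, 102L),
                    ICL2 = c(137L, 146L), ECL2 = c(172L, 195L),
                    ICL3 = c(230L, 233L), ECL3 = c(266L, 277L),
                    CT = c(316L, 355L))

#' Residue identities at the published CCR1 anchor positions
#'
#' Used by \code{\link{assignNumbering}} to refuse silent misnumbering: if a
#' model's receptor chain does not carry these residue types at these
#' positions, the map does not belong to that receptor.
#'
#' @return named character vector (residue number -> three-letter code).
#' @export
ccr1Anchors <- function() {
  c(`86` = "THR", `90` = "TRP", `113` = "TYR", `255` = "TYR",
    `280` = "ASP", `287` = "GLU", `291` = "TYR")
}

#' Ballesteros-Weinstein numbering table for human CCR1
#'
#' One row per residue 1-355 with the segment label (NT, TM1-TM7, ECL1-3,
#' ICL1-3, H8, CT) and, for TM/H8 residues, the generic helix.position label
#' anchored at the published assignments (e.g. Y291 -> 7.43).
#'
#' @return data.frame with columns \code{resno}, \code{bw}, \code{segment}.
#' @export
ccr1Numbering <- function() {
  resno <- 1:355
  bw <- rep(NA_character_, length(resno))
  segment <- rep(NA_character_, length(resno))
  for (nm in names(.ccr1_loops)) {
    rng <- .ccr1_loops[[nm]]
    segment[resno >= rng[1] & resno <= rng[2]] <- nm
  }
  for (nm in names(.ccr1_spans)) {
    s <- .ccr1_spans[[nm]]
    idx <- resno >= s$start & resno <= s$end
    segment[idx] <- nm
    hel <- sub("TM", "", sub("H", "", nm))
    pos <- 50L + (resno[idx] - s$anchor50)
    bw[idx] <- sprintf("%s.%d", hel, pos)
  }
  data.frame(resno = resno, bw = bw, segment = segment,
             stringsAsFactors = FALSE)
}

#' Read a Ballesteros-Weinstein map from two-column delimited text
#'
#' Expects columns \code{resno} and \code{bw}; an optional third column
#' \code{segment} is honored. Residues absent from the map carry no BW label.
#'
#' @param file path to a tab- or whitespace-delimited text file.
#' @return data.frame with columns \code{resno}, \code{bw} and (if present)
#'   \code{segment}.
#' @export
readBWMap <- function(file) {
  df <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("resno", "bw") %in% names(df)))
    stop("BW map must have columns 'resno' and 'bw'")
  df$resno <- as.integer(df$resno)
  df
}

#' Annotate the receptor chain with segments and BW numbers
#'
#' Attaches a numbering table to the model, restricted to the residues
#' present on the receptor chain(s). Every receptor residue receives a
#' segment label; TM and H8 residues additionally receive a BW label. Anchor
#' residues are validated against the model: a mismatch (e.g. residue 291 not
#' a tyrosine under the CCR1 map) is an error, never a silent misnumbering.
#' The operation is idempotent.
#'
#' @param model a \linkS4class{StructureModel} with at least one chain whose
#'   role is \code{"receptor"}.
#' @param map numbering table as from \code{\link{ccr1Numbering}} or
#'   \code{\link{readBWMap}}; must cover every receptor residue in the model.
#' @param anchors named character vector of expected residue identities
#'   (number -> three-letter code), checked where the residue is present;
#'   \code{NULL} skips validation.
#' @return the model with its \code{numbering} slot populated.
#' @export
assignNumbering <- function(model, map = ccr1Numbering(),
                            anchors = ccr1Anchors()) {
  roles <- chainRoles(model)
  rec_chains <- names(roles)[roles == "receptor"]
  if (!length(rec_chains))
    stop("model has no chain with role 'receptor'")
  a <- atoms(model)
  rec <- a[a$chain %in% rec_chains & !a$het, ]
  res <- unique(rec[, c("resno", "resid")])
  if (!is.null(anchors)) {
    for (rn in names(anchors)) {
      found <- res$resid[res$resno == as.integer(rn)]
      if (length(found) && !anchors[[rn]] %in% found)
        stop("anchor mismatch: receptor residue ", rn, " is ",
             paste(found, collapse = "/"), " but the map expects ",
             anchors[[rn]], "; refusing to misnumber")
    }
  }
  missing <- setdiff(res$resno, map$resno)
  if (length(missing))
    stop("numbering map does not cover receptor residue(s): ",
         paste(sort(missing), collapse = ", "))
  num <- map[map$resno %in% res$resno, , drop = FALSE]
  if (!"segment" %in% names(num)) num$segment <- NA_character_
  model@numbering <- num[order(num$resno),
                         c("resno", "bw", "segment")]
  rownames(model@numbering) <- NULL
  model
}

# Receptor residue number carrying a given BW label, or NA.
bwResidue <- function(model, bw_label) {
  num <- numbering(model)
  hit <- num$resno[!is.na(num$bw) & num$bw == bw_label]
  if (length(hit)) hit[1] else NA_integer_
}
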