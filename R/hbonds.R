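#' @include AllClasses.R structure-io.R numbering.R sasa.R sites.R
NULL

# residue-specific donor / acceptor heavy-atom tables (protein chemistry)
.sc_donors <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                   HIS = c("ND1", "NE2"), TRP = "NE1", ASN = "ND2",
                   GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH",
                   CYS = "SG")
.sc_acceptors <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                      ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1",
                      TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD",
                      CYS = "SG")
.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

.is_donor <- function(resid, name, element) {
  bbN <- name == "N" & resid != "PRO"
  sc <- mapply(function(r, n) n %in% (.sc_donors[[r]] %||% character()),
               resid, name)
  generic <- !resid %in% .standard_aa & element %in% c("N", "S")
  bbN | sc | generic
}

.is_acceptor <- function(resid, name, element) {
  bbO <- name %in% c("O", "OXT")
  sc <- mapply(function(r, n) n %in% (.sc_acceptors[[r]] %||% character()),
               resid, name)
  generic <- !resid %in% .standard_aa & element %in% c("O", "S")
  bbO | sc | generic
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect hydrogen bonds by geometric criteria
#'
#' Enumerates donor/acceptor heavy-atom pairs (N/O/S chemistry) within the
#' distance cutoff. When the donor carries resolved hydrogens, the
#' donor-H...acceptor angle must additionally pass the angle cutoff;
#' structures deposited without hydrogens (the cryo-EM norm) are assessed by
#' distance and chemistry alone. Same-residue pairs, covalent-range contacts
#' (< 2.2 A) and the backbone N(i)-O(i-1) peptide contact are excluded.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param dist_cutoff donor-acceptor heavy-atom distance cutoff (A).
#' @param angle_cutoff minimum D-H...A angle in degrees, applied only when
#'   hydrogens are present on the donor.
#' @param chains_a,chains_b optional chain-id groups; when both are given
#'   only bonds across the two groups are reported.
#' @return data.frame of bonds: donor and acceptor descriptors, heavy-atom
#'   \code{distance} (A) and \code{angle} (degrees; NA without hydrogens).
#' @export
detectHbonds <- function(model, dist_cutoff = 3.5, angle_cutoff = 120,
                         chains_a = NULL, chains_b = NULL) {
  if (dist_cutoff <= 0 || angle_cutoff <= 0)
    stop("cutoffs must be positive")
  a <- atoms(model)
  a <- a[!a$het, , drop = FALSE]
  heavy <- a[!a$element %in% c("H", "D"), , drop = FALSE]
  don <- heavy[.is_donor(heavy$resid, heavy$name, heavy$element), ,
               drop = FALSE]
  acc <- heavy[.is_acceptor(heavy$resid, heavy$name, heavy$element), ,
               drop = FALSE]
  empty <- data.frame(donor_chain = character(), donor_resno = integer(),
                      donor_resid = character(), donor_atom = character(),
                      acceptor_chain = character(),
                      acceptor_resno = integer(),
                      acceptor_resid = character(),
                      acceptor_atom = character(), distance = numeric(),
                      angle = numeric(), stringsAsFactors = FALSE)
  if (!nrow(don) || !nrow(acc)) return(empty)
  hyd <- a[a$element %in% c("H", "D"), , drop = FALSE]
  dx <- outer(don$x, acc$x, `-`)
  dy <- outer(don$y, acc$y, `-`)
  dz <- outer(don$z, acc$z, `-`)
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  hit <- which(dist <= dist_cutoff & dist >= 2.2, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- list()
  for (k in seq_len(nrow(hit))) {
    i <- hit[k, 1]; j <- hit[k, 2]
    D <- don[i, ]; A <- acc[j, ]
    same_res <- D$chain == A$chain && D$resno == A$resno &&
      D$insert == A$insert
    if (same_res) next
    # peptide-bond contact: backbone N of residue i vs backbone O of i-1
    if (D$name == "N" && A$name == "O" && D$chain == A$chain &&
        D$resno == A$resno + 1L) next
    if (!is.null(chains_a) && !is.null(chains_b)) {
      cross <- (D$chain %in% chains_a && A$chain %in% chains_b) ||
        (D$chain %in% chains_b && A$chain %in% chains_a)
      if (!cross) next
    }
    ang <- NA_real_
    if (nrow(hyd)) {
      hd <- hyd[hyd$chain == D$chain & hyd$resno == D$resno &
                  hyd$insert == D$insert, , drop = FALSE]
      if (nrow(hd)) {
        dH <- sqrt((hd$x - D$x)^2 + (hd$y - D$y)^2 + (hd$z - D$z)^2)
        hd <- hd[dH < 1.3, , drop = FALSE]  # hydrogens bonded to this donor
        if (nrow(hd)) {
          angs <- vapply(seq_len(nrow(hd)), function(m) {
            v1 <- c(D$x - hd$x[m], D$y - hd$y[m], D$z - hd$z[m])
            v2 <- c(A$x - hd$x[m], A$y - hd$y[m], A$z - hd$z[m])
            cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
            acos(pmin(1, pmax(-1, cosang))) * 180 / pi
          }, numeric(1))
          ang <- max(angs)
          if (ang < angle_cutoff) next
        }
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      donor_chain = D$chain, donor_resno = D$resno, donor_resid = D$resid,
      donor_atom = D$name, acceptor_chain = A$chain,
      acceptor_resno = A$resno, acceptor_resid = A$resid,
      acceptor_atom = A$name, distance = dist[i, j], angle = ang,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify the Y7.43 polar-network toggle state
#'
#' In the apo receptor the 7.43 tyrosine hydroxyl hydrogen-bonds toward TM2
#' (the 2.56 threonine and 2.60 tryptophan indole); on agonist engagement it
#' swings to hydrogen-bond with the 3.32 and 6.51 tyrosine hydroxyls. Each
#' alternate conformation of the 7.43 side chain (when the model was read
#' with \code{altloc = "all"}) is evaluated separately; rotamers supporting
#' both networks yield \code{"mixed"}.
#'
#' @param model an annotated \linkS4class{StructureModel} whose receptor
#'   chain carries residues at BW positions 2.56, 2.60, 3.32, 6.51 and 7.43.
#' @param dist_cutoff hydroxyl-partner heavy-atom distance cutoff (A).
#' @return one of \code{"tm2_engaged"}, \code{"tm3_tm6_engaged"},
#'   \code{"mixed"}, \code{"undetermined"}.
#' @export
polarNetworkState <- function(model, dist_cutoff = 3.5) {
  num <- numbering(model)
  if (!nrow(num)) stop("model is not annotated; run assignNumbering() first")
  need <- c("2.56", "2.60", "3.32", "6.51", "7.43")
  pos <- vapply(need, function(b) bwResidue(model, b), integer(1))
  if (anyNA(pos))
    stop("receptor lacks residues at BW position(s): ",
         paste(need[is.na(pos)], collapse = ", "))
  roles <- chainRoles(model)
  rec <- names(roles)[roles == "receptor"]
  a <- atoms(model)
  grabAtoms <- function(resno, names) {
    a[a$chain %in% rec & a$resno == resno & a$name %in% names & !a$het, ,
      drop = FALSE]
  }
  oh <- grabAtoms(pos[["7.43"]], "OH")
  if (!nrow(oh)) {
    warning("7.43 side-chain hydroxyl not resolved; state undetermined")
    return("undetermined")
  }
  tm2 <- rbind(grabAtoms(pos[["2.56"]], c("OG1", "OG")),
               grabAtoms(pos[["2.60"]], "NE1"))
  tm36 <- rbind(grabAtoms(pos[["3.32"]], "OH"),
                grabAtoms(pos[["6.51"]], "OH"))
  near <- function(p, partners) {
    if (!nrow(partners)) return(FALSE)
    d <- sqrt((partners$x - p[1])^2 + (partners$y - p[2])^2 +
                (partners$z - p[3])^2)
    any(d <= dist_cutoff)
  }
  states <- vapply(seq_len(nrow(oh)), function(i) {
    p <- c(oh$x[i], oh$y[i], oh$z[i])
    e2 <- near(p, tm2)
    e36 <- near(p, tm36)
    if (e2 && e36) "mixed" else if (e2) "tm2_engaged"
    else if (e36) "tm3_tm6_engaged" else "undetermined"
  }, character(1))
  states <- unique(states[states != "undetermined"])
  if (!length(states)) return("undetermined")
  if (length(states) > 1L || "mixed" %in% states) return("mixed")
  states
}

#' Full recognition-site interface report
#'
#' Runs the structural arm end to end on one complex: total and per-CRS
#' buried surface area between the receptor and chemokine chains,
#' per-residue delta-SASA, receptor-chemokine hydrogen bonds, and the Y7.43
#' polar-network state (\code{"undetermined"}, with a warning, when the
#' model cannot support the classification).
#'
#' @param model an annotated \linkS4class{StructureModel} with receptor and
#'   chemokine roles.
#' @param partition a \linkS4class{SitePartition}; default derived via
#'   \code{\link{defineSites}}.
#' @param probe,n_points,radii SASA settings (see \code{\link{computeSasa}}).
#' @param hbond_dist,hbond_angle hydrogen-bond cutoffs.
#' @return an \linkS4class{InterfaceReport}
#' @export
crsReport <- function(model, partition = NULL, probe = 1.4, n_points = 960L,
                      radii = NULL, hbond_dist = 3.5, hbond_angle = 120) {
  roles <- chainRoles(model)
  rec <- names(roles)[roles == "receptor"]
  chem <- names(roles)[roles == "chemokine"]
  if (!length(rec) || !length(chem))
    stop("model must have receptor and chemokine chain roles")
  if (is.null(partition)) partition <- defineSites(model)
  tot <- buriedArea(model, rec, chem, probe = probe, n_points = n_points,
                    radii = radii, detail = TRUE)
  site_bsa <- vapply(names(partition@sites), function(nm) {
    s <- partition@sites[[nm]]
    s$receptor <- intersect(s$receptor, atoms(model)$resno)
    s$chemokine <- intersect(s$chemokine, atoms(model)$resno)
    buriedArea(model, rec, chem, site = s, probe = probe,
               n_points = n_points, radii = radii)[["buried_area"]]
  }, numeric(1))
  hb <- detectHbonds(model, dist_cutoff = hbond_dist,
                     angle_cutoff = hbond_angle, chains_a = rec,
                     chains_b = chem)
  state <- tryCatch(polarNetworkState(model),
                    error = function(e) {
                      warning("polar-network state undetermined: ",
                              conditionMessage(e))
                      "undetermined"
                    })
  new("InterfaceReport",
      total_buried_area = unname(tot$totals[["buried_area"]]),
      total_delta_sasa = unname(tot$totals[["delta_sasa"]]),
      site_buried_area = site_bsa, residue_dsasa = tot$residue_dsasa,
      hbonds = hb, network_state = state)
}
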