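#' @include AllClasses.R
NULL

.water_names <- c("HOH", "WAT", "DOD")
# common cryo-EM detergent / lipid heterogroups excluded from interfaces
.detergent_names <- c("LMN", "CLR", "CHS", "GDN", "PLM", "OLA", "OLC",
                      "POV", "PC1", "Y01", "LDA", "BOG", "DDM")

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses atomic coordinates into a \linkS4class{StructureModel}. Waters and
#' ligand/detergent heteroatoms are retained but flagged (\code{het} column)
#' and excluded from interface computations by default. Alternate locations
#' are resolved according to \code{altloc}: the default keeps, per
#' (chain, residue, atom name), the altloc with the highest occupancy,
#' breaking ties in favor of altloc \code{"A"} (alphabetical).
#'
#' @param source path to a coordinate file.
#' @param format \code{"pdb"} or \code{"mmcif"}; default guessed from the
#'   file extension.
#' @param altloc \code{"occupancy"} (default policy above), \code{"all"}
#'   (keep every altloc; SASA and H-bond routines then see duplicated sites),
#'   or a single altloc letter to keep (plus blank-altloc atoms).
#' @param chain_roles optional named character vector mapping chain ids to
#'   \code{"receptor"}, \code{"chemokine"} or \code{"other"}.
#' @return a \linkS4class{StructureModel}
#' @export
readStructure <- function(source, format = c("guess", "pdb", "mmcif"),
                          altloc = "occupancy", chain_roles = character()) {
  format <- match.arg(format)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(source))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif",
                     mmcif = "mmcif",
                     stop("cannot guess format from extension '", ext,
                          "'; pass format explicitly"))
  }
  parsed <- tryCatch(
    switch(format,
           pdb = bio3d::read.pdb(source, verbose = FALSE),
           mmcif = bio3d::read.cif(source, verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", source,
                             "': ", conditionMessage(e)))
  a <- parsed$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- substr(gsub("[0-9 ']", "", a$elety), 1, 1)
  elem <- toupper(trimws(elem))
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    element = elem,
    resid = trimws(a$resid),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    chain = ifelse(is.na(a$chain), "", a$chain),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt),
    b = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE)
  atoms$het <- a$type == "HETATM" | atoms$resid %in%
    c(.water_names, .detergent_names)
  atoms <- resolveAltloc(atoms, altloc)
  model <- new("StructureModel", atoms = atoms,
               chain_roles = .fillRoles(chain_roles, unique(atoms$chain)))
  model
}

.fillRoles <- function(chain_roles, chains) {
  roles <- stats::setNames(rep("other", length(chains)), chains)
  if (length(chain_roles)) {
    unknown <- setdiff(names(chain_roles), chains)
    if (length(unknown))
      stop("chain_roles names chains absent from the structure: ",
           paste(unknown, collapse = ", "))
    roles[names(chain_roles)] <- chain_roles
  }
  roles
}

# Resolve alternate locations on an atom table.
resolveAltloc <- function(atoms, policy = "occupancy") {
  if (identical(policy, "all")) return(atoms)
  has_alt <- atoms$alt != ""
  if (!any(has_alt)) return(atoms)
  if (identical(policy, "occupancy")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
    # order: higher occupancy first, then altloc letter ('A' wins ties)
    ord <- order(key, -atoms$o, atoms$alt)
    keep <- !duplicated(key[ord])
    atoms <- atoms[ord[keep], ]
    atoms <- atoms[order(atoms$serial), ]
  } else if (is.character(policy) && nchar(policy) == 1L) {
    atoms <- atoms[!has_alt | atoms$alt == policy, ]
  } else stop("unknown altloc policy")
  rownames(atoms) <- NULL
  atoms
}

#' Write a StructureModel as a minimal PDB file
#'
#' @param model a \linkS4class{StructureModel}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeStructure <- function(model, file) {
  a <- atoms(model)
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, eleno = a$serial,
                   elety = a$name, chain = ifelse(a$chain == "", " ", a$chain),
                   insert = ifelse(a$insert == "", "", a$insert),
                   alt = ifelse(a$alt == "", "", a$alt),
                   o = a$o, b = a$b, elesy = a$element)
  invisible(file)
}

#' Select atom indices of a StructureModel
#'
#' Vectorized filter over the atom table; any argument left \code{NULL} does
#' not constrain. Hetero atoms (waters, detergents, flagged ligands) are
#' excluded unless \code{het = TRUE}.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param chain,resno,name,element,role optional filters (role refers to the
#'   chain-role map).
#' @param het include flagged heteroatoms? Default \code{FALSE}.
#' @return integer row indices into \code{atoms(model)}.
#' @export
selectAtoms <- function(model, chain = NULL, resno = NULL, name = NULL,
                        element = NULL, role = NULL, het = FALSE) {
  a <- atoms(model)
  keep <- rep(TRUE, nrow(a))
  if (!het) keep <- keep & !a$het
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(role)) {
    roles <- chainRoles(model)
    keep <- keep & a$chain %in% names(roles)[roles %in% role]
  }
  which(keep)
}

# Coordinate matrix for selected atoms.
coords <- function(model, idx = NULL) {
  a <- atoms(model)
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}
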