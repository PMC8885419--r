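# Synthetic structure builders shared across tests. Geometry is minimal but
# chemically labelled so that numbering, site, H-bond and angle code paths
# see realistic atom/residue names.

atom_df <- function(name, element, resid, resno, chain, x, y, z,
                    alt = "", o = 1, het = FALSE) {
  data.frame(serial = NA_integer_, name = unname(name),
             element = unname(element), resid = unname(resid),
             resno = as.integer(unname(resno)), insert = "",
             chain = unname(chain), x = unname(x), y = unname(y),
             z = unname(z), o = o, alt = alt, b = 0,
             het = het, stringsAsFactors = FALSE)
}

mk_model <- function(..., roles) {
  a <- do.call(rbind, list(...))
  a$serial <- seq_len(nrow(a))
  new("StructureModel", atoms = a, chain_roles = roles)
}

# Residue builders: backbone plus the side-chain atoms the classifiers use.
res_tyr <- function(resno, chain, origin, oh_at, alt = "") {
  # ring centroid midway between CB and OH; six ring atoms collapsed onto a
  # small hexagon around it (distances are what matter, not ideal geometry)
  cb <- origin + c(0, 0, 1.5)
  mid <- (cb + oh_at) / 2
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  ring <- t(vapply(seq_along(ring_names), function(i) {
    ang <- 2 * pi * i / 6
    mid + 0.8 * c(cos(ang), sin(ang), 0)
  }, numeric(3)))
  rbind(
    atom_df(c("N", "CA", "CB"), c("N", "C", "C"), "TYR", resno, chain,
            c(origin[1] - 1.4, origin[1], cb[1]),
            c(origin[2], origin[2], cb[2]),
            c(origin[3], origin[3], cb[3]), alt = alt),
    atom_df(c("C", "O"), c("C", "O"), "TYR", resno, chain,
            origin[1] + 1.4, origin[2] + c(0, 1), origin[3], alt = alt),
    atom_df(ring_names, rep("C", 6), "TYR", resno, chain,
            ring[, 1], ring[, 2], ring[, 3], alt = alt),
    atom_df("OH", "O", "TYR", resno, chain, oh_at[1], oh_at[2], oh_at[3],
            alt = alt))
}

res_simple <- function(resid, resno, chain, origin, extra_names = character(),
                       extra_elements = character(), extra_xyz = NULL) {
  bb <- atom_df(c("N", "CA", "C", "O"), c("N", "C", "C", "O"), resid, resno,
                chain, origin[1] + c(-1.4, 0, 1.4, 1.4),
                origin[2] + c(0, 0, 0, 1), origin[3])
  if (!length(extra_names)) return(bb)
  rbind(bb, atom_df(extra_names, extra_elements, resid, resno, chain,
                    extra_xyz[, 1], extra_xyz[, 2], extra_xyz[, 3]))
}

# Orthosteric pocket of the receptor in a chosen toggle state. Y291's
# hydroxyl is placed 2.8 A from the TM2 partners (apo), from the TM3/TM6
# tyrosine hydroxyls (engaged), in both rotamers as altlocs (mixed), or the
# residue is an alanine (ala).
mk_pocket <- function(state = c("apo", "engaged", "mixed", "ala")) {
  state <- match.arg(state)
  ch <- "R"
  # TM2 side at x ~ 0; TM3/TM6 side at x ~ 12
  t86 <- res_simple("THR", 86, ch, c(0, 0, 0),
                    extra_names = c("CB", "OG1", "CG2"),
                    extra_elements = c("C", "O", "C"),
                    extra_xyz = rbind(c(0, 1.5, 0), c(0, 2.2, 1.2),
                                      c(0, 2.2, -1.2)))
  w90 <- res_simple("TRP", 90, ch, c(0, 8, 0),
                    extra_names = c("CB", "CG", "CD1", "CD2", "NE1", "CE2",
                                    "CE3", "CZ2", "CZ3", "CH2"),
                    extra_elements = c("C", "C", "C", "C", "N", "C", "C",
                                      "C", "C", "C"),
                    extra_xyz = rbind(c(0, 9.5, 0), c(0, 10.6, 0.8),
                                      c(0, 10.9, 2.1), c(0, 11.8, 0.3),
                                      c(0, 12.1, 2.4), c(0, 12.6, 1.3),
                                      c(0, 12.2, -1.0), c(0, 13.9, 1.2),
                                      c(0, 13.5, -1.1), c(0, 14.3, 0.05)))
  y113 <- res_tyr(113, ch, c(12, 0, 0), c(12, 2.5, 0))
  y255 <- res_tyr(255, ch, c(12, 8, 0), c(12, 5.8, 0))
  # partner coordinates the 7.43 hydroxyl sits next to, per state
  oh_tm2 <- c(0, 2.2, 4.0)       # ~2.8 A above T86 OG1
  oh_tm36 <- c(12, 4.15, 2.4)    # ~2.8 A from both Y113 and Y255 OH
  y291 <- switch(state,
    apo = res_tyr(291, ch, c(4, 2, 3), oh_tm2),
    engaged = res_tyr(291, ch, c(9, 4, 2), oh_tm36),
    mixed = rbind(res_tyr(291, ch, c(4, 2, 3), oh_tm2, alt = "A"),
                  res_tyr(291, ch, c(9, 4, 2), oh_tm36, alt = "B")),
    ala = res_simple("ALA", 291, ch, c(6, 4, 2),
                     extra_names = "CB", extra_elements = "C",
                     extra_xyz = rbind(c(6, 5.5, 2))))
  mk_model(t86, w90, y113, y255, y291, roles = c(R = "receptor"))
}

# Minimal receptor-chemokine complex exercising the CRS partition: a
# CA-trace chemokine (residues 26-79 of the ligand) plus receptor residues
# covering the N terminus (17-26), the 7TM pocket near the chemokine
# N terminus, and CRS3-facing ECL2/ECL3/TM-tip residues.
mk_complex <- function(chem_shift = c(0, 0, 0)) {
  ch_r <- "R"; ch_l <- "L"
  chem_resno <- 26:79
  chem <- do.call(rbind, lapply(seq_along(chem_resno), function(i) {
    rn <- chem_resno[i]
    resid <- if (rn %in% c(33, 34, 56)) "CYS" else if (rn == 26) "PHE"
             else "GLY"
    # N-terminal residues (26-32) descend into the pocket (y -6 to -12);
    # the rest of the core lies above
    pos <- if (rn <= 32) c((rn - 26) * 1.5, -6 - (rn - 26), 0)
           else c((rn %% 10) * 1.8, 4 + (rn - 33) * 0.35, (rn %% 5))
    res_simple(resid, rn, ch_l, pos + chem_shift)
  }))
  nt <- do.call(rbind, lapply(17:26, function(rn) {
    resid <- if (rn == 24) "CYS" else "GLY"
    # runs alongside the chemokine core (y ~ 8)
    res_simple(resid, rn, ch_r, c((rn - 17) * 1.8, 8.5, 6))
  }))
  pocket_resno <- c(87, 90, 113, 280, 287, 291)
  pocket <- do.call(rbind, lapply(seq_along(pocket_resno), function(i) {
    rn <- pocket_resno[i]
    resid <- c(`87` = "LEU", `90` = "TRP", `113` = "TYR", `280` = "ASP",
               `287` = "GLU", `291` = "TYR")[as.character(rn)]
    # within ~4 A of the descending chemokine N-terminal segment
    res_simple(resid, rn, ch_r, c((i - 1) * 1.5, -8, 2.5))
  }))
  crs3_resno <- c(180, 185, 225, 260, 270)  # ECL2, ECL2, TM5 tip, TM6 tip, ECL3
  crs3 <- do.call(rbind, lapply(seq_along(crs3_resno), function(i) {
    res_simple("GLY", crs3_resno[i], ch_r, c((i - 1) * 2, 10, -4))
  }))
  mk_model(chem, nt, pocket, crs3,
           roles = c(R = "receptor", L = "chemokine"))
}

# Apply a rigid transform (rotation about axis by angle_deg, then shift) to
# the atoms of selected chains.
rotate_chain <- function(model, chain, angle_deg, axis = c(0, 0, 1),
                         center = c(0, 0, 0), shift = c(0, 0, 0)) {
  a <- atoms(model)
  sel <- a$chain %in% chain
  th <- angle_deg * pi / 180
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, center) %*% t(R), 2, center + shift, `+`)
  a$x[sel] <- xyz[, 1]; a$y[sel] <- xyz[, 2]; a$z[sel] <- xyz[, 3]
  model@atoms <- a
  model
}

# Leucine-like residue with flanking glycines; the CB->CG vector lies
# perpendicular to the CA-CB axis so a chi rotation of `swing_deg` about
# that axis changes the direction vector by exactly swing_deg.
mk_rotamer <- function(swing_deg = 0) {
  ch <- "R"
  flank <- do.call(rbind, lapply(c(7:9, 11:13), function(rn) {
    res_simple("GLY", rn, ch, c((rn - 10) * 3, 0, 0))
  }))
  th <- swing_deg * pi / 180
  cg <- c(2 * cos(th), 2 * sin(th), 1.5)
  res10 <- rbind(
    atom_df(c("N", "CA", "C", "O"), c("N", "C", "C", "O"), "LEU", 10, ch,
            c(-1.4, 0, 1.4, 1.4), c(0, 0, 0, 1), 0),
    atom_df(c("CB", "CG"), c("C", "C"), "LEU", 10, ch,
            c(0, cg[1]), c(0, cg[2]), c(1.5, cg[3])))
  mk_model(flank, res10, roles = c(R = "receptor"))
}

# quick FitResult factory for bias-equation tests
mk_fit <- function(emax, log10_ec50, baseline = 0, converged = TRUE,
                   degenerate = FALSE, ligand = "lig", pathway = "p") {
  new("FitResult", ligand = ligand, pathway = pathway,
      estimates = c(baseline = baseline, emax = emax,
                    log10_ec50 = log10_ec50, hill = 1),
      se = c(baseline = NA_real_, emax = NA_real_, log10_ec50 = NA_real_,
             hill = NA_real_),
      converged = converged, degenerate = degenerate,
      n_experiments_used = 1L)
}
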