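test_that("Shrake-Rupley engine matches analytic spheres and the oracle", {
  one <- mk_model(atom_df("C", "C", "TOY", 1, "A", 0, 0, 0),
                  roles = c(A = "other"))
  s <- computeSasa(one, n_points = 960)
  expect_equal(s$sasa, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.005)
  # two atoms beyond mutual reach keep their full spheres
  two <- mk_model(atom_df("C", "C", "TOY", 1, "A", 0, 0, 0),
                  atom_df("C", "C", "TOY", 2, "A", 10, 0, 0),
                  roles = c(A = "other"))
  s2 <- computeSasa(two, n_points = 960)
  expect_equal(s2$sasa, rep(4 * pi * 3.1^2, 2), tolerance = 0.005)
  # hydrogens are ignored
  withH <- mk_model(atom_df("C", "C", "TOY", 1, "A", 0, 0, 0),
                    atom_df("H1", "H", "TOY", 1, "A", 1.1, 0, 0),
                    roles = c(A = "other"))
  expect_equal(nrow(computeSasa(withH)), 1L)
  # unknown element without override errors; override fixes it
  weird <- mk_model(atom_df("Q1", "Q", "TOY", 1, "A", 0, 0, 0),
                    roles = c(A = "other"))
  expect_error(computeSasa(weird), "radius")
  expect_equal(computeSasa(weird, radii = c(Q = 2))$sasa,
               4 * pi * 3.4^2, tolerance = 0.005)
  expect_error(computeSasa(one, n_points = 50), "92")
  # overlapping dimer agrees with the independent numerical oracle within 1%
  spec <- data.frame(element = c("C", "N"), x = c(0, 3.2), y = 0, z = 0,
                     chain = c("A", "B"))
  toy <- makeToyInterface(spec)
  s3 <- computeSasa(toy$model, n_points = 960)
  expect_equal(s3$sasa, toy$truth$sasa_complex, tolerance = 0.01)
  # point-count refinement changes fixtures by < 1%
  s4 <- computeSasa(toy$model, n_points = 4000)
  expect_true(all(abs(s3$sasa - s4$sasa) / s4$sasa < 0.01))
})

test_that("buried area follows the halved delta-SASA convention", {
  spec <- data.frame(element = c("C", "C", "C"),
                     x = c(0, 1.6, 4.4), y = 0, z = 0,
                     chain = c("A", "A", "B"))
  toy <- makeToyInterface(spec)
  ba <- buriedArea(toy$model, "A", "B")
  expect_equal(ba[["buried_area"]], toy$truth$buried_area,
               tolerance = 0.01 * max(1, toy$truth$buried_area))
  expect_equal(ba[["delta_sasa"]], 2 * ba[["buried_area"]])
  # symmetry in group order
  expect_equal(buriedArea(toy$model, "B", "A")[["buried_area"]],
               ba[["buried_area"]], tolerance = 1e-9)
  # non-contacting chains bury nothing
  far <- makeToyInterface(data.frame(element = c("C", "C"), x = c(0, 30),
                                     y = 0, z = 0, chain = c("A", "B")))
  expect_equal(buriedArea(far$model, "A", "B")[["buried_area"]], 0)
  expect_error(buriedArea(toy$model, "A", "A"), "disjoint")
  expect_error(buriedArea(toy$model, "A", "B",
                          site = list(receptor = 99, chemokine = 3)),
               "outside")
})

test_that("site filtering and spectator chains behave correctly", {
  model <- assignNumbering(mk_complex(), anchors = NULL)
  part <- defineSites(model)
  full <- buriedArea(model, "R", "L", n_points = 240)
  site_bsa <- vapply(names(part@sites), function(nm)
    buriedArea(model, "R", "L", site = part@sites[[nm]],
               n_points = 240)[["buried_area"]], numeric(1))
  expect_true(all(site_bsa >= -1e-9))
  # sites need not tile the interface but cannot exceed it materially
  expect_lte(sum(site_bsa), full[["buried_area"]] * 1.05 + 1e-6)
  # a far-away spectator chain leaves areas unchanged
  spec_atoms <- atom_df("CA", "C", "GLY", 1, "Z", 500, 500, 500)
  a2 <- rbind(atoms(model), transform(spec_atoms, serial = 9999L))
  model2 <- new("StructureModel", atoms = a2,
                chain_roles = c(chainRoles(model), Z = "other"))
  model2@numbering <- numbering(model)
  expect_equal(buriedArea(model2, "R", "L", n_points = 240), full)
})

test_that("hydrogen bonds obey distance, chemistry and angle rules", {
  # ideal backbone N-H...O=C geometry at 2.9 A, 180 degrees
  donor <- rbind(
    atom_df(c("N", "CA", "C", "O"), c("N", "C", "C", "O"), "ALA", 10, "A",
            c(0, 1.2, 2.0, 2.0), c(0, 0.8, 0, 0.1), c(0, 0, 0, 1.2)),
    atom_df("H", "H", "ALA", 10, "A", -1.0, 0, 0))
  acceptor <- atom_df(c("C", "O"), c("C", "O"), "GLY", 30, "B",
                      c(-4.1, -2.9), 0, 0)
  m <- mk_model(donor, acceptor, roles = c(A = "other", B = "other"))
  hb <- detectHbonds(m)
  expect_true(any(hb$donor_atom == "N" & hb$acceptor_atom == "O" &
                    abs(hb$distance - 2.9) < 1e-6))
  expect_equal(hb$angle[hb$donor_atom == "N"][1], 180, tolerance = 1e-6)
  # beyond cutoff -> absent
  far <- mk_model(atom_df("N", "N", "ALA", 1, "A", 0, 0, 0),
                  atom_df("O", "O", "GLY", 2, "B", 3.6, 0, 0),
                  roles = c(A = "other", B = "other"))
  expect_equal(nrow(detectHbonds(far, dist_cutoff = 3.5)), 0L)
  expect_equal(nrow(detectHbonds(far, dist_cutoff = 3.7)), 1L)
  # bad angle vetoes when hydrogens are present
  bent <- mk_model(rbind(atom_df("N", "N", "ALA", 1, "A", 0, 0, 0),
                         atom_df("H", "H", "ALA", 1, "A", 0, 1.0, 0)),
                   atom_df("O", "O", "GLY", 2, "B", 2.9, 0, 0),
                   roles = c(A = "other", B = "other"))
  expect_equal(nrow(detectHbonds(bent)), 0L)  # D-H...A ~ 71 deg < 120
  expect_error(detectHbonds(far, dist_cutoff = -1), "positive")
  # chemokine H27 backbone amide vs receptor E287 carboxylate analogue
  pair <- mk_model(
    res_simple("HIS", 27, "L", c(0, 0, 0)),
    res_simple("GLU", 287, "R", c(0, 5, 0),
               extra_names = c("CB", "CG", "CD", "OE1", "OE2"),
               extra_elements = c("C", "C", "C", "O", "O"),
               extra_xyz = rbind(c(0, 6.5, 0), c(0.3, 5.0, 1.0),
                                 c(0.4, 3.5, 1.4), c(0.5, 2.0, 1.5),
                                 c(0.2, 3.8, 2.6))),
    roles = c(R = "receptor", L = "chemokine"))
  hb2 <- detectHbonds(pair, chains_a = "R", chains_b = "L")
  expect_true(any(hb2$donor_resno == 27 & hb2$donor_atom == "N" &
                    hb2$acceptor_resno == 287 &
                    hb2$acceptor_atom %in% c("OE1", "OE2")))
})

test_that("polar-network toggle states are classified per rotamer", {
  classify <- function(state) {
    m <- mk_pocket(state)
    m <- assignNumbering(m, anchors = if (state == "ala") NULL
                                      else ccr1Anchors())
    polarNetworkState(m)
  }
  expect_identical(classify("apo"), "tm2_engaged")
  expect_identical(classify("engaged"), "tm3_tm6_engaged")
  expect_identical(classify("mixed"), "mixed")
  expect_warning(st <- classify("ala"), "undetermined")
  expect_identical(st, "undetermined")
  # missing anchor residue is a hard precondition
  m <- assignNumbering(mk_pocket("apo"))
  m@atoms <- m@atoms[m@atoms$resno != 86, ]
  m@numbering <- m@numbering[m@numbering$resno != 86, ]
  expect_error(polarNetworkState(m), "2.56")
})

test_that("the full interface report assembles all components", {
  model <- assignNumbering(mk_complex(), anchors = NULL)
  rep <- suppressWarnings(crsReport(model, n_points = 240))
  expect_s4_class(rep, "InterfaceReport")
  expect_gte(rep@total_buried_area, 0)
  expect_setequal(names(rep@site_buried_area),
                  c("CRS1", "CRS1.5", "CRS2", "CRS3"))
  expect_lte(sum(rep@site_buried_area), rep@total_buried_area * 1.05 + 1e-6)
  expect_true(all(c("chain", "resno", "dsasa") %in%
                    names(rep@residue_dsasa)))
  # pocket lacks the toggle tyrosines here: state degrades gracefully
  expect_identical(rep@network_state, "undetermined")
})
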