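mini_cif <- function(path) {
  writeLines(c(
    "data_test", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . GLY A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 GLY A N 1",
    "ATOM 2 C CA . GLY A 1 1 ? 1.450 0.000 0.000 1.00 0.00 ? 1 GLY A CA 1",
    "ATOM 3 C C . GLY A 1 1 ? 2.000 1.400 0.000 1.00 0.00 ? 1 GLY A C 1",
    "ATOM 4 O O . GLY A 1 1 ? 1.500 2.300 0.700 1.00 0.00 ? 1 GLY A O 1"),
    path)
  path
}

test_that("structures round-trip and cross-format reads agree", {
  model <- mk_pocket("apo")
  tmp <- tempfile(fileext = ".pdb")
  writeStructure(model, tmp)
  back <- readStructure(tmp, chain_roles = c(R = "receptor"))
  expect_equal(nrow(atoms(back)), nrow(atoms(model)))
  expect_equal(atoms(back)$x, atoms(model)$x, tolerance = 1e-3)
  expect_equal(atoms(back)$resno, atoms(model)$resno)
  expect_identical(atoms(back)$name, atoms(model)$name)
  # same content read from PDB and mmCIF agrees
  cif <- mini_cif(tempfile(fileext = ".cif"))
  # upstream mmCIF reader warns about its beta status and the (absent)
  # helix/sheet records of this minimal file
  m_cif <- suppressWarnings(readStructure(cif))
  pdb <- tempfile(fileext = ".pdb")
  writeStructure(m_cif, pdb)
  m_pdb <- readStructure(pdb)
  expect_equal(nrow(atoms(m_pdb)), nrow(atoms(m_cif)))
  expect_equal(as.matrix(atoms(m_pdb)[, c("x", "y", "z")]),
               as.matrix(atoms(m_cif)[, c("x", "y", "z")]),
               tolerance = 1e-3)
  expect_error(readStructure(tmp, format = "bogus"))
})

test_that("altloc resolution keeps highest occupancy, ties to 'A'", {
  a <- rbind(
    atom_df("CA", "C", "GLY", 1, "A", 0, 0, 0, alt = "A", o = 0.4),
    atom_df("CA", "C", "GLY", 1, "A", 1, 0, 0, alt = "B", o = 0.6),
    atom_df("CA", "C", "GLY", 2, "A", 2, 0, 0, alt = "A", o = 0.5),
    atom_df("CA", "C", "GLY", 2, "A", 3, 0, 0, alt = "B", o = 0.5))
  a$serial <- 1:4
  res <- ChemokineBias:::resolveAltloc(a, "occupancy")
  expect_equal(nrow(res), 2L)
  expect_equal(res$alt[res$resno == 1], "B")  # higher occupancy wins
  expect_equal(res$alt[res$resno == 2], "A")  # equal occupancy: 'A'
  expect_equal(nrow(ChemokineBias:::resolveAltloc(a, "all")), 4L)
})

test_that("numbering assigns segments and BW labels at the known anchors", {
  num <- ccr1Numbering()
  expect_identical(num$bw[num$resno == 291], "7.43")
  expect_identical(num$bw[num$resno == 287], "7.39")
  expect_identical(num$bw[num$resno == 280], "7.32")
  expect_identical(num$bw[num$resno == 86], "2.56")
  expect_identical(num$bw[num$resno == 90], "2.60")
  expect_identical(num$bw[num$resno == 113], "3.32")
  expect_identical(num$bw[num$resno == 255], "6.51")
  expect_identical(num$segment[num$resno == 17], "NT")
  expect_true(is.na(num$bw[num$resno == 17]))
  # injective on TM residues
  tm <- num$bw[!is.na(num$bw)]
  expect_false(anyDuplicated(tm) > 0)

  model <- assignNumbering(mk_pocket("apo"))
  expect_identical(numbering(model)$bw[numbering(model)$resno == 291],
                   "7.43")
  # idempotent
  expect_identical(numbering(assignNumbering(model)), numbering(model))
  # anchor mismatch refuses to misnumber
  expect_error(assignNumbering(mk_pocket("ala")), "anchor mismatch")
  # shipped map file matches the in-code table
  map_file <- system.file("extdata", "ccr1_bw_map.tsv",
                          package = "ChemokineBias")
  shipped <- readBWMap(map_file)
  in_code <- ccr1Numbering()
  in_code <- in_code[!is.na(in_code$bw), ]
  expect_equal(shipped$resno, in_code$resno)
  expect_identical(shipped$bw, in_code$bw)
})

test_that("CRS partition follows the documented boundaries", {
  model <- assignNumbering(mk_complex(), anchors = NULL)
  part <- defineSites(model)
  s1 <- siteResidues(part, "CRS1")
  s15 <- siteResidues(part, "CRS1.5")
  s2 <- siteResidues(part, "CRS2")
  s3 <- siteResidues(part, "CRS3")
  # chemokine F26 precedes the first core cysteine => CRS2 chemokine set
  expect_true(26 %in% s2$chemokine)
  # 30s loop residues 50-57 sit in CRS3
  expect_true(all(50:57 %in% s3$chemokine))
  # receptor N terminus through residue 26, minus the CRS1.5 region
  expect_true(all(s1$receptor <= 26))
  expect_false(any(23:25 %in% s1$receptor))
  expect_setequal(s15$receptor, 23:25)
  # geometric pocket finds the residues placed against the chemokine N terminus
  expect_true(all(c(87, 90, 287, 291) %in% s2$receptor))
  # receptor sets pairwise disjoint (CRS1 vs CRS3 spot check + validity)
  expect_length(intersect(s1$receptor, s3$receptor), 0L)
  rec_all <- unlist(lapply(part@sites, `[[`, "receptor"))
  expect_false(anyDuplicated(rec_all) > 0)
  # serialized partition round-trips
  tmp <- tempfile(fileext = ".json")
  writeSites(part, tmp)
  expect_equal(readSites(tmp)@sites, part@sites)
  # partition is a pure function of model + config
  expect_equal(defineSites(model)@sites, part@sites)
  # absent residues are reported
  expect_error(defineSites(model, crsConfig(loop30s = 300:305)), "absent")
})
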