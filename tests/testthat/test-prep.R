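# Ligand 3D preparation and receptor/binding-site handling.

test_that("ligand variants are protonated, embedded and geometry-checked", {
  # secondary amine at pH 7.4 -> a protonated variant is present
  pl <- prepare_ligand_variants(list(x = "CC(C)NCC(O)COc1ccccc1"), pH = 7.4)
  expect_gte(length(pl), 1)
  expect_true(any(vapply(pl, function(v) v$formal_charge == 1, TRUE)))
  # neutral benzene: exactly one variant, finite coordinates
  plb <- prepare_ligand_variants(list(x = "c1ccccc1"), pH = 7.4)
  expect_identical(length(plb), 1L)
  expect_true(all(is.finite(plb[[1]]$coords)))
})

test_that("cis designs keep their Z azo dihedral through minimization", {
  d <- run_azologization("c1ccccc1CCc1ccc(O)cc1",
                         build_rule_set("typical_azologization"))
  pl <- prepare_ligand_variants(d[1, ], pH = 7.4, max_variants = 1)
  iso <- vapply(pl, `[[`, "", "isomer")
  expect_setequal(unique(iso), c("trans", "cis"))
  for (v in pl) {
    target <- if (v$isomer == "cis") 0 else 180
    dev <- abs(abs(v$azo_dihedral) - target)
    expect_lte(min(dev, 360 - dev), 30)
  }
})

test_that("minimization never increases the force-field energy kept", {
  pl <- prepare_ligand_variants(list(x = "CCCCc1ccccc1O"), pH = 7.4)
  for (v in pl) expect_lte(v$energy, v$energy_start + 1e-6)
})

test_that("local structures parse with chains, het groups and metadata", {
  pdb <- toy_receptor_pocket(tempfile(fileext = ".pdb"))
  st <- load_structure(pdb)
  expect_setequal(unique(st$pdb$atom$chain), c("A", "B"))
  expect_true("LIG" %in% st$pdb$atom$resid)
  expect_true(is.na(st$resolution))        # no resolution record, no error
  expect_error(load_structure(tempfile()), "not found")
  bad <- tempfile(fileext = ".pdb")
  writeLines("not a pdb at all", bad)
  expect_error(suppressWarnings(load_structure(bad)), "cannot parse|PDB")
})

test_that("receptor preparation selects the chain, strips waters, keeps the reference", {
  pdb <- toy_receptor_pocket(tempfile(fileext = ".pdb"))
  st <- load_structure(pdb)
  rec <- prepare_receptor(st, "A", keep_het_ids = "LIG")
  expect_true(all(rec$atom$chain == "A"))
  expect_false("HOH" %in% c(rec$atom$resid, rec$het$resid))
  expect_identical(unique(rec$het$resid), "LIG")
  expect_error(prepare_receptor(st, "Z"), "available chains: A, B")
  # idempotent
  rec2 <- prepare_receptor(rec, "A", keep_het_ids = "LIG")
  expect_identical(rec2$atom, rec$atom)
  expect_identical(rec2$het, rec$het)
})

test_that("binding sites are centered on the reference with a covering radius", {
  one <- define_binding_site(reference_ligand = matrix(c(0, 0, 0), 1, 3),
                             extra_radius = 2.0)
  expect_equal(one$center, c(0, 0, 0))
  expect_equal(one$radius, 2.0)
  two <- define_binding_site(reference_ligand = matrix(c(0, 0, 0, 2, 0, 0),
                                                       2, 3, byrow = TRUE),
                             extra_radius = 2.0)
  expect_equal(two$center, c(1, 0, 0))
  expect_equal(two$radius, 3.0)
  # containment on the pocket fixture
  pdb <- toy_receptor_pocket(tempfile(fileext = ".pdb"))
  rec <- prepare_receptor(load_structure(pdb), "A", keep_het_ids = "LIG")
  site <- define_binding_site(rec, "LIG")
  xyz <- as.matrix(rec$het[, c("x", "y", "z")])
  expect_true(all(sqrt(rowSums(sweep(xyz, 2, site$center)^2)) <= site$radius))
  expect_error(define_binding_site(rec, "XYZ"), "not found")
  f <- tempfile()
  write_binding_site(site, f)
  expect_match(readLines(f)[1], "^center ")
})
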