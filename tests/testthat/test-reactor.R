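# Transformation enumeration: rule set construction, azologization,
# azoextension, naphthalene replacement, E/Z pairs, dedup, descriptors and
# atom mapping.

test_that("rule set construction validates its inputs and its SMARTS", {
  rules <- build_rule_set()
  expect_s3_class(rules, "psw_rule_set")
  expect_true(validate_rule_set(rules))
  expect_true(all(grepl("N=N", rules$reaction)))
  expect_error(build_rule_set("no_such_category"), "invalid rule category")
  expect_error(build_rule_set(character(0)), "invalid rule category")
  expect_error(build_rule_set(max_replaced_substituent = 5), "1, 2 or 3")
  f <- tempfile()
  write_rule_set(rules, f)
  expect_identical(length(readLines(f)), nrow(rules))
})

test_that("every toy-library case yields exactly its expected product set", {
  lib <- toy_library()
  for (i in seq_len(nrow(lib))) {
    rules <- build_rule_set(strsplit(lib$categories[i], ";")[[1]],
                            naphthalene_mode = lib$naphthalene_mode[i])
    d <- if (grepl("azoextension", lib$categories[i]))
      run_azoextension(lib$smiles[i], rules)
    else run_azologization(lib$smiles[i], rules)
    dd <- deduplicate_designs(d)
    expect_identical(nrow(dd), lib$expected_count[i], info = lib$name[i])
    if (!is.na(lib$expected_products[i])) {
      expected <- canonical_smiles(strsplit(lib$expected_products[i], ";")[[1]])
      expect_setequal(dd$product_smiles_flat, expected)
    }
  }
})

test_that("heavy-atom bookkeeping holds per rule category", {
  cases <- list(
    list("c1ccccc1CCc1ccccc1", "typical_azologization", 0L),    # 2-atom -> N2
    list("c1ccccc1-c1ccccc1", "atypical_azologization", 2L),    # 0-atom adds 2
    list("c1ccccc1Cc1ccccc1", "atypical_azologization", 1L),    # 1-atom adds 1
    list("Cc1ccccc1", "typical_azoextension", 8L))              # adds N2 + C6H5
  for (cs in cases) {
    rules <- build_rule_set(cs[[2]])
    d <- if (grepl("azoextension", cs[[2]])) run_azoextension(cs[[1]], rules)
         else run_azologization(cs[[1]], rules)
    d <- d[d$rule_name != "Azolog_3atom", , drop = FALSE]
    expect_gt(nrow(d), 0)
    expect_true(all(d$n_heavy_product - d$n_heavy_parent == cs[[3]]),
                info = cs[[2]])
  }
})

test_that("every product gains exactly one aromatic azo motif over its parent", {
  parents <- c("c1ccccc1CCc1ccccc1",                    # no azo
               "Cc1ccc(cc1)/N=N/c1ccc(CCc2ccccc2)cc1")  # one pre-existing azo
  rules <- build_rule_set(c("typical_azologization", "atypical_azologization",
                            "typical_azoextension"))
  for (p in parents) {
    d <- run_reactor(p, rules)
    expect_gt(nrow(d), 0)
    n0 <- count_azo_motifs(p)
    for (s in d$product_smiles_flat)
      expect_identical(count_azo_motifs(s), n0 + 1L, info = paste(p, "->", s))
  }
})

test_that("a pre-existing azo bond keeps its geometry; only the new bond is assigned", {
  parent <- "Cc1ccc(cc1)/N=N/c1ccc(CCc2ccccc2)cc1"
  d <- run_azologization(parent, build_rule_set("typical_azologization"))
  expect_identical(nrow(d), 1L)
  # both emitted isomers still contain the parent's E-configured azo bond:
  # stripping only the new bond's partner would break; instead check that the
  # trans and cis products differ exactly at one azo bond and share the rest
  expect_identical(strip_stereo(d$trans_smiles), strip_stereo(d$cis_smiles))
  expect_identical(count_azo_motifs(d$product_smiles_flat), 2L)
  # re-perceive geometries from the emitted isomers: the parent's E bond is
  # present in both, while only the new bond switches between E and Z
  geoms <- function(s) sort(unname(unlist(mol_from_smiles(s)$azo_geom)))
  expect_identical(geoms(d$trans_smiles), c("E", "E"))
  expect_identical(geoms(d$cis_smiles), c("E", "Z"))
})

test_that("trans/cis constitution identity holds for every emitted pair", {
  d <- run_reactor("CC(C)NCC(O)COc1ccc2ccccc2c1",
                   build_rule_set(c("naphthalene_azologization",
                                    "typical_azoextension")))
  expect_gt(nrow(d), 3)
  expect_identical(strip_stereo(d$trans_smiles), strip_stereo(d$cis_smiles))
  expect_identical(strip_stereo(d$trans_smiles), d$product_smiles_flat)
  expect_true(all(d$trans_smiles != d$cis_smiles))
})

test_that("enumeration is order-independent under atom renumbering", {
  variants <- c("c1ccccc1CCc1ccc(O)cc1",      # same molecule, three writings
                "Oc1ccc(CCc2ccccc2)cc1",
                "C(c1ccccc1)Cc1ccc(O)cc1")
  rules <- build_rule_set(c("typical_azologization", "typical_azoextension"))
  sets <- lapply(variants, function(s)
    sort(unique(deduplicate_designs(run_reactor(s, rules))$product_smiles_flat)))
  expect_identical(sets[[2]], sets[[1]])
  expect_identical(sets[[3]], sets[[1]])
})

test_that("deduplication is idempotent, monotone, and merges provenance", {
  d <- run_azoextension("c1ccccc1", build_rule_set("typical_azoextension"))
  expect_identical(nrow(d), 6L)
  dd <- deduplicate_designs(d)
  expect_identical(nrow(dd), 1L)
  expect_identical(deduplicate_designs(dd), dd)
  # same product reached by two different rules keeps both provenances
  both <- rbind(
    run_azologization("c1ccccc1CCc1ccccc1", build_rule_set("typical_azologization")),
    run_azologization("c1ccccc1-c1ccccc1", build_rule_set("atypical_azologization")))
  both$parent_id <- "P"  # force same family namespace
  m <- deduplicate_designs(both)
  expect_identical(nrow(m), 1L)
  expect_setequal(strsplit(m$provenance, ";")[[1]],
                  c("Azolog_2atom", "Azolog_0atom"))
})

test_that("ring-member linkers are never transformed (no ring-opening chemistry)", {
  # indane: the CH2 bridge atoms sit in the fused 5-ring, so no azologization
  # site exists even though an aromatic-C..C..C..aromatic-C path is present
  d <- suppressWarnings(run_azologization(
    "C1Cc2ccccc2C1",
    build_rule_set(c("typical_azologization", "atypical_azologization"))))
  expect_identical(nrow(d), 0L)
})

test_that("descriptors are constitution-level and correct for azobenzene", {
  desc <- compute_descriptors("c1ccccc1N=Nc1ccccc1")
  expect_equal(desc$mw, 182.2, tolerance = 0.1)
  expect_identical(desc$nha, 14L)
  expect_equal(desc$fsp3, 0)
  expect_equal(compute_descriptors("CCCC")$fsp3, 1.0)
  d <- run_azologization("c1ccccc1CCc1ccccc1", build_rule_set("typical_azologization"))
  dt <- compute_descriptors(d$trans_smiles)
  dc <- compute_descriptors(d$cis_smiles)
  expect_equal(dt[, -1], dc[, -1], tolerance = 1e-9)
  expect_error(compute_descriptors("C1CC"), "does not parse")
})

test_that("atom mapping tracks the untransformed parent region exactly", {
  # typical azoextension: the full parent maps into the product
  d <- run_azoextension("Cc1ccccc1", build_rule_set("typical_azoextension"))
  m <- map_parent_atoms(d[1, ])
  expect_identical(nrow(m), 7L)          # all toluene heavy atoms
  expect_identical(m$parent_atom, m$product_atom)
  # bibenzyl -> azobenzene: both phenyls mapped, the CH2CH2 linker is not
  d2 <- run_azologization("c1ccccc1CCc1ccccc1", build_rule_set("typical_azologization"))
  m2 <- map_parent_atoms(d2[1, ])
  expect_identical(nrow(m2), 12L)
  expect_false(any(c(7, 8) %in% m2$parent_atom))
  # naphthalene replacement: only the substituent survives the mapping
  d3 <- run_naphthalene_azologization("Cc1ccc2ccccc2c1", "mono")
  m3 <- map_parent_atoms(d3[1, ])
  expect_identical(nrow(m3), 1L)         # the methyl carbon
})

test_that("the reactor SDF export carries isomers and annotations", {
  d <- run_azologization("c1ccccc1CCc1ccccc1", build_rule_set("typical_azologization"))
  f <- tempfile(fileext = ".sdf")
  write_designs_sdf(d, f)
  txt <- readLines(f)
  expect_identical(sum(txt == "$$$$"), 2L)          # trans + cis records
  expect_true(any(grepl("^> <isomer>$", txt)))
  expect_setequal(txt[which(grepl("^> <isomer>$", txt)) + 1], c("trans", "cis"))
})
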