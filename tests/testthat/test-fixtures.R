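# Fixture generators: the mini database, the mock engine and the toy pocket.

test_that("the manifest's predicted counts match the mining pipeline output", {
  db <- open_database(fixture_db_path())
  on.exit(close_database(db))
  mani <- fixture_manifest()
  acts <- fetch_activities(db, unlist(mani$target_ids))
  expect_identical(nrow(acts), as.integer(mani$n_activities_total))
  filt <- apply_quality_filters(acts, miner_config())
  expect_identical(nrow(filt), as.integer(mani$n_quality_pass))
  paff <- compute_paffinity(filt)
  expect_identical(nrow(paff), as.integer(mani$n_paffinity_records))
  # medians agree with the generator's bookkeeping (values are stored rounded)
  key <- paste(paff$ligand_id, paff$target_id, sep = "|")
  expect_lt(max(abs(paff$paffinity - unlist(mani$expected_paffinity[key]))), 1e-4)
  # per-target activity counts
  for (tid in unlist(mani$target_ids))
    expect_identical(nrow(fetch_activities(db, tid)),
                     as.integer(mani$activities_per_target[[tid]]))
})

test_that("a zero-dirty fixture passes quality filtering unchanged", {
  p <- generate_mini_chembl(fixture_spec(seed = 7, dirty_fraction = 0),
                            tempfile(fileext = ".db"))
  db <- open_database(p)
  on.exit(close_database(db))
  acts <- fetch_activities(db, c("CHEMBL_T1", "CHEMBL_T2", "CHEMBL_T3"))
  filt <- apply_quality_filters(acts, miner_config())
  expect_identical(nrow(filt), nrow(acts))
})

test_that("fixture generation is byte-deterministic in the seed", {
  p1 <- generate_mini_chembl(fixture_spec(seed = 99), tempfile(fileext = ".db"))
  p2 <- generate_mini_chembl(fixture_spec(seed = 99), tempfile(fileext = ".db"))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  p3 <- generate_mini_chembl(fixture_spec(seed = 100), tempfile(fileext = ".db"))
  expect_false(identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p3))))
})

test_that("the mock engine replays score tables and hashes unknowns stably", {
  st <- list(vX = data.frame(score = c(-70, -60), n_contacts = c(4, 5),
                             n_clashes = c(0, 1), n_uncontacted = c(0, 0)))
  eng <- make_mock_engine(mock_engine_config(n_poses = 2, score_table = st))
  poses <- pswdesign:::psw_dock_one(eng, NULL, NULL,
                                    list(variant_id = "vX", coords = NULL))
  expect_identical(vapply(poses, `[[`, 0, "total_score"), c(-70, -60))
  # fallback is stable across calls and independent of pose-set context
  a <- pswdesign:::psw_dock_one(eng, NULL, NULL, list(variant_id = "vx9", coords = NULL))
  b <- pswdesign:::psw_dock_one(eng, NULL, NULL, list(variant_id = "vx9", coords = NULL))
  expect_identical(vapply(a, `[[`, 0, "total_score"),
                   vapply(b, `[[`, 0, "total_score"))
  # poses are translated onto the site center
  site <- define_binding_site(reference_ligand = matrix(c(3, 4, 5), 1, 3),
                              extra_radius = 1)
  p <- pswdesign:::psw_dock_one(eng, NULL, site,
                                list(variant_id = "vX",
                                     coords = matrix(rnorm(9), 3, 3)))
  expect_equal(colMeans(p[[1]]$coords), c(3, 4, 5), tolerance = 1e-9)
})

test_that("the toy pocket parses and supports the whole prep contract", {
  pdb <- toy_receptor_pocket(tempfile(fileext = ".pdb"))
  st <- load_structure(pdb)
  expect_identical(sum(st$pdb$atom$resid == "LIG"), 6L)
  expect_gte(sum(st$pdb$atom$resid == "GLY" & st$pdb$atom$chain == "A"), 80L)
  # contacts exist between the pocket shell and the bound ligand
  rec <- prepare_receptor(st, "A", keep_het_ids = "LIG")
  met <- compute_pose_metrics(as.matrix(rec$het[, c("x", "y", "z")]), rec)
  expect_gt(met[["n_contacts"]], 0)
})

test_that("the toy library covers every transformation category", {
  lib <- toy_library()
  expect_setequal(
    unique(unlist(strsplit(lib$categories, ";"))),
    c("typical_azologization", "atypical_azologization",
      "naphthalene_azologization", "typical_azoextension",
      "atypical_azoextension"))
  expect_true(all(smiles_is_valid(lib$smiles)))
})
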