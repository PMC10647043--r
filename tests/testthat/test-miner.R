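# Mining: database access, quality filtering, pAffinity aggregation,
# classification and diversity selection.

test_that("open_database validates existence and schema", {
  db <- open_database(fixture_db_path())
  expect_s3_class(db, "psw_db")
  close_database(db)
  expect_error(open_database(tempfile()), "not found")
  broken <- tempfile(fileext = ".db")
  con <- DBI::dbConnect(RSQLite::SQLite(), broken)
  DBI::dbWriteTable(con, "target_dictionary", data.frame(tid = 1))
  DBI::dbDisconnect(con)
  expect_error(open_database(broken), "activities")
})

test_that("the target hierarchy has one sorted leaf per active target", {
  db <- open_database(fixture_db_path())
  on.exit(close_database(db))
  h <- list_target_hierarchy(db)
  expect_identical(nrow(h), 3L)
  expect_identical(length(unique(sub(" /.*", "", h$class_path))), 2L)
  expect_false(is.unsorted(h$class_path))
  expect_true(all(h$n_activities >= 1))
})

test_that("an empty database yields an empty hierarchy", {
  p <- tempfile(fileext = ".db")
  con <- DBI::dbConnect(RSQLite::SQLite(), p)
  for (tb in pswdesign:::REQUIRED_TABLES)
    DBI::dbExecute(con, sprintf(
      "CREATE TABLE %s (tid INTEGER, chembl_id TEXT, pref_name TEXT,
       organism TEXT, component_id INTEGER, protein_class_id INTEGER,
       parent_id INTEGER, class_level INTEGER, assay_id INTEGER,
       assay_type TEXT, activity_id INTEGER, molregno INTEGER,
       standard_type TEXT, standard_relation TEXT, standard_value REAL,
       standard_units TEXT, data_validity_comment TEXT,
       canonical_smiles TEXT)", tb))
  DBI::dbDisconnect(con)
  db <- open_database(p)
  on.exit(close_database(db))
  expect_identical(nrow(list_target_hierarchy(db)), 0L)
})

test_that("fetch_activities returns every seeded measurement, unfiltered", {
  db <- open_database(fixture_db_path())
  on.exit(close_database(db))
  acts <- fetch_activities(db, "CHEMBL_T1")
  expect_identical(nrow(acts), 12L)  # clean target: 6 ligands x 2 measurements
  mixed <- fetch_activities(db, c("CHEMBL_T1", "CHEMBL_T3"))
  human <- fetch_activities(db, c("CHEMBL_T1", "CHEMBL_T3"),
                            organisms = "Homo sapiens")
  expect_true(all(human$organism == "Homo sapiens"))
  expect_lt(nrow(human), nrow(mixed))
  expect_message(empty <- fetch_activities(db, "CHEMBL_NOPE"), "no such target")
  expect_identical(nrow(empty), 0L)
})

test_that("quality rules reject what they should and log every rejection", {
  rec <- rbind(make_records(ligand_id = "Lok"),
               make_records(ligand_id = "Lgt", relation = ">"),
               make_records(ligand_id = "Lnv", standard_value = NA),
               make_records(ligand_id = "Lnu", standard_units = NA),
               make_records(ligand_id = "Lfn", assay_type = "F"),
               make_records(ligand_id = "Lbs", canonical_smiles = "C1CC"),
               make_records(ligand_id = "Ldv",
                            data_validity_comment = "Outside typical range"))
  out <- apply_quality_filters(rec, miner_config())
  expect_identical(out$ligand_id, "Lok")
  rej <- attr(out, "rejections")
  expect_setequal(rej$rule, c("relation", "standard_value", "standard_units",
                              "assay_type", "smiles_parse", "data_validity"))
  # MW window: bibenzyl (182 Da) retained in [100, 800]
  expect_identical(nrow(apply_quality_filters(make_records(), miner_config())), 1L)
  # permissive mode keeps upper bounds
  perm <- miner_config(relations = c("=", "<"))
  expect_identical(nrow(apply_quality_filters(
    make_records(relation = "<"), perm)), 1L)
})

test_that("quality filtering is idempotent and never grows the record set", {
  db <- open_database(fixture_db_path())
  on.exit(close_database(db))
  acts <- fetch_activities(db, c("CHEMBL_T1", "CHEMBL_T2", "CHEMBL_T3"))
  once <- apply_quality_filters(acts, miner_config())
  twice <- apply_quality_filters(once, miner_config())
  expect_lte(nrow(once), nrow(acts))
  plain <- function(x) {
    attr(x, "rejections") <- NULL
    as.data.frame(x)
  }
  expect_identical(plain(twice), plain(once))
})

test_that("pAffinity is the unit-invariant median of -log10 molar values", {
  # single Ki = 10 nM -> 8.0
  p1 <- compute_paffinity(make_records(standard_value = 10))
  expect_equal(p1$paffinity, 8.0, tolerance = 1e-12)
  # median of {1, 100, 10} nM -> median {9, 7, 8} = 8
  p3 <- compute_paffinity(make_records(3, ligand_id = "L1",
                                       standard_value = c(1, 100, 10)))
  expect_equal(p3$paffinity, 8.0, tolerance = 1e-12)
  expect_identical(p3$n_measurements, 3L)
  # 0.001 uM == 1 nM: per-measurement values agree to 1e-9
  pu <- compute_paffinity(rbind(
    make_records(ligand_id = "L1", standard_value = 0.001, standard_units = "uM"),
    make_records(ligand_id = "L1", standard_value = 1, standard_units = "nM")))
  expect_identical(pu$n_measurements, 2L)
  expect_equal(pu$paffinity, 9.0, tolerance = 1e-9)
  # expressing one series in nM, uM and M gives identical pAffinity
  val_nM <- 37
  same <- vapply(list(c(val_nM, "nM"), c(val_nM * 1e-3, "uM"),
                      c(val_nM * 1e-9, "M")), function(vu)
    compute_paffinity(make_records(standard_value = as.numeric(vu[1]),
                                   standard_units = vu[2]))$paffinity, 0)
  expect_lt(max(same) - min(same), 1e-9)
})

test_that("pAffinity aggregation is permutation-invariant", {
  rec <- make_records(4, ligand_id = "L1", standard_value = c(2, 40, 7, 300))
  ref <- compute_paffinity(rec)$paffinity
  set.seed(1)
  for (k in 1:5) {
    perm <- rec[sample(nrow(rec)), ]
    expect_equal(compute_paffinity(perm)$paffinity, ref, tolerance = 1e-12)
  }
})

test_that("classification bins and the affinity floor are boundary-inclusive", {
  paff <- compute_paffinity(make_records(3, ligand_id = c("A", "B", "C"),
                                         standard_value = c(10^(9 - 7.5),
                                                            10^(9 - 8.0),
                                                            10^(9 - 9.1))))
  cls <- classify_and_filter(paff, miner_config(paffinity_min = 8.0))
  expect_setequal(cls$ligand_id, c("B", "C"))   # 8.0 retained, 7.5 dropped
  lab <- classify_and_filter(paff, miner_config(class_thresholds = c(6, 8)))
  expect_identical(lab$activity_class[order(lab$ligand_id)],
                   c("moderate", "active", "active"))
  empty <- classify_and_filter(compute_paffinity(make_records(0)), miner_config())
  expect_identical(nrow(empty), 0L)
})

test_that("diversity selection keeps one representative per similarity clique", {
  # identical structures collapse
  paff <- compute_paffinity(rbind(
    make_records(ligand_id = "A", canonical_smiles = "c1ccccc1CCc1ccccc1"),
    make_records(ligand_id = "B", canonical_smiles = "C(c1ccccc1)Cc1ccccc1")))
  expect_identical(nrow(select_diverse_parents(paff, 0.5)), 1L)
  # unrelated scaffolds are both kept (verify the premise, then the outcome)
  smi2 <- c("c1ccccc1CCc1ccccc1", "CC(C)NCC(O)CO")
  sim <- pswdesign:::.tanimoto_matrix(smi2)
  expect_lt(sim[1, 2], 0.5)
  paff2 <- compute_paffinity(rbind(
    make_records(ligand_id = "A", canonical_smiles = smi2[1]),
    make_records(ligand_id = "B", canonical_smiles = smi2[2])))
  expect_identical(nrow(select_diverse_parents(paff2, 0.5)), 2L)
  # single record passes through
  expect_identical(nrow(select_diverse_parents(paff2[1, ], 0.5)), 1L)
})

test_that("diversity selection matches the greedy-clique oracle on the fixture", {
  db <- open_database(fixture_db_path())
  on.exit(close_database(db))
  cfg <- miner_config(paffinity_min = 6.0)
  res <- mine_parents(db, c("CHEMBL_T1", "CHEMBL_T2", "CHEMBL_T3"), config = cfg)
  cls <- res$classified
  expect_lte(nrow(cls), 20L)
  oracle <- greedy_diverse_oracle(cls$canonical_smiles, cls$paffinity,
                                  cls$ligand_id, 0.5)
  sel <- select_diverse_parents(cls, 0.5, config = cfg)
  expect_identical(nrow(sel), length(oracle))
  # invariant: no two representatives more similar than the threshold
  sim <- pswdesign:::.tanimoto_matrix(sel$smiles)
  diag(sim) <- 0
  expect_lte(max(sim), 0.5)
})

test_that("record counts never increase along the mining pipeline", {
  db <- open_database(fixture_db_path())
  on.exit(close_database(db))
  res <- mine_parents(db, c("CHEMBL_T1", "CHEMBL_T2", "CHEMBL_T3"),
                      config = miner_config(paffinity_min = 8.0))
  expect_lte(nrow(res$filtered), nrow(res$activities))
  expect_lte(nrow(res$paffinities), nrow(res$filtered))
  expect_lte(nrow(res$classified), nrow(res$paffinities))
  expect_lte(nrow(res$parents), nrow(res$classified))
})
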