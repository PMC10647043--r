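# Seeded synthetic fixtures: a miniature ChEMBL-schema SQLite database, a
# deterministic mock docking engine, a toy molecule catalog with known
# transformation outcomes, and a synthetic receptor pocket. Everything is
# generated in code, without network access, and is byte-reproducible for a
# fixed seed.

# curated drug-like SMILES pool with azologization/azoextension handles
.fixture_smiles_pool <- function() {
  c(LIG01 = "c1ccccc1CCc1ccccc1",
    LIG02 = "c1ccccc1/C=C/c1ccccc1",
    LIG03 = "c1ccccc1-c1ccccc1",
    LIG04 = "c1ccccc1Cc1ccccc1",
    LIG05 = "c1ccccc1CCCc1ccccc1",
    LIG06 = "Cc1ccc2ccccc2c1",
    LIG07 = "Cc1ccc2cc(O)ccc2c1",
    LIG08 = "c1ccccc1OCc1ccccc1",
    LIG09 = "CCOc1ccc(CCc2ccc(O)cc2)cc1",
    LIG10 = "CN(Cc1ccccc1)c1ccccc1",
    LIG11 = "Oc1ccc(CCc2ccccn2)cc1",
    LIG12 = "CN1CCC(Cc2ccc3ccccc3c2)CC1",
    LIG13 = "COc1ccc(cc1)C(=O)Nc1ccccc1",
    LIG14 = "Clc1ccc(CCc2ccc(F)cc2)cc1",
    LIG15 = "CC(C)NCC(O)COc1ccc2ccccc2c1",
    LIG16 = "CCN(CC)CCOc1ccc(Cc2ccccc2)cc1",
    LIG17 = "Oc1ccc(cc1)C(=O)Cc1ccccc1",
    LIG18 = "CN(C)CCOc1ccc(CCc2ccc(F)cc2)cc1")
}

#' Specification for the miniature ChEMBL-schema fixture database
#'
#' @param seed integer seed; the same seed yields a byte-identical database.
#' @param n_targets number of targets (up to 3 distinct built-in targets).
#' @param n_ligands_per_target ligands with clean data per target.
#' @param n_measurements clean measurements per (ligand, target).
#' @param dirty_fraction fraction (of the clean record count) of deliberately
#'   low-quality records added, cycling through every quality-rule violation.
#' @param paff_range pAffinity range the clean measurements are drawn from
#'   (log-uniform in affinity).
#' @return list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 42L, n_targets = 3L, n_ligands_per_target = 6L,
                         n_measurements = 2L, dirty_fraction = 0.4,
                         paff_range = c(5, 10)) {
  stopifnot(n_targets >= 1, n_targets <= 3, n_ligands_per_target >= 1,
            n_measurements >= 1, dirty_fraction >= 0)
  structure(list(seed = as.integer(seed), n_targets = as.integer(n_targets),
                 n_ligands_per_target = as.integer(n_ligands_per_target),
                 n_measurements = as.integer(n_measurements),
                 dirty_fraction = dirty_fraction, paff_range = paff_range),
            class = "fixture_spec")
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Generate a miniature ChEMBL-schema SQLite database
#'
#' Emits a relational snapshot with the table subset the miner requires
#' (target_dictionary, target_components, component_class,
#' protein_classification, assays, activities, molecule_dictionary,
#' compound_structures), seeded with clean binding data plus deliberately
#' dirty records exercising every quality rule. A JSON manifest of expected
#' post-filter counts (computed from generation bookkeeping, not by running
#' the miner) is written alongside.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param path output path for the SQLite file.
#' @return the path, with the manifest at \code{paste0(path, ".manifest.json")}.
#' @export
generate_mini_chembl <- function(spec = fixture_spec(), path = tempfile(fileext = ".db")) {
  targets <- data.frame(
    tid = 1:3,
    chembl_id = c("CHEMBL_T1", "CHEMBL_T2", "CHEMBL_T3"),
    pref_name = c("Beta-2 adrenergic receptor", "Histamine H3 receptor",
                  "Voltage-gated potassium channel"),
    organism = c("Homo sapiens", "Homo sapiens", "Rattus norvegicus"),
    target_type = "SINGLE PROTEIN",
    stringsAsFactors = FALSE)[seq_len(spec$n_targets), , drop = FALSE]

  protein_classification <- data.frame(
    protein_class_id = 1:5,
    parent_id = c(NA, 1, 2, NA, 4),
    pref_name = c("Membrane receptor", "Family A G protein-coupled receptor",
                  "Monoamine receptor", "Ion channel", "Voltage-gated channel"),
    class_level = c(1, 2, 3, 1, 2), stringsAsFactors = FALSE)
  target_components <- data.frame(tid = targets$tid, component_id = targets$tid * 10L)
  component_class <- data.frame(component_id = targets$tid * 10L,
                                protein_class_id = c(3L, 3L, 5L)[seq_len(spec$n_targets)])

  pool <- .fixture_smiles_pool()
  res <- .with_seed(spec$seed, {
    mols <- data.frame(molregno = integer(0), chembl_id = character(0),
                       smiles = character(0), stringsAsFactors = FALSE)
    add_mol <- function(id, smi) {
      if (!(id %in% mols$chembl_id))
        mols <<- rbind(mols, data.frame(molregno = nrow(mols) + 1L,
                                        chembl_id = id, smiles = smi,
                                        stringsAsFactors = FALSE))
      mols$molregno[mols$chembl_id == id]
    }
    assays <- data.frame(assay_id = integer(0), chembl_id = character(0),
                         tid = integer(0), assay_type = character(0),
                         stringsAsFactors = FALSE)
    add_assay <- function(tid, type, k) {
      id <- sprintf("CHEMBL_A%d_%s%d", tid, type, k)
      assays <<- rbind(assays, data.frame(assay_id = nrow(assays) + 1L,
                                          chembl_id = id, tid = tid,
                                          assay_type = type, stringsAsFactors = FALSE))
      nrow(assays)
    }
    acts <- list()
    add_act <- function(assay_id, molregno, type, value, units, relation,
                        validity = NA_character_) {
      acts[[length(acts) + 1]] <<- data.frame(
        activity_id = length(acts) + 1L, assay_id = assay_id,
        molregno = molregno, standard_type = type, standard_relation = relation,
        standard_value = value, standard_units = units,
        data_validity_comment = validity, stringsAsFactors = FALSE)
    }

    book <- list()  # per clean (ligand,target): the sampled paffinities
    n_clean <- 0L
    for (t in seq_len(nrow(targets))) {
      a1 <- add_assay(targets$tid[t], "B", 1)
      a2 <- add_assay(targets$tid[t], "B", 2)
      lig_idx <- ((t - 1) * spec$n_ligands_per_target +
                    seq_len(spec$n_ligands_per_target) - 1) %% length(pool) + 1
      for (li in seq_along(lig_idx)) {
        id <- names(pool)[lig_idx[li]]
        mr <- add_mol(id, pool[[lig_idx[li]]])
        paffs <- round(stats::runif(spec$n_measurements,
                                    spec$paff_range[1], spec$paff_range[2]), 3)
        for (k in seq_along(paffs)) {
          # alternate units so the aggregation must be unit-invariant
          if (k %% 2 == 1) {
            value <- round(10^(9 - paffs[k]), 6); units <- "nM"
          } else {
            value <- round(10^(6 - paffs[k]), 9); units <- "uM"
          }
          type <- c("Ki", "Kd", "IC50")[(k - 1) %% 3 + 1]
          add_act(if (k %% 2 == 1) a1 else a2, mr, type, value, units, "=")
          n_clean <- n_clean + 1L
        }
        book[[paste(id, targets$chembl_id[t], sep = "|")]] <- paffs
      }
    }
    # dirty records cycling through quality-rule violations
    n_dirty <- round(spec$dirty_fraction * n_clean)
    flaws <- c("relation", "units", "value", "assay_type", "validity",
               "duplicate", "bad_smiles", "too_big", "too_small")
    # dirty records live on the second target (when present) so that the
    # first target carries exactly the clean seeded measurements
    dirty_tid <- targets$tid[min(2L, nrow(targets))]
    aF <- add_assay(dirty_tid, "F", 1)
    mr_bad <- add_mol("LIGBAD", "C1CC")               # unparsable
    mr_big <- add_mol("LIGBIG", paste0("C", strrep("C", 79)))  # MW/NHA too high
    mr_small <- add_mol("LIGSMALL", "CCO")            # below both windows
    b_assay <- assays$assay_id[assays$assay_type == "B" &
                                 assays$tid == dirty_tid][1]
    mr1 <- mols$molregno[1]
    for (d in seq_len(n_dirty)) {
      flaw <- flaws[(d - 1) %% length(flaws) + 1]
      switch(flaw,
        relation = add_act(b_assay, mr1, "Ki", 50, "nM", ">"),
        units = add_act(b_assay, mr1, "Ki", 50, NA_character_, "="),
        value = add_act(b_assay, mr1, "Ki", NA_real_, "nM", "="),
        assay_type = add_act(aF, mr1, "IC50", 50, "nM", "="),
        validity = add_act(b_assay, mr1, "Ki", 50, "nM", "=",
                           validity = "Potential transcription error"),
        duplicate = {
          dup_of <- Position(function(a)
            a$assay_id %in% assays$assay_id[assays$tid == dirty_tid &
                                              assays$assay_type == "B"], acts)
          first <- acts[[dup_of]]
          add_act(first$assay_id, first$molregno, first$standard_type,
                  first$standard_value, first$standard_units,
                  first$standard_relation)
        },
        bad_smiles = add_act(b_assay, mr_bad, "Ki", 50, "nM", "="),
        too_big = add_act(b_assay, mr_big, "Ki", 50, "nM", "="),
        too_small = add_act(b_assay, mr_small, "Ki", 50, "nM", "="))
    }
    list(mols = mols, assays = assays, acts = do.call(rbind, acts),
         book = book, n_clean = n_clean, n_dirty = n_dirty)
  })

  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbWriteTable(con, "target_dictionary", targets, overwrite = TRUE)
  DBI::dbWriteTable(con, "target_components", target_components, overwrite = TRUE)
  DBI::dbWriteTable(con, "component_class", component_class, overwrite = TRUE)
  DBI::dbWriteTable(con, "protein_classification", protein_classification, overwrite = TRUE)
  DBI::dbWriteTable(con, "assays", res$assays, overwrite = TRUE)
  DBI::dbWriteTable(con, "activities", res$acts, overwrite = TRUE)
  DBI::dbWriteTable(con, "molecule_dictionary",
                    res$mols[, c("molregno", "chembl_id")], overwrite = TRUE)
  DBI::dbWriteTable(con, "compound_structures",
                    data.frame(molregno = res$mols$molregno,
                               canonical_smiles = res$mols$smiles,
                               stringsAsFactors = FALSE), overwrite = TRUE)
  DBI::dbWriteTable(con, "version",
                    data.frame(name = sprintf("pswdesign_fixture_seed%d", spec$seed)),
                    overwrite = TRUE)

  # manifest of expected counts, from generation bookkeeping only
  paff_expected <- lapply(res$book, stats::median)
  manifest <- list(
    seed = spec$seed,
    n_targets = nrow(targets),
    n_activities_total = nrow(res$acts),
    n_clean = res$n_clean,
    n_dirty = res$n_dirty,
    n_quality_pass = res$n_clean,
    n_paffinity_records = length(res$book),
    target_ids = targets$chembl_id,
    activities_per_target = stats::setNames(
      as.list(vapply(targets$tid, function(t) {
        sum(res$acts$assay_id %in% res$assays$assay_id[res$assays$tid == t])
      }, 0L)), targets$chembl_id),
    expected_paffinity = paff_expected)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

# ---- mock docking engine ----------------------------------------------------

# deterministic 31-bit string hash
.stable_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  h
}

#' Mock docking engine configuration
#'
#' @param n_poses poses returned per ligand variant.
#' @param score_table optional named list: variant_id -> data.frame with
#'   columns \code{score}, \code{n_contacts}, \code{n_clashes},
#'   \code{n_uncontacted} (one row per pose). Variants absent from the table
#'   fall back to a deterministic hash-based score rule.
#' @return list of class \code{mock_engine_config}.
#' @export
mock_engine_config <- function(n_poses = 10, score_table = list()) {
  structure(list(n_poses = n_poses, score_table = score_table),
            class = "mock_engine_config")
}

#' Create the deterministic mock docking engine
#'
#' Satisfies the docking-engine contract: given a receptor, a binding site
#' and a prepared ligand it returns scored poses, with coordinates equal to
#' the input conformer translated to the site center. Scores and contact
#' metrics come from the configured score table, or from a deterministic
#' hash of the variant id, so results are identical across runs and worker
#' counts.
#'
#' @param config a \code{\link{mock_engine_config}}.
#' @return an engine object of class \code{psw_engine}.
#' @export
make_mock_engine <- function(config = mock_engine_config()) {
  structure(list(name = "mock", config = config),
            class = c("psw_mock_engine", "psw_engine"))
}

#' @export
print.psw_engine <- function(x, ...) {
  cat("<psw_engine>", x$name, "\n")
  invisible(x)
}

# engine contract: one ligand variant in, <= n_poses scored poses out
psw_dock_one <- function(engine, receptor, site, ligand, n_poses) {
  UseMethod("psw_dock_one")
}

#' @export
psw_dock_one.psw_mock_engine <- function(engine, receptor, site, ligand,
                                         n_poses = NULL) {
  cfg <- engine$config
  if (is.null(n_poses)) n_poses <- cfg$n_poses
  vid <- ligand$variant_id
  tab <- cfg$score_table[[vid]]
  if (!is.null(tab)) {
    tab <- as.data.frame(tab)[seq_len(min(nrow(as.data.frame(tab)), n_poses)), ,
                              drop = FALSE]
  } else {
    h <- .stable_hash(vid)
    j <- seq_len(n_poses)
    tab <- data.frame(
      score = -(40 + (h %% 400) / 10) + (j - 1) * 0.8,
      n_contacts = pmax(0L, as.integer(10 + h %% 7 - (j - 1))),
      n_clashes = as.integer((h + j) %% 3),
      n_uncontacted = as.integer(h %% 4 + (j - 1) %% 2))
  }
  coords <- ligand$coords
  if (is.null(coords)) coords <- matrix(0, nrow = 1, ncol = 3)
  center <- if (!is.null(site)) site$center else c(0, 0, 0)
  shift <- center - colMeans(coords)
  poses <- lapply(seq_len(nrow(tab)), function(j) {
    xyz <- sweep(coords, 2, -shift - c((j - 1) * 0.05, 0, 0))
    list(pose_index = j, coords = xyz, total_score = tab$score[j],
         n_contacts = tab$n_contacts[j], n_clashes = tab$n_clashes[j],
         n_uncontacted = tab$n_uncontacted[j],
         score_terms = c(total = tab$score[j]))
  })
  poses
}

# ---- toy molecule catalog ---------------------------------------------------

#' Toy molecule catalog with known transformation outcomes
#'
#' Named worked examples for every transformation category, each with the
#' expected distinct product set (as SMILES; compare after
#' canonicalization). Used by the golden-suite tests.
#'
#' @return data.frame with columns \code{name}, \code{smiles},
#'   \code{categories} (rule categories to apply, ";"-separated),
#'   \code{naphthalene_mode}, \code{expected_products} (";"-separated
#'   SMILES) and \code{expected_count}.
#' @export
toy_library <- function() {
  azb <- "c1ccccc1N=Nc1ccccc1"
  tol <- c("Cc1ccccc1N=Nc1ccccc1", "Cc1cccc(c1)N=Nc1ccccc1", "Cc1ccc(cc1)N=Nc1ccccc1")
  rows <- list(
    list("bibenzyl", "c1ccccc1CCc1ccccc1", "typical_azologization", "both", azb, 1L),
    list("stilbene", "c1ccccc1/C=C/c1ccccc1", "typical_azologization", "both", azb, 1L),
    list("diphenylether_methylene", "c1ccccc1OCc1ccccc1", "typical_azologization", "both", azb, 1L),
    list("biphenyl", "c1ccccc1-c1ccccc1", "atypical_azologization", "both", azb, 1L),
    list("diphenylmethane", "c1ccccc1Cc1ccccc1", "atypical_azologization", "both", azb, 1L),
    list("benzophenone", "O=C(c1ccccc1)c1ccccc1", "atypical_azologization", "both", azb, 1L),
    list("diphenylpropane_1_3", "c1ccccc1CCCc1ccccc1", "atypical_azologization", "both", azb, 1L),
    list("benzene", "c1ccccc1", "typical_azoextension", "both", azb, 1L),
    list("toluene", "Cc1ccccc1", "typical_azoextension", "both",
         paste(tol, collapse = ";"), 3L),
    list("fluorobenzene", "Fc1ccccc1", "atypical_azoextension", "both", azb, 1L),
    list("naphthalene_2_methyl", "Cc1ccc2ccccc2c1", "naphthalene_azologization",
         "mono", paste(tol, collapse = ";"), 3L),
    list("naphthalene_2_methyl_6_ol", "Cc1ccc2cc(O)ccc2c1",
         "naphthalene_azologization", "di", NA_character_, 19L))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], smiles = r[[2]], categories = r[[3]],
               naphthalene_mode = r[[4]], expected_products = r[[5]],
               expected_count = r[[6]], stringsAsFactors = FALSE)))
  out
}

# ---- toy receptor pocket ----------------------------------------------------

#' Write a synthetic receptor-pocket PDB fixture
#'
#' A 20-residue glycine shell (chain A) surrounding a 6-carbon ring
#' heteroatom ligand (resname LIG) at the origin, plus waters and a short
#' chain B, synthesized on a deterministic spherical lattice. Sufficient for
#' receptor preparation, binding-site and contact-metric tests; it is not a
#' real protein geometry.
#'
#' @param path output PDB path.
#' @param n_res shell residues (default 20).
#' @param shell_radius radius of the CA shell in Angstrom.
#' @return the path, invisibly.
#' @export
toy_receptor_pocket <- function(path = tempfile(fileext = ".pdb"),
                                n_res = 20, shell_radius = 4.5) {
  lines <- c("HEADER    SYNTHETIC POCKET FIXTURE",
             "TITLE     SYNTHETIC 20-RESIDUE POCKET WITH BOUND RING LIGAND",
             "REMARK    GENERATED BY pswdesign::toy_receptor_pocket; NOT A REAL PROTEIN")
  serial <- 0
  atom_line <- function(rec, name, resid, chain, resno, x, y, z, elem) {
    serial <<- serial + 1
    sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, name, " ", resid, chain, resno, x, y, z, 1, 20, elem)
  }
  # golden-angle spherical lattice for the CA shell
  for (i in seq_len(n_res)) {
    zf <- 1 - 2 * (i - 0.5) / n_res
    r <- sqrt(max(0, 1 - zf^2))
    th <- i * 2.399963229728653
    ca <- shell_radius * c(r * cos(th), r * sin(th), zf)
    dirv <- ca / sqrt(sum(ca^2))
    lines <- c(lines,
      atom_line("ATOM", "N", "GLY", "A", i, ca[1] + dirv[1] * 1.2, ca[2], ca[3], "N"),
      atom_line("ATOM", "CA", "GLY", "A", i, ca[1], ca[2], ca[3], "C"),
      atom_line("ATOM", "C", "GLY", "A", i, ca[1] + dirv[1] * 0.8,
                ca[2] + dirv[2] * 1.1, ca[3], "C"),
      atom_line("ATOM", "O", "GLY", "A", i, ca[1] + dirv[1] * 1.4,
                ca[2] + dirv[2] * 1.6, ca[3] + dirv[3] * 0.5, "O"))
  }
  # chain B stub (3 residues, translated away from the pocket)
  for (i in 1:3) {
    base <- c(20 + i * 3, 0, 0)
    lines <- c(lines,
      atom_line("ATOM", "N", "GLY", "B", i, base[1] - 1.2, base[2], base[3], "N"),
      atom_line("ATOM", "CA", "GLY", "B", i, base[1], base[2], base[3], "C"),
      atom_line("ATOM", "C", "GLY", "B", i, base[1] + 0.8, base[2] + 1.1, base[3], "C"),
      atom_line("ATOM", "O", "GLY", "B", i, base[1] + 1.4, base[2] + 1.6, base[3], "O"))
  }
  # bound ring ligand at the origin
  for (k in 1:6) {
    a <- (k - 1) * pi / 3
    lines <- c(lines, atom_line("HETATM", paste0("C", k), "LIG", "A", 201,
                                1.39 * cos(a), 1.39 * sin(a), 0, "C"))
  }
  # waters (must be removed by receptor preparation)
  for (k in 1:3)
    lines <- c(lines, atom_line("HETATM", "O", "HOH", "A", 300 + k,
                                8 + k, 8, 8, "O"))
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
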