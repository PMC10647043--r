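# Shared fixtures and independent oracles for the test suite.

# one fixture database per test run, built lazily
fixture_db_path <- local({
  path <- NULL
  function() {
    if (is.null(path)) {
      path <<- tempfile(fileext = ".db")
      generate_mini_chembl(fixture_spec(), path)
    }
    path
  }
})

fixture_manifest <- function() {
  jsonlite::read_json(paste0(fixture_db_path(), ".manifest.json"),
                      simplifyVector = TRUE)
}

# synthetic activity-record rows with sensible defaults
make_records <- function(n = 1, ligand_id = paste0("L", seq_len(n)),
                         canonical_smiles = "c1ccccc1CCc1ccccc1",
                         target_id = "T1", organism = "Homo sapiens",
                         standard_type = "Ki", standard_value = 10,
                         standard_units = "nM", relation = "=",
                         assay_id = "A1", assay_type = "B",
                         data_validity_comment = NA_character_) {
  if (n == 0) {
    out <- make_records(1)[0, , drop = FALSE]
    class(out) <- c("activity_records", "data.frame")
    return(out)
  }
  out <- data.frame(ligand_id = ligand_id, canonical_smiles = canonical_smiles,
                    target_id = target_id, organism = organism,
                    standard_type = standard_type,
                    standard_value = standard_value,
                    standard_units = standard_units, relation = relation,
                    assay_id = assay_id, assay_type = assay_type,
                    data_validity_comment = data_validity_comment,
                    stringsAsFactors = FALSE)
  class(out) <- c("activity_records", "data.frame")
  out
}

# independent greedy-clique oracle for diversity selection: sweep records in
# decreasing pAffinity (ties: id), keep those within the similarity budget
greedy_diverse_oracle <- function(smiles, paffinity, ids, threshold,
                                  fingerprint = "ECFP4") {
  fps <- lapply(smiles, function(s) {
    m <- ChemmineOB::forEachMol("SMILES", paste0(s, "\tm"), identity)
    as.logical(ChemmineOB::fingerprint_OB(m, fingerprint))
  })
  tanimoto <- function(a, b) {
    u <- sum(fps[[a]] | fps[[b]])
    if (u == 0) 0 else sum(fps[[a]] & fps[[b]]) / u
  }
  ord <- order(-paffinity, ids)
  kept <- integer(0)
  for (i in ord) {
    if (all(vapply(kept, function(j) tanimoto(i, j) <= threshold, TRUE)))
      kept <- c(kept, i)
  }
  sort(kept)
}

# exhaustive dominance oracle for Pareto pose selection
pareto_oracle <- function(poses) {
  obj <- vapply(poses, function(p)
    c(-p$n_contacts, p$n_clashes, p$n_uncontacted, p$total_score), numeric(4))
  n <- length(poses)
  nondom <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j)
      j != i && all(obj[, j] <= obj[, i]) && any(obj[, j] < obj[, i]), TRUE))
  }, TRUE)
  cand <- which(nondom)
  sc <- obj[4, cand]
  idx <- vapply(poses[cand], function(p) p$pose_index, numeric(1))
  poses[[cand[order(sc, idx)][1]]]
}

random_pose_set <- function(n) {
  lapply(seq_len(n), function(j)
    list(pose_index = j,
         n_contacts = sample(0:12, 1), n_clashes = sample(0:4, 1),
         n_uncontacted = sample(0:6, 1),
         total_score = round(stats::runif(1, -100, -20), 2)))
}

# mock-engine score tables engineered so that the family shift equals d
shift_score_table <- function(d, parent_score = -80, paffinity = 8,
                              family = "FAM") {
  # delta_pki = paffinity * (s_cis - s_trans) / parent_score
  s_trans <- parent_score
  s_cis <- parent_score + d * parent_score / paffinity
  st <- list()
  st[[paste(family, "trans", "a", sep = "_")]] <-
    data.frame(score = s_trans, n_contacts = 5, n_clashes = 0, n_uncontacted = 0)
  st[[paste(family, "cis", "a", sep = "_")]] <-
    data.frame(score = s_cis, n_contacts = 5, n_clashes = 0, n_uncontacted = 0)
  st
}

shift_ligands <- function(family = "FAM") {
  list(list(variant_id = paste(family, "trans", "a", sep = "_"),
            family_id = family, isomer = "trans", label = "a", coords = NULL),
       list(variant_id = paste(family, "cis", "a", sep = "_"),
            family_id = family, isomer = "cis", label = "a", coords = NULL))
}
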