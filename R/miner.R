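# Ligand mining from a ChEMBL-schema SQLite snapshot: retrieval, quality
# filtering, pAffinity aggregation, activity classification and
# diversity-based parent selection.

REQUIRED_TABLES <- c("target_dictionary", "target_components", "component_class",
                     "protein_classification", "assays", "activities",
                     "molecule_dictionary", "compound_structures")

# unit string -> multiplier to mol/L
.unit_to_molar <- c("M" = 1, "mM" = 1e-3, "uM" = 1e-6, "µM" = 1e-6,
                    "um" = 1e-6, "nM" = 1e-9, "pM" = 1e-12, "fM" = 1e-15)

#' Miner configuration
#'
#' Bundles the quality rules and thresholds for the mining pipeline. The
#' default quality rules mirror common curation practice for binding data:
#' binding assays only (\code{assay_type = "B"}), exact affinities
#' (\code{relation = "="}), units convertible to molar, a positive numeric
#' value, no data-validity flag, and duplicate (ligand, assay, value) rows
#' collapsed. Every rule can be relaxed.
#'
#' @param mw_range molecular weight window in Da.
#' @param nha_range heavy-atom count window.
#' @param paffinity_min minimum median pAffinity retained by
#'   \code{\link{classify_and_filter}} (NULL disables).
#' @param similarity_threshold Tanimoto cut for diversity selection.
#' @param class_thresholds ascending pAffinity cut points for class labels.
#' @param class_labels labels for the \code{length(class_thresholds)+1} bins.
#' @param assay_types allowed assay-type codes ("B" = binding).
#' @param relations allowed affinity relations; add \code{"<"} for a
#'   permissive mode keeping upper bounds.
#' @param measurement_types allowed standard types; set to
#'   \code{c("Ki","Kd")} to restrict pooling to equilibrium constants.
#' @param exclude_validity_flags reject records carrying a
#'   data-validity comment.
#' @param collapse_duplicates collapse duplicated (ligand, assay, value) rows.
#' @param fingerprint OpenBabel fingerprint name for diversity selection
#'   (circular ECFP4 by default).
#' @param linkage hclust linkage for diversity clustering.
#' @return a list of class \code{miner_config}.
#' @export
miner_config <- function(mw_range = c(100, 800), nha_range = c(7, 60),
                         paffinity_min = NULL, similarity_threshold = 0.5,
                         class_thresholds = c(6, 8),
                         class_labels = NULL,
                         assay_types = "B", relations = "=",
                         measurement_types = c("Ki", "Kd", "IC50", "EC50"),
                         exclude_validity_flags = TRUE,
                         collapse_duplicates = TRUE,
                         fingerprint = "ECFP4", linkage = "complete") {
  stopifnot(length(mw_range) == 2, mw_range[1] < mw_range[2],
            length(nha_range) == 2, nha_range[1] < nha_range[2],
            similarity_threshold >= 0, similarity_threshold <= 1,
            !is.unsorted(class_thresholds))
  if (is.null(class_labels)) {
    class_labels <- if (length(class_thresholds) == 2)
      c("inactive", "moderate", "active")
    else paste0("class", seq_len(length(class_thresholds) + 1))
  }
  stopifnot(length(class_labels) == length(class_thresholds) + 1)
  structure(list(mw_range = mw_range, nha_range = nha_range,
                 paffinity_min = paffinity_min,
                 similarity_threshold = similarity_threshold,
                 class_thresholds = class_thresholds, class_labels = class_labels,
                 assay_types = assay_types, relations = relations,
                 measurement_types = measurement_types,
                 exclude_validity_flags = exclude_validity_flags,
                 collapse_duplicates = collapse_duplicates,
                 fingerprint = fingerprint, linkage = linkage),
            class = "miner_config")
}

#' Open a ChEMBL-schema SQLite database
#'
#' @param path path to the SQLite file.
#' @return a handle of class \code{psw_db}.
#' @export
open_database <- function(path) {
  if (!file.exists(path)) stop("database file not found: ", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  tabs <- DBI::dbListTables(con)
  missing <- setdiff(REQUIRED_TABLES, tabs)
  if (length(missing) > 0) {
    DBI::dbDisconnect(con)
    stop("database schema is missing required table(s): ",
         paste(missing, collapse = ", "))
  }
  version <- tryCatch({
    if ("version" %in% tabs)
      DBI::dbGetQuery(con, "SELECT name FROM version LIMIT 1")$name[1]
    else NA_character_
  }, error = function(e) NA_character_)
  structure(list(con = con, path = path, schema_version = version),
            class = "psw_db")
}

#' @export
print.psw_db <- function(x, ...) {
  cat("<psw_db>", x$path, "\n  schema version:",
      ifelse(is.na(x$schema_version), "(unrecorded)", x$schema_version), "\n")
  invisible(x)
}

#' Close a database handle
#' @param db a \code{psw_db}.
#' @export
close_database <- function(db) {
  DBI::dbDisconnect(db$con)
  invisible(NULL)
}

#' List the protein classification hierarchy with its targets
#'
#' Walks the protein classification tree and returns one row per target that
#' has at least one activity record, with its class path and organism.
#' Output is deterministically sorted.
#'
#' @param db a \code{psw_db}.
#' @return data.frame with columns \code{class_path}, \code{protein_class},
#'   \code{target_id}, \code{pref_name}, \code{organism},
#'   \code{n_activities}.
#' @export
list_target_hierarchy <- function(db) {
  pc <- DBI::dbGetQuery(db$con,
    "SELECT protein_class_id, parent_id, pref_name, class_level FROM protein_classification")
  path_of <- function(id) {
    parts <- character(0)
    while (!is.na(id)) {
      row <- pc[pc$protein_class_id == id, ]
      if (nrow(row) == 0) break
      parts <- c(row$pref_name[1], parts)
      id <- row$parent_id[1]
    }
    paste(parts, collapse = " / ")
  }
  q <- DBI::dbGetQuery(db$con, "
    SELECT td.chembl_id AS target_id, td.pref_name, td.organism,
           cc.protein_class_id, COUNT(act.activity_id) AS n_activities
    FROM target_dictionary td
    JOIN target_components tc ON tc.tid = td.tid
    JOIN component_class cc ON cc.component_id = tc.component_id
    JOIN assays a ON a.tid = td.tid
    JOIN activities act ON act.assay_id = a.assay_id
    GROUP BY td.chembl_id, td.pref_name, td.organism, cc.protein_class_id")
  if (nrow(q) == 0)
    return(data.frame(class_path = character(0), protein_class = character(0),
                      target_id = character(0), pref_name = character(0),
                      organism = character(0), n_activities = integer(0)))
  q <- q[q$n_activities > 0, , drop = FALSE]
  q$class_path <- vapply(q$protein_class_id, path_of, "")
  q$protein_class <- vapply(q$protein_class_id, function(id) {
    row <- pc[pc$protein_class_id == id, ]
    if (nrow(row)) row$pref_name[1] else NA_character_
  }, "")
  out <- q[order(q$class_path, q$target_id, q$organism),
           c("class_path", "protein_class", "target_id", "pref_name",
             "organism", "n_activities")]
  rownames(out) <- NULL
  out
}

#' Fetch activity records for targets
#'
#' Retrieves one row per bioactivity measurement, joined with ligand
#' structure and assay metadata. No filtering or deduplication happens here;
#' unknown target ids yield empty results with a message, not an error.
#'
#' @param db a \code{psw_db}.
#' @param target_ids character vector of target accession ids.
#' @param organisms optional organism filter.
#' @return data.frame of activity records.
#' @export
fetch_activities <- function(db, target_ids, organisms = NULL) {
  stopifnot(length(target_ids) > 0)
  known <- DBI::dbGetQuery(db$con, "SELECT chembl_id FROM target_dictionary")$chembl_id
  unknown <- setdiff(target_ids, known)
  if (length(unknown) > 0)
    message("no such target id(s): ", paste(unknown, collapse = ", "))
  ph <- paste(rep("?", length(target_ids)), collapse = ",")
  sql <- sprintf("
    SELECT md.chembl_id AS ligand_id, cs.canonical_smiles,
           td.chembl_id AS target_id, td.organism,
           act.standard_type, act.standard_value, act.standard_units,
           act.standard_relation AS relation,
           a.chembl_id AS assay_id, a.assay_type,
           act.data_validity_comment
    FROM activities act
    JOIN assays a ON a.assay_id = act.assay_id
    JOIN target_dictionary td ON td.tid = a.tid
    JOIN molecule_dictionary md ON md.molregno = act.molregno
    LEFT JOIN compound_structures cs ON cs.molregno = act.molregno
    WHERE td.chembl_id IN (%s)", ph)
  out <- DBI::dbGetQuery(db$con, sql, params = as.list(target_ids))
  if (!is.null(organisms)) out <- out[out$organism %in% organisms, , drop = FALSE]
  out <- out[order(out$target_id, out$ligand_id, out$assay_id,
                   out$standard_type, out$standard_value), ]
  rownames(out) <- NULL
  class(out) <- c("activity_records", "data.frame")
  out
}

#' Apply quality filters to activity records
#'
#' Evaluates each configured rule; surviving records satisfy all of them plus
#' the molecular-weight and heavy-atom windows. Every rejection is recorded
#' with the violated rule in the \code{"rejections"} attribute. Running the
#' filter twice equals running it once.
#'
#' @param records activity records from \code{\link{fetch_activities}}.
#' @param config a \code{\link{miner_config}}.
#' @return filtered records, with attribute \code{rejections} (data.frame of
#'   ligand_id, assay_id, rule).
#' @export
apply_quality_filters <- function(records, config = miner_config()) {
  rej <- list()
  note <- function(idx, rule) {
    if (length(idx) > 0)
      rej[[length(rej) + 1]] <<- data.frame(
        ligand_id = records$ligand_id[idx],
        assay_id = records$assay_id[idx], rule = rule,
        stringsAsFactors = FALSE)
  }
  keep <- rep(TRUE, nrow(records))
  drop_if <- function(bad, rule) {
    bad <- bad & keep
    note(which(bad), rule)
    keep <<- keep & !bad
  }
  if (nrow(records) == 0) {
    attr(records, "rejections") <- data.frame(ligand_id = character(0),
                                              assay_id = character(0),
                                              rule = character(0))
    return(records)
  }
  drop_if(!(records$assay_type %in% config$assay_types), "assay_type")
  drop_if(!(records$relation %in% config$relations), "relation")
  drop_if(is.na(records$standard_value) | records$standard_value <= 0, "standard_value")
  drop_if(!(records$standard_units %in% names(.unit_to_molar)), "standard_units")
  drop_if(!(records$standard_type %in% config$measurement_types), "standard_type")
  if (config$exclude_validity_flags && "data_validity_comment" %in% names(records))
    drop_if(!is.na(records$data_validity_comment) &
              nzchar(records$data_validity_comment), "data_validity")

  # structure-level rules on the unique surviving SMILES
  usmi <- unique(records$canonical_smiles[keep])
  can <- canonical_smiles(usmi)
  parse_ok <- stats::setNames(!is.na(can), usmi)
  drop_if(!is.na(records$canonical_smiles) & keep &
            !parse_ok[records$canonical_smiles] %in% TRUE, "smiles_parse")
  drop_if(is.na(records$canonical_smiles), "smiles_parse")

  usmi <- unique(records$canonical_smiles[keep])
  if (length(usmi) > 0) {
    desc <- compute_descriptors(usmi)
    mw <- stats::setNames(desc$mw, usmi)
    nha <- stats::setNames(desc$nha, usmi)
    drop_if(keep & (mw[records$canonical_smiles] < config$mw_range[1] |
                    mw[records$canonical_smiles] > config$mw_range[2]), "mw_range")
    drop_if(keep & (nha[records$canonical_smiles] < config$nha_range[1] |
                    nha[records$canonical_smiles] > config$nha_range[2]), "nha_range")
  }
  if (config$collapse_duplicates) {
    key <- paste(records$ligand_id, records$assay_id, records$standard_type,
                 records$standard_value, records$standard_units)
    dup <- duplicated(key)
    drop_if(dup, "duplicate")
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- if (length(rej)) do.call(rbind, rej) else
    data.frame(ligand_id = character(0), assay_id = character(0),
               rule = character(0))
  class(out) <- c("activity_records", "data.frame")
  out
}

#' Aggregate measurements into median pAffinity values
#'
#' Converts each measurement to molar and takes
#' \eqn{pAffinity = -log10(value [mol/L])}; per (ligand, target, organism)
#' the median across measurements is reported. Records whose units cannot be
#' converted to a concentration are excluded with a reason.
#'
#' @param records quality-filtered activity records.
#' @return data.frame of class \code{paffinity_records} with columns
#'   \code{ligand_id}, \code{canonical_smiles}, \code{target_id},
#'   \code{organism}, \code{paffinity}, \code{n_measurements}.
#' @export
compute_paffinity <- function(records) {
  if (nrow(records) == 0) {
    out <- data.frame(ligand_id = character(0), canonical_smiles = character(0),
                      target_id = character(0), organism = character(0),
                      paffinity = numeric(0), n_measurements = integer(0))
    class(out) <- c("paffinity_records", "data.frame")
    return(out)
  }
  mult <- .unit_to_molar[records$standard_units]
  convertible <- !is.na(mult) & !is.na(records$standard_value) &
    records$standard_value > 0
  if (any(!convertible))
    message(sum(!convertible), " record(s) excluded: units not convertible to molar")
  rec <- records[convertible, , drop = FALSE]
  paff <- -log10(rec$standard_value * mult[convertible])
  key <- paste(rec$ligand_id, rec$target_id, rec$organism, sep = "\r")
  agg <- split(seq_along(paff), key)
  rows <- lapply(agg, function(idx) {
    data.frame(ligand_id = rec$ligand_id[idx[1]],
               canonical_smiles = rec$canonical_smiles[idx[1]],
               target_id = rec$target_id[idx[1]],
               organism = rec$organism[idx[1]],
               paffinity = stats::median(paff[idx]),
               n_measurements = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$target_id, out$ligand_id, out$organism), ]
  rownames(out) <- NULL
  class(out) <- c("paffinity_records", "data.frame")
  out
}

#' Classify pAffinity records and apply the minimum-affinity filter
#'
#' Labels each record by its threshold bin (boundaries are inclusive on the
#' upper bin, so a record at exactly a threshold enters the higher class) and
#' removes records below \code{paffinity_min} when set (records at exactly
#' the minimum are retained).
#'
#' @param paff_records from \code{\link{compute_paffinity}}.
#' @param config a \code{\link{miner_config}}.
#' @return classified (and possibly filtered) \code{paffinity_records} with
#'   an \code{activity_class} column.
#' @export
classify_and_filter <- function(paff_records, config = miner_config()) {
  if (nrow(paff_records) > 0) {
    bin <- findInterval(paff_records$paffinity, config$class_thresholds) + 1L
    paff_records$activity_class <- config$class_labels[bin]
    if (!is.null(config$paffinity_min))
      paff_records <- paff_records[paff_records$paffinity >= config$paffinity_min, ,
                                   drop = FALSE]
  } else {
    paff_records$activity_class <- character(0)
  }
  rownames(paff_records) <- NULL
  class(paff_records) <- c("paffinity_records", "data.frame")
  paff_records
}

# Tanimoto similarity matrix from OpenBabel fingerprints
.tanimoto_matrix <- function(smiles, fingerprint = "ECFP4") {
  fps <- lapply(smiles, function(s) {
    m <- ChemmineOB::forEachMol("SMILES", paste0(s, "\tm"), identity)
    as.logical(ChemmineOB::fingerprint_OB(m, fingerprint))
  })
  n <- length(fps)
  sim <- diag(1, n)
  if (n > 1) for (i in 2:n) for (j in 1:(i - 1)) {
    a <- fps[[i]]; b <- fps[[j]]
    u <- sum(a | b)
    sim[i, j] <- sim[j, i] <- if (u == 0) 0 else sum(a & b) / u
  }
  sim
}

#' Select chemically diverse parent ligands
#'
#' Hierarchically clusters the ligands on Tanimoto fingerprint distance,
#' cuts the tree at the similarity threshold and keeps one representative
#' per cluster (highest pAffinity; ties broken by the lexicographically
#' smallest ligand id). A final sweep (in decreasing pAffinity order)
#' guarantees that no two retained representatives exceed the similarity
#' threshold.
#'
#' @param paff_records classified \code{paffinity_records}.
#' @param similarity_threshold maximum pairwise Tanimoto similarity between
#'   representatives.
#' @param config a \code{\link{miner_config}} supplying fingerprint and
#'   linkage (threshold argument takes precedence over the config).
#' @return data.frame of parent ligands (\code{ligand_id}, \code{smiles},
#'   \code{paffinity}, \code{cluster}, \code{cluster_size}).
#' @export
select_diverse_parents <- function(paff_records,
                                   similarity_threshold = NULL,
                                   config = miner_config()) {
  if (is.null(similarity_threshold))
    similarity_threshold <- config$similarity_threshold
  out_cols <- function(idx, cluster, size) data.frame(
    ligand_id = paff_records$ligand_id[idx],
    smiles = paff_records$canonical_smiles[idx],
    paffinity = paff_records$paffinity[idx],
    cluster = cluster, cluster_size = size, stringsAsFactors = FALSE)
  n <- nrow(paff_records)
  if (n == 0) return(out_cols(integer(0), integer(0), integer(0)))
  if (n == 1) return(out_cols(1L, 1L, 1L))
  sim <- .tanimoto_matrix(paff_records$canonical_smiles, config$fingerprint)
  hc <- stats::hclust(stats::as.dist(1 - sim), method = config$linkage)
  cl <- stats::cutree(hc, h = 1 - similarity_threshold)
  reps <- vapply(sort(unique(cl)), function(k) {
    idx <- which(cl == k)
    idx[order(-paff_records$paffinity[idx], paff_records$ligand_id[idx])][1]
  }, 0L)
  # enforcement sweep: guarantee pairwise similarity <= threshold
  ord <- reps[order(-paff_records$paffinity[reps], paff_records$ligand_id[reps])]
  kept <- integer(0)
  for (i in ord) {
    if (all(sim[i, kept] <= similarity_threshold)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  res <- out_cols(kept, cl[kept],
                  vapply(cl[kept], function(k) sum(cl == k), 0L))
  rownames(res) <- NULL
  res
}

#' Write selected parents as a SMILES file
#'
#' One record per line: \code{SMILES<TAB>ligand_id<TAB>paffinity}.
#'
#' @param parents result of \code{\link{select_diverse_parents}}.
#' @param path output path.
#' @export
write_parents_smi <- function(parents, path) {
  writeLines(sprintf("%s\t%s\t%.4f", parents$smiles, parents$ligand_id,
                     parents$paffinity), path)
  invisible(path)
}

#' Read a parents SMILES file
#' @param path SMILES file written by \code{\link{write_parents_smi}} (or any
#'   \code{SMILES<TAB>id[<TAB>paffinity]} file).
#' @return data.frame with \code{ligand_id}, \code{smiles}, \code{paffinity}.
#' @export
read_parents_smi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    ligand_id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
    smiles = vapply(parts, `[[`, "", 1),
    paffinity = vapply(parts, function(p)
      if (length(p) > 2) as.numeric(p[3]) else NA_real_, 0),
    stringsAsFactors = FALSE)
}

#' Run the full mining pipeline on a database
#'
#' fetch -> quality filter -> pAffinity aggregation -> classification /
#' affinity filter -> diversity selection.
#'
#' @param db a \code{psw_db}.
#' @param target_ids targets to mine.
#' @param organisms optional organism filter.
#' @param config a \code{\link{miner_config}}.
#' @return list with elements \code{activities}, \code{filtered},
#'   \code{paffinities}, \code{classified}, \code{parents}.
#' @export
mine_parents <- function(db, target_ids, organisms = NULL,
                         config = miner_config()) {
  acts <- fetch_activities(db, target_ids, organisms)
  filt <- apply_quality_filters(acts, config)
  paff <- compute_paffinity(filt)
  cls <- classify_and_filter(paff, config)
  parents <- select_diverse_parents(cls, config = config)
  list(activities = acts, filtered = filt, paffinities = paff,
       classified = cls, parents = parents)
}
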