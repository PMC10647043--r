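# File-based staged pipeline: mine -> react -> prep -> dock -> predict ->
# report. Stages communicate through plain files (SMILES/CSV/SDF/TSV) so any
# stage can be re-run or replaced independently; a JSON manifest records
# seeds and parameters for reproducibility.

#' Default pipeline configuration
#'
#' @param seed global seed recorded in the manifest and used for every
#'   seeded step.
#' @param output_dir artifact directory.
#' @param workers parallel workers for docking.
#' @return nested configuration list of class \code{run_config}.
#' @export
default_run_config <- function(seed = 42L, output_dir = "psw_run",
                               workers = 1L) {
  structure(list(
    global = list(seed = as.integer(seed), workers = as.integer(workers),
                  output_dir = output_dir, log_level = "info"),
    miner = list(target_ids = "CHEMBL_T1", organisms = NULL,
                 paffinity_min = 8.0, similarity_threshold = 0.5),
    reactor = list(categories = c("typical_azologization",
                                  "atypical_azologization",
                                  "naphthalene_azologization"),
                   naphthalene_mode = "both", max_replaced_substituent = 1L),
    prep = list(pH = 7.4, max_variants = 1L, minimize_steps = 250L),
    dockscore = list(engine = "mock", n_poses = 10L, min_fold = 50,
                     contact_cutoff = 4.0, clash_cutoff = 2.5)),
    class = "run_config")
}

#' Save a pipeline configuration to JSON
#' @param config a \code{run_config}.
#' @param path output path.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a pipeline configuration from JSON
#'
#' Unknown keys (at the section or option level) are rejected; the loaded
#' configuration round-trips through \code{\link{save_run_config}}
#' identically.
#'
#' @param path JSON config path.
#' @return a \code{run_config}.
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  template <- unclass(default_run_config())
  bad <- setdiff(names(raw), names(template))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(raw)) {
    extra <- setdiff(names(raw[[sec]]), names(template[[sec]]))
    if (length(extra))
      stop("unknown key(s) in section ", sec, ": ", paste(extra, collapse = ", "))
    for (k in names(raw[[sec]]))
      if (!is.null(raw[[sec]][[k]])) template[[sec]][[k]] <- raw[[sec]][[k]]
  }
  structure(template, class = "run_config")
}

.pipe_path <- function(config, ...) file.path(config$global$output_dir, ...)

.log_msg <- function(config, ...) {
  if (!identical(config$global$log_level, "quiet"))
    message("[pswdesign] ", ...)
}

#' Run the design pipeline
#'
#' Executes the requested stages in order. Each stage reads the previous
#' stage's files from the output directory and writes its own; a missing
#' upstream artifact raises an error naming the required file and the stage
#' that produces it.
#'
#' \describe{
#'   \item{mine}{\code{db_path} -> parents.smi (+ activities.csv,
#'     paffinities.csv)}
#'   \item{react}{parents.smi -> designs.csv, designs.sdf}
#'   \item{prep}{designs.csv -> variants.sdf (3D, protonated, minimized)}
#'   \item{dock}{variants.sdf -> scores.tsv (Pareto-best score per variant)}
#'   \item{predict}{scores.tsv + designs.csv -> report.tsv, report.html}
#' }
#'
#' @param config a \code{run_config}.
#' @param stages subset of c("mine","react","prep","dock","predict").
#' @param db_path SQLite database for the mine stage.
#' @param receptor_path optional PDB file; when given, chain A is prepared
#'   and the binding site defined around the het group named by
#'   \code{reference_het}.
#' @param reference_het resname of the bound reference ligand.
#' @param engine docking engine object; default is the mock engine when
#'   \code{config$dockscore$engine == "mock"}.
#' @return (invisibly) a list of artifact paths.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("mine", "react", "prep", "dock", "predict"),
                         db_path = NULL, receptor_path = NULL,
                         reference_het = "LIG", engine = NULL) {
  dir.create(config$global$output_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(path, producer) {
    if (!file.exists(path))
      stop("required artifact ", path, " is missing; run the '", producer,
           "' stage first")
    path
  }
  paths <- list(parents = .pipe_path(config, "parents.smi"),
                activities = .pipe_path(config, "activities.csv"),
                paffinities = .pipe_path(config, "paffinities.csv"),
                designs = .pipe_path(config, "designs.csv"),
                designs_sdf = .pipe_path(config, "designs.sdf"),
                variants = .pipe_path(config, "variants.sdf"),
                scores = .pipe_path(config, "scores.tsv"),
                report = .pipe_path(config, "report.tsv"),
                report_html = .pipe_path(config, "report.html"),
                manifest = .pipe_path(config, "manifest.json"))

  if ("mine" %in% stages) {
    if (is.null(db_path)) stop("the mine stage requires db_path")
    .log_msg(config, "mine: ", db_path)
    db <- open_database(db_path)
    on.exit(close_database(db), add = TRUE)
    cfg <- miner_config(paffinity_min = config$miner$paffinity_min,
                        similarity_threshold = config$miner$similarity_threshold)
    res <- mine_parents(db, config$miner$target_ids, config$miner$organisms, cfg)
    utils::write.csv(res$activities, paths$activities, row.names = FALSE)
    utils::write.csv(res$classified, paths$paffinities, row.names = FALSE)
    write_parents_smi(res$parents, paths$parents)
  }
  if ("react" %in% stages) {
    parents <- read_parents_smi(need(paths$parents, "mine"))
    .log_msg(config, "react: ", nrow(parents), " parents")
    rules <- build_rule_set(config$reactor$categories,
                            naphthalene_mode = config$reactor$naphthalene_mode,
                            max_replaced_substituent = config$reactor$max_replaced_substituent)
    designs <- run_reactor(parents, rules)
    utils::write.csv(designs, paths$designs, row.names = FALSE)
    write_designs_sdf(designs, paths$designs_sdf)
  }
  if ("prep" %in% stages) {
    designs <- utils::read.csv(need(paths$designs, "react"),
                               stringsAsFactors = FALSE)
    .log_msg(config, "prep: ", nrow(designs), " designs")
    all_var <- list()
    for (i in seq_len(nrow(designs)))
      all_var <- c(all_var, prepare_ligand_variants(
        designs[i, , drop = FALSE], pH = config$prep$pH,
        max_variants = config$prep$max_variants,
        minimize_steps = config$prep$minimize_steps))
    # parents docked alongside their designs
    for (pid in unique(designs$parent_id)) {
      smi <- designs$parent_smiles[designs$parent_id == pid][1]
      pl <- prepare_ligand_variants(stats::setNames(list(smi), "parent"),
                                    pH = config$prep$pH,
                                    max_variants = config$prep$max_variants,
                                    minimize_steps = config$prep$minimize_steps)
      for (k in seq_along(pl)) {
        pl[[k]]$family_id <- paste0("PARENT|", pid)
        pl[[k]]$variant_id <- paste(pl[[k]]$family_id, pl[[k]]$isomer,
                                    pl[[k]]$label, sep = "_")
      }
      all_var <- c(all_var, pl)
    }
    write_variants_sdf(structure(all_var, class = "prepared_ligands"),
                       paths$variants)
  }
  if ("dock" %in% stages) {
    variants <- read_variants_sdf(need(paths$variants, "prep"))
    .log_msg(config, "dock: ", length(variants), " variants")
    if (is.null(engine)) {
      engine <- if (identical(config$dockscore$engine, "plants"))
        plants_engine() else
          make_mock_engine(mock_engine_config(n_poses = config$dockscore$n_poses))
    }
    receptor <- site <- NULL
    if (!is.null(receptor_path)) {
      receptor <- prepare_receptor(load_structure(receptor_path), "A",
                                   keep_het_ids = reference_het)
      site <- define_binding_site(receptor, reference_het)
    }
    docked <- dock(engine, receptor, site, variants,
                   n_poses = config$dockscore$n_poses,
                   workers = config$global$workers)
    scores <- best_scores_by_variant(docked)
    utils::write.table(scores, paths$scores, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if ("predict" %in% stages) {
    scores <- utils::read.delim(need(paths$scores, "dock"),
                                stringsAsFactors = FALSE)
    designs <- utils::read.csv(need(paths$designs, "react"),
                               stringsAsFactors = FALSE)
    .log_msg(config, "predict")
    parent_best <- list()
    for (fid in unique(scores$family_id[scores$isomer == "parent"])) {
      pid <- sub("^PARENT\\|", "", fid)
      parent_best[[pid]] <- min(scores$score[scores$family_id == fid])
    }
    preds <- list()
    for (fid in unique(designs$family_id)) {
      drow <- designs[designs$family_id == fid, , drop = FALSE][1, ]
      fam_sc <- scores[scores$family_id == fid & scores$isomer %in% c("trans", "cis"), ,
                       drop = FALSE]
      pscore <- parent_best[[drow$parent_id]]
      paff <- if ("parent_paffinity" %in% names(drow)) drow$parent_paffinity else NA
      if (is.null(pscore) || nrow(fam_sc) == 0 || is.na(paff)) next
      pr <- withCallingHandlers(
        predict_family_shift(fam_sc, list(paffinity = paff, score = pscore,
                                          family_id = fid)),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(pr)) next
      pr$parent_id <- drow$parent_id
      pr$rule_name <- drow$rule_name
      preds[[length(preds) + 1]] <- pr
    }
    report <- if (length(preds)) do.call(rbind, preds) else
      data.frame(family_id = character(0))
    if (nrow(report) > 0) {
      report$passes_min_fold <- abs(report$fold_change) >= config$dockscore$min_fold
      report <- report[order(-abs(report$fold_change), report$family_id), ]
      front <- c("family_id", "parent_id", "rule_name", "active_isomer",
                 "delta_score", "delta_pki", "fold_change_display")
      report <- report[, c(front, setdiff(names(report), front))]
    }
    write_prediction_report(report, paths$report)
    write_prediction_html(report, paths$report_html)
  }
  manifest <- list(
    package = "pswdesign",
    version = as.character(utils::packageVersion("pswdesign")),
    timestamp = NULL,  # deliberately unrecorded: outputs must be reproducible
    seed = config$global$seed,
    stages = stages,
    config = unclass(config))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}

#' Write prepared variants to an annotated SDF
#'
#' One record per variant, with variant_id, family_id, isomer, label, smiles
#' and energies as SD tags (the stage-handoff format of the prep stage).
#'
#' @param prepared a \code{prepared_ligands} list.
#' @param path output SDF.
#' @export
write_variants_sdf <- function(prepared, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (v in prepared) {
    body <- sub("^[^\n]*", v$variant_id, v$sdf)
    body <- sub("\\$\\$\\$\\$\\s*$", "", body)
    body <- sub("\\n+$", "", body)
    writeLines(body, con)
    tags <- c(variant_id = v$variant_id, family_id = v$family_id,
              isomer = v$isomer, label = v$label, smiles = v$smiles,
              formal_charge = v$formal_charge, energy = v$energy)
    for (tn in names(tags))
      writeLines(c(paste0("> <", tn, ">"), as.character(tags[[tn]]), ""), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Read prepared variants from an annotated SDF
#' @param path SDF written by \code{\link{write_variants_sdf}}.
#' @return a \code{prepared_ligands} list.
#' @export
read_variants_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  breaks <- which(lines == "$$$$")
  start <- 1
  out <- list()
  for (b in breaks) {
    rec <- lines[start:b]
    start <- b + 1
    tagpos <- grep("^> <", rec)
    tags <- list()
    for (tp in tagpos) {
      tn <- sub("^> <([^>]*)>.*$", "\\1", rec[tp])
      tags[[tn]] <- rec[tp + 1]
    }
    molblock <- rec[seq_len(if (length(tagpos)) tagpos[1] - 1 else length(rec) - 1)]
    geom <- .sdf_coords(paste(c(molblock, "$$$$"), collapse = "\n"))
    if (is.null(geom)) next
    out[[length(out) + 1]] <- list(
      variant_id = tags$variant_id, family_id = tags$family_id,
      isomer = tags$isomer, label = tags$label, smiles = tags$smiles,
      formal_charge = as.integer(tags$formal_charge),
      energy = as.numeric(tags$energy),
      coords = geom$coords, elem = geom$elem,
      sdf = paste(molblock, collapse = "\n"))
  }
  structure(out, class = "prepared_ligands")
}
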