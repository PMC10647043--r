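# Docking through a pluggable engine contract, Pareto multiobjective pose
# selection, and the docking-score-based isomeric-shift predictor
# (delta-score -> delta-pKi -> fold-change, with the >= 50-fold filter).

#' Dock prepared ligands through an engine
#'
#' Runs the engine on every prepared ligand variant and collects scored
#' poses. Execution is parallelized over a configurable worker count with
#' deterministic result ordering (results are ordered by variant, then pose
#' index, regardless of scheduling). Per-ligand engine failures flag the
#' ligand and the run continues.
#'
#' @param engine an engine object (see \code{\link{make_mock_engine}},
#'   \code{\link{plants_engine}}).
#' @param receptor a \code{psw_receptor} (or NULL for engines that do not
#'   need one).
#' @param site a \code{binding_site}.
#' @param prepared_ligands a \code{prepared_ligands} list.
#' @param n_poses poses requested per variant (default 10).
#' @param workers parallel workers (forked; 1 = sequential).
#' @return object of class \code{docked_poses}: a list with one element per
#'   variant, each holding \code{variant}, the pose list and any
#'   \code{error}; attribute \code{params} logs the engine settings.
#' @export
dock <- function(engine, receptor, site, prepared_ligands, n_poses = 10,
                 workers = 1) {
  stopifnot(inherits(engine, "psw_engine"))
  run_one <- function(lig) {
    tryCatch(list(variant = lig,
                  poses = psw_dock_one(engine, receptor, site, lig, n_poses),
                  error = NULL),
             error = function(e) list(variant = lig, poses = list(),
                                      error = conditionMessage(e)))
  }
  res <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(prepared_ligands, run_one, mc.cores = workers)
  } else {
    lapply(prepared_ligands, run_one)
  }
  ord <- order(vapply(res, function(r) r$variant$variant_id, ""))
  res <- res[ord]
  failed <- vapply(res, function(r) !is.null(r$error), TRUE)
  if (any(failed))
    warning("docking failed for variant(s): ",
            paste(vapply(res[failed], function(r) r$variant$variant_id, ""),
                  collapse = ", "))
  structure(res, class = "docked_poses",
            params = list(engine = engine$name, n_poses = n_poses,
                          workers = workers))
}

#' @export
print.docked_poses <- function(x, ...) {
  cat("<docked_poses>", length(x), "variants,",
      sum(vapply(x, function(r) length(r$poses), 0L)), "poses (engine: ",
      attr(x, "params")$engine, ")\n")
  invisible(x)
}

#' Contact, clash and uncontacted-atom counts of a pose
#'
#' A contact is a ligand/receptor heavy-atom pair within
#' \code{contact_cutoff}; a clash is a pair closer than \code{clash_cutoff}
#' (clashing pairs also count as contacts); an uncontacted atom is a ligand
#' heavy atom with no contact at all.
#'
#' @param pose a pose (list with \code{coords}) or a bare coordinate matrix.
#' @param receptor a \code{psw_receptor} or a receptor coordinate matrix.
#' @param contact_cutoff contact distance in Angstrom (default 4.0).
#' @param clash_cutoff clash distance in Angstrom (default 2.5).
#' @return named numeric vector (n_contacts, n_clashes, n_uncontacted).
#' @export
compute_pose_metrics <- function(pose, receptor, contact_cutoff = 4.0,
                                 clash_cutoff = 2.5) {
  lig <- if (is.matrix(pose)) pose else pose$coords
  if (!is.matrix(pose) && !is.null(pose$elem))
    lig <- lig[pose$elem != "H", , drop = FALSE]
  rec <- if (inherits(receptor, "psw_receptor")) receptor_coords(receptor)
         else receptor
  stopifnot(all(is.finite(lig)), all(is.finite(rec)))
  d2 <- outer(rowSums(lig^2), rowSums(rec^2), "+") - 2 * lig %*% t(rec)
  d <- sqrt(pmax(d2, 0))
  contact <- d <= contact_cutoff
  c(n_contacts = sum(contact),
    n_clashes = sum(d < clash_cutoff),
    n_uncontacted = sum(rowSums(contact) == 0))
}

#' Pareto-optimal best pose
#'
#' Selects a pose on the four-objective Pareto front (maximize contacts,
#' minimize clashes, minimize uncontacted atoms, minimize total score). When
#' several poses are Pareto-optimal, the one with the lowest total score is
#' retained; remaining ties go to the lowest pose index.
#'
#' @param poses a list of poses (each with \code{n_contacts},
#'   \code{n_clashes}, \code{n_uncontacted}, \code{total_score},
#'   \code{pose_index}).
#' @return the selected pose.
#' @export
pareto_best_pose <- function(poses) {
  if (length(poses) == 0) stop("no poses to select from")
  obj <- vapply(poses, function(p)
    c(-p$n_contacts, p$n_clashes, p$n_uncontacted, p$total_score), numeric(4))
  n <- length(poses)
  dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i && all(obj[, j] <= obj[, i]) && any(obj[, j] < obj[, i])
    }, TRUE))
  }, TRUE)
  front <- which(!dominated)
  scores <- obj[4, front]
  idx <- vapply(poses[front], function(p) p$pose_index, numeric(1))
  front[order(scores, idx)][1] -> best
  poses[[best]]
}

#' Predicted pKi from a docking score
#'
#' Scales the parent's measured pAffinity by the ratio of the variant's
#' docking score to the parent's docking score:
#' \deqn{pKi_{pred} = pAffinity_{parent} \times score / score_{parent}.}
#' This proportional model uses exactly the three inputs available to the
#' predictor (parent score, parent pAffinity, variant score), reduces to the
#' parent's measured affinity when a variant scores like its parent, and
#' makes a better (more negative) score give a higher predicted pKi. It is
#' deliberately isolated here so alternative calibrations can be plugged in.
#'
#' @param score variant docking score (lower = better).
#' @param parent_score parent docking score (must be nonzero).
#' @param parent_paffinity parent's measured median pAffinity.
#' @return predicted pKi.
#' @export
score_to_pki <- function(score, parent_score, parent_paffinity) {
  if (any(parent_score == 0)) stop("parent docking score must be nonzero")
  parent_paffinity * score / parent_score
}

#' Fold-change implied by an isomeric pKi shift
#'
#' \eqn{FC = 10^{|\Delta pKi|}}; the display convention makes the value
#' negative for cis-ON designs (median delta-pKi > 0).
#'
#' @param delta_pki isomeric shift (cis minus trans predicted pKi).
#' @param display return the signed display value (negative = cis-ON).
#' @return fold-change.
#' @export
fold_change <- function(delta_pki, display = FALSE) {
  fc <- 10^abs(delta_pki)
  if (display) fc * ifelse(delta_pki > 0, -1, 1) else fc
}

#' Predict the isomeric affinity shift of a design family
#'
#' For each protonation/tautomer variant label present for both isomers, the
#' best (Pareto-selected) trans and cis poses give
#' \eqn{\Delta Score = score_{cis} - score_{trans}},
#' \eqn{\Delta pKi = pKi_{pred}(cis) - pKi_{pred}(trans)} and
#' \eqn{FC = 10^{|\Delta pKi|}}. Medians across variant pairs define the
#' consensus: the active isomer is cis when the median \eqn{\Delta pKi} is
#' positive, trans when negative, none at zero. The display fold-change is
#' negative for cis-ON families. Unpaired variants are dropped from the
#' consensus; a family missing one isomer entirely is flagged (NULL return).
#'
#' @param family_poses data.frame with columns \code{isomer} ("trans" or
#'   "cis"), \code{label} (variant label) and \code{score} (best-pose score
#'   per variant), e.g. from \code{\link{best_scores_by_variant}}.
#' @param parent_record list or row with \code{paffinity} and \code{score}
#'   (the parent's best-pose docking score); a \code{family_id} is carried
#'   through when present.
#' @return object of class \code{shift_prediction} (a one-row data.frame
#'   with the per-family medians and consensus), or NULL with a warning when
#'   an isomer is missing.
#' @export
predict_family_shift <- function(family_poses, parent_record) {
  tr <- family_poses[family_poses$isomer == "trans", , drop = FALSE]
  ci <- family_poses[family_poses$isomer == "cis", , drop = FALSE]
  labels <- intersect(tr$label, ci$label)
  if (nrow(tr) == 0 || nrow(ci) == 0 || length(labels) == 0) {
    warning("family is missing one isomer; no prediction")
    return(NULL)
  }
  paff <- parent_record$paffinity
  pscore <- parent_record$score
  ds <- dpk <- numeric(length(labels))
  for (k in seq_along(labels)) {
    s_t <- tr$score[tr$label == labels[k]][1]
    s_c <- ci$score[ci$label == labels[k]][1]
    ds[k] <- s_c - s_t
    dpk[k] <- score_to_pki(s_c, pscore, paff) - score_to_pki(s_t, pscore, paff)
  }
  med_ds <- stats::median(ds)
  med_dpk <- stats::median(dpk)
  med_fc <- stats::median(fold_change(dpk))
  active <- if (med_dpk > 0) "cis" else if (med_dpk < 0) "trans" else "none"
  out <- data.frame(
    family_id = if (!is.null(parent_record$family_id))
      parent_record$family_id else NA_character_,
    parent_paffinity = paff, parent_score = pscore,
    n_variant_pairs = length(labels),
    delta_score = med_ds, delta_pki = med_dpk,
    fold_change = fold_change(med_dpk),
    fold_change_display = fold_change(med_dpk, display = TRUE),
    median_fold_change = med_fc,
    active_isomer = active, stringsAsFactors = FALSE)
  class(out) <- c("shift_prediction", "data.frame")
  out
}

#' Best Pareto pose score per variant
#'
#' Convenience reducer from a \code{docked_poses} object to the per-variant
#' best scores used by \code{\link{predict_family_shift}}.
#'
#' @param docked a \code{docked_poses} object.
#' @return data.frame with \code{variant_id}, \code{family_id},
#'   \code{isomer}, \code{label}, \code{score}.
#' @export
best_scores_by_variant <- function(docked) {
  rows <- lapply(docked, function(r) {
    if (length(r$poses) == 0) return(NULL)
    best <- pareto_best_pose(r$poses)
    data.frame(variant_id = r$variant$variant_id,
               family_id = if (!is.null(r$variant$family_id))
                 r$variant$family_id else NA_character_,
               isomer = if (!is.null(r$variant$isomer))
                 r$variant$isomer else NA_character_,
               label = if (!is.null(r$variant$label))
                 r$variant$label else NA_character_,
               score = best$total_score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(variant_id = character(0),
                                      family_id = character(0),
                                      isomer = character(0),
                                      label = character(0), score = numeric(0))
  rownames(out) <- NULL
  out
}

#' Filter predictions by minimum fold-change
#'
#' Retains families whose absolute fold-change is at least \code{min_fold}
#' (boundary inclusive; the default 50-fold corresponds to
#' \eqn{|\Delta pKi| \ge 1.7} within display precision). Set
#' \code{min_fold = NULL} to disable.
#'
#' @param predictions data.frame of \code{shift_prediction} rows.
#' @param min_fold minimum fold-change (default 50), or NULL.
#' @return the retained predictions.
#' @export
apply_shift_filter <- function(predictions, min_fold = 50) {
  if (is.null(min_fold)) return(predictions)
  stopifnot(min_fold >= 1)
  predictions[abs(predictions$fold_change) >= min_fold, , drop = FALSE]
}

#' PLANTS docking engine adapter
#'
#' Adapter for the PLANTS engine (ChemPLP scoring; default settings speed1,
#' 20 ants, 10 poses per variant). Requires the \code{PLANTS} binary on
#' PATH; when absent, an explicit error suggests the mock engine
#' (\code{\link{make_mock_engine}}), which the test suite uses throughout.
#'
#' @param binary path to the PLANTS executable.
#' @param search_speed PLANTS search speed setting.
#' @param ants number of ants.
#' @return an engine object of class \code{psw_engine}.
#' @export
plants_engine <- function(binary = Sys.which("PLANTS"), search_speed = "speed1",
                          ants = 20) {
  structure(list(name = "plants", binary = binary,
                 search_speed = search_speed, ants = ants),
            class = c("psw_plants_engine", "psw_engine"))
}

#' @export
psw_dock_one.psw_plants_engine <- function(engine, receptor, site, ligand,
                                           n_poses = 10) {
  if (is.null(engine$binary) || !nzchar(engine$binary) || !file.exists(engine$binary))
    stop("PLANTS binary not found; install PLANTS or use the mock engine ",
         "(make_mock_engine()) instead")
  workdir <- tempfile("plants_")
  dir.create(workdir)
  on.exit(unlink(workdir, recursive = TRUE))
  ligf <- file.path(workdir, "ligand.mol2")
  recf <- file.path(workdir, "receptor.mol2")
  writeLines(ligand$mol2 %||% stop("ligand lacks MOL2 text"), ligf)
  writeLines(receptor$mol2 %||% stop("receptor lacks MOL2 text"), recf)
  conf <- c(
    paste("protein_file", recf), paste("ligand_file", ligf),
    paste("output_dir", file.path(workdir, "out")),
    paste("bindingsite_center", paste(site$center, collapse = " ")),
    paste("bindingsite_radius", site$radius),
    paste("search_speed", engine$search_speed),
    paste("aco_ants", engine$ants),
    paste("cluster_structures", n_poses),
    "scoring_function chemplp")
  conff <- file.path(workdir, "plants.conf")
  writeLines(conf, conff)
  status <- system2(engine$binary, c("--mode", "screen", conff),
                    stdout = TRUE, stderr = TRUE)
  scoref <- file.path(workdir, "out", "ranking.csv")
  if (!file.exists(scoref)) stop("PLANTS produced no ranking output")
  rank <- utils::read.csv(scoref)
  lapply(seq_len(min(nrow(rank), n_poses)), function(j)
    list(pose_index = j, coords = NULL, total_score = rank$TOTAL_SCORE[j],
         n_contacts = NA_integer_, n_clashes = NA_integer_,
         n_uncontacted = NA_integer_, score_terms = c(total = rank$TOTAL_SCORE[j])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a prediction report as TSV
#'
#' @param predictions data.frame of predictions (rows from
#'   \code{\link{predict_family_shift}}, possibly augmented with parent and
#'   rule columns).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_prediction_report <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a minimal HTML summary of predictions
#'
#' @param predictions data.frame of predictions.
#' @param path output HTML path.
#' @return the path, invisibly.
#' @export
write_prediction_html <- function(predictions, path) {
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  head_cells <- paste0("<th>", esc(names(predictions)), "</th>", collapse = "")
  body <- apply(predictions, 1, function(r)
    paste0("<tr>", paste0("<td>", esc(r), "</td>", collapse = ""), "</tr>"))
  writeLines(c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
               "<title>Isomeric shift predictions</title></head><body>",
               "<h1>Isomeric shift predictions</h1>",
               "<table border='1'>", paste0("<tr>", head_cells, "</tr>"),
               body, "</table></body></html>"), path)
  invisible(path)
}
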