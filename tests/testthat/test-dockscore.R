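# Docking contract, pose metrics, Pareto selection and the isomeric-shift
# predictor.

test_that("the mock engine honors the pose count and the dock contract", {
  eng <- make_mock_engine(mock_engine_config(n_poses = 10))
  ligs <- list(list(variant_id = "v1", isomer = "trans", label = "a",
                    coords = matrix(rnorm(9), 3, 3)))
  dk <- dock(eng, NULL, NULL, ligs, n_poses = 10)
  expect_identical(length(dk[[1]]$poses), 10L)
  expect_identical(length(dock(eng, NULL, NULL, list(), n_poses = 10)), 0L)
})

test_that("parallel docking yields the same ordered result as sequential", {
  eng <- make_mock_engine(mock_engine_config(n_poses = 5))
  ligs <- lapply(1:6, function(i)
    list(variant_id = paste0("v", i), isomer = "trans", label = "a",
         coords = matrix(i, 2, 3)))
  d1 <- dock(eng, NULL, NULL, ligs, n_poses = 5, workers = 1)
  d2 <- dock(eng, NULL, NULL, ligs, n_poses = 5, workers = 2)
  expect_identical(best_scores_by_variant(d1), best_scores_by_variant(d2))
})

test_that("pose metrics count contacts, clashes and uncontacted atoms", {
  rec <- matrix(c(0, 0, 0), 1, 3)
  # one ligand atom at 3.5 A: contact, no clash, no uncontacted atom
  m <- compute_pose_metrics(matrix(c(3.5, 0, 0), 1, 3), rec)
  expect_equal(unname(m), c(1, 0, 0))
  # entirely beyond the cutoff: zero contacts, all atoms uncontacted
  far <- matrix(c(5, 0, 0, 0, 6, 0), 2, 3, byrow = TRUE)
  m2 <- compute_pose_metrics(far, rec)
  expect_equal(unname(m2), c(0, 0, 2))
  # a 2.0 A pair counts as both contact and clash
  m3 <- compute_pose_metrics(matrix(c(2, 0, 0), 1, 3), rec)
  expect_equal(unname(m3), c(1, 1, 0))
  # brute-force pair-enumeration oracle on random geometry
  set.seed(11)
  lig <- matrix(stats::runif(30, -4, 4), 10, 3)
  recm <- matrix(stats::runif(24, -4, 4), 8, 3)
  got <- compute_pose_metrics(lig, recm)
  nc <- ncl <- 0; unc <- 0
  for (i in 1:10) {
    hit <- FALSE
    for (j in 1:8) {
      dd <- sqrt(sum((lig[i, ] - recm[j, ])^2))
      if (dd <= 4.0) { nc <- nc + 1; hit <- TRUE }
      if (dd < 2.5) ncl <- ncl + 1
    }
    if (!hit) unc <- unc + 1
  }
  expect_equal(unname(got), c(nc, ncl, unc))
})

test_that("Pareto selection matches the exhaustive dominance oracle", {
  # a pose dominating in all four objectives wins
  dom <- list(list(pose_index = 1, n_contacts = 9, n_clashes = 0,
                   n_uncontacted = 0, total_score = -90),
              list(pose_index = 2, n_contacts = 5, n_clashes = 1,
                   n_uncontacted = 2, total_score = -60))
  expect_identical(pareto_best_pose(dom)$pose_index, 1)
  # two nondominated poses: the lower score is retained
  tie <- list(list(pose_index = 1, n_contacts = 9, n_clashes = 1,
                   n_uncontacted = 0, total_score = -80),
              list(pose_index = 2, n_contacts = 8, n_clashes = 0,
                   n_uncontacted = 0, total_score = -85))
  expect_identical(pareto_best_pose(tie)$total_score, -85)
  expect_error(pareto_best_pose(list()), "no poses")
  # 200 random instances of up to 12 poses against the oracle
  set.seed(2024)
  for (k in 1:200) {
    poses <- random_pose_set(sample(1:12, 1))
    got <- pareto_best_pose(poses)
    want <- pareto_oracle(poses)
    expect_identical(got$pose_index, want$pose_index)
    # and the selected pose is never dominated by any input pose
    for (p in poses) {
      strictly_better <- (p$n_contacts >= got$n_contacts &&
                          p$n_clashes <= got$n_clashes &&
                          p$n_uncontacted <= got$n_uncontacted &&
                          p$total_score <= got$total_score &&
                          (p$n_contacts > got$n_contacts ||
                           p$n_clashes < got$n_clashes ||
                           p$n_uncontacted < got$n_uncontacted ||
                           p$total_score < got$total_score))
      expect_false(strictly_better)
    }
  }
})

test_that("score_to_pki is the proportional rescaling with its stated identities", {
  expect_equal(score_to_pki(-80, -80, 8), 8)           # identity case
  expect_equal(score_to_pki(-100, -80, 8), 10)         # hand arithmetic
  expect_equal(score_to_pki(0, -80, 8), 0)
  expect_error(score_to_pki(-50, 0, 8), "nonzero")
  # linear in parent pAffinity
  expect_equal(score_to_pki(-90, -80, 16), 2 * score_to_pki(-90, -80, 8))
  # scale-invariant in the score pair
  expect_equal(score_to_pki(-90, -80, 8), score_to_pki(-9, -8, 8))
})

test_that("fold-change is multiplicative and boundary-consistent", {
  for (a in c(-1.3, 0.4, 2)) for (b in c(-0.7, 1.1)) {
    expect_equal(fold_change(a + b), 10^abs(a + b), tolerance = 1e-9)
    expect_equal(10^a * 10^b, 10^(a + b), tolerance = 1e-9)
  }
  expect_equal(fold_change(1.7), 10^1.7, tolerance = 1e-12)
  expect_equal(fold_change(2), 100)
  expect_equal(fold_change(2, display = TRUE), -100)   # cis-ON shows negative
})

test_that("family shift prediction follows the delta-score arithmetic", {
  mk <- function(s_trans, s_cis, labels = "a") {
    data.frame(isomer = rep(c("trans", "cis"), each = length(labels)),
               label = rep(labels, 2), score = c(s_trans, s_cis))
  }
  # equal scores: no shift, no active isomer
  p0 <- predict_family_shift(mk(-80, -80), list(paffinity = 8, score = -80))
  expect_equal(p0$delta_pki, 0)
  expect_equal(p0$fold_change, 1)
  expect_identical(p0$active_isomer, "none")
  # cis scores -100 vs trans -80 at parent (-80, pAff 8): +2 pKi, 100-fold, cis-ON
  p1 <- predict_family_shift(mk(-80, -100), list(paffinity = 8, score = -80))
  expect_equal(p1$delta_pki, 2, tolerance = 1e-12)
  expect_equal(p1$fold_change, 100, tolerance = 1e-9)
  expect_identical(p1$active_isomer, "cis")
  expect_lt(p1$fold_change_display, 0)
  # median over three variant pairs with shifts {1, 2, 9}
  fp <- mk(c(-80, -80, -80), c(-90, -100, -170), labels = c("a", "b", "c"))
  p3 <- predict_family_shift(fp, list(paffinity = 8, score = -80))
  expect_equal(p3$delta_pki, 2, tolerance = 1e-12)
  expect_identical(p3$n_variant_pairs, 3L)
  # missing isomer flags the family
  expect_warning(pn <- predict_family_shift(
    data.frame(isomer = "trans", label = "a", score = -80),
    list(paffinity = 8, score = -80)), "missing one isomer")
  expect_null(pn)
})

test_that("mock-engine-injected shifts are recovered exactly with correct labels", {
  want_label <- c(`-3` = "trans", `-1.7` = "trans", `0` = "none",
                  `1.7` = "cis", `3` = "cis")
  for (d in c(-3, -1.7, 0, 1.7, 3)) {
    eng <- make_mock_engine(mock_engine_config(
      n_poses = 1, score_table = shift_score_table(d)))
    dk <- dock(eng, NULL, NULL, shift_ligands(), n_poses = 1)
    sc <- best_scores_by_variant(dk)
    pr <- predict_family_shift(sc, list(paffinity = 8, score = -80,
                                        family_id = "FAM"))
    expect_equal(pr$delta_pki, d, tolerance = 1e-9)
    expect_identical(pr$active_isomer, unname(want_label[as.character(d)]))
    # sign consistency: cis-ON <=> negative display value <=> positive shift
    if (d != 0) {
      expect_identical(pr$active_isomer == "cis", pr$fold_change_display < 0)
      expect_identical(pr$active_isomer == "cis", pr$delta_pki > 0)
    }
  }
})

test_that("the 50-fold filter is boundary-inclusive and optional", {
  preds <- data.frame(family_id = c("a", "b", "c", "d"),
                      fold_change = c(1, 49.9, 50, 500))
  kept <- apply_shift_filter(preds, 50)
  expect_setequal(kept$family_id, c("c", "d"))
  expect_identical(apply_shift_filter(preds, NULL), preds)
  # delta-pKi 1.7 corresponds to ~50.1-fold and passes the default filter
  expect_true(fold_change(1.7) >= 50)
  p17 <- data.frame(family_id = "x", fold_change = fold_change(1.7))
  expect_identical(nrow(apply_shift_filter(p17)), 1L)
})

test_that("the PLANTS adapter fails helpfully when the binary is absent", {
  eng <- plants_engine(binary = "")
  expect_error(pswdesign:::psw_dock_one(eng, NULL, NULL,
                                        list(variant_id = "v"), 10),
               "mock engine")
})
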