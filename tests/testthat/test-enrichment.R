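mk_ranks <- function(n) stats::setNames(1:n, sprintf("bc_%03d", 1:n))

test_that("decile size uses round-half-up with a floor of one", {
  r65 <- mk_ranks(65)
  top <- decile_members(r65, 0.10, "top")
  expect_length(top, 7)  # round-half-up of 6.5
  expect_setequal(top, names(r65)[1:7])
  bottom <- decile_members(r65, 0.10, "bottom")
  expect_length(bottom, 7)
  expect_setequal(bottom, names(r65)[59:65])
  expect_length(decile_members(mk_ranks(10), 0.10, "top"), 1)
  expect_length(decile_members(mk_ranks(3), 0.10, "top"), 1)
  expect_error(decile_members(r65, 0.6), "fraction")
  expect_error(decile_members(r65, 0), "fraction")
})

test_that("top and bottom deciles are disjoint whenever 2k <= N", {
  for (n in c(10, 20, 65, 100)) {
    r <- mk_ranks(n)
    top <- decile_members(r, 0.10, "top")
    bottom <- decile_members(r, 0.10, "bottom")
    if (2 * length(top) <= n) {
      expect_length(intersect(top, bottom), 0)
    }
  }
})

mk_library <- function(n, levels, axis_col = "ionizable_lipid") {
  lib <- data.frame(barcode_id = sprintf("bc_%03d", 1:n),
                    stringsAsFactors = FALSE)
  lib[[axis_col]] <- rep_len(levels, n)
  lib$cholesterol_variant <- "cholesterol"
  lib$peg_lipid <- "C18PEG2K"
  lib$ratio_label <- "ratio_1"
  lib
}

test_that("fold enrichment is the observed/expected fraction ratio", {
  # 10 LNPs, level in 5 of them, k = 1 decile containing one of the 5
  lib <- mk_library(10, c("X", "Y"))
  fe <- fold_enrichment("bc_001", lib, "ionizable_lipid", "X")
  expect_equal(fe$observed_fraction, 1)
  expect_equal(fe$expected_fraction, 0.5)
  expect_equal(fe$fold, 2.0)
  # a level present in every LNP has fold 1 in any decile
  fe_all <- fold_enrichment(c("bc_001", "bc_004"), lib,
                            "cholesterol_variant", "cholesterol")
  expect_equal(fe_all$fold, 1)
  # absent from the decile -> fold 0
  fe0 <- fold_enrichment("bc_002", lib, "ionizable_lipid", "X")
  expect_equal(fe0$fold, 0)
  expect_error(fold_enrichment("bc_001", lib, "helper", "DOPE"), "axis")
  expect_error(fold_enrichment("zzz", lib, "ionizable_lipid", "X"),
               "belong")
})

test_that("expected-fraction-weighted folds sum to decile coverage", {
  set.seed(7)
  lib <- mk_library(65, sprintf("L%d", 1:8))
  agg <- stats::setNames(runif(65), lib$barcode_id)
  tab <- enrichment_table(agg, lib, axes = "ionizable_lipid")
  for (dir in c("top", "bottom")) {
    sub <- tab[tab$direction == dir, ]
    expect_equal(sum(sub$observed_fraction), 1, tolerance = 1e-12)
    expect_equal(sum(sub$expected_fraction), 1, tolerance = 1e-12)
    expect_equal(sum(sub$expected_fraction * sub$fold), 1,
                 tolerance = 1e-12)
  }
})

test_that("folds are invariant to monotone transforms of delivery", {
  set.seed(8)
  lib <- mk_library(40, sprintf("L%d", 1:5))
  agg <- stats::setNames(runif(40), lib$barcode_id)
  t1 <- enrichment_table(agg, lib)
  t2 <- enrichment_table(log(agg + 1), lib)
  t3 <- enrichment_table(agg * 1000, lib)
  expect_equal(t1$fold, t2$fold)
  expect_equal(t1$fold, t3$fold)
})

test_that("null permutations give mean fold 1 for every level", {
  # small calibration run; the full 10,000-permutation version runs in the
  # acceptance suite
  lib <- mk_library(65, sprintf("L%d", 1:8))
  n_perm <- 1000
  folds <- matrix(NA_real_, n_perm, 8)
  set.seed(99)
  for (p in seq_len(n_perm)) {
    ranks <- stats::setNames(sample(65), lib$barcode_id)
    members <- decile_members(ranks, 0.10, "top")
    folds[p, ] <- vapply(sprintf("L%d", 1:8), function(lv) {
      fold_enrichment(members, lib, "ionizable_lipid", lv)$fold
    }, numeric(1))
  }
  expect_true(all(abs(colMeans(folds) - 1) < 0.15))
  expect_lt(abs(mean(folds) - 1), 0.05)
})

test_that("a 10x component effect enriches top and depletes bottom", {
  des <- small_design()
  hits <- 0L
  for (seed in 1:20) {
    truth <- simulate_ground_truth(
      des$pool, default_samples(mice = 2, depth = 2e4), seed = seed,
      effects = list(ionizable_lipid = c("PPZ-A10" = 10)))
    cl <- simulate_counts(truth, seed = seed + 1000)
    dm <- delivery_matrix(cl$counts, cl$input)
    agg <- aggregate_and_rank(dm)$aggregates[, "all"]
    tab <- enrichment_table(agg, des$pool$members,
                            axes = "ionizable_lipid", fraction = 0.25,
                            control_barcode_id = "bc_ctrl")
    top <- tab[tab$level == "PPZ-A10" & tab$direction == "top", "fold"]
    bot <- tab[tab$level == "PPZ-A10" & tab$direction == "bottom", "fold"]
    hits <- hits + as.integer(top > 1 && bot < 1)
  }
  expect_gte(hits, 18)
})

test_that("bootstrap intervals are deterministic and collapse for
           identical samples", {
  set.seed(5)
  lib <- mk_library(30, sprintf("L%d", 1:5))
  col <- stats::setNames(runif(30), lib$barcode_id)
  vals_same <- cbind(s1 = col, s2 = col, s3 = col)
  b <- bootstrap_enrichment(vals_same, lib, axes = "ionizable_lipid",
                            n_boot = 200, seed = 1)
  expect_equal(b$ci_low, b$fold)
  expect_equal(b$ci_high, b$fold)
  vals <- cbind(s1 = col, s2 = stats::setNames(runif(30), lib$barcode_id),
                s3 = stats::setNames(runif(30), lib$barcode_id))
  b1 <- bootstrap_enrichment(vals, lib, axes = "ionizable_lipid",
                             n_boot = 200, seed = 2)
  b2 <- bootstrap_enrichment(vals, lib, axes = "ionizable_lipid",
                             n_boot = 200, seed = 2)
  expect_identical(b1, b2)
  expect_true(all(b1$ci_low <= b1$fold + 1e-12))
  expect_true(all(b1$ci_high >= b1$fold - 1e-12))
  expect_error(bootstrap_enrichment(vals[, 1, drop = FALSE], lib,
                                    n_boot = 200, seed = 1),
               "2 samples")
  expect_error(bootstrap_enrichment(vals, lib, n_boot = 50, seed = 1),
               "n_boot")
})

test_that("odds-ratio variant agrees in direction with the fraction ratio", {
  set.seed(11)
  lib <- mk_library(65, sprintf("L%d", 1:8))
  agg <- stats::setNames(runif(65), lib$barcode_id)
  r1 <- enrichment_table(agg, lib, axes = "ionizable_lipid")
  r2 <- enrichment_table(agg, lib, axes = "ionizable_lipid",
                         statistic = "odds_ratio")
  same_side <- sign(r1$fold - 1) * sign(r2$fold - 1)
  expect_true(all(same_side >= 0))
})
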