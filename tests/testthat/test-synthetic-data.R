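test_that("ground truth is deterministic and keeps the control lowest", {
  des <- small_design()
  for (seed in c(1L, 99L)) {
    t1 <- simulate_ground_truth(des$pool, seed = seed)
    t2 <- simulate_ground_truth(des$pool, seed = seed)
    expect_identical(t1$propensity, t2$propensity)
    expect_true(all(t1$propensity > 0))
    # control weight strictly below the per-cell-type minimum, by the
    # configured factor
    mins <- apply(t1$propensity, 2, min)
    expect_true(all(t1$control_propensity < mins))
    expect_equal(unname(t1$control_propensity), unname(0.1 * mins))
  }
  t3 <- simulate_ground_truth(des$pool, seed = 1L, control_factor = 0.01)
  expect_equal(unname(t3$control_propensity),
               unname(0.01 * apply(t3$propensity, 2, min)))
  expect_error(simulate_ground_truth(des$pool, seed = 1, error_rate = -1),
               "range")
  expect_error(simulate_ground_truth(des$pool, seed = 1,
                                     control_factor = 2), "control_factor")
})

test_that("log-propensity spread matches the requested sd", {
  des <- small_design()
  samples <- default_samples(cell_types = sprintf("ct%02d", 1:40),
                             mice = 1, depth = 10)
  # 8 LNPs x 40 cell types = 320 draws per truth; pool draws over seeds
  draws <- unlist(lapply(1:32, function(s) {
    log(simulate_ground_truth(des$pool, samples, propensity_sdlog = 0.8,
                              seed = s)$propensity)
  }))
  expect_gt(length(draws), 10000)
  expect_equal(sd(draws), 0.8, tolerance = 0.08)
  expect_equal(mean(draws), 0, tolerance = 0.05)
})

test_that("component effects multiply the propensity of matching LNPs", {
  des <- small_design()
  base <- simulate_ground_truth(des$pool, seed = 4)
  eff <- simulate_ground_truth(des$pool, seed = 4,
                               effects = list(ionizable_lipid =
                                                c("PPZ-A10" = 10)))
  hit <- des$pool$members$ionizable_lipid == "PPZ-A10"
  expect_equal(eff$propensity[hit, ], base$propensity[hit, ] * 10)
  expect_equal(eff$propensity[!hit, ], base$propensity[!hit, ])
})

test_that("input-sample read fractions recover the pool composition", {
  des <- small_design()
  sim <- simulate_input_sample(des$pool, des$scaffolds, des$primer_set,
                               depth = 5e4, error_rate = 0,
                               pcr_bias_sd = 0, seed = 8)
  frac <- sim$truth$reads / sum(sim$truth$reads)
  p <- des$pool$input_proportions[sim$truth$barcode_id]
  # the variance is dominated by the multinomial draw of template molecules
  # (depth / mean_reads_per_molecule of them), not of reads
  n_mol <- 5e4 / 10
  se <- sqrt(p * (1 - p) / n_mol)
  expect_true(all(abs(frac - p) < 4 * se + 2 / n_mol))

  skewed <- c(0.5, 0.25, rep(0.25 / 7, 7))
  names(skewed) <- c(des$pool$barcode_ids[1:2],
                     setdiff(des$pool$barcode_ids,
                             des$pool$barcode_ids[1:2]))
  pool2 <- build_pool(des$pool$members, "bc_ctrl", proportions = skewed)
  sim2 <- simulate_input_sample(pool2, des$scaffolds, des$primer_set,
                                depth = 5e4, error_rate = 0,
                                pcr_bias_sd = 0, seed = 9)
  frac2 <- sim2$truth$reads / sum(sim2$truth$reads)
  p2 <- skewed[sim2$truth$barcode_id]
  se2 <- sqrt(p2 * (1 - p2) / n_mol)
  expect_true(all(abs(frac2 - p2) < 4 * se2 + 2 / n_mol))
})

test_that("zero depth yields an empty but valid FASTQ with a warning", {
  des <- small_design()
  tmp <- withr::local_tempfile(fileext = ".fastq")
  expect_warning(
    sim <- simulate_input_sample(des$pool, des$scaffolds, des$primer_set,
                                 path = tmp, depth = 0, seed = 1),
    "depth 0")
  expect_true(file.exists(tmp))
  expect_length(Biostrings::readDNAStringSet(tmp, format = "fastq"), 0)
  expect_true(all(sim$truth$reads == 0))
})

test_that("reads carry the planted stagger + scaffold structure", {
  des <- small_design()
  truth <- simulate_ground_truth(des$pool, default_samples(mice = 1,
                                                           depth = 500),
                                 error_rate = 0, seed = 3)
  sim <- simulate_sample_reads(truth, "kupffer_m1", des$scaffolds,
                               des$primer_set, seed = 4)
  reads <- as.character(sim$reads)
  w <- nchar(reads)
  expect_true(all(w >= 91 & w <= 91 + max(des$primer_set$fwd_stagger)))
  # every read contains the forward anchor at its stagger offset
  anchor_at <- regexpr(des$primer_set$fwd_anchor, reads, fixed = TRUE)
  expect_true(all(anchor_at >= 1 &
                    anchor_at <= max(des$primer_set$fwd_stagger) + 1))
  # read names encode the planted barcode; the barcode slice agrees
  planted <- sub("^read_[0-9]+:([^:]+):.*$", "\\1", names(sim$reads))
  seqs <- stats::setNames(unname(des$barcodes$barcodes), des$barcodes$ids)
  bc_obs <- unname(substring(reads, anchor_at + 20, anchor_at + 27))
  expect_identical(bc_obs, unname(seqs[planted]))
})

test_that("simulation is byte-identical under a fixed seed", {
  des <- small_design()
  truth <- simulate_ground_truth(des$pool, default_samples(mice = 1,
                                                           depth = 2000),
                                 seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_screen(truth, des$pool, des$scaffolds, des$primer_set,
                        d1, seed = 77, gzip = FALSE)
  s2 <- simulate_screen(truth, des$pool, des$scaffolds, des$primer_set,
                        d2, seed = 77, gzip = FALSE)
  for (f in basename(unname(s1$fastq))) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_identical(readLines(s1$sample_sheet_path),
                   readLines(s2$sample_sheet_path))
  s3 <- simulate_screen(truth, des$pool, des$scaffolds, des$primer_set,
                        withr::local_tempdir(), seed = 78, gzip = FALSE)
  expect_false(identical(readLines(s1$input_fastq),
                         readLines(s3$input_fastq)))
})

test_that("distinct-UMI counts are insensitive to PCR bias", {
  des <- small_design()
  samples <- default_samples(mice = 1, depth = 2e4)
  umis_at <- function(bias_sd, seed) {
    truth <- simulate_ground_truth(des$pool, samples, pcr_bias_sd = bias_sd,
                                   error_rate = 0, seed = seed)
    sim <- simulate_sample_reads(truth, "kupffer_m1", des$scaffolds,
                                 des$primer_set, seed = seed + 100)
    sum(sim$truth$distinct_umis)
  }
  # same molecule budget; bias reshuffles reads across molecules only
  u0 <- mean(vapply(1:3, function(s) umis_at(0, s), numeric(1)))
  u1 <- mean(vapply(1:3, function(s) umis_at(1, s), numeric(1)))
  expect_equal(u1 / u0, 1, tolerance = 0.1)
})

test_that("counts-level simulation mirrors the read-level sampling law", {
  des <- small_design()
  truth <- simulate_ground_truth(des$pool,
                                 default_samples(mice = 1, depth = 5e4),
                                 error_rate = 0, pcr_bias_sd = 0, seed = 31)
  cl <- simulate_counts(truth, seed = 32)
  expect_named(cl$counts, truth$samples$sample_id)
  ct <- cl$counts[["kupffer_m1"]]
  expect_equal(sum(ct$counts$raw_reads), 5e4)
  p <- lnpscreen:::sample_probs(truth, "kupffer")
  frac <- ct$counts$raw_reads / sum(ct$counts$raw_reads)
  se <- sqrt(p * (1 - p) / 5e4)
  expect_true(all(abs(frac - p[ct$counts$barcode_id]) < 4 * se + 2 / 5e4))
  # determinism
  cl2 <- simulate_counts(truth, seed = 32)
  expect_identical(cl$counts[["kupffer_m1"]]$counts, ct$counts)
})
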