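test_that("the forward anchor is located through any stagger tail", {
  ps <- test_primer_set()
  scaffold <- paste0(ps$fwd_anchor, strrep("ACGT", 17), "ACG")
  adapter_len <- nchar(ps$fwd_adapter)
  for (i in seq_along(ps$forward)) {
    tail_i <- substr(ps$forward[i], adapter_len + 1,
                     nchar(ps$forward[i]) - nchar(ps$fwd_anchor))
    read <- paste0(tail_i, scaffold)
    off <- locate_anchor(read, ps)
    expect_equal(off, unname(nchar(tail_i)) + nchar(ps$fwd_anchor) + 1)
  }
  expect_true(is.na(locate_anchor(strrep("N", 91), ps)))
  expect_true(is.na(locate_anchor("", ps)))
})

test_that("one anchor substitution is tolerated at the same offset", {
  ps <- test_primer_set()
  read <- paste0("GAT", ps$fwd_anchor, strrep("TTGCA", 14))
  exact <- locate_anchor(read, ps, max_mismatch = 1)
  mutated <- read
  substr(mutated, 10, 10) <- if (substr(read, 10, 10) == "A") "C" else "A"
  # sliding-window Hamming oracle: best window must be at the same place
  la <- nchar(ps$fwd_anchor)
  dists <- vapply(seq_len(nchar(mutated) - la + 1), function(s) {
    naive_hamming(substr(mutated, s, s + la - 1), ps$fwd_anchor)
  }, integer(1))
  expect_equal(which.min(dists) + la, exact)
  expect_equal(locate_anchor(mutated, ps, max_mismatch = 1), exact)
  # two substitutions exceed the tolerance
  mutated2 <- mutated
  substr(mutated2, 15, 15) <- if (substr(read, 15, 15) == "G") "T" else "G"
  expect_true(is.na(locate_anchor(mutated2, ps, max_mismatch = 1)))
})

test_that("barcode and UMI are sliced at layout-defined offsets", {
  des <- small_design()
  sc <- des$scaffolds[[1]]
  read <- gsub("N", "T", sc$sequence)  # instantiate the UMI as TTTTTTT
  off <- locate_anchor(read, des$primer_set)
  got <- extract_barcode_umi(read, off, des$layout)
  expect_equal(got$barcode,
               unname(des$barcodes$barcodes[sc$barcode_id]))
  expect_equal(got$umi, "TTTTTTT")
  # truncated before the barcode interval
  expect_null(extract_barcode_umi(substr(read, 1, 22), off, des$layout))
  expect_null(extract_barcode_umi(read, NA_integer_, des$layout))
})

test_that("barcode assignment is exact-first, then unique within Hamming 1", {
  set <- generate_barcode_set(20, min_hamming = 3, seed = 13)
  set$ids <- sprintf("bc_%02d", 1:20)
  names(set$barcodes) <- set$ids
  # identity
  expect_equal(assign_barcode(unname(set$barcodes), set),
               set$ids)
  # single substitution: oracle = all-members Hamming scan
  for (i in c(1, 7, 20)) {
    obs <- unname(set$barcodes[i])
    substr(obs, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                 substr(obs, 3, 3))[1]
    d <- vapply(unname(set$barcodes), naive_hamming, integer(1), a = obs)
    expect_equal(which(d <= 1), i, ignore_attr = TRUE)
    expect_equal(assign_barcode(obs, set), set$ids[i])
  }
  # distance >= 2 from every member -> unassigned
  far <- "AAAAAAAA"
  d <- vapply(unname(set$barcodes), naive_hamming, integer(1), a = far)
  if (all(d >= 2)) {
    expect_true(is.na(assign_barcode(far, set)))
  }
  expect_true(is.na(assign_barcode("NNNNNNNN", set)))
})

test_that("a set too tight for mismatch tolerance forces exact matching", {
  set <- lnpscreen:::new_barcode_set(c("AAAAAAAA", "AAAAAAAT", "CCCCCCCC"))
  set$ids <- c("a", "b", "c")
  expect_warning(res <- assign_barcode("AAAAAAAC", set, max_mismatch = 1),
                 "forcing")
  expect_true(is.na(res))
  expect_warning(res2 <- assign_barcode("AAAAAAAT", set, max_mismatch = 1),
                 "forcing")
  expect_equal(res2, "b")
})

test_that("counting recovers simulator truth exactly at error rate 0", {
  des <- small_design()
  truth <- simulate_ground_truth(des$pool,
                                 default_samples(mice = 1, depth = 8000),
                                 error_rate = 0, seed = 51)
  sim <- simulate_sample_reads(truth, "spleen_dc_m1", des$scaffolds,
                               des$primer_set, seed = 52)
  set <- pool_barcode_set(des)
  ct <- count_sample(sim$reads, set, des$primer_set, des$layout)
  m <- match(ct$counts$barcode_id, sim$truth$barcode_id)
  expect_identical(ct$counts$raw_reads, sim$truth$reads[m])
  expect_identical(ct$counts$distinct_umis, sim$truth$distinct_umis[m])
  expect_equal(ct$unassigned_reads, 0)
  expect_equal(ct$total_reads, 8000)
})

test_that("count conservation holds on noisy input and empty input", {
  des <- small_design()
  truth <- simulate_ground_truth(des$pool,
                                 default_samples(mice = 1, depth = 5000),
                                 error_rate = 0.02, seed = 61)
  sim <- simulate_sample_reads(truth, "kupffer_m1", des$scaffolds,
                               des$primer_set, seed = 62)
  set <- pool_barcode_set(des)
  ct <- count_sample(sim$reads, set, des$primer_set, des$layout)
  expect_equal(sum(ct$counts$raw_reads) + ct$unassigned_reads,
               ct$total_reads)
  expect_true(all(ct$counts$distinct_umis <= ct$counts$raw_reads))
  qc <- counting_qc(ct)
  expect_lt(qc$assigned_fraction, 1)
  expect_gt(qc$assigned_fraction, 0.8)

  empty <- count_sample(Biostrings::DNAStringSet(), set, des$primer_set,
                        des$layout)
  expect_equal(empty$total_reads, 0)
  expect_true(all(empty$counts$raw_reads == 0))
})

test_that("raising the error rate never raises the assigned fraction", {
  des <- small_design()
  set <- pool_barcode_set(des)
  assigned_at <- function(rate, seed) {
    truth <- simulate_ground_truth(des$pool,
                                   default_samples(mice = 1, depth = 4000),
                                   error_rate = rate, seed = seed)
    sim <- simulate_sample_reads(truth, "kupffer_m1", des$scaffolds,
                                 des$primer_set, seed = seed + 7)
    ct <- count_sample(sim$reads, set, des$primer_set, des$layout)
    1 - ct$unassigned_reads / ct$total_reads
  }
  for (seed in c(71L, 72L)) {
    f <- vapply(c(0, 0.01, 0.05), assigned_at, numeric(1), seed = seed)
    expect_true(all(diff(f) <= 0.005))  # non-increasing up to noise
  }
})

test_that("reverse-complement reads are recovered when enabled", {
  des <- small_design()
  truth <- simulate_ground_truth(des$pool,
                                 default_samples(mice = 1, depth = 1000),
                                 error_rate = 0, seed = 81)
  sim <- simulate_sample_reads(truth, "kupffer_m1", des$scaffolds,
                               des$primer_set, seed = 82)
  rc <- Biostrings::reverseComplement(sim$reads)
  set <- pool_barcode_set(des)
  ct_rc <- count_sample(rc, set, des$primer_set, des$layout,
                        try_revcomp = TRUE)
  ct_fwd <- count_sample(sim$reads, set, des$primer_set, des$layout)
  expect_identical(ct_rc$counts, ct_fwd$counts)
  ct_off <- count_sample(rc, set, des$primer_set, des$layout,
                         try_revcomp = FALSE)
  expect_equal(ct_off$unassigned_reads, 1000)
})

test_that("counts tables round-trip and reject inconsistent totals", {
  ct <- counts_table("s1", data.frame(barcode_id = c("a", "b"),
                                      raw_reads = c(10L, 5L),
                                      distinct_umis = c(4L, 2L)),
                     unassigned_reads = 3L)
  expect_equal(ct$total_reads, 18L)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_counts(ct, tmp)
  back <- read_counts(tmp)
  expect_identical(back$counts, ct$counts)
  expect_identical(back$total_reads, ct$total_reads)
  expect_error(counts_table("s", data.frame(barcode_id = "a",
                                            raw_reads = 1L,
                                            distinct_umis = 2L)),
               "distinct_umis")
  expect_error(counts_table("s", data.frame(barcode_id = "a",
                                            raw_reads = 1L,
                                            distinct_umis = 1L),
                            unassigned_reads = 1L, total_reads = 5L),
               "conservation")
})
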