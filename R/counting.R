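#' Per-sample barcode counts
#'
#' Container for the raw counting stage: per-barcode read counts and
#' distinct-UMI counts plus the unassigned remainder. The conservation
#' invariant `sum(raw_reads) + unassigned_reads == total_reads` is enforced
#' at construction.
#'
#' @param sample_id Sample label.
#' @param counts data.frame `barcode_id`, `raw_reads`, `distinct_umis`.
#' @param unassigned_reads Reads not assignable to any barcode.
#' @param total_reads Total reads processed; default the implied sum.
#' @return A `counts_table`.
#' @export
counts_table <- function(sample_id, counts, unassigned_reads = 0L,
                         total_reads = sum(counts$raw_reads) +
                           unassigned_reads) {
  stopifnot(all(c("barcode_id", "raw_reads", "distinct_umis") %in%
                  names(counts)))
  if (sum(counts$raw_reads) + unassigned_reads != total_reads) {
    stop("count conservation violated: assigned + unassigned != total",
         call. = FALSE)
  }
  if (any(counts$distinct_umis > counts$raw_reads)) {
    stop("`distinct_umis` cannot exceed `raw_reads`", call. = FALSE)
  }
  structure(list(sample_id = sample_id, counts = counts,
                 unassigned_reads = as.integer(unassigned_reads),
                 total_reads = as.integer(total_reads)),
            class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat(sprintf("counts_table `%s`: %d reads, %.1f%% assigned, %d barcodes\n",
              x$sample_id, x$total_reads,
              if (x$total_reads > 0)
                100 * (1 - x$unassigned_reads / x$total_reads) else 0,
              nrow(x$counts)))
  invisible(x)
}

# Search window for the forward anchor: adapter + max stagger + anchor,
# plus a small slack for upstream indel-free shifts.
anchor_window <- function(primer_set) {
  nchar(primer_set$fwd_adapter) + max(primer_set$fwd_stagger) +
    nchar(primer_set$fwd_anchor)
}

#' Locate the universal forward anchor in a read
#'
#' Finds the best (fewest-mismatch, then leftmost) occurrence of the
#' forward-primer anchor within the staggered 5' region of a read, allowing
#' up to `max_mismatch` substitutions, and returns the position immediately
#' after it (1-based), i.e. where the scaffold payload begins.
#'
#' @param read A DNA string.
#' @param primer_set A `primer_set`.
#' @param max_mismatch Maximum substitutions in the anchor (default 1).
#' @return Integer offset, or `NA_integer_` when no acceptable match exists.
#' @export
locate_anchor <- function(read, primer_set, max_mismatch = 1L) {
  if (!nzchar(read)) return(NA_integer_)
  anchor <- primer_set$fwd_anchor
  la <- nchar(anchor)
  window <- min(nchar(read), anchor_window(primer_set))
  if (window < la) return(NA_integer_)
  anchor_chars <- utf8ToInt(anchor)
  best_mm <- max_mismatch + 1L
  best_at <- NA_integer_
  for (s in seq_len(window - la + 1L)) {
    mm <- sum(utf8ToInt(substr(read, s, s + la - 1L)) != anchor_chars)
    if (mm < best_mm) {
      best_mm <- mm
      best_at <- s
      if (mm == 0L) break
    }
  }
  if (best_mm > max_mismatch) return(NA_integer_)
  best_at + la
}

#' Extract the observed barcode and UMI from a read
#'
#' Slices the 8-nt barcode and 7-nt UMI at their layout-defined distances
#' from the end of the forward anchor.
#'
#' @param read A DNA string.
#' @param offset Position immediately after the anchor, from
#'   [locate_anchor()].
#' @param layout A `scaffold_layout`.
#' @return List `(barcode, umi)`, or `NULL` when the read is too short.
#' @export
extract_barcode_umi <- function(read, offset, layout) {
  if (is.na(offset)) return(NULL)
  off <- layout_offsets(layout)
  bc_start <- offset + off$barcode_from_anchor
  bc_end <- bc_start + off$barcode_length - 1L
  umi_start <- offset + off$umi_from_anchor
  umi_end <- umi_start + off$umi_length - 1L
  if (nchar(read) < max(bc_end, umi_end)) return(NULL)
  list(barcode = substr(read, bc_start, bc_end),
       umi = substr(read, umi_start, umi_end))
}

# Hash from every exact barcode and 1-mismatch neighbour to the member
# index; ambiguous neighbours (impossible at set distance >= 3) map to NA.
neighbor_map <- function(barcodes, max_mismatch) {
  keys <- barcodes
  vals <- seq_along(barcodes)
  if (max_mismatch >= 1L) {
    width <- nchar(barcodes[1])
    for (p in seq_len(width)) {
      for (b in DNA_BASES) {
        mut <- barcodes
        substr(mut, p, p) <- b
        changed <- mut != barcodes
        keys <- c(keys, mut[changed])
        vals <- c(vals, seq_along(barcodes)[changed])
      }
    }
  }
  # exact sequences take precedence; then ambiguous neighbours drop out
  exact <- seq_along(barcodes)
  dup_tab <- split(vals, keys)
  key_names <- names(dup_tab)
  idx <- vapply(dup_tab, function(v) {
    u <- unique(v)
    if (length(u) == 1L) u else NA_integer_
  }, integer(1))
  # a key that IS a member sequence always resolves to that member
  hit <- match(barcodes, key_names)
  idx[hit] <- exact
  stats::setNames(idx, key_names)
}

#' Assign an observed barcode to a designed set
#'
#' Exact matches win; otherwise the unique set member within Hamming
#' distance `max_mismatch` is returned. When the set's minimum pairwise
#' distance is below `2*max_mismatch + 1` the tolerance is forced to 0 with
#' a warning, since mismatch-tolerant assignment would be ambiguous.
#'
#' @param observed Character vector of observed barcode strings.
#' @param set A `barcode_set` (with `ids` when available).
#' @param max_mismatch Maximum Hamming distance (default 1).
#' @return Character vector of barcode IDs, `NA` for unassigned.
#' @export
assign_barcode <- function(observed, set, max_mismatch = 1L) {
  ids <- set$ids %||% names(set$barcodes) %||% set$barcodes
  mh <- set$min_pairwise_hamming
  if (max_mismatch > 0L && !is.na(mh) && mh < 2L * max_mismatch + 1L) {
    warning(sprintf(paste0("set min pairwise Hamming %d < %d: forcing ",
                           "max_mismatch = 0"), mh, 2L * max_mismatch + 1L),
            call. = FALSE)
    max_mismatch <- 0L
  }
  map <- neighbor_map(unname(set$barcodes), max_mismatch)
  idx <- unname(map[observed])
  out <- ids[idx]
  out[is.na(idx)] <- NA_character_
  out
}

# Vectorized anchor location over a DNAStringSet: exact first, then
# progressively more mismatches; returns 1-based offset after the anchor
# (NA = not found). Best (fewest-mismatch) match wins; leftmost on ties.
locate_anchor_vec <- function(reads, primer_set, max_mismatch) {
  anchor <- Biostrings::DNAString(primer_set$fwd_anchor)
  window <- anchor_window(primer_set)
  heads <- Biostrings::subseq(reads, 1L,
                              pmin(Biostrings::width(reads), window))
  offset <- rep(NA_integer_, length(reads))
  todo <- seq_along(reads)
  for (mm in 0:max_mismatch) {
    if (!length(todo)) break
    m <- Biostrings::vmatchPattern(anchor, heads[todo], max.mismatch = mm)
    ends <- Biostrings::endIndex(m)
    hit <- lengths(ends) > 0L
    if (any(hit)) {
      offset[todo[hit]] <- vapply(ends[hit], function(e) e[1L] + 1L,
                                  integer(1))
      todo <- todo[!hit]
    }
  }
  offset
}

#' Count barcodes in a FASTQ sample
#'
#' Streams reads through anchor location, barcode/UMI extraction and
#' mismatch-tolerant assignment, accumulating per-barcode read counts and
#' distinct (barcode, UMI) pairs. Reads whose anchor is not found are
#' optionally retried as reverse complements.
#'
#' @param fastq Path to a FASTQ file (optionally gzipped), or a
#'   `DNAStringSet` of reads.
#' @param set A `barcode_set` with IDs.
#' @param primer_set A `primer_set`.
#' @param layout A `scaffold_layout`.
#' @param max_mismatch_anchor,max_mismatch_barcode Substitution tolerances
#'   (defaults 1 and 1).
#' @param try_revcomp Retry unanchored reads reverse-complemented
#'   (default TRUE).
#' @param sample_id Label for the output table; default the file name.
#' @return A `counts_table` covering every barcode in `set` (zero rows kept).
#' @export
count_sample <- function(fastq, set, primer_set,
                         layout = scaffold_layout(primer_set),
                         max_mismatch_anchor = 1L, max_mismatch_barcode = 1L,
                         try_revcomp = TRUE, sample_id = NULL) {
  if (inherits(fastq, "DNAStringSet")) {
    reads <- fastq
    sample_id <- sample_id %||% "sample"
  } else {
    reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
    sample_id <- sample_id %||% sub("\\.f(ast)?q(\\.gz)?$", "",
                                    basename(fastq))
  }
  ids <- set$ids %||% names(set$barcodes) %||% set$barcodes
  total <- length(reads)
  if (total == 0L) {
    return(counts_table(sample_id,
                        data.frame(barcode_id = ids, raw_reads = 0L,
                                   distinct_umis = 0L,
                                   stringsAsFactors = FALSE)))
  }
  offset <- locate_anchor_vec(reads, primer_set, max_mismatch_anchor)
  if (try_revcomp && anyNA(offset)) {
    miss <- which(is.na(offset))
    rc <- Biostrings::reverseComplement(reads[miss])
    rc_off <- locate_anchor_vec(rc, primer_set, max_mismatch_anchor)
    found <- !is.na(rc_off)
    if (any(found)) {
      reads[miss[found]] <- rc[found]
      offset[miss[found]] <- rc_off[found]
    }
  }
  off <- layout_offsets(layout)
  w <- Biostrings::width(reads)
  bc_start <- offset + off$barcode_from_anchor
  bc_end <- bc_start + off$barcode_length - 1L
  umi_start <- offset + off$umi_from_anchor
  umi_end <- umi_start + off$umi_length - 1L
  ok <- !is.na(offset) & w >= pmax(bc_end, umi_end)
  seqs <- as.character(reads[ok])
  obs_bc <- substring(seqs, bc_start[ok], bc_end[ok])
  obs_umi <- substring(seqs, umi_start[ok], umi_end[ok])
  assigned <- assign_barcode(obs_bc, set, max_mismatch_barcode)
  keep <- !is.na(assigned)
  raw <- tabulate(match(assigned[keep], ids), nbins = length(ids))
  pair <- unique(paste0(assigned[keep], ":", obs_umi[keep]))
  umi_counts <- tabulate(match(sub(":.*$", "", pair), ids),
                         nbins = length(ids))
  counts_table(sample_id,
               data.frame(barcode_id = ids, raw_reads = raw,
                          distinct_umis = umi_counts,
                          stringsAsFactors = FALSE),
               unassigned_reads = total - sum(raw),
               total_reads = total)
}

#' Count every sample on a sample sheet
#'
#' @param sample_sheet data.frame with `sample_id` and `fastq` columns.
#' @param fastq_dir Directory holding the FASTQ files.
#' @param ... Passed to [count_sample()].
#' @inheritParams count_sample
#' @return Named list of `counts_table`s.
#' @export
count_samples <- function(sample_sheet, fastq_dir, set, primer_set, ...) {
  stopifnot(all(c("sample_id", "fastq") %in% names(sample_sheet)))
  out <- lapply(seq_len(nrow(sample_sheet)), function(i) {
    path <- file.path(fastq_dir, sample_sheet$fastq[i])
    if (!file.exists(path)) {
      stop(sprintf("FASTQ for sample `%s` not found: %s",
                   sample_sheet$sample_id[i], path), call. = FALSE)
    }
    count_sample(path, set, primer_set, ...,
                 sample_id = sample_sheet$sample_id[i])
  })
  stats::setNames(out, sample_sheet$sample_id)
}

#' Counting QC summary
#'
#' Run-level diagnostics: assigned fraction and per-barcode UMI saturation
#' (reads per distinct UMI, the PCR-bias monitor the 7-nt random region
#' exists for).
#'
#' @param ct A `counts_table`.
#' @return List: `assigned_fraction`, `umi_saturation` (data.frame
#'   `barcode_id`, `raw_reads`, `distinct_umis`, `reads_per_umi`).
#' @export
counting_qc <- function(ct) {
  d <- ct$counts
  list(
    assigned_fraction = if (ct$total_reads > 0)
      sum(d$raw_reads) / ct$total_reads else NA_real_,
    umi_saturation = data.frame(
      barcode_id = d$barcode_id, raw_reads = d$raw_reads,
      distinct_umis = d$distinct_umis,
      reads_per_umi = ifelse(d$distinct_umis > 0,
                             d$raw_reads / d$distinct_umis, NA_real_),
      stringsAsFactors = FALSE)
  )
}

#' Write / read a counts table
#'
#' Delimited form with columns `sample_id`, `barcode_id`, `raw_reads`,
#' `distinct_umis` plus an `unassigned`/`total` header comment.
#'
#' @param ct A `counts_table`.
#' @param path File path.
#' @return `write_counts()` returns `path` invisibly; `read_counts()` a
#'   `counts_table`.
#' @export
write_counts <- function(ct, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unassigned_reads=%d total_reads=%d",
                     ct$unassigned_reads, ct$total_reads), con)
  utils::write.table(cbind(sample_id = ct$sample_id, ct$counts), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- as.integer(regmatches(header,
                                gregexpr("[0-9]+", header))[[1]])
  tab <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  counts_table(tab$sample_id[1],
               tab[, c("barcode_id", "raw_reads", "distinct_umis")],
               unassigned_reads = meta[1], total_reads = meta[2])
}
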