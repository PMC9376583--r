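#' Size of the barcode sequence space
#'
#' Number of distinct DNA barcodes of a given length over the four-letter
#' alphabet, i.e. `4^length`. An 8-nt barcode region yields 65,536 codes.
#'
#' @param length Barcode length in nucleotides (positive integer).
#' @return Number of distinct barcodes (numeric; exact for `length <= 26`).
#' @examples
#' barcode_space_size(8) # 65536
#' @export
barcode_space_size <- function(length) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 1 || length != floor(length)) {
    stop("`length` must be a positive integer", call. = FALSE)
  }
  4^length
}

new_barcode_set <- function(barcodes) {
  width <- nchar(barcodes[1])
  counts <- per_position_base_counts(barcodes)
  structure(
    list(
      barcodes = barcodes,
      length = width,
      min_pairwise_hamming = min_pairwise_hamming(barcodes),
      per_position_base_counts = counts
    ),
    class = "barcode_set"
  )
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf("barcode_set: %d codes, %d nt, min pairwise Hamming %s\n",
              length(x$barcodes), x$length, x$min_pairwise_hamming))
  invisible(x)
}

# Base composition per barcode position: length x 4 count table.
per_position_base_counts <- function(barcodes) {
  m <- seq_matrix(barcodes)
  counts <- vapply(seq_len(ncol(m)), function(p) {
    tabulate(match(m[, p], DNA_BASES), nbins = 4L)
  }, integer(4))
  counts <- t(counts)
  dimnames(counts) <- list(position = seq_len(ncol(m)), base = DNA_BASES)
  counts
}

#' Generate an error-tolerant barcode set
#'
#' Greedy rejection sampling of `n` distinct DNA barcodes with a guaranteed
#' minimum pairwise Hamming distance, plus an anti-bleaching composition rule:
#' at every position, no single base may occupy more than `diversity_ceiling`
#' of the set. Per-cycle base diversity keeps amplicon runs from losing
#' cluster registration on pattern-less flow cells.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nucleotides (default 8).
#' @param min_hamming Minimum pairwise Hamming distance (default 3, so that
#'   single-mismatch assignment is unambiguous).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param diversity_ceiling Maximum fraction of the set any one base may
#'   occupy at a single position (default 0.75). Ignored for `n == 1`.
#' @param max_attempts Candidate draws before giving up (default `500 * n`).
#' @return A `barcode_set` with elements `barcodes`, `length`,
#'   `min_pairwise_hamming` and `per_position_base_counts`.
#' @examples
#' bs <- generate_barcode_set(66, seed = 1)
#' bs$min_pairwise_hamming >= 3
#' @export
generate_barcode_set <- function(n, length = 8L, min_hamming = 3L, seed,
                                 diversity_ceiling = 0.75,
                                 max_attempts = 500L * n) {
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  if (min_hamming < 1L) stop("`min_hamming` must be >= 1", call. = FALSE)
  if (min_hamming > length) {
    stop("`min_hamming` cannot exceed the barcode length", call. = FALSE)
  }
  if (n > barcode_space_size(length)) {
    stop(sprintf("requested %d barcodes but only %s length-%d codes exist",
                 n, format(barcode_space_size(length), big.mark = ","),
                 length), call. = FALSE)
  }
  with_seed(seed, {
    accepted <- matrix(character(0), nrow = 0L, ncol = length)
    attempts <- 0L
    while (nrow(accepted) < n) {
      if (attempts >= max_attempts) {
        stop(sprintf(paste0("barcode set generation failed: %d/%d codes after ",
                            "%d attempts (length %d, min Hamming %d); ",
                            "relax the constraints or raise `max_attempts`"),
                     nrow(accepted), n, attempts, length, min_hamming),
             call. = FALSE)
      }
      attempts <- attempts + 1L
      cand <- sample(DNA_BASES, length, replace = TRUE)
      ok <- nrow(accepted) == 0L ||
        all(rowSums(accepted != matrix(cand, nrow = nrow(accepted),
                                       ncol = length, byrow = TRUE)) >=
              min_hamming)
      if (!ok) next
      # anti-bleaching: reject candidates that would lock a position once the
      # set is large enough for the ceiling to be meaningful
      if (n > 1L) {
        grown <- rbind(accepted, cand)
        frac <- apply(grown, 2L, function(col) max(table(col))) / nrow(grown)
        # only enforce once enough codes are present that the ceiling is
        # attainable at all (1/ceiling codes)
        if (nrow(grown) >= ceiling(1 / diversity_ceiling) &&
            any(frac > diversity_ceiling)) {
          next
        }
      }
      accepted <- rbind(accepted, cand)
    }
    codes <- apply(accepted, 1L, paste0, collapse = "")
    set <- new_barcode_set(codes)
    if (n > 1L) {
      frac <- apply(set$per_position_base_counts, 1L, max) / n
      if (any(frac > diversity_ceiling + 1e-12)) {
        stop("barcode set generation failed the per-position diversity ceiling",
             call. = FALSE)
      }
    }
    set
  })
}

#' Read a nested-PCR primer table
#'
#' Loads the 8 forward + 8 reverse staggered primers used for amplicon
#' library preparation. Primer sequences may be written in the
#' whitespace-grouped triplet dialect (`TCG TCG GCA ...`); spaces are
#' stripped. The universal anchors are computed as the longest common
#' 3'-terminal subsequence of each orientation, the shared adapter as the
#' longest common 5' prefix, and each primer's stagger length as
#' `nchar(primer) - nchar(adapter) - nchar(anchor)`.
#'
#' @param path Two-column delimited file (`name`, `sequence`); forward primer
#'   names must start with `FWD`, reverse with `RVS`. Defaults to the primer
#'   set shipped with the package.
#' @return A `primer_set` list: `forward`, `reverse` (named sequence vectors),
#'   `fwd_anchor`, `rvs_anchor`, `fwd_adapter`, `rvs_adapter`,
#'   `fwd_stagger`, `rvs_stagger` (named integer vectors).
#' @examples
#' ps <- load_primer_set()
#' ps$fwd_anchor
#' @export
load_primer_set <- function(path = system.file("extdata",
                                               "nested_pcr_primers.tsv",
                                               package = "lnpscreen")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "sequence") %in% names(tab))) {
    stop("primer table needs `name` and `sequence` columns", call. = FALSE)
  }
  seqs <- toupper(gsub("[[:space:]]", "", tab$sequence))
  if (!all(grepl("^[ACGT]+$", seqs))) {
    stop("primer sequences must be DNA (A/C/G/T)", call. = FALSE)
  }
  names(seqs) <- tab$name
  fwd <- seqs[grepl("^FWD", tab$name)]
  rvs <- seqs[grepl("^RVS", tab$name)]
  if (length(fwd) == 0L || length(rvs) == 0L) {
    stop("primer table must contain FWD_* and RVS_* primers", call. = FALSE)
  }
  build <- function(primers, label) {
    anchor <- longest_common_suffix(primers)
    if (nchar(anchor) == 0L) {
      stop(sprintf("%s primers share no common 3' anchor", label),
           call. = FALSE)
    }
    adapter <- longest_common_prefix(primers)
    stagger <- nchar(primers) - nchar(adapter) - nchar(anchor)
    if (any(stagger < 0L)) {
      # adapter and anchor overlap (identical primers): no stagger structure
      stagger <- pmax(stagger, 0L)
    }
    if (anyDuplicated(stagger)) {
      stop(sprintf("%s primers have duplicate stagger lengths", label),
           call. = FALSE)
    }
    list(anchor = anchor, adapter = adapter, stagger = stagger)
  }
  f <- build(fwd, "forward")
  r <- build(rvs, "reverse")
  structure(
    list(forward = fwd, reverse = rvs,
         fwd_anchor = f$anchor, rvs_anchor = r$anchor,
         fwd_adapter = f$adapter, rvs_adapter = r$adapter,
         fwd_stagger = f$stagger, rvs_stagger = r$stagger),
    class = "primer_set"
  )
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("primer_set: %d forward / %d reverse primers\n",
              length(x$forward), length(x$reverse)))
  cat(sprintf("  fwd anchor: %s (staggers %s)\n", x$fwd_anchor,
              paste(sort(x$fwd_stagger), collapse = ",")))
  cat(sprintf("  rvs anchor: %s (staggers %s)\n", x$rvs_anchor,
              paste(sort(x$rvs_stagger), collapse = ",")))
  invisible(x)
}

longest_common_prefix <- function(x) {
  w <- min(nchar(x))
  chars <- lapply(x, function(s) strsplit(substr(s, 1L, w), "")[[1]])
  k <- 0L
  for (p in seq_len(w)) {
    if (length(unique(vapply(chars, `[[`, "", p))) > 1L) break
    k <- p
  }
  substr(x[1], 1L, k)
}

longest_common_suffix <- function(x) {
  rev1 <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  rev1(longest_common_prefix(vapply(x, rev1, "")))
}

# Fixed default sequences for the segments the screen does not read out.
# The probe site hosts a hydrolysis-probe assay for droplet digital PCR;
# the spacer pads the scaffold to its design length. Both are configurable.
DEFAULT_PROBE_SITE <- "TACCAGTCCTGAGGTACAGC"
DEFAULT_SPACER <- "CAGTAACGGTAGCCTA"

#' Default 91-nt scaffold layout
#'
#' Segment order and lengths for the single-stranded barcode scaffold:
#' universal forward primer region, 8-nt barcode, 7-nt degenerate region
#' (UMI), ddPCR probe site, spacer, universal reverse primer region. Primer
#' regions are taken from the primer set anchors (the reverse region is the
#' reverse complement of the reverse anchor, so the reverse primer anneals to
#' the scaffold 3' end); the spacer is sized so segment lengths sum to the
#' scaffold length.
#'
#' @param primer_set A `primer_set` from [load_primer_set()].
#' @param scaffold_length Total scaffold length (default 91).
#' @param probe_site,spacer Fixed sequences for the non-readout segments;
#'   `spacer = NULL` sizes a default spacer automatically.
#' @return A `scaffold_layout` list of named segments, each with `length` and
#'   a fixed `sequence` where one applies (`NA` for barcode8/umi7).
#' @export
scaffold_layout <- function(primer_set, scaffold_length = 91L,
                            probe_site = DEFAULT_PROBE_SITE,
                            spacer = NULL) {
  fwd_region <- primer_set$fwd_anchor
  rvs_region <- revcomp(primer_set$rvs_anchor)
  fixed <- nchar(fwd_region) + 8L + 7L + nchar(probe_site) + nchar(rvs_region)
  pad <- scaffold_length - fixed
  if (is.null(spacer)) {
    if (pad < 0L) {
      stop("segments exceed the scaffold length; shorten the probe site",
           call. = FALSE)
    }
    spacer <- paste(rep(strsplit(DEFAULT_SPACER, "")[[1]],
                        length.out = max(pad, 0L)), collapse = "")
  }
  segments <- list(
    fwd_primer_region = list(length = nchar(fwd_region), sequence = fwd_region),
    barcode8 = list(length = 8L, sequence = NA_character_),
    umi7 = list(length = 7L, sequence = NA_character_),
    probe_site = list(length = nchar(probe_site), sequence = probe_site),
    spacer = list(length = nchar(spacer), sequence = spacer),
    rvs_primer_region = list(length = nchar(rvs_region), sequence = rvs_region)
  )
  total <- sum(vapply(segments, `[[`, integer(1), "length"))
  if (total != scaffold_length) {
    stop(sprintf("segment lengths sum to %d, not %d", total, scaffold_length),
         call. = FALSE)
  }
  structure(list(segments = segments, scaffold_length = scaffold_length),
            class = "scaffold_layout")
}

#' Assemble a barcode scaffold
#'
#' Builds the full single-stranded scaffold for one barcode: the fixed layout
#' with the 8-nt barcode inserted and the 7-nt degenerate region emitted as
#' `NNNNNNN` (each physical molecule carries its own random 7-mer, drawn by
#' the simulator or by oligo synthesis).
#'
#' @param barcode8 An 8-nt DNA barcode.
#' @param primer_set A `primer_set`.
#' @param layout A `scaffold_layout`; default derives one from `primer_set`.
#' @param barcode_id Identifier stored with the scaffold.
#' @param phosphorothioate_ends Number of terminal nucleotides flagged as
#'   phosphorothioate-modified at each end (annotation only; default 2).
#' @return A `barcode_scaffold`: `barcode_id`, `sequence` (91 nt),
#'   `segments` (data.frame of half-open 0-based intervals) and
#'   `phosphorothioate_ends`.
#' @export
assemble_scaffold <- function(barcode8, primer_set,
                              layout = scaffold_layout(primer_set),
                              barcode_id = barcode8,
                              phosphorothioate_ends = 2L) {
  if (!grepl("^[ACGT]{8}$", barcode8)) {
    stop("`barcode8` must be an 8-nt A/C/G/T string", call. = FALSE)
  }
  segs <- layout$segments
  if (sum(vapply(segs, `[[`, integer(1), "length")) != layout$scaffold_length) {
    stop("layout segment lengths do not sum to the scaffold length",
         call. = FALSE)
  }
  pieces <- vapply(names(segs), function(nm) {
    s <- segs[[nm]]
    switch(nm,
           barcode8 = barcode8,
           umi7 = strrep("N", s$length),
           s$sequence)
  }, character(1))
  sequence <- paste(pieces, collapse = "")
  ends <- cumsum(vapply(segs, `[[`, integer(1), "length"))
  starts <- c(0L, utils::head(ends, -1L))
  structure(
    list(barcode_id = barcode_id,
         sequence = sequence,
         segments = data.frame(name = names(segs), start = starts, end = ends,
                               row.names = NULL),
         phosphorothioate_ends = as.integer(phosphorothioate_ends)),
    class = "barcode_scaffold"
  )
}

# Scaffold coordinates the counting stage needs, derived from a layout:
# distances of the barcode and UMI from the end of the forward anchor.
layout_offsets <- function(layout) {
  lens <- vapply(layout$segments, `[[`, integer(1), "length")
  ends <- cumsum(lens)
  starts <- ends - lens
  anchor_end <- ends[["fwd_primer_region"]]
  list(
    barcode_from_anchor = unname(starts[["barcode8"]] - anchor_end),
    barcode_length = unname(lens[["barcode8"]]),
    umi_from_anchor = unname(starts[["umi7"]] - anchor_end),
    umi_length = unname(lens[["umi7"]])
  )
}

#' Write / read a barcode set as FASTA
#'
#' One record per barcode; record IDs are the barcode IDs. Round-trips
#' exactly.
#'
#' @param x A `barcode_set` (or named character vector of sequences).
#' @param path Output FASTA path.
#' @param ids Record IDs; default `bc_001`-style labels.
#' @return `write_barcode_fasta()` returns `path` invisibly;
#'   `read_barcode_fasta()` returns a `barcode_set` with an `ids` element.
#' @export
write_barcode_fasta <- function(x, path, ids = NULL) {
  seqs <- if (inherits(x, "barcode_set")) x$barcodes else x
  if (is.null(ids)) {
    ids <- names(seqs) %||%
      sprintf("bc_%03d", seq_along(seqs))
  }
  dna <- Biostrings::DNAStringSet(unname(seqs))
  names(dna) <- ids
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' @rdname write_barcode_fasta
#' @export
read_barcode_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  set <- new_barcode_set(as.character(dna))
  set$ids <- names(dna)
  names(set$barcodes) <- names(dna)
  set
}
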