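# Shared small fixtures, built in code.

test_primer_set <- local({
  ps <- NULL
  function() {
    if (is.null(ps)) ps <<- load_primer_set()
    ps
  }
})

# A small screen: 3 lipids x 2 cholesterols x 1 PEG x 2 ratios = 12
# formulations, 8 passing QC, plus the control barcode.
small_design <- function(n_pass = 8L, seed = 42L) {
  forms <- enumerate_formulations(
    lipids = c("PPZ-A10", "PPZ-A11", "PPZ-B10"),
    cholesterols = default_cholesterols(),
    pegs = "C18PEG2K",
    ratios = default_ratios()[1:2]
  )
  set <- generate_barcode_set(nrow(forms) + 1L, seed = seed)
  ids <- c(forms$barcode_id, "bc_ctrl")
  set$ids <- ids
  names(set$barcodes) <- ids
  qc <- simulate_qc(forms, n_pass = n_pass, seed = seed + 1L)
  parts <- apply_qc(forms, qc)
  pool <- build_pool(parts$pass, "bc_ctrl")
  ps <- test_primer_set()
  layout <- scaffold_layout(ps)
  list(formulations = forms, barcodes = set, qc = parts, pool = pool,
       primer_set = ps, layout = layout,
       scaffolds = pool_scaffolds(pool, set, ps, layout))
}

# Barcode set restricted to a pool's barcodes (what the counter matches
# against).
pool_barcode_set <- function(design) {
  keep <- design$barcodes$ids %in% design$pool$barcode_ids
  seqs <- unname(design$barcodes$barcodes[keep])
  set <- lnpscreen:::new_barcode_set(seqs)
  set$ids <- design$barcodes$ids[keep]
  names(set$barcodes) <- set$ids
  set
}

# Independent single-read oracle: sliding-window Hamming scan for the
# anchor (leftmost best match), then full-string Hamming against every
# barcode. Deliberately naive and quadratic.
naive_hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

naive_assign_read <- function(read, set, primer_set, layout,
                              max_mm_anchor = 1L, max_mm_barcode = 1L) {
  anchor <- primer_set$fwd_anchor
  la <- nchar(anchor)
  window <- min(nchar(read),
                nchar(primer_set$fwd_adapter) + max(primer_set$fwd_stagger) +
                  la)
  best <- max_mm_anchor + 1L
  at <- NA_integer_
  if (window >= la) {
    for (s in seq_len(window - la + 1L)) {
      mm <- naive_hamming(substr(read, s, s + la - 1L), anchor)
      if (mm < best) {
        best <- mm
        at <- s
      }
    }
  }
  if (is.na(at) || best > max_mm_anchor) return(NA_character_)
  off <- lnpscreen:::layout_offsets(layout)
  bc_start <- at + la + off$barcode_from_anchor
  bc_end <- bc_start + off$barcode_length - 1L
  if (nchar(read) < bc_end) return(NA_character_)
  obs <- substr(read, bc_start, bc_end)
  ids <- set$ids
  d <- vapply(unname(set$barcodes), naive_hamming, integer(1), a = obs)
  if (any(d == 0L)) return(ids[which(d == 0L)[1]])
  hits <- which(d <= max_mm_barcode)
  if (length(hits) == 1L) ids[hits] else NA_character_
}
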