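#' Simulate a dynamic-light-scattering QC table
#'
#' Draws plausible instrument readouts for a formulation library so that a
#' chosen number of LNPs pass the size/monodispersity gate: passing particles
#' get diameters well inside (20, 200) nm; failing particles are split
#' between oversized aggregates and polydisperse preparations.
#'
#' @param formulations Formulation table.
#' @param n_pass Number of formulations that should pass QC (default 65, the
#'   screened library size).
#' @param seed Integer seed.
#' @return data.frame `lnp_id`, `diameter_nm`, `monodisperse`, `pdi`.
#' @export
simulate_qc <- function(formulations, n_pass = 65L, seed) {
  n <- nrow(formulations)
  if (n_pass > n) stop("`n_pass` exceeds the library size", call. = FALSE)
  with_seed(seed, {
    pass_idx <- sort(sample.int(n, n_pass))
    diameter <- numeric(n)
    mono <- logical(n)
    pdi <- numeric(n)
    diameter[pass_idx] <- stats::runif(n_pass, 60, 180)
    mono[pass_idx] <- TRUE
    pdi[pass_idx] <- stats::runif(n_pass, 0.05, 0.25)
    fail_idx <- setdiff(seq_len(n), pass_idx)
    if (length(fail_idx)) {
      oversized <- stats::runif(length(fail_idx)) < 0.5
      diameter[fail_idx] <- ifelse(oversized,
                                   stats::runif(length(fail_idx), 210, 400),
                                   stats::runif(length(fail_idx), 60, 180))
      mono[fail_idx] <- oversized  # polydisperse preparations fail the
                                   # autocorrelation criterion instead
      pdi[fail_idx] <- ifelse(oversized,
                              stats::runif(length(fail_idx), 0.05, 0.25),
                              stats::runif(length(fail_idx), 0.35, 0.7))
    }
    data.frame(lnp_id = formulations$lnp_id, diameter_nm = diameter,
               monodisperse = mono, pdi = pdi, stringsAsFactors = FALSE)
  })
}

#' Default sorted-cell sample grid
#'
#' The cell populations the screen reads out (the three most transfected
#' populations) crossed with replicate mice.
#'
#' @param cell_types Character vector of cell populations.
#' @param mice Number of mice (default 3).
#' @param depth Sequencing depth (reads) per sorted sample.
#' @return data.frame `sample_id`, `mouse`, `cell_type`, `depth`.
#' @export
default_samples <- function(cell_types = c("kupffer", "spleen_macrophage",
                                           "spleen_dc"),
                            mice = 3L, depth = 1e5) {
  grid <- expand.grid(mouse = seq_len(mice), cell_type = cell_types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_m%d", grid$cell_type, grid$mouse),
             mouse = grid$mouse, cell_type = grid$cell_type,
             depth = depth, stringsAsFactors = FALSE)
}

#' Simulate ground-truth delivery propensities
#'
#' Draws a log-normal relative delivery weight for every LNP x cell type
#' (delivery across a pooled screen spans orders of magnitude, which a
#' log-scale model captures), optionally multiplied by component-level
#' effects, and sets the unencapsulated control barcode's weight below the
#' minimum LNP weight by a fixed factor — naked DNA does not readily enter
#' cells.
#'
#' @param pool A `screen_pool`.
#' @param samples Sample grid as from [default_samples()].
#' @param propensity_sdlog SD of log-propensities across LNPs (default 1).
#' @param control_factor Control weight as a fraction of the per-cell-type
#'   minimum LNP weight (default 0.1; must be in (0, 1)).
#' @param pcr_bias_sd SD of the per-molecule log-normal amplification factor
#'   (default 0.5).
#' @param error_rate Per-base substitution probability (default 0.005).
#' @param mean_reads_per_molecule Target amplification depth; sets how many
#'   template molecules underlie a sample's reads (default 10).
#' @param effects Optional named list of component effects, e.g.
#'   `list(ionizable_lipid = c("PPZ-A10" = 10))`: every LNP whose component
#'   matches has its propensity multiplied in every cell type.
#' @param seed Integer seed.
#' @return A `ground_truth` list: `propensity` (LNP-barcode x cell-type
#'   matrix), `control_propensity` (named per cell type), `samples`,
#'   the simulation parameters and `seed`.
#' @export
simulate_ground_truth <- function(pool, samples = default_samples(),
                                  propensity_sdlog = 1, control_factor = 0.1,
                                  pcr_bias_sd = 0.5, error_rate = 0.005,
                                  mean_reads_per_molecule = 10, seed,
                                  effects = NULL) {
  if (propensity_sdlog < 0 || pcr_bias_sd < 0 || error_rate < 0 ||
      error_rate >= 1 || mean_reads_per_molecule <= 0) {
    stop("simulation parameters out of range", call. = FALSE)
  }
  if (control_factor <= 0 || control_factor >= 1) {
    stop("`control_factor` must be in (0, 1)", call. = FALSE)
  }
  member_bcs <- pool$members$barcode_id
  cell_types <- unique(samples$cell_type)
  with_seed(seed, {
    prop <- matrix(stats::rlnorm(length(member_bcs) * length(cell_types),
                                 meanlog = 0, sdlog = propensity_sdlog),
                   nrow = length(member_bcs),
                   dimnames = list(member_bcs, cell_types))
    if (!is.null(effects)) {
      for (axis in names(effects)) {
        if (!axis %in% names(pool$members)) {
          stop(sprintf("unknown component axis `%s` in `effects`", axis),
               call. = FALSE)
        }
        eff <- effects[[axis]]
        for (level in names(eff)) {
          hit <- pool$members[[axis]] == level
          prop[hit, ] <- prop[hit, ] * eff[[level]]
        }
      }
    }
    control <- control_factor * apply(prop, 2L, min)
    structure(
      list(propensity = prop, control_propensity = control,
           samples = samples, propensity_sdlog = propensity_sdlog,
           control_factor = control_factor, pcr_bias_sd = pcr_bias_sd,
           error_rate = error_rate,
           mean_reads_per_molecule = mean_reads_per_molecule,
           control_barcode_id = pool$control_barcode_id,
           input_proportions = pool$input_proportions, seed = seed),
      class = "ground_truth"
    )
  })
}

# Per-barcode sampling probabilities for a sorted-cell sample:
# input proportion x delivery propensity, renormalized.
sample_probs <- function(truth, cell_type) {
  w <- c(truth$propensity[, cell_type],
         stats::setNames(truth$control_propensity[[cell_type]],
                         truth$control_barcode_id))
  q <- truth$input_proportions[names(w)]
  p <- q * w
  p / sum(p)
}

# Build scaffolds for every barcode in a pool (members + control).
#' Assemble scaffolds for all pool barcodes
#'
#' @param pool A `screen_pool`.
#' @param barcode_set A `barcode_set` whose `ids` cover the pool barcodes
#'   (as read back from the design FASTA).
#' @param primer_set A `primer_set`.
#' @param layout Scaffold layout (default from the primer set).
#' @return Named list of `barcode_scaffold` objects keyed by barcode ID.
#' @export
pool_scaffolds <- function(pool, barcode_set, primer_set,
                           layout = scaffold_layout(primer_set)) {
  ids <- barcode_set$ids %||% names(barcode_set$barcodes)
  if (is.null(ids)) stop("`barcode_set` carries no barcode IDs", call. = FALSE)
  missing <- setdiff(pool$barcode_ids, ids)
  if (length(missing)) {
    stop(sprintf("no barcode sequence for pool member(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  seqs <- stats::setNames(unname(barcode_set$barcodes), ids)
  lapply(stats::setNames(pool$barcode_ids, pool$barcode_ids), function(id) {
    assemble_scaffold(seqs[[id]], primer_set, layout, barcode_id = id)
  })
}

# Inject i.i.d. substitution errors into DNA strings (vectorized draw of the
# per-read error count; per-event base flips applied in one pass).
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  w <- nchar(seqs)
  k <- stats::rbinom(length(seqs), w, error_rate)
  hit <- which(k > 0L)
  if (!length(hit)) return(seqs)
  pos_list <- lapply(hit, function(i) sample.int(w[i], k[i]))
  idx <- rep(hit, k[hit])
  pos <- unlist(pos_list, use.names = FALSE)
  old <- substring(seqs[idx], pos, pos)
  # substitute with one of the three other bases, uniformly
  shift <- sample.int(3L, length(old), replace = TRUE)
  new <- DNA_BASES[(match(old, DNA_BASES) - 1L + shift) %% 4L + 1L]
  for (j in seq_along(idx)) {
    substr(seqs[idx[j]], pos[j], pos[j]) <- new[j]
  }
  seqs
}

simulate_reads_core <- function(probs, scaffolds, primer_set, depth,
                                pcr_bias_sd, error_rate,
                                mean_reads_per_molecule, umi_length = 7L,
                                quality_char = "I") {
  ids <- names(probs)
  if (depth == 0L) {
    return(list(reads = Biostrings::DNAStringSet(), qualities = character(0),
                truth = data.frame(barcode_id = ids, molecules = 0L,
                                   reads = 0L, stringsAsFactors = FALSE)))
  }
  n_mol <- max(1L, round_half_up(depth / mean_reads_per_molecule))
  mol_counts <- as.integer(stats::rmultinom(1L, n_mol, probs))
  mol_bc <- rep.int(seq_along(ids), mol_counts)
  umis <- random_dna(n_mol, umi_length)
  # per-molecule amplification factor; reads allocated across molecules
  w <- stats::rlnorm(n_mol, meanlog = 0, sdlog = pcr_bias_sd)
  reads_per_mol <- as.integer(stats::rmultinom(1L, depth, w))
  mol_of_read <- rep.int(seq_len(n_mol), reads_per_mol)
  # molecule sequence = scaffold with its UMI instantiated
  first <- scaffolds[[1]]
  segs <- first$segments
  u <- segs[segs$name == "umi7", ]
  pre <- vapply(scaffolds, function(s) substr(s$sequence, 1L, u$start), "")
  post <- vapply(scaffolds,
                 function(s) substr(s$sequence, u$end + 1L,
                                    nchar(s$sequence)), "")
  mol_seq <- paste0(pre[mol_bc], umis, post[mol_bc])
  # staggered forward primer tail, uniform over the 8 primers
  adapter_len <- nchar(primer_set$fwd_adapter)
  tails <- vapply(primer_set$forward, function(p) {
    substr(p, adapter_len + 1L,
           nchar(p) - nchar(primer_set$fwd_anchor))
  }, "")
  tail_of_read <- sample(tails, depth, replace = TRUE)
  seqs <- paste0(tail_of_read, mol_seq[mol_of_read])
  seqs <- inject_errors(seqs, error_rate)
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- sprintf("read_%d:%s:mol%d", seq_len(depth),
                          ids[mol_bc[mol_of_read]], mol_of_read)
  mol_seen <- unique(mol_of_read)
  # distinct (barcode, UMI) pairs among sequenced molecules: what an exact
  # UMI collapse can recover (7-mer collisions merge molecules)
  pairs <- unique(paste0(mol_bc[mol_seen], ":", umis[mol_seen]))
  pair_bc <- as.integer(sub(":.*", "", pairs))
  truth <- data.frame(
    barcode_id = ids,
    molecules = mol_counts,
    molecules_sequenced = tabulate(mol_bc[mol_seen], nbins = length(ids)),
    distinct_umis = tabulate(pair_bc, nbins = length(ids)),
    reads = tabulate(mol_bc[mol_of_read], nbins = length(ids)),
    stringsAsFactors = FALSE
  )
  list(reads = reads,
       qualities = strrep(quality_char, nchar(seqs)),
       truth = truth)
}

write_fastq <- function(sim, path) {
  qual <- Biostrings::BStringSet(sim$qualities)
  Biostrings::writeXStringSet(sim$reads, filepath = path, format = "fastq",
                              qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Simulate amplicon reads for one sorted-cell sample
#'
#' Draws template molecules multinomially with probabilities proportional to
#' input proportion x delivery propensity, gives each molecule a fresh
#' random 7-nt UMI, amplifies each molecule by a log-normal PCR-bias factor
#' (reads are allocated across molecules proportionally to the factor),
#' prefixes each read with a uniformly chosen staggered forward-primer tail,
#' and applies i.i.d. substitution errors. Quality strings are constant.
#'
#' @param truth A `ground_truth`.
#' @param sample_id A sample ID present in `truth$samples`.
#' @param scaffolds Named scaffold list from [pool_scaffolds()].
#' @param primer_set A `primer_set`.
#' @param path Output FASTQ path (`.gz` for gzip); `NULL` keeps reads in
#'   memory.
#' @param depth Read count; default the sample's depth in `truth$samples`.
#' @param seed Integer seed.
#' @return List: `path`, `reads` (`DNAStringSet`, only when `path` is NULL),
#'   `truth` (per-barcode molecule and read counts), `sample_id`.
#' @export
simulate_sample_reads <- function(truth, sample_id, scaffolds, primer_set,
                                  path = NULL, depth = NULL, seed) {
  row <- truth$samples[truth$samples$sample_id == sample_id, ]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown sample `%s`", sample_id), call. = FALSE)
  }
  depth <- as.integer(depth %||% row$depth)
  if (depth == 0L) warning("depth 0: writing an empty FASTQ", call. = FALSE)
  probs <- sample_probs(truth, row$cell_type)
  sim <- with_seed(seed, {
    simulate_reads_core(probs, scaffolds[names(probs)], primer_set, depth,
                        truth$pcr_bias_sd, truth$error_rate,
                        truth$mean_reads_per_molecule)
  })
  out <- list(sample_id = sample_id, truth = sim$truth)
  if (is.null(path)) {
    out$reads <- sim$reads
    out$qualities <- sim$qualities
  } else {
    write_fastq(sim, path)
    out$path <- path
  }
  out
}

#' Simulate the injected input-pool sample
#'
#' As [simulate_sample_reads()] but with delivery propensities identically 1:
#' reads reflect the pool composition only. This is the "input" library the
#' delivery quantification normalizes against.
#'
#' @inheritParams simulate_sample_reads
#' @param pool A `screen_pool`.
#' @param pcr_bias_sd,error_rate,mean_reads_per_molecule Simulation
#'   parameters (defaults as in [simulate_ground_truth()]).
#' @return As [simulate_sample_reads()], with `sample_id = "input"`.
#' @export
simulate_input_sample <- function(pool, scaffolds, primer_set, path = NULL,
                                  depth = 1e5, pcr_bias_sd = 0.5,
                                  error_rate = 0.005,
                                  mean_reads_per_molecule = 10, seed) {
  depth <- as.integer(depth)
  if (depth == 0L) warning("depth 0: writing an empty FASTQ", call. = FALSE)
  probs <- pool$input_proportions
  sim <- with_seed(seed, {
    simulate_reads_core(probs, scaffolds[names(probs)], primer_set, depth,
                        pcr_bias_sd, error_rate, mean_reads_per_molecule)
  })
  out <- list(sample_id = "input", truth = sim$truth)
  if (is.null(path)) {
    out$reads <- sim$reads
    out$qualities <- sim$qualities
  } else {
    write_fastq(sim, path)
    out$path <- path
  }
  out
}

#' Simulate a whole screen to FASTQ files
#'
#' Writes one FASTQ per sorted-cell sample plus the input-pool sample, a
#' sample sheet, per-sample truth tables and a run manifest recording every
#' parameter and seed.
#'
#' @param truth A `ground_truth`.
#' @param pool A `screen_pool`.
#' @param scaffolds Named scaffold list.
#' @param primer_set A `primer_set`.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed (per-sample seeds are drawn from this stream).
#' @param gzip Write gzipped FASTQ (default TRUE).
#' @return List: `sample_sheet` (data.frame `sample_id`, `mouse`,
#'   `cell_type`, `fastq`), `input_fastq`, `truth_tables` (per sample),
#'   `manifest` path.
#' @export
simulate_screen <- function(truth, pool, scaffolds, primer_set, outdir,
                            seed, gzip = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  n <- nrow(truth$samples)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n + 1L))
  files <- file.path(outdir, paste0(truth$samples$sample_id, ext))
  truth_tables <- vector("list", n)
  for (i in seq_len(n)) {
    res <- simulate_sample_reads(truth, truth$samples$sample_id[i], scaffolds,
                                 primer_set, path = files[i], seed = seeds[i])
    truth_tables[[i]] <- res$truth
  }
  names(truth_tables) <- truth$samples$sample_id
  input_path <- file.path(outdir, paste0("input", ext))
  input <- simulate_input_sample(pool, scaffolds, primer_set,
                                 path = input_path,
                                 depth = max(truth$samples$depth),
                                 pcr_bias_sd = truth$pcr_bias_sd,
                                 error_rate = truth$error_rate,
                                 mean_reads_per_molecule =
                                   truth$mean_reads_per_molecule,
                                 seed = seeds[n + 1L])
  truth_tables$input <- input$truth
  sheet <- data.frame(truth$samples[, c("sample_id", "mouse", "cell_type")],
                      fastq = basename(files), stringsAsFactors = FALSE)
  sheet_path <- file.path(outdir, "sample_sheet.tsv")
  write_table_tsv(sheet, sheet_path)
  for (nm in names(truth_tables)) {
    write_table_tsv(truth_tables[[nm]],
                    file.path(outdir, sprintf("truth_%s.tsv", nm)))
  }
  manifest <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(list(
    seed = seed, sample_seeds = as.integer(seeds),
    propensity_sdlog = truth$propensity_sdlog,
    control_factor = truth$control_factor,
    pcr_bias_sd = truth$pcr_bias_sd, error_rate = truth$error_rate,
    mean_reads_per_molecule = truth$mean_reads_per_molecule,
    control_barcode_id = truth$control_barcode_id,
    n_members = nrow(pool$members),
    total_dose_mg_per_kg = pool$total_dose_mg_per_kg
  ), manifest)
  list(sample_sheet = sheet, sample_sheet_path = sheet_path,
       fastq = stats::setNames(files, truth$samples$sample_id),
       input_fastq = input_path, truth_tables = truth_tables,
       manifest = manifest)
}

#' Counts-level screen simulation
#'
#' Fast path that skips read strings: per sample, template molecules are
#' drawn multinomially from input x propensity and reads are allocated over
#' molecules with log-normal PCR-bias weights, exactly as in the read
#' simulator, but the result is returned directly as counts tables. Useful
#' for Monte-Carlo studies of the rank-based statistics where the FASTQ and
#' extraction layers are not under test.
#'
#' @param truth A `ground_truth`.
#' @param input_depth Depth of the input sample (default the max sample
#'   depth).
#' @param seed Integer seed.
#' @return List: `counts` (list of `counts_table` per sample), `input`
#'   (a `counts_table`).
#' @export
simulate_counts <- function(truth, input_depth = NULL, seed) {
  n <- nrow(truth$samples)
  input_depth <- as.integer(input_depth %||% max(truth$samples$depth))
  with_seed(seed, {
    draw <- function(probs, depth, sample_id) {
      n_mol <- max(1L, round_half_up(depth / truth$mean_reads_per_molecule))
      mol_counts <- as.integer(stats::rmultinom(1L, n_mol, probs))
      w <- stats::rlnorm(n_mol, 0, truth$pcr_bias_sd)
      mol_bc <- rep.int(seq_along(probs), mol_counts)
      reads_per_mol <- as.integer(stats::rmultinom(1L, depth, w))
      raw <- vapply(split(reads_per_mol, factor(mol_bc,
                                                levels = seq_along(probs))),
                    sum, integer(1))
      # one distinct UMI per sequenced molecule (7-mer collisions ignored at
      # this resolution)
      umis <- tabulate(mol_bc[reads_per_mol > 0L], nbins = length(probs))
      counts_table(sample_id,
                   data.frame(barcode_id = names(probs),
                              raw_reads = unname(raw),
                              distinct_umis = umis,
                              stringsAsFactors = FALSE),
                   unassigned_reads = 0L)
    }
    counts <- lapply(seq_len(n), function(i) {
      draw(sample_probs(truth, truth$samples$cell_type[i]),
           as.integer(truth$samples$depth[i]), truth$samples$sample_id[i])
    })
    names(counts) <- truth$samples$sample_id
    input <- draw(truth$input_proportions, input_depth, "input")
    list(counts = counts, input = input)
  })
}
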