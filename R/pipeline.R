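#' Default run configuration
#'
#' A complete, validated configuration for the end-to-end pipeline:
#' design (components, ratios, barcode parameters), QC thresholds, pool
#' dosing, simulation parameters, counting tolerances, quantification and
#' enrichment settings. Any field can be overridden via `...` or a YAML
#' file.
#'
#' @param ... Named overrides merged over the defaults (nested lists merge
#'   by name).
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    design = list(
      lipids = default_lipids(),
      cholesterols = default_cholesterols(),
      pegs = default_pegs(),
      helper = "DOPE",
      ratios = default_ratios(),
      barcode_length = 8L,
      min_hamming = 3L,
      diversity_ceiling = 0.75,
      scaffold_length = 91L,
      seed = 20201L
    ),
    qc = list(d_min_nm = 20, d_max_nm = 200, pdi_max = 0.3,
              n_pass = 65L, seed = 20202L),
    pool = list(total_dose_mg_per_kg = 1.5,
                mrna_to_barcode_mass_ratio = 10,
                control_barcode_id = "bc_ctrl"),
    sim = list(cell_types = c("kupffer", "spleen_macrophage", "spleen_dc"),
               mice = 3L, depth = 1e5, propensity_sdlog = 1,
               control_factor = 0.1, pcr_bias_sd = 0.5, error_rate = 0.005,
               mean_reads_per_molecule = 10, seed = 20203L),
    counting = list(max_mismatch_anchor = 1L, max_mismatch_barcode = 1L,
                    try_revcomp = TRUE),
    quant = list(pseudocount = 0.5),
    enrichment = list(fraction = 0.10, n_boot = 1000L, seed = 20204L)
  )
  structure(merge_config(cfg, list(...)), class = "run_config")
}

# Merge config sections one level deep: sections combine by name, but a
# value inside a section (including list-valued ones such as `ratios`)
# replaces the default wholesale.
merge_config <- function(base, override, depth = 1L) {
  for (nm in names(override)) {
    if (depth > 0L && is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], depth - 1L)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the package defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- structure(merge_config(unclass(default_config()), user),
                   class = "run_config")
  cfg$config_path <- path
  cfg$config_hash <- unname(tools::md5sum(path))
  cfg
}

#' Validate a run configuration
#'
#' Collects every problem before reporting, so one run surfaces all
#' configuration errors at once.
#'
#' @param config A `run_config`.
#' @return Invisibly `TRUE` when valid; otherwise stops with the full error
#'   list. Use `validate_config(config, stop_on_error = FALSE)` to get the
#'   character vector of errors.
#' @param stop_on_error Stop (default) or return the error vector.
#' @export
validate_config <- function(config, stop_on_error = TRUE) {
  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)
  d <- config$design
  if (length(d$lipids) == 0L) push("design: empty lipid list")
  if (length(d$cholesterols) == 0L) push("design: empty cholesterol list")
  if (length(d$pegs) == 0L) push("design: empty PEG-lipid list")
  if (length(d$ratios) == 0L) push("design: no molar ratios")
  for (nm in names(d$ratios)) {
    r <- unlist(d$ratios[[nm]])
    if (length(r) != 4L || any(r <= 0)) {
      push(sprintf("design: ratio `%s` is not 4 positive percentages", nm))
    } else if (abs(sum(r) - 100) > 1e-6) {
      push(sprintf("design: ratio `%s` sums to %g, not 100", nm, sum(r)))
    }
  }
  if (d$barcode_length < 1L) push("design: barcode_length must be >= 1")
  if (d$min_hamming < 1L) push("design: min_hamming must be >= 1")
  if (is.null(d$seed)) push("design: seed must be explicit")
  q <- config$qc
  if (!(q$d_min_nm < q$d_max_nm)) push("qc: d_min_nm must be < d_max_nm")
  p <- config$pool
  if (p$total_dose_mg_per_kg <= 0) push("pool: total dose must be positive")
  if (!nzchar(p$control_barcode_id %||% "")) {
    push("pool: control_barcode_id required")
  }
  s <- config$sim
  if (s$error_rate < 0 || s$error_rate >= 1) {
    push("sim: error_rate must be in [0, 1)")
  }
  if (s$pcr_bias_sd < 0) push("sim: pcr_bias_sd must be >= 0")
  if (s$depth < 0) push("sim: depth must be >= 0")
  if (!is.null(s$control_factor) &&
      (s$control_factor <= 0 || s$control_factor >= 1)) {
    push("sim: control_factor must be in (0, 1)")
  }
  if (is.null(s$seed)) push("sim: seed must be explicit")
  ct <- config$counting
  if (ct$max_mismatch_anchor < 0L || ct$max_mismatch_barcode < 0L) {
    push("counting: mismatch tolerances must be >= 0")
  }
  if (config$quant$pseudocount < 0) push("quant: pseudocount must be >= 0")
  e <- config$enrichment
  if (e$fraction <= 0 || e$fraction > 0.5) {
    push("enrichment: fraction must be in (0, 0.5]")
  }
  if (e$n_boot < 100L) push("enrichment: n_boot must be >= 100")
  for (nm in c("primer_table", "barcode_fasta", "qc_table", "sample_sheet",
               "fastq_dir")) {
    pth <- config$paths[[nm]]
    if (!is.null(pth) && !file.exists(pth)) {
      push(sprintf("paths: %s does not exist: %s", nm, pth))
    }
  }
  if (length(errs)) {
    if (stop_on_error) {
      stop(paste0("invalid configuration:\n  - ",
                  paste(errs, collapse = "\n  - ")), call. = FALSE)
    }
    return(errs)
  }
  invisible(TRUE)
}

#' Run the design stage
#'
#' Enumerates the formulation library, designs one barcode per formulation
#' plus the unencapsulated control, assembles scaffolds, applies QC (from a
#' provided table or the QC simulator) and builds the injected pool. Writes
#' the barcode FASTA, formulation/QC/pool tables and a manifest when
#' `outdir` is given.
#'
#' @param config A `run_config`.
#' @param outdir Optional output directory.
#' @param qc_table Optional measured QC table; default simulates one with
#'   `config$qc$n_pass` passing LNPs.
#' @return List: `formulations`, `barcodes` (`barcode_set` with IDs),
#'   `scaffolds`, `primer_set`, `layout`, `qc`, `pool`, and output paths
#'   when written.
#' @export
run_design <- function(config = default_config(), outdir = NULL,
                       qc_table = NULL) {
  validate_config(config)
  formulations <- enumerate_formulations(
    lipids = config$design$lipids,
    cholesterols = config$design$cholesterols,
    pegs = config$design$pegs,
    helper = config$design$helper,
    ratios = lapply(config$design$ratios, unlist)
  )
  n_bc <- nrow(formulations) + 1L
  set <- generate_barcode_set(n_bc, length = config$design$barcode_length,
                              min_hamming = config$design$min_hamming,
                              seed = config$design$seed,
                              diversity_ceiling =
                                config$design$diversity_ceiling)
  ids <- c(formulations$barcode_id, config$pool$control_barcode_id)
  set$ids <- ids
  names(set$barcodes) <- ids
  primer_set <- load_primer_set(config$paths$primer_table %||%
                                  system.file("extdata",
                                              "nested_pcr_primers.tsv",
                                              package = "lnpscreen"))
  layout <- scaffold_layout(primer_set,
                            scaffold_length = config$design$scaffold_length)
  if (is.null(qc_table)) {
    qc_table <- simulate_qc(formulations, n_pass = config$qc$n_pass,
                            seed = config$qc$seed)
  }
  qc <- apply_qc(formulations, qc_table, d_min_nm = config$qc$d_min_nm,
                 d_max_nm = config$qc$d_max_nm, pdi_max = config$qc$pdi_max)
  pool <- build_pool(qc$pass,
                     control_barcode_id = config$pool$control_barcode_id,
                     total_dose_mg_per_kg = config$pool$total_dose_mg_per_kg,
                     mrna_to_barcode_mass_ratio =
                       config$pool$mrna_to_barcode_mass_ratio)
  scaffolds <- pool_scaffolds(pool, set, primer_set, layout)
  out <- list(formulations = formulations, barcodes = set,
              scaffolds = scaffolds, primer_set = primer_set,
              layout = layout, qc = qc, pool = pool)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- list(
      barcode_fasta = file.path(outdir, "barcodes.fasta"),
      formulations = file.path(outdir, "formulations.tsv"),
      qc = file.path(outdir, "qc_table.tsv"),
      pool = file.path(outdir, "pool.tsv"),
      manifest = file.path(outdir, "design_manifest.yaml")
    )
    write_barcode_fasta(set, out$paths$barcode_fasta)
    write_table_tsv(formulations, out$paths$formulations)
    write_table_tsv(qc_table, out$paths$qc)
    pool_tab <- data.frame(barcode_id = pool$barcode_ids,
                           input_proportion =
                             unname(pool$input_proportions),
                           is_control = pool$barcode_ids ==
                             pool$control_barcode_id,
                           stringsAsFactors = FALSE)
    write_table_tsv(pool_tab, out$paths$pool)
    yaml::write_yaml(list(
      n_formulations = nrow(formulations),
      n_pass_qc = nrow(qc$pass),
      n_barcodes = length(set$barcodes),
      min_pairwise_hamming = set$min_pairwise_hamming,
      total_dose_mg_per_kg = pool$total_dose_mg_per_kg,
      per_particle_dose_mg_per_kg = pool$per_particle_dose_mg_per_kg,
      config_hash = config$config_hash %||% NA,
      seeds = list(barcode = config$design$seed, qc = config$qc$seed)
    ), out$paths$manifest)
  }
  out
}

#' Run the screen stage
#'
#' From a design (and FASTQ files — simulated here when none are supplied):
#' count every sample, quantify normalized delivery against the input pool,
#' aggregate and rank, run the negative-control check, and compute decile
#' fold enrichment with bootstrap intervals.
#'
#' @param design Output of [run_design()].
#' @param config A `run_config`.
#' @param outdir Optional output directory for tables and (when simulating)
#'   FASTQ files.
#' @param sample_sheet,fastq_dir Optional real data: a sheet with
#'   `sample_id`, `cell_type`, `fastq` and the directory holding the files
#'   (plus an `input` entry or `input_fastq` argument).
#' @param input_fastq Path to the input-pool FASTQ when using real data.
#' @return List: `counts`, `input_counts`, `delivery` (`delivery_matrix`),
#'   `aggregates`, `ranks`, `control_check`, `enrichment`, `truth` (when
#'   simulated), plus output paths when written.
#' @export
run_screen <- function(design, config = default_config(), outdir = NULL,
                       sample_sheet = NULL, fastq_dir = NULL,
                       input_fastq = NULL) {
  validate_config(config)
  simulate <- is.null(sample_sheet)
  truth <- NULL
  if (simulate) {
    samples <- default_samples(cell_types = config$sim$cell_types,
                               mice = config$sim$mice,
                               depth = config$sim$depth)
    truth <- simulate_ground_truth(
      design$pool, samples,
      propensity_sdlog = config$sim$propensity_sdlog,
      control_factor = config$sim$control_factor,
      pcr_bias_sd = config$sim$pcr_bias_sd,
      error_rate = config$sim$error_rate,
      mean_reads_per_molecule = config$sim$mean_reads_per_molecule,
      seed = config$sim$seed)
    fastq_dir <- if (is.null(outdir)) tempfile("fastq_") else
      file.path(outdir, "fastq")
    sim <- simulate_screen(truth, design$pool, design$scaffolds,
                           design$primer_set, fastq_dir,
                           seed = config$sim$seed)
    sample_sheet <- sim$sample_sheet
    input_fastq <- sim$input_fastq
  } else {
    if (nrow(sample_sheet) == 0L) stop("empty sample sheet", call. = FALSE)
    if (is.null(input_fastq)) {
      stop("`input_fastq` is required with a real sample sheet",
           call. = FALSE)
    }
  }
  pool_set <- design$barcodes
  keep <- pool_set$ids %in% design$pool$barcode_ids
  pool_barcodes <- new_barcode_set(unname(pool_set$barcodes[keep]))
  pool_barcodes$ids <- pool_set$ids[keep]
  names(pool_barcodes$barcodes) <- pool_barcodes$ids
  counts <- count_samples(sample_sheet, fastq_dir, pool_barcodes,
                          design$primer_set, layout = design$layout,
                          max_mismatch_anchor =
                            config$counting$max_mismatch_anchor,
                          max_mismatch_barcode =
                            config$counting$max_mismatch_barcode,
                          try_revcomp = config$counting$try_revcomp)
  input_counts <- count_sample(input_fastq, pool_barcodes, design$primer_set,
                               layout = design$layout,
                               max_mismatch_anchor =
                                 config$counting$max_mismatch_anchor,
                               max_mismatch_barcode =
                                 config$counting$max_mismatch_barcode,
                               try_revcomp = config$counting$try_revcomp,
                               sample_id = "input")
  delivery <- delivery_matrix(counts, input_counts,
                              pseudocount = config$quant$pseudocount)
  ar <- aggregate_and_rank(delivery)
  ctrl <- control_check(delivery, design$pool$control_barcode_id)
  agg_all <- stats::setNames(ar$aggregates[, "all"],
                             rownames(ar$aggregates))
  enr <- bootstrap_enrichment(
    delivery$values, design$pool$members,
    n_boot = config$enrichment$n_boot,
    fraction = config$enrichment$fraction,
    control_barcode_id = design$pool$control_barcode_id,
    seed = config$enrichment$seed)
  out <- list(counts = counts, input_counts = input_counts,
              delivery = delivery, aggregates = ar$aggregates,
              ranks = ar$ranks, control_check = ctrl, enrichment = enr,
              truth = truth, sample_sheet = sample_sheet)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      counts = file.path(outdir, "counts.tsv"),
      delivery = file.path(outdir, "delivery_matrix.tsv"),
      aggregates = file.path(outdir, "aggregates.tsv"),
      control_check = file.path(outdir, "control_check.tsv"),
      enrichment = file.path(outdir, "enrichment.tsv"),
      manifest = file.path(outdir, "screen_manifest.yaml")
    )
    all_counts <- do.call(rbind, lapply(c(counts, list(input_counts)),
                                        function(ct) {
      cbind(sample_id = ct$sample_id, ct$counts,
            unassigned_reads = ct$unassigned_reads,
            total_reads = ct$total_reads)
    }))
    write_table_tsv(all_counts, paths$counts)
    dm <- data.frame(barcode_id = rownames(delivery$values),
                     delivery$values, check.names = FALSE)
    write_table_tsv(dm, paths$delivery)
    write_table_tsv(data.frame(barcode_id = rownames(ar$aggregates),
                               aggregate = ar$aggregates[, "all"],
                               rank = ar$ranks[, "all"]),
                    paths$aggregates)
    write_table_tsv(ctrl, paths$control_check)
    write_table_tsv(enr, paths$enrichment)
    yaml::write_yaml(list(
      simulated = simulate,
      n_samples = nrow(sample_sheet),
      config_hash = config$config_hash %||% NA,
      seeds = list(sim = config$sim$seed,
                   enrichment = config$enrichment$seed),
      control_is_lowest = all(ctrl$control_is_lowest)
    ), paths$manifest)
    out$paths <- paths
  }
  out
}
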