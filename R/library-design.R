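#' Default library components
#'
#' The screened combinatorial space: 8 piperazine-core ionizable lipids in
#' two scaffolds (A: two-carbon amide linker, B: three-carbon), 2 cholesterol
#' variants, 2 PEG-lipids, the helper lipid DOPE, and 4 molar ratios
#' (ionizable : cholesterol : PEG : helper, percent), giving
#' 8 x 2 x 2 x 4 = 128 formulations.
#'
#' @name library_defaults
#' @export
default_lipids <- function() {
  c("PPZ-A10", "PPZ-A11", "PPZ-A12", "PPZ-A18-2Z",
    "PPZ-B10", "PPZ-B11", "PPZ-B12", "PPZ-B18-2Z")
}

#' @rdname library_defaults
#' @export
default_cholesterols <- function() c("cholesterol", "20a-OH-cholesterol")

#' @rdname library_defaults
#' @export
default_pegs <- function() c("C14PEG2K", "C18PEG2K")

#' @rdname library_defaults
#' @export
default_ratios <- function() {
  list(ratio_1 = c(30, 30, 1, 39),
       ratio_2 = c(35, 46.5, 2.5, 16),
       ratio_3 = c(45, 39.5, 2.5, 13),
       ratio_4 = c(50, 35, 2.5, 12.5))
}

RATIO_COMPONENTS <- c("ionizable", "cholesterol", "peg", "helper")

check_ratios <- function(ratios) {
  if (is.null(names(ratios))) {
    names(ratios) <- sprintf("ratio_%d", seq_along(ratios))
  }
  for (nm in names(ratios)) {
    r <- ratios[[nm]]
    if (length(r) != 4L || any(!is.finite(r)) || any(r <= 0)) {
      stop(sprintf("molar ratio `%s` must be 4 positive percentages", nm),
           call. = FALSE)
    }
    if (abs(sum(r) - 100) > 1e-6) {
      stop(sprintf("molar ratio `%s` sums to %g, not 100", nm, sum(r)),
           call. = FALSE)
    }
  }
  ratios
}

#' Enumerate the combinatorial formulation library
#'
#' Full Cartesian product of ionizable lipids, cholesterol variants,
#' PEG-lipids and molar ratios with a single helper lipid, in a stable
#' deterministic order (ratio varies fastest, then PEG, cholesterol, lipid).
#' Each formulation is assigned a sequential `lnp_id` and `barcode_id`.
#'
#' @param lipids,cholesterols,pegs Character vectors of component names.
#' @param helper Single helper lipid name (default `"DOPE"`).
#' @param ratios Named list of 4-part molar ratios
#'   (ionizable, cholesterol, PEG, helper), each summing to 100.
#' @param barcode_ids Optional barcode IDs (recycled in enumeration order);
#'   default `bc_001` ... .
#' @return data.frame with one row per formulation: `lnp_id`,
#'   `ionizable_lipid`, `cholesterol_variant`, `peg_lipid`, `helper_lipid`,
#'   `ratio_label`, `mr_ionizable`, `mr_cholesterol`, `mr_peg`, `mr_helper`,
#'   `barcode_id`.
#' @examples
#' nrow(enumerate_formulations()) # 128
#' @export
enumerate_formulations <- function(lipids = default_lipids(),
                                   cholesterols = default_cholesterols(),
                                   pegs = default_pegs(),
                                   helper = "DOPE",
                                   ratios = default_ratios(),
                                   barcode_ids = NULL) {
  if (length(lipids) == 0L || length(cholesterols) == 0L ||
      length(pegs) == 0L || length(ratios) == 0L || length(helper) != 1L) {
    stop("component lists must be non-empty and `helper` a single name",
         call. = FALSE)
  }
  ratios <- check_ratios(ratios)
  grid <- expand.grid(ratio_label = names(ratios), peg_lipid = pegs,
                      cholesterol_variant = cholesterols,
                      ionizable_lipid = lipids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # expand.grid varies the first column fastest; reorder columns for reading
  grid <- grid[, c("ionizable_lipid", "cholesterol_variant", "peg_lipid",
                   "ratio_label")]
  n <- nrow(grid)
  mr <- do.call(rbind, ratios[grid$ratio_label])
  colnames(mr) <- paste0("mr_", RATIO_COMPONENTS)
  out <- data.frame(
    lnp_id = sprintf("LNP_%03d", seq_len(n)),
    grid,
    helper_lipid = helper,
    mr,
    barcode_id = if (is.null(barcode_ids)) sprintf("bc_%03d", seq_len(n))
                 else rep_len(barcode_ids, n),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Apply the dynamic-light-scattering quality-control filter
#'
#' An LNP enters the pool only if its intensity-average hydrodynamic
#' diameter is strictly between `d_min_nm` and `d_max_nm` and the particle is
#' monodisperse (stable autocorrelation function with a single inflection
#' point, recorded by the instrument operator as a boolean, or derived from a
#' polydispersity index `pdi <= pdi_max` when only PDI is available).
#'
#' @param formulations Formulation table from [enumerate_formulations()].
#' @param qc_table data.frame with `lnp_id`, `diameter_nm`, and
#'   `monodisperse` (logical) and/or `pdi` (numeric); exactly one row per
#'   formulation.
#' @param d_min_nm,d_max_nm Diameter bounds in nm (default 20 and 200,
#'   strict inequalities).
#' @param pdi_max PDI threshold used only when `monodisperse` is absent
#'   (default 0.3).
#' @return List with `pass` and `fail` formulation tables (each gains
#'   `diameter_nm`, `monodisperse`, `qc_pass`); the two partition the input.
#' @export
apply_qc <- function(formulations, qc_table, d_min_nm = 20, d_max_nm = 200,
                     pdi_max = 0.3) {
  if (!all(c("lnp_id", "diameter_nm") %in% names(qc_table))) {
    stop("`qc_table` needs `lnp_id` and `diameter_nm` columns", call. = FALSE)
  }
  dup <- unique(qc_table$lnp_id[duplicated(qc_table$lnp_id)])
  missing <- setdiff(formulations$lnp_id, qc_table$lnp_id)
  if (length(dup) || length(missing)) {
    stop(sprintf("QC table mismatch%s%s",
                 if (length(missing)) paste0("; missing: ",
                                             paste(missing, collapse = ", "))
                 else "",
                 if (length(dup)) paste0("; duplicated: ",
                                         paste(dup, collapse = ", "))
                 else ""),
         call. = FALSE)
  }
  qc <- qc_table[match(formulations$lnp_id, qc_table$lnp_id), ]
  mono <- if ("monodisperse" %in% names(qc)) as.logical(qc$monodisperse)
          else if ("pdi" %in% names(qc)) qc$pdi <= pdi_max
          else stop("`qc_table` needs a `monodisperse` or `pdi` column",
                    call. = FALSE)
  pass <- qc$diameter_nm > d_min_nm & qc$diameter_nm < d_max_nm & mono
  out <- formulations
  out$diameter_nm <- qc$diameter_nm
  out$monodisperse <- mono
  out$qc_pass <- pass
  list(pass = out[pass, , drop = FALSE],
       fail = out[!pass, , drop = FALSE])
}

#' Build the injected screen pool
#'
#' Collects the QC-passing LNPs plus one unencapsulated control barcode into
#' the injected mixture, with dose accounting. The control barcode is part of
#' the sequenced input (it contributes an input proportion) but is not an
#' LNP, so the per-particle dose divides the total dose by the number of LNP
#' members only.
#'
#' @param pass_list Formulation table of QC-passing LNPs (needs `lnp_id`,
#'   `barcode_id`).
#' @param control_barcode_id Barcode ID of the naked-DNA negative control.
#' @param total_dose_mg_per_kg Total nucleic acid dose (default 1.5 mg/kg).
#' @param proportions Optional named input proportions over all member
#'   barcodes plus the control; must sum to 1. Default uniform.
#' @param mrna_to_barcode_mass_ratio Cargo mass ratio metadata (default 10).
#' @return A `screen_pool`: `members` (formulation table), `barcode_ids`,
#'   `control_barcode_id`, `input_proportions` (named, sums to 1),
#'   `total_dose_mg_per_kg`, `per_particle_dose_mg_per_kg`,
#'   `mrna_to_barcode_mass_ratio`.
#' @examples
#' pool <- build_pool(data.frame(lnp_id = sprintf("L%02d", 1:65),
#'                               barcode_id = sprintf("bc_%03d", 1:65)),
#'                    control_barcode_id = "bc_ctrl")
#' round(pool$per_particle_dose_mg_per_kg, 3) # 0.023
#' @export
build_pool <- function(pass_list, control_barcode_id,
                       total_dose_mg_per_kg = 1.5, proportions = NULL,
                       mrna_to_barcode_mass_ratio = 10) {
  if (nrow(pass_list) == 0L) stop("`pass_list` is empty", call. = FALSE)
  if (control_barcode_id %in% pass_list$barcode_id) {
    stop("the control barcode must not belong to a pool member", call. = FALSE)
  }
  ids <- c(pass_list$barcode_id, control_barcode_id)
  if (anyDuplicated(ids)) stop("duplicate barcode IDs in pool", call. = FALSE)
  if (is.null(proportions)) {
    proportions <- stats::setNames(rep(1 / length(ids), length(ids)), ids)
  } else {
    if (!setequal(names(proportions), ids)) {
      stop("`proportions` must cover every member barcode plus the control",
           call. = FALSE)
    }
    proportions <- proportions[ids]
    if (abs(sum(proportions) - 1) > 1e-9) {
      stop(sprintf("`proportions` sum to %.12g, not 1", sum(proportions)),
           call. = FALSE)
    }
  }
  structure(
    list(members = pass_list,
         barcode_ids = ids,
         control_barcode_id = control_barcode_id,
         input_proportions = proportions,
         total_dose_mg_per_kg = total_dose_mg_per_kg,
         per_particle_dose_mg_per_kg = total_dose_mg_per_kg / nrow(pass_list),
         mrna_to_barcode_mass_ratio = mrna_to_barcode_mass_ratio),
    class = "screen_pool"
  )
}

#' @export
print.screen_pool <- function(x, ...) {
  cat(sprintf(paste0("screen_pool: %d LNPs + control `%s`; total dose %g ",
                     "mg/kg (%.3f mg/kg/particle)\n"),
              nrow(x$members), x$control_barcode_id, x$total_dose_mg_per_kg,
              x$per_particle_dose_mg_per_kg))
  invisible(x)
}

#' Write / read pipeline tables
#'
#' Plain TSV round-trip helpers for formulation, QC, counts and delivery
#' tables.
#'
#' @param x data.frame.
#' @param path File path.
#' @return `write_table_tsv()` returns `path` invisibly; `read_table_tsv()`
#'   the data.frame.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
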