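ENRICHMENT_AXES <- c("ionizable_lipid", "cholesterol_variant", "peg_lipid",
                     "molar_ratio")

axis_column <- function(axis) {
  if (!axis %in% ENRICHMENT_AXES) {
    stop(sprintf("unknown component axis `%s` (use one of: %s)", axis,
                 paste(ENRICHMENT_AXES, collapse = ", ")), call. = FALSE)
  }
  if (axis == "molar_ratio") "ratio_label" else axis
}

#' Top- or bottom-decile members
#'
#' The `k` best- or worst-ranked LNPs, with `k = max(1, round(fraction * N))`
#' under round-half-up (10% of a 65-LNP screen is the top 7). The
#' unencapsulated control is expected to be excluded upstream (ranks are
#' over screened LNPs only).
#'
#' @param ranks Named integer vector of LNP ranks (1 = highest delivery), a
#'   permutation of `1..N`.
#' @param fraction Decile fraction in (0, 0.5] (default 0.10).
#' @param direction `"top"` or `"bottom"`.
#' @return Character vector of `k` LNP/barcode IDs.
#' @export
decile_members <- function(ranks, fraction = 0.10,
                           direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5) {
    stop("`fraction` must be in (0, 0.5]", call. = FALSE)
  }
  n <- length(ranks)
  k <- max(1L, as.integer(round_half_up(fraction * n)))
  if (direction == "top") names(ranks)[ranks <= k]
  else names(ranks)[ranks > n - k]
}

#' Fold enrichment of a component level in a decile
#'
#' How over- or under-represented a component level (a particular ionizable
#' lipid, cholesterol variant, PEG-lipid or molar ratio) is among the top or
#' bottom decile of ranked LNPs, relative to random chance:
#' `fold = observed_fraction / expected_fraction`, where observed is the
#' level's share of the decile and expected its share of the whole screened
#' library. `fold > 1` means enrichment. An odds-ratio variant of the same
#' comparison (`(a/b)/(c/d)` on the 2x2 decile x level table) is available
#' via `statistic = "odds_ratio"`.
#'
#' @param members Decile member IDs from [decile_members()].
#' @param library Screened formulation table (must contain `id_col` and the
#'   component columns).
#' @param axis One of `"ionizable_lipid"`, `"cholesterol_variant"`,
#'   `"peg_lipid"`, `"molar_ratio"`.
#' @param level Component level to score.
#' @param id_col Column identifying LNPs (default `"barcode_id"`).
#' @param statistic `"ratio"` (fraction ratio, default) or `"odds_ratio"`.
#' @return List: `axis`, `level`, `k`, `observed_fraction`,
#'   `expected_fraction`, `fold` (`NA` when the level is absent from the
#'   library).
#' @export
fold_enrichment <- function(members, library, axis, level,
                            id_col = "barcode_id",
                            statistic = c("ratio", "odds_ratio")) {
  statistic <- match.arg(statistic)
  col <- axis_column(axis)
  if (!all(members %in% library[[id_col]])) {
    stop("decile members must belong to the library", call. = FALSE)
  }
  lev <- library[[col]]
  if (!level %in% lev) {
    stop(sprintf("level `%s` not present on axis `%s`", level, axis),
         call. = FALSE)
  }
  in_decile <- library[[id_col]] %in% members
  k <- sum(in_decile)
  observed <- mean(lev[in_decile] == level)
  expected <- mean(lev == level)
  fold <- if (expected > 0) {
    if (statistic == "ratio") observed / expected
    else {
      a <- sum(in_decile & lev == level)
      b <- sum(in_decile & lev != level)
      cc <- sum(!in_decile & lev == level)
      d <- sum(!in_decile & lev != level)
      (a / max(b, 0.5)) / (cc / max(d, 0.5))
    }
  } else NA_real_
  list(axis = axis, level = level, k = k, observed_fraction = observed,
       expected_fraction = expected, fold = fold)
}

#' Enrichment table over all levels of the component axes
#'
#' Ranks the screened LNPs by aggregated normalized delivery (control
#' excluded), takes the top and bottom deciles, and scores every level of
#' every requested component axis.
#'
#' @param aggregates Named numeric vector of aggregated normalized delivery
#'   per barcode (e.g. the `"all"` column of [aggregate_and_rank()]).
#' @param library Screened formulation table.
#' @param axes Component axes (default all four).
#' @param fraction Decile fraction (default 0.10).
#' @param control_barcode_id Optional control to drop before ranking.
#' @param id_col LNP identifier column (default `"barcode_id"`).
#' @param statistic Passed to [fold_enrichment()].
#' @return data.frame: `axis`, `level`, `direction`, `k`,
#'   `observed_fraction`, `expected_fraction`, `fold`.
#' @export
enrichment_table <- function(aggregates, library, axes = ENRICHMENT_AXES,
                             fraction = 0.10, control_barcode_id = NULL,
                             id_col = "barcode_id",
                             statistic = c("ratio", "odds_ratio")) {
  statistic <- match.arg(statistic)
  if (!is.null(control_barcode_id)) {
    aggregates <- aggregates[setdiff(names(aggregates), control_barcode_id)]
  }
  aggregates <- aggregates[intersect(names(aggregates), library[[id_col]])]
  if (!length(aggregates)) stop("no screened LNPs to rank", call. = FALSE)
  lib <- library[match(names(aggregates), library[[id_col]]), ]
  ord <- order(-aggregates, names(aggregates))
  ranks <- stats::setNames(integer(length(aggregates)), names(aggregates))
  ranks[ord] <- seq_along(aggregates)
  rows <- list()
  for (direction in c("top", "bottom")) {
    members <- decile_members(ranks, fraction, direction)
    for (axis in axes) {
      col <- axis_column(axis)
      for (level in unique(lib[[col]])) {
        fe <- fold_enrichment(members, lib, axis, level, id_col, statistic)
        rows[[length(rows) + 1L]] <-
          data.frame(axis = axis, level = level, direction = direction,
                     k = fe$k, observed_fraction = fe$observed_fraction,
                     expected_fraction = fe$expected_fraction,
                     fold = fe$fold, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Bootstrap resampling intervals for fold enrichment
#'
#' Resamples the sample columns of the delivery matrix with replacement,
#' recomputes aggregate -> ranks -> deciles -> folds, and reports the 2.5/97.5
#' percentile interval per axis level and direction. Point folds are from
#' the observed (unresampled) data.
#'
#' @param values Barcode x sample matrix of normalized delivery (control
#'   excluded or passed via `control_barcode_id`).
#' @param library Screened formulation table.
#' @param axes Component axes.
#' @param n_boot Number of bootstrap replicates (>= 100; default 1000).
#' @param fraction Decile fraction.
#' @param control_barcode_id Optional control row to drop.
#' @param seed Integer seed.
#' @param id_col LNP identifier column.
#' @return data.frame as [enrichment_table()] plus `ci_low`, `ci_high`.
#' @export
bootstrap_enrichment <- function(values, library, axes = ENRICHMENT_AXES,
                                 n_boot = 1000L, fraction = 0.10,
                                 control_barcode_id = NULL, seed,
                                 id_col = "barcode_id") {
  if (inherits(values, "delivery_matrix")) values <- values$values
  if (n_boot < 100L) stop("`n_boot` must be >= 100", call. = FALSE)
  if (ncol(values) < 2L) {
    stop("bootstrap needs at least 2 samples", call. = FALSE)
  }
  point <- enrichment_table(rowMeans(values), library, axes, fraction,
                            control_barcode_id, id_col)
  key <- function(tab) paste(tab$axis, tab$level, tab$direction)
  boots <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      cols <- sample.int(ncol(values), ncol(values), replace = TRUE)
      enrichment_table(rowMeans(values[, cols, drop = FALSE]), library, axes,
                       fraction, control_barcode_id, id_col)$fold
    })
  })
  mat <- do.call(cbind, boots)
  ci <- t(apply(mat, 1L, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE, names = FALSE))
  point$ci_low <- ci[, 1]
  point$ci_high <- ci[, 2]
  point
}
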