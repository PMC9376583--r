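#' Normalized delivery for one sample
#'
#' A barcode's normalized delivery is its within-sample count proportion
#' corrected by its proportion in the injected input pool: with sample
#' proportions `p_i = c_i / sum(c)` and input proportions
#' `q_i = c_i^in / sum(c^in)`, delivery is `d_i = (p_i/q_i) / sum_j(p_j/q_j)`
#' so the sample column sums to 1. A pseudocount is added to every barcode in
#' both tables before forming proportions; it guards against zero input
#' counts and stabilizes log-scale displays.
#'
#' @param counts A `counts_table` for a sorted-cell sample.
#' @param input_counts A `counts_table` for the injected input pool.
#' @param pseudocount Added to every barcode's raw count in both tables
#'   (default 0.5; set 0 to disable).
#' @return Named numeric vector of normalized delivery, summing to 1.
#' @examples
#' s <- counts_table("s", data.frame(barcode_id = c("a", "b", "c"),
#'                                   raw_reads = c(40L, 40L, 20L),
#'                                   distinct_umis = c(1L, 1L, 1L)))
#' i <- counts_table("input", data.frame(barcode_id = c("a", "b", "c"),
#'                                       raw_reads = c(100L, 100L, 100L),
#'                                       distinct_umis = c(1L, 1L, 1L)))
#' normalized_delivery(s, i, pseudocount = 0) # 0.4 0.4 0.2
#' @export
normalized_delivery <- function(counts, input_counts, pseudocount = 0.5) {
  ids <- counts$counts$barcode_id
  if (!setequal(ids, input_counts$counts$barcode_id)) {
    stop("sample and input tables cover different barcode sets",
         call. = FALSE)
  }
  ci <- input_counts$counts$raw_reads[
    match(ids, input_counts$counts$barcode_id)] + pseudocount
  if (any(ci <= 0)) {
    bad <- ids[ci <= 0]
    stop(sprintf("zero input count and no pseudocount for barcode(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cs <- counts$counts$raw_reads + pseudocount
  p <- cs / sum(cs)
  q <- ci / sum(ci)
  r <- p / q
  stats::setNames(r / sum(r), ids)
}

#' Build the delivery matrix for a screen
#'
#' One normalized-delivery column per sorted-cell sample.
#'
#' @param counts_list Named list of `counts_table`s (one per sample).
#' @param input_counts The input-pool `counts_table`.
#' @inheritParams normalized_delivery
#' @return A `delivery_matrix`: `values` (barcode x sample matrix, columns
#'   sum to 1), `input_proportions` (pseudocounted input fractions).
#' @export
delivery_matrix <- function(counts_list, input_counts, pseudocount = 0.5) {
  cols <- lapply(counts_list, normalized_delivery, input_counts = input_counts,
                 pseudocount = pseudocount)
  ids <- names(cols[[1]])
  values <- vapply(cols, function(x) x[ids], numeric(length(ids)))
  ci <- input_counts$counts$raw_reads[
    match(ids, input_counts$counts$barcode_id)] + pseudocount
  structure(
    list(values = values,
         input_proportions = stats::setNames(ci / sum(ci), ids)),
    class = "delivery_matrix"
  )
}

#' Aggregate normalized delivery and rank LNPs
#'
#' Arithmetic mean of each barcode's normalized delivery over the samples of
#' each group, with a within-group rank (1 = highest delivery). Ties are
#' broken deterministically by barcode ID, so ranks are always a permutation
#' of `1..N`.
#'
#' @param matrix A `delivery_matrix` or bare barcode x sample numeric matrix.
#' @param grouping Named character vector mapping sample -> group; default
#'   one `"all"` group over every sample.
#' @return List: `aggregates` (barcode x group matrix), `ranks` (integer
#'   matrix, same shape).
#' @export
aggregate_and_rank <- function(matrix,
                               grouping = NULL) {
  values <- if (inherits(matrix, "delivery_matrix")) matrix$values else matrix
  if (is.null(grouping)) {
    grouping <- stats::setNames(rep("all", ncol(values)), colnames(values))
  }
  missing <- setdiff(colnames(values), names(grouping))
  if (length(missing)) {
    stop(sprintf("samples without a group: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  groups <- unique(grouping[colnames(values)])
  agg <- vapply(groups, function(g) {
    cols <- colnames(values)[grouping[colnames(values)] == g]
    if (!length(cols)) stop(sprintf("empty group `%s`", g), call. = FALSE)
    rowMeans(values[, cols, drop = FALSE])
  }, numeric(nrow(values)))
  agg <- base::matrix(agg, nrow = nrow(values),
                      dimnames = list(rownames(values), groups))
  ranks <- apply(agg, 2L, function(v) {
    ord <- order(-v, rownames(agg))
    r <- integer(length(v))
    r[ord] <- seq_along(v)
    r
  })
  ranks <- base::matrix(as.integer(ranks), nrow = nrow(values),
                        dimnames = dimnames(agg))
  list(aggregates = agg, ranks = ranks)
}

#' Negative-control sanity check
#'
#' The unencapsulated barcode is injected naked; free DNA does not readily
#' enter cells, so its normalized delivery should be the lowest of all
#' barcodes when aggregated across samples. Reports, per group, whether the
#' control is strictly the minimum and its margin (ratio of the next-lowest
#' barcode's aggregate to the control's).
#'
#' @param matrix A `delivery_matrix` or barcode x sample matrix.
#' @param control_barcode_id Control barcode ID (must be a row).
#' @param grouping As in [aggregate_and_rank()].
#' @return data.frame `group`, `control_is_lowest`, `margin_ratio`,
#'   `control_delivery`, `next_lowest_barcode`.
#' @export
control_check <- function(matrix, control_barcode_id, grouping = NULL) {
  ar <- aggregate_and_rank(matrix, grouping)
  agg <- ar$aggregates
  if (!control_barcode_id %in% rownames(agg)) {
    stop(sprintf("control barcode `%s` not present", control_barcode_id),
         call. = FALSE)
  }
  res <- lapply(colnames(agg), function(g) {
    v <- agg[, g]
    ctrl <- v[[control_barcode_id]]
    others <- v[setdiff(names(v), control_barcode_id)]
    nl <- names(others)[which.min(others)]
    data.frame(group = g,
               control_is_lowest = ctrl < min(others),
               margin_ratio = min(others) / ctrl,
               control_delivery = ctrl,
               next_lowest_barcode = nl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
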