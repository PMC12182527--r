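#' Benjamini-Hochberg adjustment and significance calling
#'
#' `adjust_fdr()` appends a `p_adj` column (Benjamini-Hochberg step-up,
#' via [stats::p.adjust()]) computed over the tested markers of a scan.
#' `call_significant()` appends a logical `significant` column: a marker is
#' significant iff `-log10(p_adj)` strictly exceeds the threshold (default
#' 3).
#'
#' @param scan A `scan_result` tibble (or any tibble with a `p` column).
#' @param threshold_neglog10 Significance threshold on the `-log10` scale.
#' @param on Column to threshold: adjusted (default) or raw p-values.  The
#'   adjusted option reflects the intended pipeline; raw thresholding is
#'   exposed because the two conventions differ materially.
#' @return The input with `p_adj` / `significant` columns appended.
#' @export
adjust_fdr <- function(scan) {
  scan$p_adj <- stats::p.adjust(scan$p, method = "BH")
  scan
}

#' @rdname adjust_fdr
#' @export
call_significant <- function(scan, threshold_neglog10 = 3,
                             on = c("p_adj", "p")) {
  on <- match.arg(on)
  if (on == "p_adj" && is.null(scan[["p_adj"]])) scan <- adjust_fdr(scan)
  pv <- scan[[on]]
  scan$significant <- !is.na(pv) & -log10(pv) > threshold_neglog10
  scan
}

#' Call QTL regions from significant markers
#'
#' Per chromosome, significant markers are sorted by position and split into
#' clusters wherever consecutive significant markers are separated by
#' `gap_cM` or more without a significant marker in between.  A cluster is
#' called a QTL region iff some `window_cM`-wide window (anchored at a member
#' marker) contains at least `min_markers` of its markers; the region extent
#' is the span of the cluster's member positions.
#'
#' @param scan A scan tibble with `significant` (see [call_significant()]),
#'   `chrom`, `pos_cM` and `p_adj` columns.
#' @param min_markers Minimum significant markers within the density window
#'   (default 5).
#' @param window_cM Density window width in cM (default 5).
#' @param gap_cM Gap splitting clusters into separate regions (default 5).
#' @return A tibble of class `qtl_regions`: `region`, `chrom`, `start_cM`,
#'   `end_cM`, `n_markers`, `min_p_adj`.
#' @export
call_qtl_regions <- function(scan, min_markers = 5, window_cM = 5,
                             gap_cM = 5) {
  sig <- dplyr::arrange(dplyr::filter(scan, .data$significant),
                        .data$chrom, .data$pos_cM)
  empty <- tibble::tibble(region = integer(), chrom = integer(),
                          start_cM = numeric(), end_cM = numeric(),
                          n_markers = integer(), min_p_adj = numeric())
  if (nrow(sig) == 0) {
    return(structure(empty, class = c("qtl_regions", class(empty))))
  }
  out <- sig |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(cluster = cumsum(c(0, diff(.data$pos_cM)) >= gap_cM)) |>
    dplyr::group_by(.data$chrom, .data$cluster) |>
    dplyr::summarise(
      start_cM = min(.data$pos_cM),
      end_cM = max(.data$pos_cM),
      n_markers = dplyr::n(),
      min_p_adj = if ("p_adj" %in% names(sig)) min(.data$p_adj) else NA_real_,
      dense = {
        pos <- .data$pos_cM
        max(vapply(pos, function(a) sum(pos >= a & pos <= a + window_cM),
                   1L)) >= min_markers
      },
      .groups = "drop"
    ) |>
    dplyr::filter(.data$dense) |>
    dplyr::select(-"cluster", -"dense")
  out <- dplyr::mutate(out, region = dplyr::row_number(), .before = 1)
  structure(out, class = c("qtl_regions", class(empty)))
}

#' Evaluate detected regions against the simulated truth
#'
#' A simulated QTL counts as detected iff some called region overlaps the
#' detection window `[pos - window_cM, pos + window_cM]` on its chromosome.
#' `TPR = detected QTL / simulated QTL`.  A region overlapping no QTL window
#' is a false detection; `FD = false regions / total regions`, with the
#' convention that FD is 100% when QTL were simulated but no region was
#' called.  A region overlapping several QTL windows counts each of them as
#' detected and is not false.
#'
#' @param regions A [call_qtl_regions()] result.
#' @param qtl A tibble with `chrom` and `pos_cM` of the simulated QTL.
#' @param window_cM Detection half-window around a QTL in cM (default 2.5).
#' @return A list with `tpr`, `fd`, `detected` (logical per QTL),
#'   `n_regions`, `n_false`.
#' @export
evaluate_detection <- function(regions, qtl, window_cM = 2.5) {
  n_sim <- nrow(qtl)
  stopifnot(n_sim >= 1)
  if (nrow(regions) == 0) {
    return(list(tpr = 0, fd = 1, detected = rep(FALSE, n_sim),
                n_regions = 0L, n_false = 0L))
  }
  hit <- vapply(seq_len(n_sim), function(i) {
    regions$chrom == qtl$chrom[i] &
      regions$start_cM <= qtl$pos_cM[i] + window_cM &
      regions$end_cM >= qtl$pos_cM[i] - window_cM
  }, logical(nrow(regions)))
  hit <- matrix(hit, nrow = nrow(regions))
  detected <- apply(hit, 2, any)
  false_region <- !apply(hit, 1, any)
  list(tpr = mean(detected),
       fd = sum(false_region) / nrow(regions),
       detected = detected,
       n_regions = nrow(regions),
       n_false = sum(false_region))
}
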