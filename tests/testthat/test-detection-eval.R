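scan_stub <- function(pos, p, chrom = 1L, significant = NULL) {
  out <- tibble::tibble(
    marker_index = seq_along(pos),
    marker = sprintf("m%03d", seq_along(pos)),
    chrom = rep_len(chrom, length(pos)),
    pos_cM = pos, statistic = NA_real_, p = p, status = "tested")
  if (!is.null(significant)) {
    out$p_adj <- p
    out$significant <- significant
  }
  out
}

test_that("BH adjustment matches the step-up hand computation", {
  s <- adjust_fdr(scan_stub(1:3, c(0.01, 0.02, 0.03)))
  expect_equal(s$p_adj, rep(0.03, 3))          # m = 3, all raised to 3*p/k
  expect_equal(adjust_fdr(scan_stub(1, 0.2))$p_adj, 0.2)   # single p unchanged
  expect_equal(adjust_fdr(scan_stub(1:4, rep(1, 4)))$p_adj, rep(1, 4))
  # monotone: order preserved
  set.seed(61)
  p <- runif(50)
  s2 <- adjust_fdr(scan_stub(1:50, p))
  expect_equal(order(s2$p_adj, p), order(p))
})

test_that("significance is a strict -log10 threshold on adjusted values", {
  s <- call_significant(adjust_fdr(scan_stub(1:3, c(1e-4, 1e-3, 0.5))))
  # after BH with m = 3: 3e-4, 1.5e-3, 0.5 -> only the first clears 1e-3
  expect_equal(s$significant, c(TRUE, FALSE, FALSE))
  s1 <- call_significant(scan_stub(1, 1e-3 + 1e-16))
  expect_false(s1$significant)                  # boundary is strict
  s0 <- call_significant(adjust_fdr(scan_stub(numeric(), numeric())))
  expect_equal(nrow(s0), 0)
  # raw-p thresholding flag
  sraw <- call_significant(scan_stub(1:3, c(1e-4, 1e-3, 0.5)), on = "p")
  expect_equal(sraw$significant, c(TRUE, FALSE, FALSE))
})

test_that("region calling applies the density and gap rules", {
  sig5 <- scan_stub(c(10, 10.5, 11, 11.5, 12), rep(1e-9, 5),
                    significant = rep(TRUE, 5))
  r <- call_qtl_regions(sig5)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start_cM, r$end_cM), c(10, 12))
  expect_equal(r$n_markers, 5L)

  # four markers are below the count rule
  r4 <- call_qtl_regions(scan_stub(c(1, 1.3, 1.6, 2), rep(1e-9, 4),
                                   significant = rep(TRUE, 4)))
  expect_equal(nrow(r4), 0)

  # two five-marker clusters 6 cM apart become two regions
  pos <- c(seq(0, 2, by = 0.5), seq(8, 10, by = 0.5))
  r2 <- call_qtl_regions(scan_stub(pos, rep(1e-9, 10),
                                   significant = rep(TRUE, 10)))
  expect_equal(nrow(r2), 2)
  # a gap of exactly 5 cM also splits
  pos5 <- c(seq(0, 2, by = 0.5), seq(7, 9, by = 0.5))
  expect_equal(nrow(call_qtl_regions(scan_stub(pos5, rep(1e-9, 10),
                                               significant = rep(TRUE, 10)))), 2)

  # five markers whose every 5 cM window holds at most four: no region
  spread <- scan_stub(c(0, 1.5, 3, 4.5, 6), rep(1e-9, 5),
                      significant = rep(TRUE, 5))
  expect_equal(nrow(call_qtl_regions(spread)), 0)

  # translation in cM does not change the calls
  shifted <- call_qtl_regions(scan_stub(pos + 7, rep(1e-9, 10),
                                        significant = rep(TRUE, 10)))
  expect_equal(shifted$start_cM, r2$start_cM + 7)

  # non-significant markers are ignored entirely
  mix <- scan_stub(c(10, 10.5, 11, 11.5, 12, 13), rep(1e-9, 6),
                   significant = c(rep(TRUE, 5), FALSE))
  expect_equal(call_qtl_regions(mix)$end_cM, 12)
})

test_that("evaluation computes TPR and FD with the 100% convention", {
  qtl <- tibble::tibble(chrom = 1L, pos_cM = 11)
  none <- call_qtl_regions(scan_stub(1, 1, significant = FALSE))
  ev0 <- evaluate_detection(none, qtl)
  expect_equal(ev0$tpr, 0)
  expect_equal(ev0$fd, 1)                       # no detection -> FD 100%

  regions <- tibble::tibble(region = 1:2, chrom = 1L,
                            start_cM = c(10, 40), end_cM = c(12, 41),
                            n_markers = 5L, min_p_adj = 1e-5)
  ev <- evaluate_detection(regions, qtl)
  expect_equal(ev$tpr, 1)
  expect_equal(ev$fd, 0.5)
  expect_equal(ev$n_false, 1L)

  # window edges: region within pos +/- 2.5 counts
  edge <- tibble::tibble(region = 1L, chrom = 1L, start_cM = 13.4,
                         end_cM = 14, n_markers = 5L, min_p_adj = 1e-5)
  expect_equal(evaluate_detection(edge, qtl)$tpr, 1)
  far <- tibble::tibble(region = 1L, chrom = 1L, start_cM = 13.6,
                        end_cM = 14, n_markers = 5L, min_p_adj = 1e-5)
  expect_equal(evaluate_detection(far, qtl)$tpr, 0)

  # wrong chromosome never matches
  off <- tibble::tibble(region = 1L, chrom = 2L, start_cM = 10,
                        end_cM = 12, n_markers = 5L, min_p_adj = 1e-5)
  expect_equal(evaluate_detection(off, qtl)$tpr, 0)
})

test_that("evaluation is exhaustive and multi-QTL regions are not false", {
  qtl <- tibble::tibble(chrom = c(1L, 1L, 2L), pos_cM = c(10, 12, 30))
  regions <- tibble::tibble(region = 1:2, chrom = c(1L, 2L),
                            start_cM = c(9, 50), end_cM = c(13, 52),
                            n_markers = 5L, min_p_adj = 1e-5)
  ev <- evaluate_detection(regions, qtl)
  # region 1 overlaps both chromosome-1 QTL windows: both detected, not false
  expect_equal(ev$detected, c(TRUE, TRUE, FALSE))
  expect_equal(ev$tpr, 2 / 3)
  expect_equal(ev$n_false, 1L)
  expect_equal(sum(ev$detected) + sum(!ev$detected), nrow(qtl))
  expect_equal(ev$n_regions, nrow(regions))
})

test_that("pure-noise scans almost never call a region at default thresholds", {
  set.seed(62)
  calls <- replicate(50, {
    p <- runif(2000)
    map_pos <- rep(seq(0, 69, length.out = 223), 9)[1:2000]
    s <- call_significant(adjust_fdr(
      scan_stub(map_pos, p, chrom = rep(1:9, each = 223)[1:2000])))
    nrow(call_qtl_regions(s))
  })
  expect_lte(mean(calls > 0), 0.05)
})
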