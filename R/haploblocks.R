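#' Build a haploblock catalog for a phased population
#'
#' Haplotypes are cut into consecutive, non-overlapping windows of
#' `window_size` markers (blocks never span chromosome boundaries; a trailing
#' window shorter than `window_size` is kept as a short block so chromosome
#' ends are not discarded).  Each block haplotype -- the allele string of one
#' strand over the window -- is encoded as an integer and its occurrences are
#' tallied over all 2N haplotypes of the population.
#'
#' @param pop A `founder_population` (phased by construction).
#' @param window_size Markers per block (default 5; at most 30).
#' @return A `haploblock_catalog`: list with `blocks` (tibble: `block`,
#'   `chrom`, `start`, `end` marker indices), `codes` (2N x B integer matrix
#'   of block-haplotype codes, rows = haplotypes, two consecutive rows per
#'   individual), and `counts` (list of per-block named count tables).
#' @export
build_catalog <- function(pop, window_size = 5) {
  stopifnot(inherits(pop, "founder_population"),
            window_size >= 1, window_size <= 30)
  cache <- map_cache(pop$map)
  blocks <- dplyr::bind_rows(lapply(seq_len(cache$n_chrom), function(c) {
    starts <- seq(cache$first[c], cache$last[c], by = window_size)
    tibble::tibble(chrom = c, start = starts,
                   end = pmin(starts + window_size - 1L, cache$last[c]))
  }))
  blocks$block <- seq_len(nrow(blocks))
  blocks <- blocks[, c("block", "chrom", "start", "end")]

  n <- length(pop$genomes)
  b <- nrow(blocks)
  pow2 <- 2L^(0:(window_size - 1L))
  codes <- matrix(0L, nrow = 2L * n, ncol = b)
  for (k in seq_len(n)) {
    g <- pop$genomes[[k]]
    for (j in seq_len(b)) {
      idx <- blocks$start[j]:blocks$end[j]
      w <- pow2[seq_along(idx)]
      codes[2L * k - 1L, j] <- sum(g$a1[idx] * w)
      codes[2L * k, j] <- sum(g$a2[idx] * w)
    }
  }
  counts <- lapply(seq_len(b), function(j) table(codes[, j]))
  structure(list(blocks = blocks, codes = codes, counts = counts,
                 n_individuals = n, window_size = window_size),
            class = "haploblock_catalog")
}

#' @export
print.haploblock_catalog <- function(x, ...) {
  cat(sprintf("<haploblock_catalog: %d blocks of %d markers, %d individuals>\n",
              nrow(x$blocks), x$window_size, x$n_individuals))
  invisible(x)
}

# Occurrence count of each block haplotype carried by haplotype row `h`.
hap_block_counts <- function(catalog, h) {
  vapply(seq_along(catalog$counts), function(j) {
    as.integer(catalog$counts[[j]][as.character(catalog$codes[h, j])])
  }, 1L)
}

#' Haplotype rarity scores
#'
#' For one individual, the rarity score sums `1 / occurrences(block
#' haplotype)` over both haplotypes and all blocks of the catalog: an
#' individual whose block haplotypes are unique scores `2B` for `B` blocks,
#' one carrying only population-universal haplotypes scores `2B / (2N)`.
#'
#' @param catalog A `haploblock_catalog`.
#' @param individuals Individual indices (default: all).
#' @return A numeric vector of scores.
#' @export
rarity_score <- function(catalog, individuals = seq_len(catalog$n_individuals)) {
  vapply(individuals, function(k) {
    sum(1 / hap_block_counts(catalog, 2L * k - 1L)) +
      sum(1 / hap_block_counts(catalog, 2L * k))
  }, 1.0)
}

#' Select a maximally diverse subset of individuals
#'
#' Two-stage core-collection heuristic: the `n_seed` individuals with the
#' highest haplotype rarity scores are taken first; the remainder are added
#' one by one, each time choosing the individual contributing the largest
#' number of block haplotypes not yet represented in the chosen set.  Only
#' block haplotypes present at least twice in the population count toward
#' coverage (singletons are likely genotyping, imputation or phasing
#' artefacts).  Ties -- in rarity or in coverage gain -- are broken by lowest
#' individual index, making the selection deterministic.
#'
#' @param pop A `founder_population`.
#' @param catalog Optional precomputed `haploblock_catalog` for `pop`.
#' @param n_total Total subset size (default 300).
#' @param n_seed Rarity-seeded subset size (default 25; capped at `n_total`).
#' @param window_size Passed to [build_catalog()] when `catalog` is missing.
#' @return An integer vector of `n_total` individual indices in selection
#'   order, with the individual ids as names.
#' @export
select_diverse_subset <- function(pop, catalog = NULL, n_total = 300,
                                  n_seed = 25, window_size = 5) {
  n <- length(pop$genomes)
  if (n_total > n) {
    stop("`n_total` exceeds the population size.", call. = FALSE)
  }
  n_seed <- min(n_seed, n_total)
  if (is.null(catalog)) catalog <- build_catalog(pop, window_size)

  scores <- rarity_score(catalog)
  chosen <- order(-scores, seq_len(n))[seq_len(n_seed)]

  if (n_total > n_seed) {
    # universe of countable items: (block, code) with population count >= 2,
    # encoded as item ids; per individual the set of item ids carried
    b <- nrow(catalog$blocks)
    keys <- paste(rep(seq_len(b), each = 2L * n), as.vector(catalog$codes))
    cnt <- catalog$codes
    for (j in seq_len(b)) {
      cnt[, j] <- as.integer(catalog$counts[[j]][as.character(catalog$codes[, j])])
    }
    eligible <- as.vector(cnt) >= 2L
    item <- match(keys, unique(keys[eligible]))  # NA for singleton items
    item_mat <- matrix(item, nrow = 2L * n, ncol = b)
    ind_items <- lapply(seq_len(n), function(k) {
      unique(stats::na.omit(c(item_mat[2L * k - 1L, ], item_mat[2L * k, ])))
    })
    n_items <- suppressWarnings(max(item, na.rm = TRUE))
    covered <- logical(max(n_items, 1L))
    for (k in chosen) covered[ind_items[[k]]] <- TRUE
    remaining <- setdiff(seq_len(n), chosen)
    while (length(chosen) < n_total) {
      gains <- vapply(remaining, function(k) sum(!covered[ind_items[[k]]]), 1L)
      pick <- remaining[which.max(gains)]   # which.max: first index wins ties
      covered[ind_items[[pick]]] <- TRUE
      chosen <- c(chosen, pick)
      remaining <- setdiff(remaining, pick)
    }
  }
  names(chosen) <- names(pop$genomes)[chosen]
  chosen
}
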