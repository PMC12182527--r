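#' Quantitative trait architecture: QTL, wild background, elite polygenes
#'
#' The trait is purely additive and built from three effect sets over the
#' marker panel, all effects non-negative and attached to allele *copies*
#' according to their origin tag:
#'
#' * **Elite polygenic background** (infinitesimal model): every marker
#'   carries the same small effect `E / M` on elite-origin copies of either
#'   allele, where `E` is the haploid elite total (default 100 arbitrary
#'   trait units) and `M` the marker count.  A fully homozygous elite
#'   genotype is worth `2E`.
#' * **Wild QTL**: `n_qtl` distinct markers, polymorphic in the selected wild
#'   subset, drawn at random; at each, one of the two wild alleles (chosen
#'   uniformly) carries an effect on wild-origin copies, the other wild
#'   allele carries 0.  Effects follow the geometric series
#'   `e_i = emax * (1/2)^(i-1)` with `emax` defaulting to 5% of `E`.
#' * **Wild genomic background**: the remaining wild total, `E/2 - sum(QTL
#'   effects)`, is spread equally over all non-QTL markers and attached to
#'   wild-origin copies of either allele, so that the haploid wild total is
#'   exactly half the elite total.
#'
#' @name trait_model
NULL

#' Draw a QTL configuration
#'
#' Samples `n_qtl` distinct markers polymorphic within the supplied wild
#' genomes, picks the effect-carrying allele uniformly at each, and assigns
#' geometric-series effects.  QTL are redrawn fresh for every simulation run.
#'
#' @param wilds List of wild `diploid_genome`s (the selected subset).
#' @param map A `genetic_map`.
#' @param n_qtl Number of QTL (the study grid uses 1, 2 or 5).
#' @param emax_percent Largest QTL effect as a percentage of the haploid
#'   elite total (default 5).
#' @param elite_total Haploid elite total `E` in trait units (default 100).
#' @return A tibble of class `qtl_config`: `qtl`, `marker_index`, `marker`,
#'   `chrom`, `pos_cM`, `allele`, `effect`, `allele_freq` (frequency of the
#'   effect allele among the wild genomes).
#' @export
assign_qtl_effects <- function(wilds, map, n_qtl, emax_percent = 5,
                               elite_total = 100) {
  stopifnot(n_qtl >= 1, emax_percent > 0, elite_total > 0)
  dose <- Reduce(`+`, lapply(wilds, dosage))
  n2 <- 2L * length(wilds)
  polymorphic <- which(dose > 0L & dose < n2)
  if (length(polymorphic) < n_qtl) {
    stop(sprintf("Only %d polymorphic markers in the wild subset; %d QTL requested.",
                 length(polymorphic), n_qtl), call. = FALSE)
  }
  markers <- sample(polymorphic, n_qtl)
  alleles <- sample(0:1, n_qtl, replace = TRUE)
  effects <- (emax_percent / 100 * elite_total) * 0.5^(seq_len(n_qtl) - 1)
  freq1 <- dose[markers] / n2
  mtab <- tibble::as_tibble(map)[markers, ]
  structure(tibble::tibble(
    qtl = seq_len(n_qtl),
    marker_index = as.integer(markers),
    marker = mtab$marker,
    chrom = mtab$chrom,
    pos_cM = mtab$pos_cM,
    allele = as.integer(alleles),
    effect = effects,
    allele_freq = ifelse(alleles == 1L, freq1, 1 - freq1)
  ), class = c("qtl_config", class(tibble::tibble())))
}

#' Assemble the full effect table
#'
#' Combines elite polygenes, wild QTL and the wild genomic background into
#' one additive effect table with the accounting identity
#' `haploid elite total = 2 x haploid wild total` holding exactly.
#'
#' @param qtl A [assign_qtl_effects()] result (or `NULL` for no QTL).
#' @param map A `genetic_map`.
#' @param elite_total Haploid elite total `E` (default 100 trait units).
#' @return An `effect_table`: list with `elite_per_marker`, `background`
#'   (per-copy wild background effect at non-QTL markers), `qtl`,
#'   `elite_total`, `wild_total`, `n_markers`.
#' @export
effect_table <- function(qtl, map, elite_total = 100) {
  m <- n_markers(map)
  qtl_sum <- if (is.null(qtl)) 0 else sum(qtl$effect)
  if (qtl_sum >= elite_total / 2) {
    stop(sprintf(
      "Invalid architecture: QTL effects (%.4g) exhaust the wild total E/2 = %.4g.",
      qtl_sum, elite_total / 2), call. = FALSE)
  }
  n_qtl <- if (is.null(qtl)) 0L else nrow(qtl)
  structure(list(
    elite_per_marker = elite_total / m,
    background = (elite_total / 2 - qtl_sum) / (m - n_qtl),
    background_total = elite_total / 2 - qtl_sum,
    qtl = qtl,
    elite_total = elite_total,
    wild_total = elite_total / 2,
    n_markers = m
  ), class = "effect_table")
}

#' @export
print.effect_table <- function(x, ...) {
  cat(sprintf(
    "<effect_table: %d markers, E = %g (elite), wild total = %g (%d QTL summing %g + background %g)>\n",
    x$n_markers, x$elite_total, x$wild_total,
    if (is.null(x$qtl)) 0L else nrow(x$qtl),
    if (is.null(x$qtl)) 0 else sum(x$qtl$effect), x$background_total))
  invisible(x)
}

#' Serialize an effect table for audit
#'
#' One row per (marker class, allele, origin) effect assignment.
#'
#' @param x An `effect_table`.
#' @param ... Unused.
#' @return A tibble with `marker`, `allele`, `origin`, `effect`.
#' @export
tidy.effect_table <- function(x, ...) {
  qtl_markers <- if (is.null(x$qtl)) character() else x$qtl$marker
  dplyr::bind_rows(
    tibble::tibble(marker = "<all>", allele = NA_integer_,
                   origin = "elite", effect = x$elite_per_marker),
    tibble::tibble(marker = "<non-QTL>", allele = NA_integer_,
                   origin = "wild", effect = x$background),
    if (!is.null(x$qtl)) {
      tibble::tibble(marker = qtl_markers, allele = x$qtl$allele,
                     origin = "wild", effect = x$qtl$effect)
    }
  )
}

#' Genotypic value of a diploid genome
#'
#' Sums, over both haplotypes and all markers, the effect attached to each
#' (allele, origin) copy: elite polygenes on elite-origin copies, wild
#' background on wild-origin copies at non-QTL markers, and QTL effects on
#' wild-origin copies of the effect allele.
#'
#' @param g A `diploid_genome`.
#' @param effects An [effect_table()].
#' @return Genotypic value in trait units.
#' @export
genotypic_value <- function(g, effects) {
  if (length(g$a1) != effects$n_markers) {
    stop("Genome width does not match the effect table.", call. = FALSE)
  }
  w1 <- g$o1 > 0L
  w2 <- g$o2 > 0L
  n_elite <- sum(!w1) + sum(!w2)
  n_wild <- sum(w1) + sum(w2)
  value <- effects$elite_per_marker * n_elite
  qtl <- effects$qtl
  if (!is.null(qtl) && nrow(qtl) > 0) {
    q <- qtl$marker_index
    wild_at_qtl <- sum(w1[q]) + sum(w2[q])
    hits <- (w1[q] & g$a1[q] == qtl$allele) + (w2[q] & g$a2[q] == qtl$allele)
    value <- value + sum(qtl$effect * hits) +
      effects$background * (n_wild - wild_at_qtl)
  } else {
    value <- value + effects$background * n_wild
  }
  value
}

# Vectorized genotypic values for a genome_batch (one value per offspring;
# batch matrices are markers x offspring).
batch_genotypic_values <- function(batch, effects) {
  W1 <- batch$O1 > 0L
  W2 <- batch$O2 > 0L
  m <- nrow(W1)
  n_wild <- colSums(W1) + colSums(W2)
  n_elite <- 2L * m - n_wild
  value <- effects$elite_per_marker * n_elite
  qtl <- effects$qtl
  if (!is.null(qtl) && nrow(qtl) > 0) {
    q <- qtl$marker_index
    wild_at_qtl <- colSums(W1[q, , drop = FALSE]) + colSums(W2[q, , drop = FALSE])
    hit <- rep(0, ncol(W1))
    for (i in seq_along(q)) {
      hit <- hit + qtl$effect[i] *
        ((W1[q[i], ] & batch$A1[q[i], ] == qtl$allele[i]) +
         (W2[q[i], ] & batch$A2[q[i], ] == qtl$allele[i]))
    }
    value + hit + effects$background * (n_wild - wild_at_qtl)
  } else {
    value + effects$background * n_wild
  }
}

#' Simulate entry phenotypes at a set heritability
#'
#' Adds one normal nongenetic deviate per entry to the entry-mean genotypic
#' values.  The genetic variance `v_g` is the variance of the entry values of
#' the realized mapping population; the noise variance follows from the
#' broad-sense heritability, `h2 = v_g / (v_g + v_e)`, i.e. `v_e = v_g *
#' (1 - h2) / h2`.
#'
#' @param values Numeric vector of entry genotypic values.
#' @param h2 Broad-sense heritability in `(0, 1]` (the study grid is 0.5 to
#'   0.9).
#' @param noise Optional vector of standard-normal deviates, one per entry.
#'   Supplying the same deviates across an `h2` grid yields common random
#'   numbers, so that lowering `h2` strictly inflates every entry's noise.
#' @return A list with `phenotype`, `v_g`, `v_e`, `h2`.
#' @export
simulate_phenotypes <- function(values, h2, noise = NULL) {
  stopifnot(h2 > 0, h2 <= 1)
  v_g <- stats::var(values)
  if (!is.finite(v_g) || v_g <= 0) {
    stop("Degenerate mapping population: entry genotypic values have zero variance.",
         call. = FALSE)
  }
  v_e <- v_g * (1 - h2) / h2
  if (is.null(noise)) noise <- stats::rnorm(length(values))
  list(phenotype = values + sqrt(v_e) * noise, v_g = v_g, v_e = v_e, h2 = h2)
}
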