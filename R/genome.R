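#' Origin-tagged diploid genomes
#'
#' A `diploid_genome` holds the two phased haplotypes of one individual over a
#' marker index: biallelic alleles (0/1) plus an integer origin tag per allele
#' copy identifying the founder haplotype it descends from.  Positive tags are
#' wild founder haplotypes (tag `2k - 1` and `2k` for wild founder `k`);
#' negative tags are elite-pool haplotypes.  Tags travel untouched through
#' meiosis, which is what lets the pipeline score wild vs elite genome
#' content even where the two pools carry identical SNP alleles.
#'
#' @param hap1,hap2 Integer vectors of 0/1 alleles, equal length.
#' @param origin1,origin2 Integer origin tags, same length as the haplotypes.
#' @param id Optional individual label.
#' @return An object of class `diploid_genome`.
#' @export
diploid_genome <- function(hap1, hap2, origin1, origin2, id = NA_character_) {
  m <- length(hap1)
  if (length(hap2) != m || length(origin1) != m || length(origin2) != m) {
    stop("Haplotype and origin vectors must all have the same length.", call. = FALSE)
  }
  structure(
    list(a1 = as.integer(hap1), a2 = as.integer(hap2),
         o1 = as.integer(origin1), o2 = as.integer(origin2),
         id = id),
    class = "diploid_genome"
  )
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat(sprintf(
    "<diploid_genome%s: %d markers, het %.2f%%, wild genome %.1f%%>\n",
    if (is.na(x$id)) "" else paste0(" ", x$id),
    length(x$a1), 100 * heterozygosity(x), 100 * wild_genome_fraction(x)))
  invisible(x)
}

check_same_width <- function(a, b) {
  if (length(a$a1) != length(b$a1)) {
    stop("Genomes have different marker counts.", call. = FALSE)
  }
  invisible(TRUE)
}

check_genome_map <- function(g, map) {
  if (length(g$a1) != n_markers(map)) {
    stop("Genome width does not match the genetic map.", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-individual summaries of a diploid genome
#'
#' `heterozygosity()` is the fraction of markers with differing alleles on the
#' two haplotypes.  `dosage()` is the 0/1/2 count of the "1" allele per
#' marker -- the origin-blind coding a SNP array would deliver, used for
#' kinship and the association scan.  `wild_genome_fraction()` is the share of
#' the 2M allele copies carrying a wild origin tag.
#' `wild_haplotype_coverage()` averages, over markers, the number of
#' *distinct* wild founder haplotypes present among the two copies (0 to 2):
#' a wild individual scores 2, its doubled haploid 1, and a backcross-derived
#' doubled haploid 0.25 in expectation.
#'
#' @param g A `diploid_genome`.
#' @return A scalar (or integer vector for `dosage()`).
#' @export
heterozygosity <- function(g) mean(g$a1 != g$a2)

#' @rdname heterozygosity
#' @export
dosage <- function(g) g$a1 + g$a2

#' @rdname heterozygosity
#' @export
wild_genome_fraction <- function(g) {
  (sum(g$o1 > 0L) + sum(g$o2 > 0L)) / (2L * length(g$o1))
}

#' @rdname heterozygosity
#' @export
wild_haplotype_coverage <- function(g) {
  w1 <- g$o1 > 0L
  w2 <- g$o2 > 0L
  mean(w1 + w2 - (w1 & w2 & g$o1 == g$o2))
}
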