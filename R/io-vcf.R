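#' Write a founder population as a phased VCF plus map TSV
#'
#' Serializes phased genotypes as a minimal VCFv4.2 file (GT field with the
#' `|` separator, one contig per chromosome) alongside the genetic map in the
#' TSV layout of [write_genetic_map()].  Together the two files are the
#' package's interchange format: externally phased real data written the same
#' way can replace a synthetic population transparently via
#' [read_phased_vcf()].  Base-pair POS is a scaled copy of the cM position
#' (1 cM = 10 kb) kept only to satisfy the format; the map TSV carries the
#' authoritative genetic positions.
#'
#' @param pop A `founder_population`.
#' @param vcf_path,map_path Output paths.
#' @return `pop`, invisibly.
#' @export
write_phased_vcf <- function(pop, vcf_path, map_path = NULL) {
  map <- tibble::as_tibble(pop$map)
  n <- length(pop$genomes)
  pos_bp <- round(map$pos_cM * 1e4) + 1
  # guarantee strictly increasing POS within chromosome after rounding
  pos_bp <- unlist(lapply(split(pos_bp, map$chrom), function(p) {
    for (i in seq_along(p)[-1]) if (p[i] <= p[i - 1]) p[i] <- p[i - 1] + 1
    p
  }), use.names = FALSE)

  gt <- vapply(pop$genomes, function(g) paste0(g$a1, "|", g$a2),
               character(nrow(map)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=wildmap",
    sprintf("##contig=<ID=%d>", sort(unique(map$chrom))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(pop$genomes)), collapse = "\t")
  )
  body <- paste(map$chrom, pos_bp, map$marker, "A", "T", ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)
  if (!is.null(map_path)) write_genetic_map(pop$map, map_path)
  invisible(pop)
}

#' Read a phased VCF plus map TSV as a founder population
#'
#' Counterpart of [write_phased_vcf()].  Genotypes must be phased (`|`
#' separated); each individual's two strands receive fresh wild founder
#' origin tags, so the read population can seed the crossing designs exactly
#' like a generated one.
#'
#' @param vcf_path Path to a phased VCF.
#' @param map_path Path to the genetic-map TSV (`marker`, `chrom`, `pos_cM`).
#' @param id Population label.
#' @return A `founder_population`.
#' @export
read_phased_vcf <- function(vcf_path, map_path, id = "pop1") {
  map <- read_genetic_map(map_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ord <- match(map$marker, rownames(gt))
  if (anyNA(ord)) {
    stop("VCF does not contain all markers listed in the map TSV.", call. = FALSE)
  }
  gt <- gt[ord, , drop = FALSE]
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("Unphased genotypes found ('/'): the reader requires phased input.",
         call. = FALSE)
  }
  m <- nrow(gt)
  samples <- colnames(gt)
  genomes <- lapply(seq_along(samples), function(k) {
    parts <- strsplit(gt[, k], "|", fixed = TRUE)
    a1 <- as.integer(vapply(parts, `[`, "", 1L))
    a2 <- as.integer(vapply(parts, `[`, "", 2L))
    diploid_genome(a1, a2, rep(2L * k - 1L, m), rep(2L * k, m),
                   id = samples[k])
  })
  names(genomes) <- samples
  new_founder_population(genomes, map, id)
}
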