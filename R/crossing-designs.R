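#' Crossing designs M1-M9
#'
#' The nine designs turn one wild individual into the pre-testcross parent of
#' one mapping-population entry.  Per wild beet, exactly one random offspring
#' plant is carried per intermediate generation:
#'
#' * `M1` wild itself; `M2` one selfed progeny; `M3` one doubled haploid;
#' * `M4` wild x elite F1; `M5` one selfed F1 progeny (F1S1); `M6` one DH of
#'   the F1;
#' * `M7` F1 backcrossed to the same elite (B1); `M8` one selfed B1 progeny;
#'   `M9` one DH of the B1.
#'
#' The entry's progeny are testcrosses of the pre-testcross genome to the
#' common tester, with fresh tester gametes drawn per offspring.
#'
#' @name crossing_designs
NULL

design_ids <- function() paste0("M", 1:9)

# One pre-testcross genome for a design, from one wild individual.
pre_testcross_genome <- function(design, wild, elite, map) {
  switch(design,
    M1 = wild,
    M2 = self_cross(wild, map),
    M3 = make_dh(wild, map),
    M4 = cross(wild, elite, map),
    M5 = self_cross(cross(wild, elite, map), map),
    M6 = make_dh(cross(wild, elite, map), map),
    M7 = cross(cross(wild, elite, map), elite, map),
    M8 = self_cross(cross(cross(wild, elite, map), elite, map), map),
    M9 = make_dh(cross(cross(wild, elite, map), elite, map), map),
    stop(sprintf("Unknown crossing design '%s' (expected M1..M9).", design),
         call. = FALSE)
  )
}

#' Build one mapping-population entry
#'
#' Applies the design's crossing path to one wild individual (carrying one
#' random individual per intermediate generation), then produces
#' `n_offspring` testcross progeny with the common tester.  The entry's scan
#' genotype is the 0/1/2 dosage of the *pre-testcross* genome: genotyping
#' happens before the testcross, so tester alleles never enter the scan.
#'
#' @param design One of `"M1"`..`"M9"`.
#' @param wild,elite,tester `diploid_genome`s on the same map.
#' @param n_offspring Number of testcross progeny (default 594, i.e. six
#'   field plots of 99 beets).
#' @param map A `genetic_map`.
#' @param keep_progeny Keep the progeny batch in the result (set `FALSE` to
#'   drop it after computing `progeny_summary`).
#' @return A `mapping_entry`: list with `wild_parent_id`, `design`,
#'   `pre_genome`, `scan_genotype` (integer dosage vector), `progeny`
#'   (a genome batch or `NULL`) and `n_progeny`.
#' @export
build_entry <- function(design, wild, elite, tester, n_offspring = 594,
                        map = NULL, keep_progeny = TRUE) {
  stopifnot(design %in% design_ids(), n_offspring >= 1, !is.null(map))
  check_genome_map(wild, map)
  check_same_width(wild, elite)
  check_same_width(wild, tester)
  pre <- pre_testcross_genome(design, wild, elite, map)
  progeny <- cross_batch(pre, tester, map, n_offspring)
  structure(list(
    wild_parent_id = wild$id,
    design = design,
    pre_genome = pre,
    scan_genotype = dosage(pre),
    progeny = if (keep_progeny) progeny else NULL,
    n_progeny = as.integer(n_offspring),
    mean_progeny_wild_fraction = mean(batch_wild_fraction(progeny))
  ), class = "mapping_entry")
}

#' Build a mapping population for one crossing design
#'
#' One entry per selected wild individual.  When an `effect_table` is
#' supplied, each entry's genotypic value (the mean genotypic value of its
#' testcross progeny) is computed on the fly and the progeny batches are
#' discarded, keeping memory flat for large experiments.
#'
#' @param design One of `"M1"`..`"M9"`.
#' @param wilds List of wild `diploid_genome`s (the selected subset).
#' @param elite,tester Common elite line and tester genomes.
#' @param n_offspring Testcross progeny per entry (default 594).
#' @param map A `genetic_map`.
#' @param effects Optional [effect_table()] used to score progeny and drop
#'   them immediately.
#' @param keep_progeny Keep progeny batches (ignored when `effects` is
#'   given).
#' @return A `mapping_population`: list with `design`, `map`, `entries`
#'   (tibble: `entry`, `wild_parent_id`, `genotypic_value`,
#'   `mean_progeny_wild_fraction`), `scan_genotypes` (entries x markers
#'   integer dosage matrix) and `pre_genomes` / `progeny` lists.
#' @export
build_mapping_population <- function(design, wilds, elite, tester,
                                     n_offspring = 594, map = NULL,
                                     effects = NULL, keep_progeny = FALSE) {
  if (length(wilds) == 0) {
    stop("`wilds` must contain at least one selected individual.", call. = FALSE)
  }
  stopifnot(!is.null(map))
  keep <- keep_progeny && is.null(effects)
  entries <- vector("list", length(wilds))
  values <- rep(NA_real_, length(wilds))
  for (i in seq_along(wilds)) {
    e <- build_entry(design, wilds[[i]], elite, tester, n_offspring, map,
                     keep_progeny = TRUE)
    if (!is.null(effects)) {
      values[i] <- mean(batch_genotypic_values(e$progeny, effects))
    }
    if (!keep) e$progeny <- NULL
    entries[[i]] <- e
  }
  scan <- do.call(rbind, lapply(entries, `[[`, "scan_genotype"))
  rownames(scan) <- vapply(entries, `[[`, "", "wild_parent_id")
  structure(list(
    design = design,
    map = map,
    entries = tibble::tibble(
      entry = seq_along(entries),
      wild_parent_id = rownames(scan),
      genotypic_value = values,
      mean_progeny_wild_fraction =
        vapply(entries, `[[`, 1.0, "mean_progeny_wild_fraction")
    ),
    scan_genotypes = scan,
    pre_genomes = lapply(entries, `[[`, "pre_genome"),
    progeny = if (keep) lapply(entries, `[[`, "progeny") else NULL,
    n_offspring = as.integer(n_offspring)
  ), class = "mapping_population")
}

#' @export
print.mapping_population <- function(x, ...) {
  cat(sprintf("<mapping_population %s: %d entries x %d testcross progeny, %d markers>\n",
              x$design, nrow(x$entries), x$n_offspring, ncol(x$scan_genotypes)))
  invisible(x)
}

#' @export
tidy.mapping_population <- function(x, ...) x$entries
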