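#' Specification for a synthetic wild founder population
#'
#' Collects the knobs of the synthetic-population generator.  The defaults
#' describe the wild sea beet populations the pipeline is designed around:
#' roughly a thousand genotyped individuals per population, 16,076 SNPs on
#' nine chromosomes totalling 625 cM, mean per-individual heterozygosity in
#' the low teens (here 14%), mean minor allele frequency around 10%, and low
#' linkage disequilibrium created by many generations of outcrossing
#' (emulated by a random-mating burn-in).
#'
#' @param n_individuals Number of diploid individuals.
#' @param n_markers,n_chromosomes,total_map_length Map dimensions (markers,
#'   chromosomes, total cM); used when no map is supplied downstream.
#' @param target_heterozygosity Desired population mean fraction of
#'   heterozygous markers per individual, in `[0, 1]`.
#' @param maf_mean Desired mean minor allele frequency in `(0, 0.5]`.
#' @param burn_in_generations Rounds of random mating applied after the
#'   founders are drawn, recombining the ancestral haplotypes so LD decays
#'   with map distance and relatives share recombination-shaped blocks.
#' @param n_founder_haplotypes Effective number of distinct ancestral
#'   haplotypes the founder strands are drawn from.  A finite pool is what
#'   lets nearby markers tag each other (and a withheld causal site): each
#'   allele exists on a limited set of ancestral backgrounds, as for young
#'   alleles in a real population.  The default of 6 reproduces, at typical
#'   panel densities, the local tagging effectiveness that association
#'   mapping in wild populations relies on; the burn-in sets the map-distance
#'   decay scale.
#' @param seed Integer seed for the generator.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_individuals = 1000,
                            n_markers = 16076,
                            n_chromosomes = 9,
                            total_map_length = 625,
                            target_heterozygosity = 0.14,
                            maf_mean = 0.10,
                            burn_in_generations = 20,
                            n_founder_haplotypes = 6,
                            seed = 1L) {
  stopifnot(n_individuals >= 2, n_markers >= n_chromosomes,
            n_chromosomes >= 1, total_map_length > 0,
            burn_in_generations >= 0, n_founder_haplotypes >= 2)
  if (maf_mean <= 0 || maf_mean > 0.5) {
    stop("`maf_mean` must lie in (0, 0.5].", call. = FALSE)
  }
  if (target_heterozygosity < 0 || target_heterozygosity > 1) {
    stop("`target_heterozygosity` must lie in [0, 1].", call. = FALSE)
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes),
    total_map_length = total_map_length,
    target_heterozygosity = target_heterozygosity,
    maf_mean = maf_mean,
    burn_in_generations = as.integer(burn_in_generations),
    n_founder_haplotypes = as.integer(n_founder_haplotypes),
    seed = as.integer(seed)
  ), class = "population_spec")
}

# Calibrate the ancestral allele-frequency law and the mating system.
# The per-marker derived-allele frequency is Beta(a, b) with the L-shape
# parameter fixed (a = 0.4) and the mean solved so that the *realized* mean
# minor allele frequency -- the folded mean of the BetaBinomial(K) pool
# frequency -- hits maf_mean.  That spectrum implies a Hardy-Weinberg mean
# heterozygosity H = 2 (1 - 1/K) E[p(1-p)]; the remaining gap to the (lower)
# heterozygosity target is closed by an inbreeding coefficient
# F = 1 - target/H, realized through partial selfing during burn-in.  An
# excess-heterozygosity target (target > H) has no mating-system solution
# and errors out.
beta_frequency_shape <- function(maf_mean, target_het, pool_size = Inf) {
  a <- 0.4
  k <- pool_size
  folded_mean <- function(mu) {
    b <- a * (1 - mu) / mu
    if (is.finite(k)) {
      c_ <- 0:k
      pmf <- exp(lchoose(k, c_) + lbeta(c_ + a, k - c_ + b) - lbeta(a, b))
      sum(pmin(c_, k - c_) / k * pmf)
    } else {
      stats::integrate(function(p) pmin(p, 1 - p) * stats::dbeta(p, a, b),
                       0, 1, rel.tol = 1e-8)$value
    }
  }
  # folded mean rises with mu up to ~0.35 then flattens; stay on the rising
  # branch
  hi <- stats::optimize(folded_mean, c(0.05, 0.5), maximum = TRUE)$maximum
  mu <- if (folded_mean(hi) <= maf_mean) {
    hi
  } else if (folded_mean(0.02) >= maf_mean) {
    0.02
  } else {
    stats::uniroot(function(m) folded_mean(m) - maf_mean, c(0.02, hi),
                   tol = 1e-7)$root
  }
  b <- a * (1 - mu) / mu
  v <- mu * (1 - mu) / (a + b + 1)
  h_hwe <- 2 * (1 - 1 / min(k, .Machine$double.xmax)) * (mu - v - mu^2)
  if (target_het > h_hwe + 0.025) {
    stop(sprintf(
      paste0("Unattainable calibration: target heterozygosity %.3f exceeds ",
             "the Hardy-Weinberg ceiling %.3f implied by maf_mean = %.3f ",
             "(heterozygote excess cannot be produced by the mating system)."),
      target_het, h_hwe, maf_mean), call. = FALSE)
  }
  list(a = a, b = b, inbreeding = max(0, 1 - target_het / h_hwe))
}

#' Generate a synthetic wild founder population
#'
#' Per-marker allele frequencies are drawn from a Beta law calibrated so that
#' the realized mean minor allele frequency matches `spec$maf_mean` and the
#' expected mean heterozygosity matches `spec$target_heterozygosity`.  An
#' ancestral pool of `spec$n_founder_haplotypes` haplotypes is drawn at
#' linkage equilibrium from those frequencies; every founder strand is a
#' random pool member, and the population is then run through
#' `spec$burn_in_generations` rounds of mixed mating -- mostly random
#' outcrossing, plus the partial-selfing fraction the heterozygosity
#' calibration demands (wild populations show excess homozygosity relative
#' to Hardy-Weinberg, from fine-scale substructure and inbreeding; a selfing
#' rate `s` yields the equivalent equilibrium `F = s/(2-s)`).  The finite
#' pool plus burn-in is what creates realistic structure: relatives share
#' recombination-shaped haplotype blocks and marker-marker LD decays with
#' map distance (strong below ~1 cM, weak beyond a few cM at the default
#' burn-in length).  Origin tags are assigned *after* burn-in: the returned
#' individuals are the wild founders whose haplotypes the crossing designs
#' track (individual `k` carries tags `2k - 1` and `2k`).
#'
#' @param spec A [population_spec()].
#' @param map Optional `genetic_map`; generated from the spec dimensions
#'   (even spacing) when missing.
#' @param id Population label.
#' @return A `founder_population`: list with `genomes` (list of
#'   `diploid_genome`), `map`, and `id`.
#' @export
generate_wild_population <- function(spec, map = NULL, id = "pop1") {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(map)) {
    map <- generate_genetic_map(spec$n_markers, spec$n_chromosomes,
                                spec$total_map_length)
  }
  if (n_markers(map) != spec$n_markers) {
    stop("Map marker count does not match the population spec.", call. = FALSE)
  }
  set.seed(spec$seed)
  n <- spec$n_individuals
  m <- spec$n_markers
  k <- spec$n_founder_haplotypes
  shape <- beta_frequency_shape(spec$maf_mean, spec$target_heterozygosity,
                                pool_size = k)
  p <- stats::rbeta(m, shape$a, shape$b)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)

  pool <- matrix(stats::rbinom(k * m, 1L, rep(p, each = k)), nrow = k)
  draw <- function() pool[sample.int(k, 1L), ]
  genomes <- lapply(seq_len(n), function(i) {
    diploid_genome(draw(), draw(), integer(m), integer(m))
  })

  # mixed mating: a selfing rate s gives equilibrium inbreeding F = s/(2-s),
  # emulating the homozygosity excess (F_IS) that fine-scale substructure
  # and partial inbreeding produce in real wild populations
  selfing_rate <- 2 * shape$inbreeding / (1 + shape$inbreeding)
  for (gen in seq_len(spec$burn_in_generations)) {
    dams <- sample.int(n, n, replace = TRUE)
    sires <- sample.int(n, n, replace = TRUE)
    selfed <- stats::runif(n) < selfing_rate
    sires[selfed] <- dams[selfed]
    clash <- which(sires == dams & !selfed)   # outcrossed offspring: no selfing
    while (length(clash) > 0) {
      sires[clash] <- sample.int(n, length(clash), replace = TRUE)
      clash <- clash[sires[clash] == dams[clash]]
    }
    genomes <- lapply(seq_len(n), function(i) {
      cross(genomes[[dams[i]]], genomes[[sires[i]]], map)
    })
  }

  ids <- sprintf("%s_i%0*d", id, nchar(n), seq_len(n))
  genomes <- lapply(seq_len(n), function(k) {
    g <- genomes[[k]]
    diploid_genome(g$a1, g$a2, rep(2L * k - 1L, m), rep(2L * k, m), id = ids[k])
  })
  names(genomes) <- ids
  new_founder_population(genomes, map, id)
}

new_founder_population <- function(genomes, map, id = "pop1") {
  stopifnot(length(genomes) >= 1)
  widths <- vapply(genomes, function(g) length(g$a1), 1L)
  if (any(widths != n_markers(map))) {
    stop("All genomes must match the map's marker count.", call. = FALSE)
  }
  structure(list(genomes = genomes, map = map, id = id),
            class = "founder_population")
}

#' @export
print.founder_population <- function(x, ...) {
  cat(sprintf("<founder_population %s: %d individuals, %d markers, mean het %.2f%%, mean MAF %.2f%%>\n",
              x$id, length(x$genomes), n_markers(x$map),
              100 * mean_heterozygosity(x), 100 * mean_maf(x)))
  invisible(x)
}

#' Population-level summaries
#'
#' `mean_heterozygosity()` averages per-individual heterozygosity;
#' `allele_frequencies()` gives the per-marker frequency of the "1" allele;
#' `mean_maf()` averages the folded (minor) allele frequency over markers.
#' `tidy()` on a `founder_population` returns one row per individual.
#'
#' @param pop A `founder_population`.
#' @return A scalar, numeric vector, or tibble.
#' @export
mean_heterozygosity <- function(pop) {
  mean(vapply(pop$genomes, heterozygosity, 1.0))
}

#' @rdname mean_heterozygosity
#' @export
allele_frequencies <- function(pop) {
  tot <- Reduce(`+`, lapply(pop$genomes, function(g) g$a1 + g$a2))
  tot / (2 * length(pop$genomes))
}

#' @rdname mean_heterozygosity
#' @export
mean_maf <- function(pop) {
  p <- allele_frequencies(pop)
  mean(pmin(p, 1 - p))
}

#' @rdname mean_heterozygosity
#' @param x A `founder_population`.
#' @param ... Unused.
#' @export
tidy.founder_population <- function(x, ...) {
  tibble::tibble(
    id = names(x$genomes),
    heterozygosity = vapply(x$genomes, heterozygosity, 1.0, USE.NAMES = FALSE),
    wild_genome_fraction =
      vapply(x$genomes, wild_genome_fraction, 1.0, USE.NAMES = FALSE)
  )
}

#' Generate the elite line
#'
#' An almost fully inbred elite genotype: heterozygous at exactly
#' `floor(het_fraction * M)` randomly placed markers (so at most the
#' requested fraction) and homozygous elsewhere, with every allele copy
#' origin-tagged as elite.  The default 1% ceiling mirrors an elite sugar
#' beet inbred.
#'
#' @param map A `genetic_map`.
#' @param het_fraction Fraction of heterozygous markers in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A `diploid_genome` with elite origin tags (-1, -2).
#' @export
generate_elite_line <- function(map, het_fraction = 0.01, seed = NULL) {
  stopifnot(het_fraction >= 0, het_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- n_markers(map)
  a1 <- stats::rbinom(m, 1L, 0.5)
  a2 <- a1
  k <- floor(het_fraction * m)
  if (k > 0) {
    het_loci <- sample.int(m, k)
    a2[het_loci] <- 1L - a2[het_loci]
  }
  diploid_genome(a1, a2, rep(-1L, m), rep(-2L, m), id = "elite")
}

#' Generate the tester
#'
#' The tester is modelled as a within-pool two-way hybrid: the F1 of two
#' fully homozygous elite-pool lines that differ at exactly
#' `floor(divergence * M)` markers, so its heterozygosity equals the
#' divergence.  The default 24.44% matches a CMS-sterile sugar beet tester
#' hybrid.  All origin tags are elite (the tester contributes elite-pool
#' genome, tags -3 and -4).
#'
#' @param map A `genetic_map`.
#' @param elite Optional elite `diploid_genome` whose first haplotype seeds
#'   the first pool line; a random homozygous line is used otherwise.
#' @param divergence Fraction of markers at which the two pool lines differ.
#' @param seed Optional integer seed.
#' @return A `diploid_genome`.
#' @export
generate_tester <- function(map, elite = NULL, divergence = 0.2444,
                            seed = NULL) {
  stopifnot(divergence >= 0, divergence <= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- n_markers(map)
  line_a <- if (is.null(elite)) stats::rbinom(m, 1L, 0.5) else elite$a1
  line_b <- line_a
  k <- floor(divergence * m)
  if (k > 0) {
    div_loci <- sample.int(m, k)
    line_b[div_loci] <- 1L - line_b[div_loci]
  }
  diploid_genome(line_a, line_b, rep(-3L, m), rep(-4L, m), id = "tester")
}
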