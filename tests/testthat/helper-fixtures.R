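# Shared fixtures, built in code.  The cached population is generated once
# per test session.

.fixture_env <- new.env(parent = emptyenv())

# A homozygous diploid genome with uniform origin tags.
hom_genome <- function(alleles, origin = 1L, id = NA_character_) {
  alleles <- as.integer(alleles)
  diploid_genome(alleles, alleles, rep(as.integer(origin), length(alleles)),
                 rep(as.integer(origin), length(alleles)), id = id)
}

# A fully heterozygous two-strand genome from two allele vectors.
phased_genome <- function(a1, a2, o1 = 1L, o2 = 2L, id = NA_character_) {
  m <- length(a1)
  diploid_genome(a1, a2, rep(as.integer(o1), m), rep(as.integer(o2), m), id = id)
}

# Single-chromosome map with given positions.
pos_map <- function(pos, chrom = 1L) {
  new_genetic_map(tibble::tibble(
    marker = sprintf("m%03d", seq_along(pos)), chrom = chrom, pos_cM = pos))
}

# Small wild population + map, cached across test files.
small_wild_pop <- function() {
  if (is.null(.fixture_env$pop)) {
    map <- generate_genetic_map(600, 3, 210)
    spec <- population_spec(n_individuals = 120, n_markers = 600,
                            n_chromosomes = 3, total_map_length = 210,
                            burn_in_generations = 8, seed = 101)
    .fixture_env$pop <- generate_wild_population(spec, map, id = "test")
  }
  .fixture_env$pop
}

# Elite line and tester on the cached population's map.
small_elite <- function() generate_elite_line(small_wild_pop()$map, seed = 77)
small_tester <- function() {
  generate_tester(small_wild_pop()$map, small_elite(), seed = 78)
}
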