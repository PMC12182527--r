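#' Meiosis and crossing primitives
#'
#' Gametes are simulated under the Haldane model: per chromosome the
#' crossover count is Poisson with mean `length / 100` (length in cM),
#' crossover positions are uniform along the chromosome and there is no
#' interference or obligate chiasma.  The starting strand is chosen with
#' probability 1/2 and each locus copies both the allele and the origin tag
#' from the active parental strand.  All randomness comes from R's global
#' RNG, so callers obtain reproducibility with `set.seed()`.
#'
#' @param parent,a,b `diploid_genome` objects sharing the map's marker index.
#' @param map A `genetic_map`.
#' @return `meiosis()` returns a list with elements `a` (alleles) and `o`
#'   (origin tags) for one gamete; `cross()`, `self_cross()` and `make_dh()`
#'   return a `diploid_genome`.
#' @examples
#' map <- generate_genetic_map(20, 2, 100)
#' f <- diploid_genome(rep(0, 20), rep(1, 20), rep(1, 20), rep(2, 20))
#' set.seed(1)
#' offspring <- cross(f, f, map)
#' @export
meiosis <- function(parent, map) {
  check_genome_map(parent, map)
  use1 <- gamete_strands(map_cache(map), 1L)[, 1L]
  a <- parent$a1; o <- parent$o1
  a[!use1] <- parent$a2[!use1]
  o[!use1] <- parent$o2[!use1]
  list(a = a, o = o)
}

# Active-strand indicators for n independent gametes as an n x M logical
# matrix (TRUE = copy from haplotype 1).  Per chromosome, each gamete's
# crossover count is Poisson(L/100); crossover positions are binned between
# adjacent markers (tabulate) and the per-marker crossover counts accumulate
# along the chromosome, so the strand at marker j is start + #crossovers
# before j (mod 2).
gamete_strands <- function(cache, n) {
  out <- matrix(FALSE, cache$n_markers, n)   # markers x gametes, transposed on return
  for (c in seq_len(cache$n_chrom)) {
    pos <- cache$pos[[c]] - cache$pos[[c]][1L]
    mc <- length(pos)
    rows <- cache$first[c]:cache$last[c]
    start <- sample.int(2L, n, replace = TRUE) - 1L
    k <- stats::rpois(n, cache$len[c] / 100)
    ktot <- sum(k)
    if (ktot == 0L) {
      out[rows, ] <- matrix(start == 0L, mc, n, byrow = TRUE)
      next
    }
    xo <- stats::runif(ktot, 0, cache$len[c])
    gi <- rep.int(seq_len(n), k)
    bin <- findInterval(xo, pos)          # crossover lies between markers bin, bin+1
    # (mc+1) x n crossover tallies, column-major; seed row "bin 0" with the
    # start parity so one running cumsum yields start + #crossovers before
    # each marker for every gamete at once
    ivec <- tabulate((gi - 1L) * (mc + 1L) + bin + 1L, nbins = n * (mc + 1L))
    head_idx <- (seq_len(n) - 1L) * (mc + 1L) + 1L
    ivec[head_idx] <- ivec[head_idx] + start
    v <- cumsum(ivec)
    off <- c(0L, v[head_idx[-1L] - 1L])   # running total at each column start
    cnt <- matrix(v - rep(off, each = mc + 1L), mc + 1L, n)
    out[rows, ] <- (cnt[seq_len(mc), , drop = FALSE] %% 2L) == 0L
  }
  out
}

#' @rdname meiosis
#' @export
cross <- function(a, b, map) {
  check_same_width(a, b)
  ga <- meiosis(a, map)
  gb <- meiosis(b, map)
  diploid_genome(ga$a, gb$a, ga$o, gb$o)
}

#' @rdname meiosis
#' @export
self_cross <- function(a, map) {
  ga <- meiosis(a, map)
  gb <- meiosis(a, map)
  diploid_genome(ga$a, gb$a, ga$o, gb$o)
}

#' @rdname meiosis
#' @export
make_dh <- function(a, map) {
  g <- meiosis(a, map)
  diploid_genome(g$a, g$a, g$o, g$o)
}

# Batched gametes from one parent: returns list(A = M x n allele matrix,
# O = M x n origin matrix), one column per gamete.  Equivalent to n
# independent meiosis() calls but cheaper in the progeny hot path.
meiosis_batch <- function(parent, map, n) {
  check_genome_map(parent, map)
  cache <- map_cache(map)
  m <- cache$n_markers
  strands <- gamete_strands(cache, n)
  A <- matrix(parent$a2, m, n)
  O <- matrix(parent$o2, m, n)
  idx <- which(strands)
  marker_of <- ((idx - 1L) %% m) + 1L
  A[idx] <- parent$a1[marker_of]
  O[idx] <- parent$o1[marker_of]
  list(A = A, O = O)
}

# Batched biparental cross: n offspring of a x b as a `genome_batch`
# (A1/A2 allele and O1/O2 origin matrices, markers x offspring).
cross_batch <- function(a, b, map, n) {
  check_same_width(a, b)
  ga <- meiosis_batch(a, map, n)
  gb <- meiosis_batch(b, map, n)
  structure(list(A1 = ga$A, A2 = gb$A, O1 = ga$O, O2 = gb$O),
            class = "genome_batch")
}

# Extract offspring i of a genome_batch as a diploid_genome.
batch_genome <- function(batch, i) {
  diploid_genome(batch$A1[, i], batch$A2[, i], batch$O1[, i], batch$O2[, i])
}

# Per-offspring wild-genome fraction for a genome_batch.
batch_wild_fraction <- function(batch) {
  (colSums(batch$O1 > 0L) + colSums(batch$O2 > 0L)) / (2L * nrow(batch$O1))
}
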