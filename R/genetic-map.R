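#' Generate a genetic map
#'
#' Builds a marker map spread over a given number of chromosomes with a fixed
#' total genetic length.  Markers are partitioned across chromosomes as evenly
#' as the counts allow (the first `n_markers %% n_chromosomes` chromosomes get
#' one extra marker) and chromosomes all have equal genetic length
#' `total_length / n_chromosomes`.  Within a chromosome the first marker sits
#' at 0 cM and the last at the chromosome end.
#'
#' @param n_markers Total number of markers (>= `n_chromosomes`).
#' @param n_chromosomes Number of chromosomes.
#' @param total_length Total map length in centimorgan, summed over
#'   chromosomes.
#' @param spacing `"even"` for an arithmetic grid per chromosome,
#'   `"uniform_random"` for marker positions drawn uniformly (endpoints kept).
#' @param seed Optional integer seed, used only when `spacing =
#'   "uniform_random"`.
#'
#' @return A tibble of class `genetic_map` with columns `marker` (id),
#'   `chrom` (integer) and `pos_cM` (numeric, strictly increasing within
#'   chromosome).
#' @examples
#' map <- generate_genetic_map(90, 9, 625)
#' mean_marker_spacing(generate_genetic_map(16076, 9, 625))
#' @export
generate_genetic_map <- function(n_markers, n_chromosomes, total_length,
                                 spacing = c("even", "uniform_random"),
                                 seed = NULL) {
  spacing <- match.arg(spacing)
  stopifnot(is.numeric(n_markers), is.numeric(n_chromosomes),
            is.numeric(total_length), length(n_markers) == 1)
  if (n_markers < n_chromosomes) {
    stop("`n_markers` must be at least `n_chromosomes` (one marker per chromosome).",
         call. = FALSE)
  }
  if (total_length <= 0) stop("`total_length` must be positive.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n_markers <- as.integer(n_markers)
  n_chromosomes <- as.integer(n_chromosomes)
  chrom_len <- total_length / n_chromosomes
  base <- n_markers %/% n_chromosomes
  m_per_chrom <- rep(base, n_chromosomes) +
    rep(c(1L, 0L), c(n_markers %% n_chromosomes,
                     n_chromosomes - n_markers %% n_chromosomes))

  pos <- lapply(seq_len(n_chromosomes), function(c) {
    m <- m_per_chrom[c]
    if (m == 1L) return(0)
    if (spacing == "even") {
      seq(0, chrom_len, length.out = m)
    } else {
      sort(c(0, stats::runif(m - 2L, 0, chrom_len), chrom_len))
    }
  })

  map <- tibble::tibble(
    marker = sprintf("m%0*d", nchar(n_markers), seq_len(n_markers)),
    chrom = rep(seq_len(n_chromosomes), m_per_chrom),
    pos_cM = unlist(pos)
  )
  new_genetic_map(map)
}

#' Construct a genetic map from a marker table
#'
#' @param x A data frame with columns `marker`, `chrom`, `pos_cM`.
#' @return The same table as a validated `genetic_map` tibble with an internal
#'   lookup cache used by the meiosis simulator.
#' @export
new_genetic_map <- function(x) {
  x <- tibble::as_tibble(x)[, c("marker", "chrom", "pos_cM")]
  x$chrom <- as.integer(x$chrom)
  ord <- order(x$chrom, x$pos_cM)
  x <- x[ord, ]
  split_pos <- split(x$pos_cM, x$chrom)
  if (any(vapply(split_pos, anyDuplicated, 1L) > 0)) {
    stop("Marker positions must be strictly increasing within a chromosome.",
         call. = FALSE)
  }
  ends <- cumsum(lengths(split_pos))
  cache <- list(
    n_markers = nrow(x),
    n_chrom = length(split_pos),
    pos = split_pos,
    # chromosome genetic length: span of its markers (terminal markers anchor
    # the chromosome ends for generated maps)
    len = vapply(split_pos, function(p) max(p) - min(p), 1.0),
    first = c(1L, utils::head(ends, -1L) + 1L),
    last = ends
  )
  attr(x, "map_cache") <- cache
  class(x) <- c("genetic_map", class(x))
  x
}

map_cache <- function(map) {
  cache <- attr(map, "map_cache")
  if (is.null(cache)) cache <- attr(new_genetic_map(map), "map_cache")
  cache
}

#' Number of markers on a genetic map
#' @param map A `genetic_map`.
#' @return Integer marker count.
#' @export
n_markers <- function(map) map_cache(map)$n_markers

#' Mean adjacent marker spacing of a map
#'
#' Average genetic distance between adjacent markers on the same chromosome,
#' in centimorgan.  Chromosomes carrying a single marker contribute no pairs;
#' if the map has no adjacent pairs at all the spacing is reported as 0 over
#' 0 pairs (`NaN` avoided by returning 0).
#'
#' @param map A `genetic_map`.
#' @return Mean spacing in cM (0 when the map has no adjacent marker pairs).
#' @export
mean_marker_spacing <- function(map) {
  cache <- map_cache(map)
  gaps <- unlist(lapply(cache$pos, diff))
  if (length(gaps) == 0) return(0)
  mean(gaps)
}

#' Read / write a genetic map as TSV
#'
#' Plain tab-separated interchange format with columns `marker`, `chrom`,
#' `pos_cM`, so externally supplied maps can replace generated ones.
#'
#' @param map A `genetic_map`.
#' @param path File path.
#' @return `write_genetic_map()` returns `map` invisibly; `read_genetic_map()`
#'   returns a `genetic_map`.
#' @export
write_genetic_map <- function(map, path) {
  readr::write_tsv(tibble::as_tibble(map)[, c("marker", "chrom", "pos_cM")], path)
  invisible(map)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         marker = readr::col_character(),
                         chrom = readr::col_integer(),
                         pos_cM = readr::col_double()
                       ))
  new_genetic_map(x)
}
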