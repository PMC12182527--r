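#' Configure a crossing-design power experiment
#'
#' Describes the full factorial experiment: populations x designs x
#' heritabilities x QTL numbers x replicates.  The study-scale defaults
#' mirror the reference setting (N = 300 selected wilds, 594 testcross
#' progeny per entry, heritabilities 0.5-0.9, 1/2/5 QTL, largest QTL effect
#' 5% of the elite total, 1000 runs); desk-scale runs override `n_reps`,
#' `n_offspring` and the population dimensions.
#'
#' @param populations List of `founder_population` objects, or of
#'   [population_spec()]s to be generated at run time.
#' @param designs Subset of `"M1"`..`"M9"`.
#' @param h2 Heritability grid in `(0, 1]`.
#' @param n_qtl Grid of simulated QTL counts.
#' @param n_reps Independent simulation runs per cell.
#' @param n_select Wild individuals selected per population (haploblock
#'   diversity selection); use the full population when it is not larger.
#' @param n_offspring Testcross progeny per entry.
#' @param emax_percent Largest QTL effect, percent of the haploid elite
#'   total.
#' @param elite_total Haploid elite total `E` in trait units.
#' @param threshold_neglog10 Significance threshold on `-log10(adjusted p)`.
#' @param threshold_on `"p_adj"` (default) or `"p"`.
#' @param detection_window_cM Detection half-window around a QTL.
#' @param region_min_markers,region_window_cM,region_gap_cM Region-calling
#'   rule: a cluster of significant markers is a QTL region iff some
#'   `region_window_cM` window holds at least `region_min_markers` of them;
#'   clusters split at gaps of `region_gap_cM` or more.  The defaults
#'   (5 markers / 5 cM / 5 cM) presume the study-scale marker density of
#'   about 26 markers per cM; desk-scale maps should scale
#'   `region_min_markers` down in proportion to their density.
#' @param seed Master seed; every run derives its own sub-seed from it and
#'   its coordinates, so results do not depend on execution order.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(populations,
                              designs = design_ids(),
                              h2 = c(0.5, 0.6, 0.7, 0.8, 0.9),
                              n_qtl = c(1, 2, 5),
                              n_reps = 50,
                              n_select = 300,
                              n_offspring = 594,
                              emax_percent = 5,
                              elite_total = 100,
                              threshold_neglog10 = 3,
                              threshold_on = c("p_adj", "p"),
                              detection_window_cM = 2.5,
                              region_min_markers = 5,
                              region_window_cM = 5,
                              region_gap_cM = 5,
                              seed = 1L) {
  if (inherits(populations, "founder_population") ||
      inherits(populations, "population_spec")) {
    populations <- list(populations)
  }
  stopifnot(length(populations) >= 1, length(designs) >= 1,
            length(h2) >= 1, length(n_qtl) >= 1, n_reps >= 1,
            all(designs %in% design_ids()), all(h2 > 0), all(h2 <= 1))
  structure(list(
    populations = populations, designs = designs, h2 = h2,
    n_qtl = as.integer(n_qtl), n_reps = as.integer(n_reps),
    n_select = as.integer(n_select), n_offspring = as.integer(n_offspring),
    emax_percent = emax_percent, elite_total = elite_total,
    threshold_neglog10 = threshold_neglog10,
    threshold_on = match.arg(threshold_on),
    detection_window_cM = detection_window_cM,
    region_min_markers = as.integer(region_min_markers),
    region_window_cM = region_window_cM,
    region_gap_cM = region_gap_cM,
    seed = as.integer(seed)
  ), class = "experiment_config")
}

# Deterministic sub-seed from the master seed and run coordinates
# (Lehmer-style mixing, exact in doubles, result < 2^31 - 1).
subseed <- function(master, ...) {
  s <- master %% 2147483647
  for (x in c(...)) s <- (s * 48271 + x + 1) %% 2147483647
  as.integer(s)
}

#' Run the full crossing-design experiment
#'
#' For each population: generate or take the founders, select the diverse
#' subset, then for every (replicate, QTL number, design) draw a fresh QTL
#' configuration, rebuild the mapping population, and for every heritability
#' simulate phenotypes (common random numbers across the h2 grid within a
#' run), fit the polygenic model, scan all markers except the QTL markers,
#' adjust p-values, call regions and score TPR/FD against the simulated
#' truth.  Runs whose polygenic stage degenerates are recorded as failed
#' with TPR 0 and FD 1 (the no-detection convention), never dropped.
#'
#' @param config An [experiment_config()].
#' @param progress Print one line per population/replicate block.
#' @return A tibble of class `experiment_result`, one row per (population,
#'   design, h2, n_qtl, rep): `tpr`, `fd`, `n_regions`, `n_false`,
#'   `failed`, plus list-columns `qtl_detected`, `qtl_freq`, `qtl_effect`
#'   (per-QTL detail, frequencies measured in the selected subset).
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  for (p_i in seq_along(config$populations)) {
    pop <- config$populations[[p_i]]
    if (inherits(pop, "population_spec")) {
      pop <- generate_wild_population(pop, id = paste0("pop", p_i))
    }
    map <- pop$map
    set.seed(subseed(config$seed, p_i, 0L))
    elite <- generate_elite_line(map)
    tester <- generate_tester(map, elite)
    if (config$n_select < length(pop$genomes)) {
      sel <- select_diverse_subset(pop, n_total = config$n_select)
    } else {
      sel <- seq_along(pop$genomes)
    }
    wilds <- pop$genomes[sel]

    for (rep_i in seq_len(config$n_reps)) {
      if (progress) {
        message(sprintf("population %d (%s), rep %d/%d",
                        p_i, pop$id, rep_i, config$n_reps))
      }
      for (q_i in seq_along(config$n_qtl)) {
        # one QTL draw per run, shared by all designs: the designs are
        # compared on a common trait realization (common random numbers)
        set.seed(subseed(config$seed, p_i, rep_i, q_i))
        qtl <- tryCatch(
          assign_qtl_effects(wilds, map, config$n_qtl[q_i],
                             emax_percent = config$emax_percent,
                             elite_total = config$elite_total),
          error = function(e) e)
        for (d_i in seq_along(config$designs)) {
          design <- config$designs[d_i]
          set.seed(subseed(config$seed, p_i, rep_i, q_i, d_i))
          rows[[length(rows) + 1L]] <- run_one(
            config, pop$id, design, wilds, elite, tester, map, qtl = qtl,
            n_qtl = config$n_qtl[q_i], rep_i = rep_i)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("experiment_result", class(out)))
}

# One (population, design, n_qtl, rep) cell across the whole h2 grid.
run_one <- function(config, pop_id, design, wilds, elite, tester, map,
                    qtl, n_qtl, rep_i) {
  no_qtl <- list(rep(FALSE, n_qtl))
  na_qtl <- list(rep(NA_real_, n_qtl))
  base <- tibble::tibble(
    population = pop_id, design = design, n_qtl = .env$n_qtl, rep = rep_i,
    h2 = config$h2, tpr = 0, fd = 1, n_regions = 0L, n_false = 0L,
    failed = FALSE,
    qtl_detected = no_qtl,
    qtl_freq = na_qtl,
    qtl_effect = na_qtl
  )
  res <- tryCatch({
    if (inherits(qtl, "error")) stop(qtl)
    eff <- effect_table(qtl, map, elite_total = config$elite_total)
    mp <- build_mapping_population(design, wilds, elite, tester,
                                   n_offspring = config$n_offspring,
                                   map = map, effects = eff)
    kin <- kinship_matrix(mp$scan_genotypes)
    noise <- stats::rnorm(nrow(mp$entries))
    base$qtl_freq <- list(qtl$allele_freq)
    base$qtl_effect <- list(qtl$effect)
    for (i in seq_along(config$h2)) {
      ph <- simulate_phenotypes(mp$entries$genotypic_value, config$h2[i],
                                noise = noise)
      fit <- fit_polygenic(ph$phenotype, kin)
      scan <- scan_markers(mp, fit, exclude = qtl$marker_index)
      scan <- call_significant(adjust_fdr(scan),
                               threshold_neglog10 = config$threshold_neglog10,
                               on = config$threshold_on)
      regions <- call_qtl_regions(scan,
                                  min_markers = config$region_min_markers,
                                  window_cM = config$region_window_cM,
                                  gap_cM = config$region_gap_cM)
      ev <- evaluate_detection(regions, qtl,
                               window_cM = config$detection_window_cM)
      base$tpr[i] <- ev$tpr
      base$fd[i] <- ev$fd
      base$n_regions[i] <- ev$n_regions
      base$n_false[i] <- ev$n_false
      base$qtl_detected[[i]] <- ev$detected
    }
    base
  }, error = function(e) {
    base$failed <- TRUE
    attr(base, "error") <- conditionMessage(e)
    base
  })
  res
}

#' Aggregate an experiment result table
#'
#' Mean TPR and FD per group, plus run counts.  With `per_qtl = TRUE` the
#' per-QTL detail is unnested first and, if `freq_bin_width` is given, QTL
#' are binned by the frequency of their effect allele among the selected
#' wild individuals (bin edges at multiples of the width; `1 / (2 *
#' n_selected)` reproduces the single-allele-copy resolution).
#'
#' @param result An `experiment_result` tibble.
#' @param by Character vector of grouping columns.
#' @param per_qtl Aggregate per QTL (detection rate of individual QTL)
#'   instead of per run.
#' @param freq_bin_width Optional allele-frequency bin width used when
#'   `per_qtl = TRUE`.
#' @return A summary tibble.
#' @export
aggregate_results <- function(result, by = c("design", "h2", "n_qtl"),
                              per_qtl = FALSE, freq_bin_width = NULL) {
  stopifnot(nrow(result) >= 1)
  if (!per_qtl) {
    return(result |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(tpr = mean(.data$tpr), fd = mean(.data$fd),
                       n_runs = dplyr::n(), .groups = "drop"))
  }
  long <- result |>
    dplyr::select(dplyr::all_of(unique(c(by, "qtl_detected", "qtl_freq",
                                         "qtl_effect")))) |>
    tidyr::unnest(c("qtl_detected", "qtl_freq", "qtl_effect"))
  if (!is.null(freq_bin_width)) {
    long$freq_class <- round(
      ceiling(round(long$qtl_freq / freq_bin_width, 9)) * freq_bin_width, 9)
    by <- c(by, "freq_class")
  }
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(tpr = mean(.data$qtl_detected), n_qtl_obs = dplyr::n(),
                     .groups = "drop")
}

#' Summary plot of detection power and false detection rate
#'
#' @param result An `experiment_result` or [aggregate_results()] output with
#'   `design`, `h2`, `tpr`, `fd` columns.
#' @return A ggplot object: TPR and FD by design, coloured by heritability,
#'   faceted by number of QTL when present.
#' @export
plot_power_summary <- function(result) {
  if (!"n_runs" %in% names(result)) {
    by <- intersect(c("design", "h2", "n_qtl"), names(result))
    result <- aggregate_results(result, by = by)
  }
  long <- tidyr::pivot_longer(result, c("tpr", "fd"),
                              names_to = "measure", values_to = "rate")
  long$measure <- toupper(long$measure)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$design, 100 * .data$rate,
                                          fill = factor(.data$h2))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "crossing design", y = "rate (%)",
                  fill = expression(h^2)) +
    ggplot2::theme_minimal()
  if ("n_qtl" %in% names(long)) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$measure),
                                 cols = ggplot2::vars(.data$n_qtl),
                                 labeller = ggplot2::label_both)
  } else {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$measure))
  }
  p
}
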