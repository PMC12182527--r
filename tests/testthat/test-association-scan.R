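# iid dosage matrix under Hardy-Weinberg equilibrium
hwe_genotypes <- function(n, m, p = NULL) {
  if (is.null(p)) p <- runif(m, 0.1, 0.5)
  matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
}

test_that("kinship is symmetric and treats identical genomes as self", {
  set.seed(41)
  G <- hwe_genotypes(30, 400)
  G[2, ] <- G[1, ]
  K <- kinship_matrix(G)
  expect_identical(K, t(K))
  expect_equal(K[1, 2], K[1, 1])
  expect_error(kinship_matrix(matrix(2, 5, 10)), "monomorphic")
})

test_that("unrelated HWE individuals have near-zero mean kinship", {
  set.seed(42)
  n <- 80
  K <- kinship_matrix(hwe_genotypes(n, 2000))
  off <- K[upper.tri(K)]
  # sample-frequency centering forces sum(g - 2p-hat) = 0 per marker, so the
  # off-diagonal mean sits at -mean(diag)/(n-1) rather than exactly 0
  centering_bias <- -mean(diag(K)) / (n - 1)
  expect_lt(abs(mean(off) - centering_bias), 3 * sd(off) / sqrt(length(off)))
  expect_lt(abs(mean(diag(K)) - 0.5), 0.05)
})

test_that("ibs kinship is a valid alternative estimator", {
  set.seed(43)
  G <- hwe_genotypes(20, 300)
  K <- kinship_matrix(G, method = "ibs")
  expect_identical(K, t(K))
  expect_equal(unique(diag(K)), 0.5)
})

test_that("with zero polygenic variance the score test is least squares", {
  set.seed(44)
  n <- 20; m <- 50
  G <- hwe_genotypes(n, m)
  y <- rnorm(n)
  fit <- fit_polygenic(y, diag(0.5, n), h_ratio = 0)
  s2_ml <- sum((y - mean(y))^2) / n
  for (j in seq_len(m)) {
    got <- score_test(G[, j], fit)
    gc <- G[, j] - mean(G[, j])
    oracle <- sum(gc * (y - mean(y)))^2 / (s2_ml * sum(gc^2))
    expect_equal(got$statistic, oracle, tolerance = 1e-6)
  }
})

test_that("variance components are recovered by maximum likelihood", {
  set.seed(45)
  n <- 150
  G <- hwe_genotypes(n, 800)
  K <- kinship_matrix(G)
  phi <- 2 * K
  eig <- eigen(phi, symmetric = TRUE)
  h_true <- 0.6; s2 <- 4
  hs <- replicate(50, {
    y <- eig$vectors %*% (sqrt(pmax(h_true * eig$values + (1 - h_true), 0) * s2) * rnorm(n))
    fit_polygenic(as.numeric(y), K)$h_ratio
  })
  # allow the O(1/n) downward ML boundary bias on top of Monte Carlo error
  expect_lt(abs(mean(hs) - h_true), 3 * sd(hs) / sqrt(50) + 2 / 150)
})

test_that("a null polygenic model estimates a near-zero heritability ratio", {
  set.seed(46)
  n <- 300
  K <- kinship_matrix(hwe_genotypes(n, 600))
  y <- rnorm(n)
  fit <- fit_polygenic(y, K)
  expect_lte(fit$h_ratio, 0.3)
  expect_equal(fit$sigma_g2 + fit$sigma_e2, var(y) * (n - 1) / n,
               tolerance = 0.05)
})

test_that("degenerate phenotypes are rejected", {
  K <- diag(0.5, 10)
  expect_error(fit_polygenic(rep(1, 10), K), "zero variance")
  expect_error(fit_polygenic(c(rnorm(9), NA), K), "finite")
})

test_that("the score statistic is invariant to affine dosage rescaling", {
  set.seed(47)
  n <- 40
  G <- hwe_genotypes(n, 10)
  K <- kinship_matrix(hwe_genotypes(n, 500))
  y <- rnorm(n)
  fit <- fit_polygenic(y, K)
  for (j in 1:10) {
    a <- score_test(G[, j], fit)$statistic
    b <- score_test(3 + 2 * G[, j], fit)$statistic
    expect_equal(a, b, tolerance = 1e-10)
  }
  expect_true(is.na(score_test(rep(2, n), fit)$statistic))
})

test_that("null score-test p-values are approximately uniform", {
  set.seed(48)
  n <- 120; m <- 2000
  G <- hwe_genotypes(n, m)
  K <- kinship_matrix(G)
  y <- rnorm(n)
  fit <- fit_polygenic(y, K)
  map <- generate_genetic_map(m, 9, 625)
  scan <- scan_markers(G, fit, map = map)
  p <- scan$p[scan$status == "tested"]
  expect_lt(abs(mean(scan$statistic[scan$status == "tested"]) - 1), 0.15)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("scan masks excluded and monomorphic markers", {
  set.seed(49)
  n <- 30; m <- 60
  G <- hwe_genotypes(n, m)
  G[, 5] <- 1   # constant
  K <- kinship_matrix(G)
  y <- rnorm(n)
  fit <- fit_polygenic(y, K)
  map <- generate_genetic_map(m, 2, 50)
  scan <- scan_markers(G, fit, exclude = c(10L, 11L), map = map)
  expect_equal(scan$status[5], "monomorphic")
  expect_equal(scan$status[10:11], c("excluded", "excluded"))
  expect_true(all(is.na(scan$p[c(5, 10, 11)])))
  expect_true(all(!is.na(scan$p[scan$status == "tested"])))
  # scan and single-marker score_test agree
  j <- which(scan$status == "tested")[1]
  expect_equal(scan$statistic[j], score_test(G[, j], fit)$statistic)

  all_gone <- scan_markers(G, fit, exclude = seq_len(m), map = map)
  expect_true(all(all_gone$status == "excluded"))
})

test_that("tidy and glance summarise a polygenic fit", {
  set.seed(50)
  n <- 30
  K <- kinship_matrix(hwe_genotypes(n, 300))
  y <- rnorm(n)
  fit <- fit_polygenic(y, K)
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "sigma_g2", "sigma_e2"))
  gl <- glance(fit)
  expect_equal(gl$n, n)
  expect_gte(gl$sigma_g2, 0)
  # residuals of the polygenic model have mean ~ 0
  expect_lt(abs(mean(fit$residuals)), 0.1)
})

test_that("a strong common QTL is localized by the scan", {
  # marker spacing close to the study panel, so the withheld causal site has
  # tight proxies; the genome-wide minimum p should then fall within the
  # 2.5 cM detection window in the vast majority of runs
  map <- generate_genetic_map(1500, 3, 150)
  spec <- population_spec(n_individuals = 120, n_markers = 1500,
                          n_chromosomes = 3, total_map_length = 150,
                          burn_in_generations = 8, seed = 101)
  pop <- generate_wild_population(spec, map)
  elite <- generate_elite_line(map, seed = 77)
  tester <- generate_tester(map, elite, seed = 78)
  wilds <- pop$genomes[1:100]
  dose <- Reduce(`+`, lapply(wilds, dosage))
  common <- which(dose >= 0.3 * 200 & dose <= 0.7 * 200)
  set.seed(51)
  hits <- replicate(20, {
    idx <- sample(common, 1)
    qtl <- tibble::tibble(qtl = 1L, marker_index = idx,
                          marker = map$marker[idx],
                          chrom = map$chrom[idx],
                          pos_cM = map$pos_cM[idx],
                          allele = 1L, effect = 5,
                          allele_freq = dose[idx] / 200)
    eff <- effect_table(qtl, map)
    mp <- build_mapping_population("M1", wilds, elite, tester,
                                   n_offspring = 40, map = map,
                                   effects = eff)
    ph <- simulate_phenotypes(mp$entries$genotypic_value, 0.9)
    fit <- fit_polygenic(ph$phenotype, kinship_matrix(mp$scan_genotypes))
    scan <- scan_markers(mp, fit, exclude = idx)
    best <- scan$marker_index[which.min(scan$p)]
    scan$chrom[best] == qtl$chrom &&
      abs(scan$pos_cM[best] - qtl$pos_cM) <= 2.5
  })
  expect_gte(mean(hits), 0.8)
})
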