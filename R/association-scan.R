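#' Marker-based kinship matrix
#'
#' Frequency-weighted allele-sharing estimator on 0/1/2 dosages:
#' `K_ij = mean over markers of (g_i - 2p)(g_j - 2p) / (2p(1-p))`, divided by
#' 2 so that the self-kinship of an outbred individual in Hardy-Weinberg
#' equilibrium is about 0.5.  Monomorphic markers carry no information and
#' are skipped.  A plain identity-by-state option is provided as an
#' alternative (`method = "ibs"`: mean shared-allele fraction per marker).
#'
#' @param genotypes Entries x markers numeric matrix of 0/1/2 dosages.
#' @param method `"freq"` (default) or `"ibs"`.
#' @return A symmetric `n x n` kinship matrix.
#' @export
kinship_matrix <- function(genotypes, method = c("freq", "ibs")) {
  method <- match.arg(method)
  stopifnot(is.matrix(genotypes), nrow(genotypes) >= 2)
  p <- colMeans(genotypes) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) {
    stop("All markers are monomorphic across entries; kinship is undefined.",
         call. = FALSE)
  }
  g <- genotypes[, poly, drop = FALSE]
  p <- p[poly]
  if (method == "freq") {
    z <- sweep(g, 2, 2 * p)
    z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
    k <- tcrossprod(z) / (2 * ncol(z))
  } else {
    # IBS: per marker 1 - |g_i - g_j| / 2, averaged over markers
    k <- matrix(0, nrow(g), nrow(g))
    for (j in seq_len(ncol(g))) {
      k <- k + 1 - abs(outer(g[, j], g[, j], "-")) / 2
    }
    k <- k / (2 * ncol(g))
  }
  (k + t(k)) / 2
}

#' Fit the polygenic mixed model by maximum likelihood
#'
#' Fits `y = mu + X beta + G + e` with `Var(G) = sigma_G^2 * Phi` and
#' `Var(e) = sigma_e^2 * I`, where `Phi = 2 * kinship` (correlation scale).
#' The likelihood is profiled on the heritability ratio `h = sigma_G^2 /
#' (sigma_G^2 + sigma_e^2)` via the eigendecomposition of `Phi` and a
#' bounded 1-D search on `[0, 1]` (tolerance 1e-8); at the optimum the ML
#' variance estimates, the residuals adjusted for the polygenic (family)
#' effect, and the inverse phenotypic covariance matrix are returned for the
#' downstream score test.
#'
#' @param phenotypes Numeric vector of entry phenotypes.
#' @param kinship Kinship matrix from [kinship_matrix()] (diagonal about
#'   0.5).
#' @param covariates Optional numeric matrix of fixed-effect covariates
#'   (columns); the intercept is always included.
#' @param h_ratio Optionally fix the heritability ratio instead of
#'   estimating it (e.g. 0 for the no-polygene limit).
#' @return A `polygenic_fit`: list with `mu`, `beta`, `sigma_g2`, `sigma_e2`,
#'   `h_ratio`, `residuals` (`y* = e-hat`), `loglik`, and the
#'   eigendecomposition pieces used to apply `V^{-1}` cheaply.
#' @export
fit_polygenic <- function(phenotypes, kinship, covariates = NULL,
                          h_ratio = NULL) {
  y <- as.numeric(phenotypes)
  n <- length(y)
  if (anyNA(y) || any(!is.finite(y))) {
    stop("Phenotypes must be finite and non-missing.", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    stop("Degenerate phenotypes: zero variance.", call. = FALSE)
  }
  stopifnot(nrow(kinship) == n)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)

  phi <- 2 * kinship
  eig <- eigen(phi, symmetric = TRUE)
  if (min(eig$values) < 0) {
    # numerically non-PSD kinship: small diagonal jitter
    jitter <- 1e-6 * mean(diag(phi)) - min(eig$values)
    eig$values <- eig$values + jitter
  }
  lambda <- eig$values
  U <- eig$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)

  neg2ll <- function(h) {
    d <- h * lambda + (1 - h)
    w <- 1 / d
    XtWX <- crossprod(Xt, Xt * w)
    XtWy <- crossprod(Xt, yt * w)
    beta <- solve(XtWX, XtWy)
    r <- yt - Xt %*% beta
    s2 <- sum(r^2 * w) / n
    n * log(2 * pi * s2) + sum(log(d)) + n
  }

  if (is.null(h_ratio)) {
    opt <- stats::optimize(neg2ll, c(0, 1), tol = 1e-8)
    h <- opt$minimum
    # flat-likelihood guard near the boundaries
    if (neg2ll(0) <= opt$objective) h <- 0
  } else {
    stopifnot(h_ratio >= 0, h_ratio <= 1)
    h <- h_ratio
  }

  d <- h * lambda + (1 - h)
  w <- 1 / d
  beta <- solve(crossprod(Xt, Xt * w), crossprod(Xt, yt * w))
  fixed <- as.numeric(X %*% beta)
  s2 <- sum((yt - Xt %*% beta)^2 * w) / n  # ML total variance sigma_p^2
  sigma_g2 <- h * s2
  sigma_e2 <- (1 - h) * s2
  dv <- s2 * d                             # eigenvalues of V
  # polygenic BLUP and family-adjusted residuals:
  # e-hat = sigma_e2 * V^{-1} (y - X beta)
  resid_mar <- y - fixed
  ghat <- sigma_g2 * (U %*% (lambda * (crossprod(U, resid_mar) / dv)))
  residuals <- as.numeric(resid_mar - ghat)

  structure(list(
    mu = beta[1], beta = drop(beta), sigma_g2 = sigma_g2,
    sigma_e2 = sigma_e2, h_ratio = h, residuals = residuals,
    residuals_marginal = resid_mar,
    loglik = -0.5 * neg2ll(h), n = n,
    U = U, v_eigen = dv, fixed = fixed
  ), class = "polygenic_fit")
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat(sprintf(
    "<polygenic_fit: n = %d, sigma_g2 = %.4g, sigma_e2 = %.4g, h ratio = %.3f, logLik = %.2f>\n",
    x$n, x$sigma_g2, x$sigma_e2, x$h_ratio, x$loglik))
  invisible(x)
}

#' Tidiers for polygenic fits
#'
#' `tidy()` returns the fixed-effect and variance-component estimates one row
#' each; `glance()` returns a one-row model summary.
#'
#' @param x A `polygenic_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.polygenic_fit <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$beta), "sigma_g2", "sigma_e2"),
    estimate = c(unname(x$beta), x$sigma_g2, x$sigma_e2),
    type = c(rep("fixed", length(x$beta)), "variance", "variance")
  )
}

#' @rdname tidy.polygenic_fit
#' @export
glance.polygenic_fit <- function(x, ...) {
  tibble::tibble(n = x$n, sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
                 h_ratio = x$h_ratio, logLik = x$loglik)
}

# Apply V^{-1} to a vector using the stored eigendecomposition.
vinv_apply <- function(fit, v) {
  fit$U %*% (crossprod(fit$U, v) / fit$v_eigen)
}

#' Single-marker score test on polygenic residuals
#'
#' Computes `((g - E[g])' V^{-1} residualY)^2 / ((g - E[g])' V^{-1} (g -
#' E[g]))` with `E[g]` the mean dosage, `residualY` the covariate-adjusted
#' phenotypes (`y - X beta-hat`; the polygenic family structure is accounted
#' for through `V^{-1}`, following the mixed-model score test of Chen &
#' Abecasis) and `V^{-1}` the inverse phenotypic covariance from the
#' polygenic fit.  The statistic is referred to the chi-squared distribution
#' with 1 df.  In the `sigma_g2 = 0` limit (`V` proportional to `I`) it
#' reduces exactly to the ordinary least-squares marginal score statistic.
#' A constant dosage vector has a zero denominator and is flagged untestable
#' (`NA`).
#'
#' @param g Dosage vector (length = entries).
#' @param fit A [fit_polygenic()] result.
#' @return A list with `statistic` and `p` (both `NA` for a constant
#'   marker).
#' @export
score_test <- function(g, fit) {
  stopifnot(length(g) == fit$n)
  if (stats::var(g) == 0) return(list(statistic = NA_real_, p = NA_real_))
  gc <- g - mean(g)
  vg <- vinv_apply(fit, gc)
  stat <- drop(crossprod(vg, fit$residuals_marginal))^2 / drop(crossprod(gc, vg))
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Genome scan of a mapping population
#'
#' Applies the score test to every non-excluded, non-constant marker of a
#' mapping population's scan genotypes (pre-testcross dosages).  Markers
#' carrying simulated QTL effects are excluded by the caller -- the array is
#' assumed not to genotype the causal site, so detection must come from
#' linked markers.
#'
#' @param population A `mapping_population` (or an entries x markers dosage
#'   matrix).
#' @param fit A [fit_polygenic()] result on the same entries.
#' @param exclude Integer marker indices to mask (e.g. QTL markers).
#' @param map A `genetic_map`; taken from the population when available.
#' @return A tibble of class `scan_result`: `marker_index`, `marker`,
#'   `chrom`, `pos_cM`, `statistic`, `p`, `status` (`"tested"`,
#'   `"excluded"`, `"monomorphic"`).
#' @export
scan_markers <- function(population, fit, exclude = integer(), map = NULL) {
  if (inherits(population, "mapping_population")) {
    G <- population$scan_genotypes
    if (is.null(map)) map <- population$map
  } else {
    G <- population
  }
  stopifnot(is.matrix(G), nrow(G) == fit$n, !is.null(map))
  m <- ncol(G)
  stopifnot(m == n_markers(map), all(exclude >= 1), all(exclude <= m))

  status <- rep("tested", m)
  status[apply(G, 2, function(col) stats::var(col) == 0)] <- "monomorphic"
  status[exclude] <- "excluded"
  test_idx <- which(status == "tested")

  stat <- rep(NA_real_, m)
  p <- rep(NA_real_, m)
  if (length(test_idx) > 0) {
    Gc <- sweep(G[, test_idx, drop = FALSE], 2, colMeans(G[, test_idx, drop = FALSE]))
    a <- vinv_apply(fit, fit$residuals_marginal)
    num <- drop(crossprod(Gc, a))^2
    W <- crossprod(fit$U, Gc)
    den <- colSums(W^2 / fit$v_eigen)
    stat[test_idx] <- num / den
    p[test_idx] <- stats::pchisq(stat[test_idx], df = 1, lower.tail = FALSE)
  }
  mtab <- tibble::as_tibble(map)
  out <- tibble::tibble(
    marker_index = seq_len(m),
    marker = mtab$marker,
    chrom = mtab$chrom,
    pos_cM = mtab$pos_cM,
    statistic = stat,
    p = p,
    status = status
  )
  class(out) <- c("scan_result", class(out))
  out
}

#' Manhattan-style plot of a scan result
#'
#' @param object A `scan_result` (optionally with a `p_adj` column from
#'   [adjust_fdr()]).
#' @param threshold Horizontal reference line on the `-log10(p)` scale.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_result <- function(object, threshold = 3, ...) {
  df <- dplyr::filter(object, .data$status == "tested")
  df$neglog10p <- -log10(if ("p_adj" %in% names(df)) df$p_adj else df$p)
  ggplot2::ggplot(df, ggplot2::aes(.data$pos_cM, .data$neglog10p)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "red") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
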