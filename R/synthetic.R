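#' Specify covariance structure by heritabilities, SDs and correlations
#'
#' A compact parameterization of the genetic and residual covariance
#' matrices: per-trait broad-sense heritability `h2` and phenotypic standard
#' deviation `sd_p`, plus genetic (`r_g`) and environmental (`r_e`)
#' correlation matrices.
#'
#' @param h2 Numeric vector of heritabilities in (0, 1].
#' @param sd_p Numeric vector of phenotypic standard deviations (trait
#'   units), same length as `h2`.
#' @param r_g,r_e Correlation matrices (symmetric, unit diagonal, entries in
#'   \[-1, 1\]).
#' @param traits Optional trait names.
#' @return An object of class `covariance_spec`.
#' @export
covariance_spec <- function(h2, sd_p, r_g, r_e, traits = NULL) {
  n <- length(h2)
  stopifnot(length(sd_p) == n, all(h2 > 0), all(h2 <= 1), all(sd_p > 0))
  r_g <- check_correlation(as.matrix(r_g), n, "r_g")
  r_e <- check_correlation(as.matrix(r_e), n, "r_e")
  if (is.null(traits)) traits <- paste0("trait", seq_len(n))
  structure(list(h2 = as.numeric(h2), sd_p = as.numeric(sd_p),
                 r_g = r_g, r_e = r_e, traits = as.character(traits)),
            class = "covariance_spec")
}

check_correlation <- function(R, n, label) {
  if (!all(dim(R) == c(n, n))) stop(label, " must be ", n, " x ", n)
  if (max(abs(R - t(R))) > 1e-8) stop(label, " must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop(label, " must have unit diagonal")
  if (any(abs(R) > 1 + 1e-12)) stop(label, " entries must lie in [-1, 1]")
  (R + t(R)) / 2
}

#' Build genetic parameters from a covariance specification
#'
#' Constructs `G = D_g r_g D_g` with `D_g = diag(sd_p * sqrt(h2))`, the
#' residual covariance analogously with `sqrt(1 - h2)`, and `P = G + E`.
#' Heritabilities are recovered exactly by construction.
#'
#' @param spec A [covariance_spec()].
#' @param panel Optional [trait_panel()] supplying trait order and names; by
#'   default a minimal panel is built from the spec (unit "unit", mean 0 -
#'   sufficient for simulation, not for percent gains).
#' @param repair Passed to [genetic_parameters()]: clip slightly negative
#'   eigenvalues arising from indefinite correlation inputs.
#' @return A [genetic_parameters()] object.
#' @export
build_covariances <- function(spec, panel = NULL, repair = FALSE) {
  dg <- spec$sd_p * sqrt(spec$h2)
  de <- spec$sd_p * sqrt(1 - spec$h2)
  G <- diag(dg, length(dg)) %*% spec$r_g %*% diag(dg, length(dg))
  E <- diag(de, length(de)) %*% spec$r_e %*% diag(de, length(de))
  if (is.null(panel)) {
    panel <- trait_panel(spec$traits, rep("unit", length(spec$traits)),
                         rep(0, length(spec$traits)),
                         reference = spec$traits[1L])
  }
  dimnames(G) <- dimnames(E) <- list(panel$name, panel$name)
  genetic_parameters(panel, G, G + E, repair = repair)
}

#' The default 16-trait Miscanthus sinensis emulation panel
#'
#' Ships the 16 phenology, morphometric and cell-wall traits of a
#' 138-genotype M. sinensis breeding population with their published current
#' means and broad-sense heritabilities (0.48-0.89). The genetic correlation
#' structure is an emulation, not a reproduction of the marker-estimated
#' matrices: the published values are used where stated - a weak
#' flowering-yield correlation (0.19) and strong flowering-senescence /
#' flowering-moisture correlations (|r| = 0.85, signed so that delayed
#' flowering lowers senescence and raises harvest moisture) - and all other
#' correlations are modest (|r| <= 0.3) plausible defaults: positive
#' correlations among size traits and with yield, mild negative
#' lignin-cellulose and lignin-yield correlations. Environmental
#' correlations are a damped version of the genetic ones. Phenotypic SDs are
#' set to plausible coefficients of variation for each trait type. The
#' resulting correlation matrices are repaired to the nearest PSD matrix if
#' needed.
#'
#' @return A list with `panel` (a [trait_panel()]) and `spec`
#'   (a [covariance_spec()]).
#' @export
default_panel <- function() {
  traits <- c("DOYFS1", "AvgeSen", "BaseDiameter", "DryMatter",
              "LeafLength", "LeafWidth", "MaxCanopyHeight", "Moisture",
              "StatureLeafAngle", "StatureStemAngle", "StemDiameter",
              "TallestStem", "TransectCount", "Cellulose",
              "Hemicellulose", "Lignin")
  units <- c("d", "score0-10", "mm", "g", "cm", "cm", "cm", "%",
             "score0-1", "score1-4", "mm", "cm", "count", "%", "%", "%")
  means <- c(221.21, 7.34, 398.72, 1065.47, 52.43, 1.42, 144.67, 30.65,
             0.66, 1.97, 5.37, 176.82, 27.63, 42.14, 32.81, 8.95)
  h2 <- c(0.89, 0.83, 0.52, 0.54, 0.65, 0.64, 0.77, 0.59,
          0.50, 0.48, 0.60, 0.88, 0.51, 0.79, 0.60, 0.66)
  # phenotypic SDs: generous CVs for size/yield traits, tighter for
  # percentages and bounded scores
  sd_p <- c(18, 1.5, 80, 320, 10, 0.30, 30, 5.0,
            0.20, 0.55, 1.1, 38, 8, 2.5, 2.0, 0.9)
  n <- length(traits)
  r_g <- diag(n)
  dimnames(r_g) <- list(traits, traits)
  set_r <- function(R, a, b, v) { R[a, b] <- v; R[b, a] <- v; R }
  r_g <- set_r(r_g, "DOYFS1", "DryMatter", 0.19)
  r_g <- set_r(r_g, "DOYFS1", "AvgeSen", -0.85)
  r_g <- set_r(r_g, "DOYFS1", "Moisture", 0.85)
  r_g <- set_r(r_g, "AvgeSen", "Moisture", -0.70)
  # size/architecture traits co-vary moderately with each other and yield
  size <- c("BaseDiameter", "MaxCanopyHeight", "StemDiameter",
            "TallestStem", "TransectCount")
  for (s in size) r_g <- set_r(r_g, s, "DryMatter", 0.30)
  for (k in seq_along(size)) {
    for (l in seq_along(size)) {
      if (k < l) r_g <- set_r(r_g, size[k], size[l], 0.25)
    }
  }
  r_g <- set_r(r_g, "LeafLength", "LeafWidth", 0.30)
  r_g <- set_r(r_g, "LeafLength", "DryMatter", 0.20)
  r_g <- set_r(r_g, "LeafWidth", "DryMatter", 0.20)
  r_g <- set_r(r_g, "LeafLength", "TallestStem", 0.25)
  r_g <- set_r(r_g, "StatureLeafAngle", "StatureStemAngle", 0.25)
  # cell wall: lignin trades off against cellulose and digestible yield
  r_g <- set_r(r_g, "Cellulose", "Lignin", -0.25)
  r_g <- set_r(r_g, "Cellulose", "Hemicellulose", -0.20)
  r_g <- set_r(r_g, "Lignin", "DryMatter", -0.10)
  r_g <- set_r(r_g, "Cellulose", "DryMatter", 0.10)
  r_g <- set_r(r_g, "Moisture", "DryMatter", 0.15)
  r_g <- nearest_correlation(r_g)
  # environmental correlations: same pattern, damped
  r_e <- nearest_correlation(diag(n) + 0.5 * (r_g - diag(diag(r_g))))
  panel <- trait_panel(traits, units, means, h2 = h2,
                       reference = "DryMatter")
  spec <- covariance_spec(h2, sd_p, r_g, r_e, traits = traits)
  list(panel = panel, spec = spec)
}

# Clip negative eigenvalues and rescale to unit diagonal.
nearest_correlation <- function(R, floor_ev = 1e-6) {
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(ev$values) >= floor_ev) return((R + t(R)) / 2)
  vals <- pmax(ev$values, floor_ev)
  M <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  dimnames(M) <- dimnames(R)
  (M + t(M)) / 2
}

#' Simulate a clonally replicated population
#'
#' True breeding values are drawn from a zero-mean multivariate normal with
#' covariance `G`; each of `reps` clonal replicates adds an independent
#' residual with covariance `E = P - G`. Phenotype = mean + breeding value +
#' residual.
#'
#' @param params A [genetic_parameters()] object.
#' @param means Numeric n-vector of trait means (default 0).
#' @param N Number of genotypes (>= 2).
#' @param reps Clonal replicates per genotype (>= 1).
#' @param seed Integer seed; the population is reproducible given the seed.
#' @return An object of class `synthetic_population`: list with `bv`
#'   (N x n true breeding values), `phenotypes` (N x n x reps array),
#'   `genotype_means` (N x n, phenotypes averaged over replicates), `means`,
#'   `params`, `reps`, `seed`.
#' @export
simulate_population <- function(params, means = NULL, N, reps = 1L,
                                seed = 1L) {
  n <- length(params$traits)
  if (is.null(means)) means <- rep(0, n)
  stopifnot(N >= 2, reps >= 1, length(means) == n)
  set.seed(as.integer(seed))
  E <- params$P - params$G
  bv <- MASS::mvrnorm(N, mu = rep(0, n), Sigma = params$G)
  if (N == 1L) bv <- matrix(bv, nrow = 1L)
  colnames(bv) <- params$traits
  ph <- array(NA_real_, dim = c(N, n, reps),
              dimnames = list(NULL, params$traits, NULL))
  zeroE <- max(abs(E)) < 1e-300
  for (r in seq_len(reps)) {
    res <- if (zeroE) matrix(0, N, n) else
      MASS::mvrnorm(N, mu = rep(0, n), Sigma = E)
    ph[, , r] <- sweep(bv + res, 2L, means, "+")
  }
  gm <- apply(ph, c(1L, 2L), mean)
  structure(list(bv = bv, phenotypes = ph, genotype_means = gm,
                 means = means, params = params, reps = reps,
                 seed = as.integer(seed), ids = seq_len(N)),
            class = "synthetic_population")
}

#' Moment estimates of G and P from a clonally replicated population
#'
#' Classical clonal-replicate decomposition: the covariance of genotype
#' means estimates `G + E / reps`, and the pooled within-genotype covariance
#' estimates `E`; so `G_hat = cov(means) - E_hat / reps` and
#' `P_hat = G_hat + E_hat`. Unbiased moment estimators, intended for
#' parameter-recovery testing.
#'
#' @param pop A [simulate_population()] result with `reps >= 2`.
#' @return A list with `G_hat`, `P_hat`, `E_hat`.
#' @export
estimate_covariances <- function(pop) {
  if (pop$reps < 2L) stop("covariance estimation needs reps >= 2")
  N <- nrow(pop$bv)
  n <- ncol(pop$bv)
  reps <- pop$reps
  gm <- pop$genotype_means
  # pooled within-genotype covariance
  Ew <- matrix(0, n, n)
  for (r in seq_len(reps)) {
    d <- pop$phenotypes[, , r] - gm
    Ew <- Ew + crossprod(d)
  }
  E_hat <- Ew / (N * (reps - 1L))
  G_hat <- stats::cov(gm) - E_hat / reps
  dimnames(G_hat) <- dimnames(E_hat) <- list(pop$params$traits,
                                             pop$params$traits)
  list(G_hat = G_hat, P_hat = G_hat + E_hat, E_hat = E_hat)
}

#' Realized genetic response to truncation selection on an index
#'
#' Scores genotype-mean phenotypes with the index, keeps the top
#' `ceiling(p * N)` genotypes (ties broken by stable genotype order), and
#' returns the mean true breeding value of the selected group minus the
#' population mean breeding value - the Monte-Carlo counterpart of the
#' predicted response `(i(p) / sigma_I) * G b`.
#'
#' @param pop A [simulate_population()] result.
#' @param b Numeric n-vector of index weights.
#' @param p Selected fraction in (0, 1).
#' @return Named numeric n-vector of realized genetic gains (trait units).
#' @export
realized_response <- function(pop, b, p) {
  stopifnot(p > 0, p < 1)
  scores <- score_index(b, pop$genotype_means)
  if (max(scores) - min(scores) < 1e-12 * max(abs(scores), 1)) {
    warning("degenerate selection: all index scores equal")
  }
  N <- length(scores)
  k <- ceiling(p * N)
  sel <- order(-scores, pop$ids)[seq_len(k)]
  stats::setNames(colMeans(pop$bv[sel, , drop = FALSE]) - colMeans(pop$bv),
                  pop$params$traits)
}
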