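#' Construct a trait panel
#'
#' A trait panel fixes the canonical trait order used by every vector and
#' matrix in the pipeline, together with per-trait units and current
#' population means. Percent-of-mean desired gains and relative-change
#' reporting are both expressed against these means.
#'
#' @param names Character vector of unique, non-empty trait identifiers.
#' @param units Character vector of unit strings (e.g. "d", "g", "cm", "%").
#' @param means Numeric vector of current population means, in trait units.
#' @param h2 Optional numeric vector of broad-sense heritabilities in (0, 1].
#' @param reference Name of the reference trait for economic-value ratios;
#'   must be one of `names`. Default `"DryMatter"` (dry biomass per plant).
#'
#' @return An object of class `trait_panel`: a data frame with columns
#'   `name`, `unit`, `mean` (and `h2` when supplied) and attribute
#'   `reference`.
#' @export
trait_panel <- function(names, units, means, h2 = NULL,
                        reference = "DryMatter") {
  names <- as.character(names)
  if (length(names) == 0L || anyNA(names) || any(!nzchar(names))) {
    stop("trait names must be non-empty")
  }
  if (anyDuplicated(names)) {
    stop("duplicate trait names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (length(units) != length(names) || length(means) != length(names)) {
    stop("'units' and 'means' must match the length of 'names'")
  }
  means <- as.numeric(means)
  if (anyNA(means)) stop("trait means must be numeric and non-missing")
  if (!reference %in% names) {
    stop("reference trait '", reference, "' is not in the panel")
  }
  panel <- data.frame(name = names, unit = as.character(units),
                      mean = means, stringsAsFactors = FALSE)
  if (!is.null(h2)) {
    h2 <- as.numeric(h2)
    if (length(h2) != length(names)) stop("'h2' must match 'names'")
    if (any(h2 <= 0 | h2 > 1, na.rm = TRUE)) {
      stop("heritabilities must lie in (0, 1]")
    }
    panel$h2 <- h2
  }
  attr(panel, "reference") <- reference
  class(panel) <- c("trait_panel", "data.frame")
  panel
}

#' @export
print.trait_panel <- function(x, ...) {
  cat("Trait panel:", nrow(x), "traits (reference:",
      attr(x, "reference"), ")\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

n_traits <- function(panel) nrow(panel)

reference_trait <- function(panel) attr(panel, "reference")

#' Validate genetic and phenotypic covariance matrices against a panel
#'
#' Checks that `G` and `P` are square, labelled and ordered like the panel,
#' symmetric (symmetry is then enforced exactly by averaging each matrix with
#' its transpose), that `G` and the residual covariance `E = P - G` are
#' positive semi-definite, and that every implied heritability
#' `G[j,j] / P[j,j]` lies in (0, 1]. Marker-estimated covariance matrices are
#' often slightly indefinite; with `repair = TRUE` eigenvalues below
#' `eps * max(eigenvalue)` are clipped up to that floor (with a warning)
#' instead of raising an error. Repair is opt-in so that genuinely bad inputs
#' are not silently masked.
#'
#' @param panel A [trait_panel()].
#' @param G,P Numeric n x n genetic and phenotypic variance-covariance
#'   matrices in panel trait order (dimnames, when present, must match).
#' @param repair Logical; clip small negative eigenvalues instead of failing.
#' @param tol Relative tolerance for the symmetry and PSD checks.
#'
#' @return An object of class `genetic_parameters`: a list with elements
#'   `G`, `P` (both symmetrized, dimnames set to panel traits) and `traits`.
#' @export
genetic_parameters <- function(panel, G, P, repair = FALSE, tol = 1e-8) {
  G <- as_trait_matrix(G, panel, "G")
  P <- as_trait_matrix(P, panel, "P")
  G <- check_symmetric(G, "G", tol)
  P <- check_symmetric(P, "P", tol)
  h2 <- ifelse(diag(P) > 0, diag(G) / diag(P), NA_real_)
  bad <- which(!is.na(h2) & (h2 <= 0 | h2 > 1 + tol))
  if (length(bad)) {
    stop("heritability outside (0, 1] for trait(s): ",
         paste(panel$name[bad], collapse = ", "))
  }
  G <- check_psd(G, "G", repair = repair, tol = tol)
  E <- check_psd(P - G, "E = P - G", repair = repair, tol = tol)
  P <- G + E
  structure(list(G = G, P = P, traits = panel$name),
            class = "genetic_parameters")
}

#' Validate (and optionally repair) an existing parameter set
#'
#' Idempotent wrapper around the `genetic_parameters` checks: applying it to
#' an already-validated object returns an equal object.
#'
#' @inheritParams genetic_parameters
#' @param params A `genetic_parameters` object or a list with `G` and `P`.
#' @return A validated `genetic_parameters` object.
#' @export
validate_parameters <- function(panel, params, repair = FALSE, tol = 1e-8) {
  genetic_parameters(panel, params$G, params$P, repair = repair, tol = tol)
}

#' @export
print.genetic_parameters <- function(x, ...) {
  cat("Genetic parameters for", length(x$traits), "traits\n")
  cat("  h2 range:", paste(signif(range(diag(x$G) / diag(x$P)), 3),
                           collapse = " - "), "\n")
  invisible(x)
}

as_trait_matrix <- function(M, panel, label) {
  M <- as.matrix(M)
  n <- n_traits(panel)
  if (nrow(M) != n || ncol(M) != n) {
    stop(label, " must be ", n, " x ", n, ", got ",
         nrow(M), " x ", ncol(M))
  }
  if (!is.null(rownames(M)) && !identical(rownames(M), panel$name)) {
    if (!setequal(rownames(M), panel$name)) {
      stop(label, " trait labels do not match the panel")
    }
    M <- M[panel$name, panel$name, drop = FALSE]
  }
  storage.mode(M) <- "double"
  dimnames(M) <- list(panel$name, panel$name)
  M
}

check_symmetric <- function(M, label, tol) {
  scale <- max(abs(M), 1e-300)
  if (max(abs(M - t(M))) > tol * scale) {
    stop(label, " is not symmetric (relative tolerance ", tol, ")")
  }
  (M + t(M)) / 2
}

check_psd <- function(M, label, repair = FALSE, tol = 1e-8) {
  ev <- eigen(M, symmetric = TRUE)
  lmax <- max(ev$values, 0)
  floor_ev <- tol * lmax
  if (min(ev$values) < -floor_ev) {
    if (!repair) {
      stop(label, " is not positive semi-definite (smallest eigenvalue ",
           signif(min(ev$values), 4), "); rerun with repair = TRUE ",
           "to clip small negative eigenvalues")
    }
    warning("clipping ", sum(ev$values < floor_ev),
            " eigenvalue(s) of ", label, " up to ", signif(floor_ev, 3))
    vals <- pmax(ev$values, floor_ev)
    M <- ev$vectors %*% (vals * t(ev$vectors))
    M <- (M + t(M)) / 2
  } else if (min(ev$values) < 0) {
    # within tolerance of zero: clip silently to keep downstream chol() happy
    vals <- pmax(ev$values, 0)
    M <- ev$vectors %*% (vals * t(ev$vectors))
    M <- (M + t(M)) / 2
  }
  M
}

#' Define a breeding scenario of desired genetic gains
#'
#' A scenario names a subset of traits and the genetic gain desired for each,
#' either in absolute trait units or as a percent of the current population
#' mean. A desired gain of zero is legal and means "hold this trait
#' unchanged" - it is a constraint, not an omission.
#'
#' @param name Scenario identifier, e.g. `"S1"`.
#' @param gains Data frame with columns `trait`, `value`, `mode`
#'   (`"absolute"` or `"percent"`), one row per targeted trait; or a named
#'   numeric vector (taken as absolute gains).
#'
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, gains) {
  if (is.numeric(gains) && !is.null(names(gains))) {
    gains <- data.frame(trait = names(gains), value = as.numeric(gains),
                        mode = "absolute", stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(gains),
            all(c("trait", "value", "mode") %in% names(gains)))
  if (nrow(gains) < 1L) stop("a scenario needs at least one desired gain")
  gains$trait <- as.character(gains$trait)
  gains$value <- as.numeric(gains$value)
  gains$mode <- match.arg(gains$mode, c("absolute", "percent"),
                          several.ok = TRUE)
  if (anyDuplicated(gains$trait)) {
    stop("duplicate trait in scenario gains: ",
         paste(unique(gains$trait[duplicated(gains$trait)]), collapse = ", "))
  }
  structure(list(name = as.character(name), gains = gains),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario", x$name, "-", nrow(x$gains), "desired gain(s):\n")
  g <- x$gains
  cat(paste0("  ", g$trait, ": ", g$value,
             ifelse(g$mode == "percent", " %", " (absolute)"),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Resolve a scenario's desired gains to absolute trait units
#'
#' Percent entries are converted as `q = pct / 100 * mean`; absolute entries
#' pass through. The result follows panel order.
#'
#' @param scen A [scenario()].
#' @param panel A [trait_panel()].
#' @return A list with `Q` (named numeric vector of absolute gains, in the
#'   panel order of the targeted traits) and `mask` (integer indices of the
#'   targeted traits within the panel).
#' @export
absolute_gains <- function(scen, panel) {
  g <- scen$gains
  missing <- setdiff(g$trait, panel$name)
  if (length(missing)) {
    stop("scenario targets unknown trait(s): ",
         paste(missing, collapse = ", "))
  }
  idx <- match(g$trait, panel$name)
  ord <- order(idx)
  g <- g[ord, , drop = FALSE]
  idx <- idx[ord]
  q <- numeric(nrow(g))
  for (k in seq_len(nrow(g))) {
    if (g$mode[k] == "percent") {
      mu <- panel$mean[idx[k]]
      if (mu == 0) {
        stop("relative gain on trait '", g$trait[k], "' with mean 0")
      }
      q[k] <- g$value[k] / 100 * mu
    } else {
      q[k] <- g$value[k]
    }
  }
  names(q) <- g$trait
  list(Q = q, mask = idx)
}

#' Economic assumptions for monetizing trait changes
#'
#' @param density Plants per hectare (default 4444, a 1.5 x 1.5 m grid).
#' @param price Currency per tonne of dry biomass (default 70).
#' @param currency Currency label used in reports (default the euro sign).
#' @return An object of class `economic_assumptions`.
#' @export
economic_assumptions <- function(density = 4444, price = 70,
                                 currency = "€") {
  if (density <= 0) stop("density must be positive")
  if (price < 0) stop("price must be non-negative")
  structure(list(density = density, price = price,
                 grams_per_tonne = 1e6, currency = currency),
            class = "economic_assumptions")
}
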