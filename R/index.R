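#' Score individuals on a selection index
#'
#' The index is the linear combination `I = b'X` of phenotypic trait values.
#'
#' @param b Numeric n-vector of index weights.
#' @param X Numeric n-vector of phenotypes, or an N x n matrix (one row per
#'   individual).
#' @return A scalar index value, or a length-N vector for a matrix input.
#' @export
score_index <- function(b, X) {
  b <- as.numeric(b)
  if (is.matrix(X)) {
    if (ncol(X) != length(b)) stop("length of b must match columns of X")
    return(drop(X %*% b))
  }
  if (length(X) != length(b)) stop("length of b must match length of X")
  sum(b * as.numeric(X))
}

#' Smith-Hazel index weights from economic values
#'
#' Solves `P b = G a` for the weights that maximize the correlation between
#' the index and the aggregate breeding value `a'g`. Implemented as a
#' symmetric linear solve; `P` must be invertible.
#'
#' @param params A [genetic_parameters()] object.
#' @param a Numeric n-vector of economic values (value per unit of genetic
#'   change in each trait).
#' @return Named numeric n-vector of index weights `b`.
#' @export
smith_hazel_weights <- function(params, a) {
  a <- as.numeric(a)
  if (length(a) != length(params$traits)) stop("length of a must equal n")
  warn_if_ill_conditioned(params$P, "P")
  b <- solve_sym(params$P, params$G %*% a, "P")
  stats::setNames(drop(b), params$traits)
}

#' Desired-gains index weights when every trait has a target
#'
#' In the full case (m = n targeted traits) the weights solve `G b = Q`.
#'
#' @param params A [genetic_parameters()] object.
#' @param Q Numeric n-vector of desired genetic gains in trait units.
#' @return Named numeric n-vector of index weights.
#' @export
desired_gain_weights_full <- function(params, Q) {
  Q <- as.numeric(Q)
  if (length(Q) != length(params$traits)) stop("length of Q must equal n")
  warn_if_ill_conditioned(params$G, "G")
  b <- solve_sym(params$G, Q, "G")
  stats::setNames(drop(b), params$traits)
}

#' Restricted desired-gains index weights (gains on a trait subset)
#'
#' For m <= n targeted traits the weights are
#' `b = P^-1 G* [G*' P^-1 G*]^-1 Q`, where `G*` keeps the m columns of `G`
#' for the targeted traits. This is the minimum-variance index achieving the
#' desired gains exactly: the expected response `G b` equals `Q` on the
#' targeted traits. Implemented with nested linear solves; no matrix is
#' inverted explicitly.
#'
#' @param params A [genetic_parameters()] object.
#' @param Q Numeric m-vector of desired genetic gains (trait units).
#' @param mask Integer indices or trait names of the m targeted traits.
#' @return Named numeric n-vector of index weights.
#' @export
restricted_gain_weights <- function(params, Q, mask) {
  mask <- resolve_mask(mask, params$traits, sort = FALSE)
  Q <- as.numeric(Q)
  if (length(Q) != length(mask)) stop("length of Q must match the mask")
  ord <- order(mask)
  mask <- mask[ord]
  Q <- Q[ord]
  warn_if_ill_conditioned(params$P, "P")
  Gstar <- params$G[, mask, drop = FALSE]
  PinvG <- solve_sym(params$P, Gstar, "P")       # P^-1 G*
  M <- crossprod(Gstar, PinvG)                   # G*' P^-1 G*, m x m
  M <- (M + t(M)) / 2
  y <- tryCatch(solve(M, Q), error = function(e) {
    stop("desired gains unattainable/degenerate: G*' P^-1 G* is ",
         "rank-deficient (", conditionMessage(e), ")")
  })
  stats::setNames(drop(PinvG %*% y), params$traits)
}

#' Implied economic values of an index
#'
#' Inverts the Smith-Hazel construction: the economic values under which a
#' given weight vector is optimal solve `G a = P b`. Together with
#' [smith_hazel_weights()] this forms an exact roundtrip when `G` and `P`
#' are invertible.
#'
#' @param params A [genetic_parameters()] object.
#' @param b Numeric n-vector of index weights.
#' @return Named numeric n-vector of economic values.
#' @export
implied_economic_values <- function(params, b) {
  b <- as.numeric(b)
  if (length(b) != length(params$traits)) stop("length of b must equal n")
  warn_if_ill_conditioned(params$G, "G")
  a <- solve_sym(params$G, params$P %*% b, "G")
  stats::setNames(drop(a), params$traits)
}

#' Normalize economic values to a reference trait
#'
#' Divides every economic value by the reference trait's, so ratios read
#' "value per unit of change relative to one unit of the reference trait"
#' (e.g. grams of dry biomass per plant).
#'
#' @param a Named numeric vector of economic values.
#' @param ref Reference trait name (or index); its ratio becomes 1.
#' @return Named numeric vector of ratios.
#' @export
normalize_economic_values <- function(a, ref) {
  if (is.character(ref)) {
    if (!ref %in% names(a)) stop("reference trait '", ref, "' not found")
    ref <- match(ref, names(a))
  }
  if (a[ref] == 0) stop("economic value of the reference trait is zero")
  a / a[ref]
}

#' Format economic-value ratios for reporting
#'
#' Ratios with magnitude >= 10 print as integers, smaller ones to one
#' decimal, mirroring how breeding-objective tables typically quote them.
#'
#' @param ratios Numeric vector of normalized economic values.
#' @return Character vector of formatted ratios.
#' @export
format_econ_ratios <- function(ratios) {
  ifelse(abs(ratios) >= 10,
         formatC(round(ratios), format = "d"),
         formatC(round(ratios, 1), format = "f", digits = 1))
}

#' Correlated responses to index selection
#'
#' Under single-generation truncation selection with intensity equal to the
#' index standard deviation, the expected genetic change in all n traits is
#' `Q* = G b`, including traits with no specified target.
#'
#' @param params A [genetic_parameters()] object.
#' @param b Numeric n-vector of index weights.
#' @return Named numeric n-vector of expected responses, in trait units.
#' @export
correlated_responses <- function(params, b) {
  b <- as.numeric(b)
  if (length(b) != length(params$traits)) stop("length of b must equal n")
  stats::setNames(drop(params$G %*% b), params$traits)
}

#' Index standard deviation and required selection intensity
#'
#' The index standard deviation is `sigma_I = sqrt(b' P b)`. When the
#' desired gains are to be achieved in a single generation, the required
#' selection intensity equals `sigma_I`.
#'
#' @param params A [genetic_parameters()] object.
#' @param b Numeric n-vector of index weights.
#' @return A list with `sigma_I` and `i` (equal under the single-generation
#'   assumption).
#' @export
index_sd_and_intensity <- function(params, b) {
  b <- as.numeric(b)
  v <- drop(crossprod(b, params$P %*% b))
  if (v < -1e-12 * max(abs(params$P))) {
    stop("negative index variance: P is not positive semi-definite")
  }
  s <- sqrt(max(v, 0))
  list(sigma_I = s, i = s)
}

#' Responses as percent of current means
#'
#' @param Q_star Named numeric vector of absolute responses (trait units).
#' @param panel A [trait_panel()].
#' @return Numeric vector `100 * Q_star / mean`, in panel order.
#' @export
relative_change <- function(Q_star, panel) {
  idx <- if (!is.null(names(Q_star))) match(names(Q_star), panel$name)
         else seq_along(Q_star)
  if (anyNA(idx)) stop("unknown trait in Q_star")
  mu <- panel$mean[idx]
  if (any(mu == 0)) {
    stop("zero current mean for trait(s): ",
         paste(panel$name[idx][mu == 0], collapse = ", "))
  }
  stats::setNames(100 * as.numeric(Q_star) / mu, panel$name[idx])
}

# --- internal helpers -----------------------------------------------------

resolve_mask <- function(mask, traits, sort = TRUE) {
  if (is.character(mask)) {
    idx <- match(mask, traits)
    if (anyNA(idx)) {
      stop("unknown trait(s) in mask: ",
           paste(mask[is.na(idx)], collapse = ", "))
    }
    mask <- idx
  }
  mask <- as.integer(mask)
  if (anyDuplicated(mask) || any(mask < 1L) || any(mask > length(traits))) {
    stop("mask must be distinct trait indices in 1..n")
  }
  if (sort) sort(mask) else mask
}

# Symmetric solve via Cholesky with LU fallback; errors name the matrix.
solve_sym <- function(M, rhs, label) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) {
    return(backsolve(ch, forwardsolve(t(ch), rhs)))
  }
  tryCatch(solve(M, rhs), error = function(e) {
    stop("matrix ", label, " is singular: ", conditionMessage(e))
  })
}

warn_if_ill_conditioned <- function(M, label, threshold = 1e12) {
  k <- tryCatch(kappa(M, exact = FALSE), error = function(e) Inf)
  if (is.finite(k) && k > threshold) {
    warning("matrix ", label, " is ill-conditioned (condition number ~ ",
            signif(k, 3), "); results may be unstable")
  }
  invisible(k)
}
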