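#' Dry-biomass equivalent of a trait change
#'
#' Converts a genetic change in a secondary trait into the per-hectare dry
#' biomass it is worth, via its relative economic value expressed in grams of
#' dry matter per plant per unit of the trait:
#' `tonnes/ha = density * delta * econ_ratio / grams_per_tonne`.
#'
#' @param delta Change in the trait, in trait units.
#' @param econ_ratio Relative economic value: grams of dry biomass per plant
#'   equivalent to one unit of change in the trait.
#' @param econ An [economic_assumptions()] object.
#' @return Tonnes of dry biomass per hectare.
#' @export
biomass_equivalent <- function(delta, econ_ratio,
                               econ = economic_assumptions()) {
  econ$density * delta * econ_ratio / econ$grams_per_tonne
}

#' Monetary value of a per-hectare biomass amount
#'
#' @param tonnes_per_ha Tonnes of dry biomass per hectare.
#' @param econ An [economic_assumptions()] object.
#' @return Currency per hectare (unrounded; reports round to whole units).
#' @export
monetary_value <- function(tonnes_per_ha, econ = economic_assumptions()) {
  tonnes_per_ha * econ$price
}

#' Run a desired-gains index selection scenario end to end
#'
#' Deterministic pipeline: resolve the desired gains to absolute units,
#' compute restricted index weights, correlated responses for all traits,
#' implied economic values and their reference-trait ratios, the index
#' standard deviation, the required selection intensity and the implied
#' selected fraction, relative changes, and per-hectare monetized
#' equivalents of the targeted secondary traits.
#'
#' Monetization uses each targeted trait's absolute desired gain as the
#' change being valued (`monetize_mode = "absolute"`); pass explicit deltas
#' to [monetize_trait()] for other conventions (e.g. valuing a percentage
#' trait per printed percent figure rather than per percent-of-mean).
#'
#' @param panel A [trait_panel()].
#' @param params A [genetic_parameters()] object.
#' @param scen A [scenario()].
#' @param econ An [economic_assumptions()] object.
#' @return An object of class `scenario_report`: a list with the scenario,
#'   `solution` (b, a, Q_star, sigma_I, i, p), `table` (one row per trait:
#'   trait, unit, current_mean, delta, pct_change, weight_b, econ_value_a,
#'   econ_ratio), `econ_ratios` over the targeted traits, and `monetized`
#'   (per targeted secondary trait: delta, tonnes per ha, currency per ha).
#' @export
run_scenario <- function(panel, params, scen,
                         econ = economic_assumptions()) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  ag <- stage("absolute_gains", absolute_gains(scen, panel))
  b <- stage("restricted_gain_weights",
             restricted_gain_weights(params, ag$Q, ag$mask))
  Q_star <- stage("correlated_responses", correlated_responses(params, b))
  a <- stage("implied_economic_values", implied_economic_values(params, b))
  ref <- reference_trait(panel)
  ratios <- stage("normalize_economic_values",
                  normalize_economic_values(a, ref))
  sdi <- stage("index_sd_and_intensity", index_sd_and_intensity(params, b))
  p <- stage("fraction_from_intensity", fraction_from_intensity(sdi$i))
  pct <- stage("relative_change", relative_change(Q_star, panel))

  targeted <- panel$name[ag$mask]
  secondary <- setdiff(targeted, ref)
  monetized <- data.frame(
    trait = secondary,
    delta = unname(ag$Q[secondary]),
    econ_ratio = unname(ratios[secondary]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  monetized$tonnes_per_ha <-
    biomass_equivalent(monetized$delta, monetized$econ_ratio, econ)
  monetized$value_per_ha <- monetary_value(monetized$tonnes_per_ha, econ)

  tab <- data.frame(
    trait = panel$name,
    unit = panel$unit,
    current_mean = panel$mean,
    delta = as.numeric(Q_star),
    pct_change = as.numeric(pct),
    weight_b = as.numeric(b),
    econ_value_a = as.numeric(a),
    econ_ratio = as.numeric(ratios),
    stringsAsFactors = FALSE
  )

  structure(list(
    scenario = scen,
    panel = panel,
    solution = list(b = b, a = a, Q_star = Q_star,
                    sigma_I = sdi$sigma_I, i = sdi$i, p = p),
    table = tab,
    econ_ratios = ratios[targeted],
    monetized = monetized,
    monetize_mode = "absolute",
    econ = econ
  ), class = "scenario_report")
}

#' Monetize an explicit trait change under a report's economic values
#'
#' The change being valued is decoupled from the scenario's desired gains:
#' e.g. a moisture constraint can be valued per percentage point even though
#' its desired gain is zero, or a cell-wall trait per printed percent figure.
#'
#' @param report A `scenario_report`.
#' @param trait Trait name.
#' @param delta Change in trait units to value.
#' @param econ Optional [economic_assumptions()]; defaults to the report's.
#' @return A one-row data frame with delta, econ_ratio, tonnes_per_ha and
#'   value_per_ha.
#' @export
monetize_trait <- function(report, trait, delta, econ = report$econ) {
  ratios <- report$table$econ_ratio
  names(ratios) <- report$table$trait
  if (!trait %in% names(ratios)) stop("unknown trait '", trait, "'")
  t_ha <- biomass_equivalent(delta, ratios[[trait]], econ)
  data.frame(trait = trait, delta = delta, econ_ratio = ratios[[trait]],
             tonnes_per_ha = t_ha, value_per_ha = monetary_value(t_ha, econ),
             stringsAsFactors = FALSE)
}

#' Refine a scenario by holding additional traits unchanged
#'
#' Appends zero-gain constraints for the given traits and suffixes the
#' scenario name with `*`. The original scenario is unchanged.
#'
#' @param scen A [scenario()].
#' @param hold_constant Character vector of traits to constrain to zero
#'   change. Traits already targeted with a nonzero gain are an error.
#' @return A new [scenario()].
#' @export
refine_scenario <- function(scen, hold_constant) {
  hold_constant <- as.character(hold_constant)
  if (length(hold_constant) == 0L) return(scen)
  clash <- intersect(hold_constant,
                     scen$gains$trait[scen$gains$value != 0])
  if (length(clash)) {
    stop("trait(s) already constrained with nonzero gains: ",
         paste(clash, collapse = ", "))
  }
  new_traits <- setdiff(hold_constant, scen$gains$trait)
  gains <- rbind(scen$gains,
                 data.frame(trait = new_traits, value = 0,
                            mode = "absolute", stringsAsFactors = FALSE))
  scenario(paste0(scen$name, "*"), gains)
}

#' Compare scenario reports side by side
#'
#' One column pair (delta, percent) per scenario; traits whose response
#' changes sign between any two scenarios are flagged.
#'
#' @param ... Two or more `scenario_report` objects on the same panel.
#' @return A data frame with trait, unit, current_mean, per-scenario
#'   `delta_<name>` / `pct_<name>` columns, and a logical `sign_flip`.
#' @export
compare_scenarios <- function(...) {
  reports <- list(...)
  if (length(reports) < 2L) stop("need at least two reports")
  base <- reports[[1L]]$panel
  for (r in reports[-1L]) {
    if (!identical(r$panel$name, base$name)) stop("panel mismatch")
  }
  out <- data.frame(trait = base$name, unit = base$unit,
                    current_mean = base$mean, stringsAsFactors = FALSE)
  deltas <- sapply(reports, function(r) r$table$delta)
  for (k in seq_along(reports)) {
    nm <- reports[[k]]$scenario$name
    out[[paste0("delta_", nm)]] <- reports[[k]]$table$delta
    out[[paste0("pct_", nm)]] <- reports[[k]]$table$pct_change
  }
  out$sign_flip <- apply(deltas, 1L, function(d) {
    any(d > 0) && any(d < 0)
  })
  out
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Scenario", x$scenario$name, "\n")
  cat(sprintf("  sigma_I = %.4f; required intensity i = %.2f; selected top %.1f %%\n",
              x$solution$sigma_I, x$solution$i, 100 * x$solution$p))
  tr <- x$econ_ratios
  cat("  economic-value ratios (", reference_trait(x$panel), " = 1): ",
      paste(names(tr), format_econ_ratios(tr), sep = " = ",
            collapse = ", "), "\n", sep = "")
  tab <- x$table
  tab$delta <- sprintf("%.2f", tab$delta)
  tab$pct_change <- sprintf("%.1f", tab$pct_change)
  print.data.frame(tab[, c("trait", "unit", "current_mean",
                           "delta", "pct_change")],
                   row.names = FALSE)
  if (nrow(x$monetized)) {
    cat("  monetized (mode:", x$monetize_mode, "):\n")
    m <- x$monetized
    cat(sprintf("    %s: delta %.2f -> %.2f t/ha -> %s%d/ha\n",
                m$trait, m$delta, m$tonnes_per_ha, x$econ$currency,
                round(m$value_per_ha)), sep = "")
  }
  invisible(x)
}
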