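#' Prey category weight table
#'
#' Per-delivery biomass is estimated from a table of mean whole-item masses
#' (grams) per prey category. The field protocol extrapolates these means from
#' prey weighed during nest controls; they are site- and study-specific, so
#' the table is a required configuration input rather than a built-in
#' constant. An illustrative example ships with the package
#' (\code{system.file("extdata", "prey_weights_example.yaml", package =
#' "kitepeck")}); its values are synthetic placeholders, not field estimates.
#'
#' \code{read_prey_weights()} reads a YAML mapping \code{category: grams};
#' \code{validate_prey_weights()} checks it (all masses > 0) and, when the
#' \code{unclassified} category is absent, fills it with the mean of the
#' classified category weights.
#'
#' @param path path to a YAML file mapping prey categories to grams.
#' @param weights a named numeric vector or list of per-category masses.
#' @return a named numeric vector over the six prey categories.
#' @export
read_prey_weights <- function(path) {
  validate_prey_weights(yaml::read_yaml(path))
}

#' @rdname read_prey_weights
#' @export
validate_prey_weights <- function(weights) {
  w <- unlist(weights)
  if (is.null(names(w)) || !is.numeric(w))
    kite_error("weights must be a named numeric category -> grams mapping",
               "kitepeck_config_error")
  unknown <- setdiff(names(w), KITE_PREY_CATEGORIES)
  if (length(unknown))
    kite_error(sprintf("unknown prey category in weights: %s",
                       paste(unknown, collapse = ", ")),
               "kitepeck_config_error")
  if (any(!is.finite(w) | w <= 0))
    kite_error("all category weights must be finite and > 0",
               "kitepeck_config_error")
  if (!"unclassified" %in% names(w))
    w[["unclassified"]] <- mean(w)
  w[intersect(KITE_PREY_CATEGORIES, names(w))]
}

#' Estimated mass of single prey deliveries
#'
#' The observer's visual mass estimate takes precedence when present;
#' otherwise the category mean whole-item mass is scaled by the delivered
#' fraction (whole, half or quarter item).
#'
#' @param deliveries a validated deliveries table (columns \code{category},
#'   \code{fraction}, \code{observer_mass_g}).
#' @param weights a validated category weight table (see
#'   [validate_prey_weights()]); may be \code{NULL} if every row has an
#'   observer estimate.
#' @return numeric vector of grams, one per delivery.
#' @export
estimate_delivery_mass <- function(deliveries, weights = NULL) {
  n <- nrow(deliveries)
  if (!n) return(numeric(0))
  out <- as.numeric(deliveries$observer_mass_g)
  need <- is.na(out)
  if (any(need)) {
    if (is.null(weights))
      kite_error("deliveries without observer mass present but no weight table given",
                 "kitepeck_config_error")
    weights <- validate_prey_weights(weights)
    cat_w <- weights[deliveries$category[need]]
    if (anyNA(cat_w))
      kite_error(sprintf("no weight configured for category '%s'",
                         deliveries$category[need][which(is.na(cat_w))[1]]),
                 "kitepeck_config_error")
    out[need] <- as.numeric(cat_w) * deliveries$fraction[need]
  }
  out
}

#' Daily delivered biomass per brood
#'
#' Sums the per-delivery mass estimates over each brood-day. Days with no
#' deliveries contribute 0 g (they simply do not appear in the aggregate
#' table; [brood_day_covariates()] fills covered days with 0).
#'
#' @inheritParams estimate_delivery_mass
#' @param brood_id,date optional scalars; when both are given the function
#'   returns the single brood-day total (0 if no deliveries).
#' @return either a data frame (\code{brood_id}, \code{date},
#'   \code{biomass_g}) or a scalar number of grams.
#' @export
daily_biomass <- function(deliveries, weights = NULL, brood_id = NULL,
                          date = NULL) {
  if (!is.null(brood_id) && !is.null(date)) {
    sub <- deliveries[deliveries$brood_id == brood_id &
                        deliveries$date == as.Date(date), , drop = FALSE]
    return(sum(estimate_delivery_mass(sub, weights)))
  }
  if (!nrow(deliveries))
    return(data.frame(brood_id = character(0), date = as.Date(character(0)),
                      biomass_g = numeric(0)))
  g <- estimate_delivery_mass(deliveries, weights)
  agg <- aggregate(g, by = list(brood_id = deliveries$brood_id,
                                date = deliveries$date), FUN = sum)
  names(agg)[3] <- "biomass_g"
  agg[order(agg$brood_id, agg$date), , drop = FALSE]
}
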