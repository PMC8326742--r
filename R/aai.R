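#' Load and validate an EU-scale AAI weight configuration
#'
#' The configuration lists four domains (employment; participation in
#' society; independent, healthy and secure living; capacity and enabling
#' environment), each with indicator weights that must sum to 100 within
#' the domain, and domain weights that must sum to 100 overall. The file
#' shipped with the package carries the standard 35/35/10/20 weighting.
#'
#' @param path YAML file; defaults to the bundled configuration.
#' @return object of class `aai_config`: list of domains.
#' @export
#' @examples
#' cfg <- aai_eu_config()
#' vapply(cfg$domains, `[[`, 0, "domain_weight")
aai_eu_config <- function(path = system.file("extdata", "aai_eu_weights.yaml",
                                             package = "agewell")) {
  cfg <- yaml::read_yaml(path)
  dw <- vapply(cfg$domains, function(d) as.numeric(d$domain_weight), 0)
  if (abs(sum(dw) - 100) > 1e-9) {
    stopf("domain weights sum to %g, not 100", sum(dw))
  }
  for (d in cfg$domains) {
    iw <- vapply(d$indicators, function(i) as.numeric(i$weight), 0)
    if (abs(sum(iw) - 100) > 1e-9) {
      stopf("indicator weights in domain '%s' sum to %g, not 100", d$name, sum(iw))
    }
  }
  structure(cfg, class = "aai_config")
}

#' EU-scale Active Ageing Index
#'
#' Each indicator is on a 0-100 scale (higher = more active ageing). A
#' domain score is the indicator-weighted mean, and the overall index the
#' domain-weighted mean of domain scores:
#' `domain = sum(indicator * weight) / 100`,
#' `overall = sum(domain * domain_weight) / 100`.
#'
#' @param indicators named numeric vector, values in \[0, 100\]; every
#'   indicator named in the configuration must be present.
#' @param config an [aai_eu_config()].
#' @return object of class `aai`: list with `scale = "eu"`,
#'   `domain_scores`, `overall`.
#' @export
#' @examples
#' cfg <- aai_eu_config()
#' nm <- unlist(lapply(cfg$domains, function(d) vapply(d$indicators, `[[`, "", "name")))
#' aai_eu(setNames(rep(50, length(nm)), nm), cfg)$overall  # 50
aai_eu <- function(indicators, config = aai_eu_config()) {
  ds <- vapply(config$domains, function(d) {
    nm <- vapply(d$indicators, function(i) i$name, "")
    w <- vapply(d$indicators, function(i) as.numeric(i$weight), 0)
    miss <- setdiff(nm, names(indicators))
    if (length(miss)) stopf("missing indicator(s): %s", paste(miss, collapse = ", "))
    v <- indicators[nm]
    if (any(v < 0 | v > 100)) stopf("indicator outside [0, 100]: %s",
                                    paste(nm[v < 0 | v > 100], collapse = ", "))
    sum(v * w) / 100
  }, 0)
  names(ds) <- vapply(config$domains, function(d) d$name, "")
  dw <- vapply(config$domains, function(d) as.numeric(d$domain_weight), 0)
  structure(list(scale = "eu", domain_scores = ds,
                 overall = sum(ds * dw) / 100),
            class = "aai")
}

#' Derived EU AAI capacity indicators from a life table
#'
#' Two of the capacity-domain indicators are computed rather than surveyed:
#' the chance-of-long-life proxy `min(100, 100 * e(55) / 50)` (remaining
#' life expectancy of 50 years at age 55) and the share of healthy life
#' expectancy at 55, `100 * DFLE(55) / e(55)`.
#'
#' @param lt a [lifetable()] with a boundary at age 55.
#' @param prev a [prevalence_schedule()] aligned with `lt` at 55+.
#' @return named vector with `remaining_life_expectancy_50_at_55` and
#'   `share_healthy_life_expectancy_at_55`.
#' @export
aai_capacity_indicators <- function(lt, prev) {
  e55 <- life_expectancy_at(lt, 55)
  he <- sullivan_expectancy(lt, prev, 55)
  c(remaining_life_expectancy_50_at_55 = min(100, 100 * e55 / 50),
    share_healthy_life_expectancy_at_55 = 100 * he$free_LE / e55)
}

#' HDI-style min-max normalisation
#'
#' @param actual observed value.
#' @param min,max goalposts; `max` must exceed `min`.
#' @return `(actual - min) / (max - min)`, clamped to \[0, 1\] with a
#'   warning when the actual value falls outside the goalposts.
#' @export
#' @examples
#' hdi_normalize(0.66, 0, 1)
hdi_normalize <- function(actual, min, max) {
  if (max <= min) stopf("max goalpost must exceed min")
  idx <- (actual - min) / (max - min)
  if (any(idx < 0 | idx > 1)) {
    warnf("value outside the [min, max] goalposts; index clamped")
    idx <- pmin(pmax(idx, 0), 1)
  }
  idx
}

#' WHO-scale Active Ageing Index
#'
#' Fifteen binary indicators in three dimensions: health (three wellness +
#' three physical-activity indicators), community participation (three),
#' and security (three financial + three physical). The actual score of a
#' dimension is the sum of positive responses; each dimension index is the
#' HDI normalisation of that sum against goalposts 0 and the indicator
#' count; the overall index is the unweighted mean of the three dimension
#' indices, classified by the UNDP thresholds of
#' [classify_index_level()].
#'
#' @param positives either a logical/0-1 matrix of respondents x 15
#'   indicators (columns ordered health 1-6, participation 7-9, security
#'   10-15), or a length-15 vector of group-level proportions positive.
#' @return object of class `aai`: list with `scale = "who"`,
#'   `dimension_indices` (health, participation, security), `overall`,
#'   `level`.
#' @export
#' @examples
#' aai_who(c(rep(0.5, 6), rep(1, 3), rep(0, 6)))  # overall 0.5
aai_who <- function(positives) {
  groups <- list(health = 1:6, participation = 7:9, security = 10:15)
  if (is.matrix(positives) || is.data.frame(positives)) {
    positives <- as.matrix(positives)
    if (ncol(positives) != 15L) stopf("expected 15 indicators, got %d", ncol(positives))
    per_dim <- vapply(groups, function(g) {
      mean(hdi_normalize(rowSums(positives[, g, drop = FALSE]), 0, length(g)))
    }, 0)
  } else {
    if (length(positives) != 15L) stopf("expected 15 indicators, got %d", length(positives))
    per_dim <- vapply(groups, function(g) {
      hdi_normalize(sum(positives[g]), 0, length(g))
    }, 0)
  }
  overall <- mean(per_dim)
  structure(list(scale = "who", dimension_indices = per_dim,
                 overall = overall, level = classify_index_level(overall)),
            class = "aai")
}

#' Classify an index value by the UNDP development-level thresholds
#'
#' Low below 0.5, medium from 0.5 up to (but excluding) 0.8, high from 0.8
#' to 1. Classification compares the raw, unrounded value.
#'
#' @param index value(s) in \[0, 1\].
#' @return factor with levels `low`, `medium`, `high`.
#' @export
#' @examples
#' classify_index_level(c(0.45, 0.66, 0.8))
classify_index_level <- function(index) {
  if (any(index < 0 | index > 1)) stopf("index outside [0, 1]")
  factor(ifelse(index < 0.5, "low", ifelse(index < 0.8, "medium", "high")),
         levels = c("low", "medium", "high"))
}

#' @export
print.aai <- function(x, ...) {
  if (x$scale == "eu") {
    cat("Active Ageing Index (EU scale)\n")
    for (nm in names(x$domain_scores)) {
      cat(sprintf("  %-34s %6.1f\n", nm, x$domain_scores[[nm]]))
    }
    cat(sprintf("  overall: %.1f\n", x$overall))
  } else {
    cat("Active Ageing Index (WHO scale)\n")
    for (nm in names(x$dimension_indices)) {
      cat(sprintf("  %-14s %5.2f\n", nm, x$dimension_indices[[nm]]))
    }
    cat(sprintf("  overall: %.2f (%s)\n", x$overall, x$level))
  }
  invisible(x)
}
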