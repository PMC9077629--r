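# Hypothesis adjudication: translate a ranked model suite plus fitted
# geometry into one of four biological hypotheses per analysis side, and
# classify individual studies against a 95% band around the one-to-one line.
#
# The four hypotheses, as geometry on the paired plot:
#   null            — points on the one-to-one line; insularity has no effect.
#   proportional    — a line departing from the one-to-one line across the
#                     whole observed range (proportional loss of diversity
#                     within populations / proportional increase of
#                     divergence among populations).
#   above_threshold — departure only above an interior crossing point x*.
#   below_threshold — departure only below an interior crossing point x*.

hypothesis_labels <- c("null", "proportional", "above_threshold",
                       "below_threshold")

#' Crossing point of a fitted line with the one-to-one line
#'
#' Solves `a + b x = x`: `x* = a / (1 − b)`. For `b = 1` the lines are
#' parallel (identical when `a = 0`) and there is no crossing.
#'
#' @param a Intercept.
#' @param b Slope.
#' @return The crossing point, or `NA` when `b = 1`.
#' @export
crossing_point <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  if (b == 1) return(NA_real_)
  a / (1 - b)
}

#' Adjudicate among the four insularity hypotheses
#'
#' Applies a decision table to a ranked model comparison:
#'
#' 1. Models within `null_threshold` AICc of the best are considered
#'    statistically indistinguishable; among them, the model with the fewest
#'    parameters classifies (so if the one-to-one null is in that set, the
#'    verdict is `null`).
#' 2. A linear or semi-null classifier is read through its crossing point
#'    `x*` with the one-to-one line relative to the observed x-range:
#'    an interior crossing indicates a threshold effect (which side depends
#'    on the slope and the analysis side), a crossing outside the range a
#'    proportional effect across the whole range.
#' 3. A transformed or broken-stick classifier is read geometrically: the
#'    taxon-averaged fitted curve is compared to the one-to-one line over
#'    the x-range, and the hypothesis follows from where the absolute
#'    deviation exceeds `deviation_tol` (default half the classifier's
#'    residual standard deviation).
#'
#' @param comparison A [gd_comparison][compare_models()] containing the full
#'   suite for one side.
#' @param side `"within"` or `"among"`; inferred from the fits when `NULL`.
#' @param x_range Observed x-range; defaults to the fitted data's range.
#' @param null_threshold AICc indistinguishability band (default 2).
#' @param deviation_tol Tolerance for the geometric rule, in response units.
#' @return A `gd_verdict`: list with `side`, `hypothesis`,
#'   `classifier_model`, `top_models` (tibble), `diagnostics` (slope,
#'   intercept, x_star, x_range, crossing_within_range) and a `narrative`
#'   string.
#' @export
classify_hypothesis <- function(comparison, side = NULL, x_range = NULL,
                                null_threshold = 2, deviation_tol = NULL) {
  stopifnot(inherits(comparison, "gd_comparison"))
  fits <- comparison$fits
  sides <- unique(purrr::map_chr(fits, ~ .x$side %||% NA_character_))
  sides <- sides[!is.na(sides)]
  if (length(sides) > 1) abort("Fits from different analysis sides; cannot adjudicate.")
  side <- side %||% (if (length(sides) == 1) sides else
    abort("Analysis side unknown; pass side = \"within\" or \"among\"."))
  side <- match.arg(side, c("within", "among"))

  tab <- comparison$table
  x_range <- x_range %||% range(fits[[1]]$data$x)

  top <- tab[tab$delta_aicc <= null_threshold, ]
  classifier_name <- top$model[order(top$k, top$delta_aicc)][1]
  fit <- fits[[classifier_name]]

  cf <- fit$coefficients
  a <- if ("intercept" %in% names(cf)) unname(cf[["intercept"]]) else 0
  b <- if ("slope" %in% names(cf)) unname(cf[["slope"]]) else NA_real_

  if (classifier_name %in% c("null", "semi_null", "linear")) {
    xs <- crossing_point(a, b)
    res <- classify_line(a, b, xs, x_range, side)
  } else {
    tol <- deviation_tol %||% (0.5 * sqrt(fit$sigma2))
    res <- classify_curve(fit, x_range, tol, side)
    xs <- res$x_star
  }

  diagnostics <- list(
    slope = b, intercept = a,
    x_star = if (isTRUE(b == 1)) NA_real_ else xs,
    x_range = x_range,
    crossing_within_range = is.finite(xs) && xs > x_range[1] && xs < x_range[2],
    deviation_tol = if (classifier_name %in%
                        c("log_transformed", "exp_transformed", "broken_stick"))
      deviation_tol %||% (0.5 * sqrt(fit$sigma2)) else NA_real_
  )

  narrative <- sprintf(
    paste0("Side '%s': classifier '%s' (of %d model(s) within %.3g AICc of ",
           "best); %s Verdict: %s."),
    side, classifier_name, nrow(top), null_threshold, res$explain,
    res$hypothesis
  )

  structure(
    list(side = side, hypothesis = res$hypothesis,
         classifier_model = classifier_name,
         top_models = dplyr::select(top, "model", "delta_aicc", "weight", "k"),
         diagnostics = diagnostics, narrative = narrative),
    class = "gd_verdict"
  )
}

# Decision table for straight-line classifiers. Labels name the region of
# the observed range, relative to the crossing point, where the departure
# from the one-to-one line grows; a crossing outside the range means the
# departure spans the whole range (proportional).
classify_line <- function(a, b, x_star, x_range, side) {
  if (b == 1) {
    if (a == 0) {
      return(list(hypothesis = "null",
                  explain = "line coincides with the one-to-one line."))
    }
    return(list(
      hypothesis = "proportional",
      explain = sprintf("parallel offset %+.3g from the one-to-one line.", a)
    ))
  }
  interior <- x_star > x_range[1] && x_star < x_range[2]
  pos <- if (interior) "interior" else if (x_star <= x_range[1]) "low" else "high"
  hyp <- if (side == "within") {
    if (b < 1) switch(pos, interior = "above_threshold",
                      low = "proportional", high = "below_threshold")
    else switch(pos, interior = "below_threshold",
                low = "above_threshold", high = "proportional")
  } else {
    if (b < 1) switch(pos, interior = "below_threshold",
                      low = "proportional", high = "above_threshold")
    else switch(pos, interior = "above_threshold",
                low = "proportional", high = "below_threshold")
  }
  list(hypothesis = hyp,
       explain = sprintf(
         "slope %.4g, crossing x* = %.4g %s the observed range [%.3g, %.3g].",
         b, x_star, if (interior) "inside" else "outside",
         x_range[1], x_range[2]))
}

# Geometric rule for curved / segmented classifiers: locate where the
# taxon-averaged fitted curve deviates from the one-to-one line by more
# than tol across the observed range.
classify_curve <- function(fit, x_range, tol, side, n_grid = 201) {
  grid <- seq(x_range[1], x_range[2], length.out = n_grid)
  dev <- predict(fit, tibble::tibble(x = grid)) - grid
  exceed <- abs(dev) > tol
  if (!any(exceed)) {
    return(list(hypothesis = "null", x_star = NA_real_,
                explain = sprintf(
                  "fitted curve within %.3g of the one-to-one line everywhere.",
                  tol)))
  }
  if (all(exceed)) {
    return(list(hypothesis = "proportional", x_star = NA_real_,
                explain = sprintf(
                  "fitted curve departs by more than %.3g across the whole range.",
                  tol)))
  }
  first <- which(exceed)[1]
  last <- utils::tail(which(exceed), 1)
  suffix <- all(exceed[first:n_grid])  # deviation only above an interior x
  prefix <- all(exceed[1:last])        # deviation only below an interior x
  if (suffix && !prefix) {
    return(list(hypothesis = "above_threshold", x_star = grid[first],
                explain = sprintf(
                  "fitted curve departs from the one-to-one line above x = %.4g.",
                  grid[first])))
  }
  if (prefix && !suffix) {
    return(list(hypothesis = "below_threshold", x_star = grid[last],
                explain = sprintf(
                  "fitted curve departs from the one-to-one line below x = %.4g.",
                  grid[last])))
  }
  # non-contiguous exceedance: fall back to the dominant side of the largest
  # on-line stretch
  mid <- (first + last) / 2
  above_mass <- mean(abs(dev[grid > grid[mid]]))
  below_mass <- mean(abs(dev[grid <= grid[mid]]))
  hyp <- if (above_mass >= below_mass) "above_threshold" else "below_threshold"
  list(hypothesis = hyp, x_star = grid[round(mid)],
       explain = "non-monotone deviation pattern; classified by dominant side.")
}

#' @export
print.gd_verdict <- function(x, ...) {
  cat("<gd_verdict> ", x$side, ": ", x$hypothesis, "\n", sep = "")
  cat("  ", x$narrative, "\n", sep = "")
  invisible(x)
}

#' @method tidy gd_verdict
#' @export
tidy.gd_verdict <- function(x, ...) {
  tibble::tibble(
    side = x$side, hypothesis = x$hypothesis,
    classifier_model = x$classifier_model,
    slope = x$diagnostics$slope, intercept = x$diagnostics$intercept,
    x_star = x$diagnostics$x_star,
    x_min = x$diagnostics$x_range[1], x_max = x$diagnostics$x_range[2],
    crossing_within_range = x$diagnostics$crossing_within_range
  )
}

#' Classify individual studies against the one-to-one band
#'
#' Draws a band of half-width `z(1 − alpha/2) * sigma` around the one-to-one
#' line (plus taxon deviations when the null fit includes them), where sigma
#' is the null fit's maximum-likelihood residual standard deviation, and
#' labels each paired point as within, above, or below the band. This
#' summarizes how many individual study systems are consistent with
#' insularity having no effect.
#'
#' @param points Paired points the null fit was computed on.
#' @param null_fit The one-to-one `gd_fit` (model `"null"`).
#' @param alpha Band level (default 0.05 for a 95% band).
#' @param band_quantile `"normal"` (default) or `"t"` (uses n − k residual
#'   degrees of freedom).
#' @return A tibble (unit_id if present, study_id, x, y, deviation, label)
#'   with attributes `half_width` and `counts` (named: within_band,
#'   above_band, below_band).
#' @export
classify_studies <- function(points, null_fit, alpha = 0.05,
                             band_quantile = c("normal", "t")) {
  band_quantile <- match.arg(band_quantile)
  stopifnot(inherits(null_fit, "gd_fit"))
  if (null_fit$model != "null") {
    abort("classify_studies() expects the one-to-one null fit.")
  }
  if (digest_points(points) != digest_points(null_fit$data)) {
    abort("Points differ from those the null fit was computed on.")
  }
  sigma <- sqrt(null_fit$sigma2)
  q <- if (band_quantile == "normal") qnorm(1 - alpha / 2) else
    qt(1 - alpha / 2, df = max(null_fit$n - null_fit$k, 1))
  half_width <- q * sigma

  dev <- points$y - predict(null_fit, points)
  if (sigma == 0) {
    warn("Null fit has zero residual variance; points classified by sign.")
    label <- dplyr::case_when(dev > 0 ~ "above_band", dev < 0 ~ "below_band",
                              TRUE ~ "within_band")
  } else {
    label <- dplyr::case_when(dev > half_width ~ "above_band",
                              dev < -half_width ~ "below_band",
                              TRUE ~ "within_band")
  }

  keep <- intersect(c("unit_id", "study_id", "species", "taxon_group"),
                    names(points))
  out <- dplyr::bind_cols(
    points[keep],
    tibble::tibble(x = points$x, y = points$y, deviation = dev, label = label)
  )
  attr(out, "half_width") <- half_width
  attr(out, "counts") <- c(
    within_band = sum(label == "within_band"),
    above_band = sum(label == "above_band"),
    below_band = sum(label == "below_band")
  )
  out
}
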