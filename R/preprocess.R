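# Standardization and paired aggregation.
#
# Heterogeneous published metrics (heterozygosity, allelic richness, FST, ...)
# are z-scored per metric type across all population-level values of that
# type, so that metrics with different native units can be averaged on a
# common scale. Each study unit then collapses to one (x, y) point per
# analysis side, and each side is translated so its minimum coordinate is
# exactly 1 (making log transforms well defined downstream).

#' Z-standardize each metric type across the dataset
#'
#' For every metric type present, computes the mean and standard deviation
#' (n − 1 denominator) over *all* population-level values of that type across
#' all retained studies, and adds a `z_value` column to both the GD and the
#' divergence tables. The standardization constants are stored for reporting
#' and inverse transformation.
#'
#' @param records A [record_set][as_record_set], typically the output of
#'   [validate_inclusion()].
#' @return The record set with `z_value` columns added and a new component
#'   `standardization` — a tibble (table, metric_type, mean, sd, n_values).
#' @export
standardize <- function(records) {
  stopifnot(inherits(records, "record_set"))

  std_one <- function(tab, label) {
    if (nrow(tab) == 0) {
      return(list(tab = tab,
                  const = tibble::tibble(table = character(),
                                         metric_type = character(),
                                         mean = double(), sd = double(),
                                         n_values = integer())))
    }
    const <- tab |>
      dplyr::group_by(.data$metric_type) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                       n_values = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(table = label, .before = 1)
    degenerate <- const$metric_type[!is.finite(const$sd) | const$sd == 0]
    if (length(degenerate) > 0) {
      abort(sprintf(
        "Metric type(s) with zero variance (cannot standardize): %s",
        paste(degenerate, collapse = ", ")
      ))
    }
    tab <- tab |>
      dplyr::left_join(dplyr::select(const, "metric_type", "mean", "sd"),
                       by = "metric_type") |>
      dplyr::mutate(z_value = (.data$value - .data$mean) / .data$sd) |>
      dplyr::select(-"mean", -"sd")
    list(tab = tab, const = const)
  }

  gd <- std_one(records$gd, "gd")
  dv <- std_one(records$divergence, "divergence")
  out <- records
  out$gd <- gd$tab
  out$divergence <- dv$tab
  out$standardization <- dplyr::bind_rows(gd$const, dv$const)
  out
}

#' Collapse studies to paired points for the within-population analysis
#'
#' Per study unit, each population's standardized values are first averaged
#' across the metric types it reports, then those population means are
#' averaged across the non-insular populations (the x coordinate) and across
#' the insular populations (the y coordinate). Averaging populations first
#' prevents a study that reports many metrics for a single population from
#' dominating its own point; `average = "flat"` instead averages all
#' (population, metric) cells with equal weight.
#'
#' @param std A standardized record set from [standardize()].
#' @param average `"population_first"` (default) or `"flat"`.
#' @return A tibble of paired points: unit_id, study_id, species,
#'   taxon_group, side ("within"), x, y, n_metrics_averaged,
#'   n_non_insular, n_insular.
#' @export
pair_within <- function(std, average = c("population_first", "flat")) {
  average <- match.arg(average)
  stopifnot(inherits(std, "record_set"))
  if (is.null(std$gd$z_value)) abort("Run standardize() before pairing.")
  gd <- std$gd
  if (nrow(gd) == 0) {
    abort("No GD records available for the within-population analysis.")
  }

  pop_means <- if (average == "population_first") {
    gd |>
      dplyr::group_by(.data$unit_id, .data$study_id, .data$species,
                      .data$taxon_group, .data$population_id, .data$insular) |>
      dplyr::summarise(z = mean(.data$z_value),
                       n_metrics = dplyr::n(), .groups = "drop")
  } else {
    # every (population, metric) cell weighted equally within a study side
    gd |>
      dplyr::mutate(z = .data$z_value, n_metrics = 1L) |>
      dplyr::select("unit_id", "study_id", "species", "taxon_group",
                    "population_id", "insular", "z", "n_metrics")
  }

  pts <- pop_means |>
    dplyr::group_by(.data$unit_id, .data$study_id, .data$species,
                    .data$taxon_group) |>
    dplyr::summarise(
      x = mean(.data$z[!.data$insular]),
      y = mean(.data$z[.data$insular]),
      n_metrics_averaged = sum(.data$n_metrics),
      n_non_insular = dplyr::n_distinct(.data$population_id[!.data$insular]),
      n_insular = dplyr::n_distinct(.data$population_id[.data$insular]),
      .groups = "drop"
    )

  dropped <- pts[!is.finite(pts$x) | !is.finite(pts$y), ]
  if (nrow(dropped) > 0) {
    warn(paste0("Study unit(s) without z-values on one side skipped: ",
                paste(dropped$unit_id, collapse = ", ")))
    pts <- pts[is.finite(pts$x) & is.finite(pts$y), ]
  }
  dplyr::mutate(pts, side = "within", .after = "taxon_group")
}

#' Collapse studies to paired points for the among-population analysis
#'
#' Per study unit, x is the mean standardized divergence over all
#' non-insular/non-insular population pairs and y the mean over all
#' insular/non-insular pairs. Insular/insular pairs are excluded (they were
#' rare in the literature: most studies have a single insular population)
#' and counted in the output attribute `n_ins_ins_excluded`.
#'
#' @inheritParams pair_within
#' @return A tibble of paired points: unit_id, study_id, species,
#'   taxon_group, side ("among"), x, y, n_metrics_averaged, n_non_non_pairs,
#'   n_ins_non_pairs.
#' @export
pair_among <- function(std) {
  stopifnot(inherits(std, "record_set"))
  if (nrow(std$divergence) == 0) {
    abort("No divergence records available for the among-population analysis.")
  }
  if (is.null(std$divergence$z_value)) abort("Run standardize() before pairing.")

  classed <- pair_classes(std)
  n_ins_ins <- sum(classed$pair_class == "ins_ins")
  classed <- classed[classed$pair_class != "ins_ins", ]

  taxa <- std$study_index |>
    dplyr::distinct(.data$unit_id, .data$taxon_group)

  pts <- classed |>
    dplyr::group_by(.data$unit_id, .data$study_id, .data$species) |>
    dplyr::summarise(
      x = mean(.data$z_value[.data$pair_class == "non_non"]),
      y = mean(.data$z_value[.data$pair_class == "ins_non"]),
      n_metrics_averaged = dplyr::n_distinct(.data$metric_type),
      n_non_non_pairs = sum(.data$pair_class == "non_non"),
      n_ins_non_pairs = sum(.data$pair_class == "ins_non"),
      .groups = "drop"
    ) |>
    dplyr::left_join(taxa, by = "unit_id") |>
    dplyr::relocate("taxon_group", .after = "species")

  dropped <- pts[!is.finite(pts$x) | !is.finite(pts$y), ]
  if (nrow(dropped) > 0) {
    warn(paste0("Study unit(s) without both pair classes skipped: ",
                paste(dropped$unit_id, collapse = ", ")))
    pts <- pts[is.finite(pts$x) & is.finite(pts$y), ]
  }
  pts <- dplyr::mutate(pts, side = "among", .after = "taxon_group")
  attr(pts, "n_ins_ins_excluded") <- n_ins_ins
  pts
}

#' Shift paired points so the dataset minimum is exactly 1
#'
#' Adds the constant c = 1 − min(x, y) to both axes of every point, so that
#' the smallest coordinate across the whole side equals 1 and logarithmic
#' model terms are defined. Both axes receive the same constant, so slopes,
#' intercept geometry relative to the one-to-one line, and all pairwise
#' differences are preserved.
#'
#' @param paired A tibble of paired points from [pair_within()] or
#'   [pair_among()].
#' @return A list with `points` (the shifted tibble, also carrying the shift
#'   in attribute `shift_constant`) and `shift_constant`.
#' @export
shift_to_unit_min <- function(paired) {
  if (nrow(paired) == 0) abort("No paired points to shift.")
  vals <- c(paired$x, paired$y)
  if (any(!is.finite(vals))) abort("Non-finite paired values; cannot shift.")
  shift <- 1 - min(vals)
  paired$x <- paired$x + shift
  paired$y <- paired$y + shift
  attr(paired, "shift_constant") <- shift
  list(points = paired, shift_constant = shift)
}

#' Standardize, pair and shift in one call
#'
#' Convenience wrapper running [standardize()], the side-appropriate pairing
#' ([pair_within()] or [pair_among()]), and [shift_to_unit_min()]. The shift
#' constant is computed per analysis side, since the two sides draw on
#' different metric families.
#'
#' @inheritParams pair_within
#' @param records A validated [record_set][as_record_set].
#' @param side `"within"` or `"among"`.
#' @return The shifted paired-point tibble (attribute `shift_constant`).
#' @export
prepare_pairs <- function(records, side = c("within", "among"),
                          average = c("population_first", "flat")) {
  side <- match.arg(side)
  std <- standardize(records)
  pts <- if (side == "within") pair_within(std, average) else pair_among(std)
  shift_to_unit_min(pts)$points
}
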