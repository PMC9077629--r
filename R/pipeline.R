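# End-to-end orchestration: validate -> standardize -> pair -> fit ->
# compare -> adjudicate -> classify, with table rendering and file outputs.

#' Run the full paired insularity analysis
#'
#' Orchestrates the pipeline for one or both analysis sides and returns all
#' intermediate and final artifacts. Input is either a
#' [record_set][as_record_set] or a [synth_config()] (in which case the
#' dataset is generated first and the ground truth is attached to the
#' report). All analysis stages are deterministic; randomness lives only in
#' the generator.
#'
#' @param records A `record_set`, or `NULL` when `synth` is given.
#' @param synth Optional [synth_config()] used to generate the input.
#' @param side `"within"`, `"among"`, or `"both"`.
#' @param taxon Include taxon fixed effects in the within-side models
#'   (default `TRUE`; the among-side models never include them).
#' @param average Averaging order for [pair_within()].
#' @param alpha Level of the one-to-one band in [classify_studies()].
#' @param null_threshold AICc indistinguishability band for
#'   [classify_hypothesis()].
#' @param output_dir Optional directory; when given, per-side TSVs
#'   (comparison table, paired points with fitted-curve evaluations, study
#'   band classification), a verdict JSON (if the jsonlite package is
#'   available) and a run manifest are written.
#' @param ... Passed to [fit_broken_stick()].
#' @return A `gd_run_report`: list with `sides` (per side: `points`,
#'   `fits`, `comparison`, `verdict`, `bands`, `bands_raw` (band around the
#'   unadjusted one-to-one line when taxon effects are enabled), `table`
#'   (rendered comparison)), `records` (post-inclusion), `exclusions`,
#'   `truth` (for synthetic input) and `manifest`.
#' @export
run_pipeline <- function(records = NULL, synth = NULL,
                         side = c("both", "within", "among"),
                         taxon = TRUE,
                         average = c("population_first", "flat"),
                         alpha = 0.05, null_threshold = 2,
                         output_dir = NULL, ...) {
  side <- match.arg(side)
  average <- match.arg(average)
  truth <- NULL
  if (is.null(records)) {
    if (is.null(synth)) abort("Provide records or a synth config.")
    gen <- generate_metadataset(synth)
    records <- gen$records
    truth <- gen$truth
  }
  validated <- validate_inclusion(records)
  sides <- if (side == "both") c("within", "among") else side

  side_results <- purrr::map(setNames(sides, sides), function(s) {
    pts <- prepare_pairs(validated, side = s, average = average)
    use_taxon <- taxon && s == "within"
    fits <- fit_model_suite(pts, side = s, taxon = use_taxon, ...)
    # a broken-stick fit whose breakpoint sits at the data boundary means
    # segmentation does not improve on a straight line; it is reported but
    # excluded from the AICc ranking (its breakpoint is not a valid interior
    # estimate)
    fits_ranked <- fits
    if (isTRUE(fits$broken_stick$boundary_flag)) {
      fits_ranked$broken_stick <- NULL
    }
    cmp <- compare_models(fits_ranked)
    verdict <- classify_hypothesis(cmp, side = s,
                                   null_threshold = null_threshold)
    bands <- classify_studies(pts, fits$null, alpha = alpha)
    bands_raw <- if (use_taxon) {
      classify_studies(pts, fit_constrained_linear(
        pts, slope = "fixed", intercept = "fixed", taxon = FALSE),
        alpha = alpha)
    } else {
      bands
    }
    list(points = pts, fits = fits, comparison = cmp, verdict = verdict,
         bands = bands, bands_raw = bands_raw,
         table = render_comparison_table(cmp, side = s))
  })

  manifest <- list(
    sides = sides, taxon = taxon, average = average, alpha = alpha,
    null_threshold = null_threshold,
    n_units_input = dplyr::n_distinct(records$study_index$unit_id),
    n_points = purrr::map_int(side_results, ~ nrow(.x$points)),
    shift_constant = purrr::map_dbl(side_results,
                                    ~ attr(.x$points, "shift_constant")),
    seed = if (!is.null(truth)) truth$seed else NA_integer_,
    package_version = as.character(utils::packageVersion("insuladiv"))
  )

  report <- structure(
    list(sides = side_results, records = validated,
         exclusions = validated$exclusions, truth = truth,
         manifest = manifest),
    class = "gd_run_report"
  )
  if (!is.null(output_dir)) write_run_report(report, output_dir)
  report
}

#' @export
print.gd_run_report <- function(x, ...) {
  cat("<gd_run_report>\n")
  for (s in names(x$sides)) {
    r <- x$sides[[s]]
    cat("  ", s, ": n = ", nrow(r$points), " studies; verdict: ",
        r$verdict$hypothesis, " (best model ",
        r$comparison$table$model[1], ", weight ",
        sprintf("%.3f", r$comparison$table$weight[1]), ")\n", sep = "")
  }
  invisible(x)
}

#' Render a model-comparison table for reporting
#'
#' Rows sorted by ascending ΔAICc; the best model's ΔAICc printed as an em
#' dash, weights to three decimals with values below 0.0005 shown as
#' `"<0.001"`, and each model annotated with the biological hypotheses it
#' can support. A broken-stick fit whose breakpoint sat at the data
#' boundary is marked in a note column.
#'
#' @param comparison A [gd_comparison][compare_models()].
#' @param side `"within"` or `"among"` (controls the hypothesis wording);
#'   inferred from the comparison when possible.
#' @return A tibble of character columns: model, hypothesis, delta_aicc,
#'   weight, note.
#' @export
render_comparison_table <- function(comparison, side = NULL) {
  stopifnot(inherits(comparison, "gd_comparison"))
  tab <- comparison$table
  side <- side %||% tab$side[!is.na(tab$side)][1] %||% "within"

  fmt_weight <- function(w) ifelse(w < 0.0005, "<0.001", sprintf("%.3f", w))
  fmt_delta <- function(d) {
    out <- sprintf("%.1f", d)
    out[d == min(d)] <- "—"
    out
  }

  tibble::tibble(
    model = tab$model,
    hypothesis = hypothesis_mapping(tab$model, side),
    delta_aicc = fmt_delta(tab$delta_aicc),
    weight = fmt_weight(tab$weight),
    note = ifelse(tab$boundary_flag, "breakpoint at data boundary", "")
  )
}

hypothesis_mapping <- function(models, side) {
  within_map <- c(
    null = "within—null",
    semi_null = "within—proportional loss",
    linear = paste0("within—proportional loss, above-threshold or ",
                    "below-threshold (parameter-dependent)"),
    log_transformed = "within—above threshold",
    exp_transformed = "within—threshold effect (geometry-dependent)",
    broken_stick = paste0("within—above or below threshold ",
                          "(breakpoint-dependent)")
  )
  among_map <- c(
    null = "among—null",
    semi_null = "among—proportional increase",
    linear = paste0("among—proportional increase, above-threshold or ",
                    "below-threshold (parameter-dependent)"),
    exp_transformed = paste0("among—above or below threshold ",
                             "(parameter-dependent)"),
    broken_stick = paste0("among—above or below threshold ",
                          "(breakpoint-dependent)")
  )
  map <- if (side == "within") within_map else among_map
  unname(ifelse(models %in% names(map), map[models], ""))
}

write_run_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(report$sides)) {
    r <- report$sides[[s]]
    readr::write_tsv(r$table,
                     file.path(output_dir, paste0("comparison_", s, ".tsv")))
    grid <- tibble::tibble(x = seq(min(r$points$x), max(r$points$x),
                                   length.out = 101))
    curves <- purrr::map_dfr(names(r$fits), function(m) {
      tibble::tibble(model = m, x = grid$x,
                     y = predict(r$fits[[m]], grid))
    })
    readr::write_tsv(dplyr::select(r$points, -dplyr::any_of("side")),
                     file.path(output_dir, paste0("paired_points_", s, ".tsv")))
    readr::write_tsv(curves,
                     file.path(output_dir, paste0("fitted_curves_", s, ".tsv")))
    readr::write_tsv(r$bands,
                     file.path(output_dir, paste0("study_bands_", s, ".tsv")))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      v <- r$verdict
      jsonlite::write_json(
        list(side = v$side, hypothesis = v$hypothesis,
             classifier_model = v$classifier_model,
             diagnostics = v$diagnostics, narrative = v$narrative,
             top_models = v$top_models),
        file.path(output_dir, paste0("verdict_", s, ".json")),
        auto_unbox = TRUE, digits = NA
      )
    }
  }
  if (!is.null(report$exclusions) && nrow(report$exclusions) > 0) {
    readr::write_tsv(report$exclusions,
                     file.path(output_dir, "exclusion_log.tsv"))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(report$manifest,
                         file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(output_dir)
}
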