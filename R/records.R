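# Literature-style record sets: construction, validation, inclusion filtering.

#' Build a record set from in-memory tables
#'
#' A *record set* bundles the two tables a quantitative insularity synthesis
#' works from: population-level genetic-diversity (GD) measurements and
#' pairwise divergence measurements, plus a per-study roster of populations
#' with their insular flags. Each (study, species) combination is treated as
#' an independent analysis unit, so a study contributing several species
#' yields one paired point per species.
#'
#' Validation performed here: categorical labels are normalized to the
#' canonical vocabularies (see [taxon_groups]); duplicate
#' (study, population, metric) keys are an error; divergence pairs are stored
#' in canonical sorted order and self-pairs are an error; heterozygosity-type
#' and fixation-type metrics outside \[0, 1\] raise a warning (published
#' values occasionally exceed the bound through rounding, so data are never
#' silently dropped).
#'
#' @param gd Data frame of GD measurements with columns `study_id`,
#'   `taxon_group`, `population_id`, `insular` (logical), `metric_type`,
#'   `value`; optional `species`, `habitat`, `marker_type`.
#' @param divergence Optional data frame of pairwise divergence measurements
#'   with columns `study_id`, `population_id_a`, `population_id_b`,
#'   `metric_type`, `value`; optional `species`.
#' @param roster Optional data frame listing populations with no GD
#'   measurement of their own (columns `study_id`, `population_id`,
#'   `insular`, `taxon_group`; optional `species`), merged into the study
#'   index so divergence-only studies can be analyzed.
#' @param taxon_aliases Named character vector mapping literature taxon
#'   labels onto the six canonical groups; see [default_taxon_aliases()].
#'
#' @return An object of class `record_set`: a list with tibbles `gd`,
#'   `divergence`, `study_index`, and a `parse_log` (empty here; populated by
#'   [read_records()]).
#' @seealso [read_records()], [validate_inclusion()], [write_records()]
#' @export
#' @examples
#' gd <- tibble::tibble(
#'   study_id = "s1", taxon_group = "birds",
#'   population_id = c("mainland1", "mainland2", "island"),
#'   insular = c(FALSE, FALSE, TRUE),
#'   metric_type = "heterozygosity", value = c(0.71, 0.69, 0.55)
#' )
#' as_record_set(gd)
as_record_set <- function(gd, divergence = NULL, roster = NULL,
                          taxon_aliases = default_taxon_aliases()) {
  gd <- normalize_gd(gd, taxon_aliases)
  divergence <- normalize_divergence(divergence)

  study_index <- build_study_index(gd, divergence, roster, taxon_aliases)

  # Every population referenced by a divergence record must be on the roster.
  if (nrow(divergence) > 0) {
    referenced <- dplyr::bind_rows(
      dplyr::select(divergence, "unit_id", population_id = "population_id_a"),
      dplyr::select(divergence, "unit_id", population_id = "population_id_b")
    ) |> dplyr::distinct()
    missing <- dplyr::anti_join(
      referenced, study_index,
      by = c("unit_id", "population_id")
    )
    if (nrow(missing) > 0) {
      abort(paste0(
        "Divergence records reference populations absent from the study ",
        "roster: ",
        paste(utils::head(paste0(missing$unit_id, "/", missing$population_id), 5),
              collapse = ", "),
        if (nrow(missing) > 5) " ..." else ""
      ))
    }
  }

  structure(
    list(
      gd = gd,
      divergence = divergence,
      study_index = study_index,
      parse_log = tibble::tibble(
        file = character(), line = integer(), reason = character()
      )
    ),
    class = "record_set"
  )
}

#' @export
print.record_set <- function(x, ...) {
  n_units <- dplyr::n_distinct(x$study_index$unit_id)
  cat("<record_set> ", n_units, " study unit(s); ",
      nrow(x$gd), " GD record(s); ",
      nrow(x$divergence), " divergence record(s)\n", sep = "")
  if (!is.null(x$exclusions) && nrow(x$exclusions) > 0) {
    cat("  inclusion-filtered; ", nrow(x$exclusions),
        " exclusion log entr(ies)\n", sep = "")
  }
  invisible(x)
}

make_unit_id <- function(study_id, species) {
  species <- as.character(species %||% NA)
  ifelse(is.na(species) | species == "",
         as.character(study_id),
         paste(study_id, species, sep = "::"))
}

canonicalize_labels <- function(x, vocabulary, field, aliases = NULL) {
  x <- tolower(trimws(as.character(x)))
  if (!is.null(aliases)) {
    hit <- match(x, names(aliases))
    x[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  canon <- vocabulary[match(x, tolower(vocabulary))]
  if (anyNA(canon[!is.na(x)])) {
    bad <- unique(x[is.na(canon) & !is.na(x)])
    abort(sprintf(
      "Unknown %s label(s): %s. Allowed: %s.",
      field, paste(bad, collapse = ", "), paste(vocabulary, collapse = ", ")
    ))
  }
  canon
}

parse_insular <- function(x) {
  if (is.logical(x)) return(x)
  x_chr <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    x_chr %in% c("true", "t", "yes", "y", "1", "insular") ~ TRUE,
    x_chr %in% c("false", "f", "no", "n", "0", "non-insular", "noninsular") ~ FALSE,
    TRUE ~ NA
  )
  if (anyNA(out)) {
    abort(sprintf("Cannot interpret insular flag value(s): %s",
                  paste(unique(x_chr[is.na(out)]), collapse = ", ")))
  }
  out
}

normalize_gd <- function(gd, taxon_aliases) {
  required <- c("study_id", "taxon_group", "population_id", "insular",
                "metric_type", "value")
  missing <- setdiff(required, names(gd))
  if (length(missing) > 0) {
    abort(paste0("GD table lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  gd <- tibble::as_tibble(gd)
  gd$study_id <- as.character(gd$study_id)
  gd$population_id <- as.character(gd$population_id)
  gd$species <- as.character(gd[["species"]] %||% NA_character_)
  gd$habitat <- if (is.null(gd[["habitat"]])) NA_character_ else
    canonicalize_labels(gd$habitat, c("marine", "terrestrial", "freshwater"),
                        "habitat")
  gd$marker_type <- if (is.null(gd[["marker_type"]])) NA_character_ else
    canonicalize_labels(gd$marker_type,
                        c("microsatellite", "allozyme", "RFLP", "SNP", "mtDNA"),
                        "marker_type")
  gd$taxon_group <- canonicalize_labels(gd$taxon_group, taxon_groups,
                                        "taxon_group", taxon_aliases)
  gd$metric_type <- canonicalize_labels(gd$metric_type, gd_metric_types,
                                        "metric_type")
  gd$insular <- parse_insular(gd$insular)
  gd$value <- as.numeric(gd$value)
  if (any(!is.finite(gd$value))) {
    abort("GD values must be finite numbers; use read_records() to collect unparseable rows into a report.")
  }
  gd$unit_id <- make_unit_id(gd$study_id, gd$species)

  dup <- gd |>
    dplyr::count(.data$unit_id, .data$population_id, .data$metric_type) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "Duplicate (study, population, metric) key(s): ",
      paste(paste0(dup$unit_id, "/", dup$population_id, "/", dup$metric_type),
            collapse = ", ")
    ))
  }

  oob <- gd$metric_type %in% unit_interval_gd_metrics &
    (gd$value < 0 | gd$value > 1)
  if (any(oob)) {
    warn(sprintf(
      "%d heterozygosity/haplotype-diversity value(s) outside [0, 1]; retained verbatim.",
      sum(oob)
    ))
  }
  gd[c("unit_id", "study_id", "species", "taxon_group", "habitat",
       "population_id", "insular", "metric_type", "value", "marker_type")]
}

normalize_divergence <- function(divergence) {
  empty <- tibble::tibble(
    unit_id = character(), study_id = character(), species = character(),
    population_id_a = character(), population_id_b = character(),
    metric_type = character(), value = double()
  )
  if (is.null(divergence) || nrow(divergence) == 0) return(empty)
  required <- c("study_id", "population_id_a", "population_id_b",
                "metric_type", "value")
  missing <- setdiff(required, names(divergence))
  if (length(missing) > 0) {
    abort(paste0("Divergence table lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  d <- tibble::as_tibble(divergence)
  d$study_id <- as.character(d$study_id)
  d$species <- as.character(d[["species"]] %||% NA_character_)
  d$population_id_a <- as.character(d$population_id_a)
  d$population_id_b <- as.character(d$population_id_b)
  d$metric_type <- canonicalize_labels(d$metric_type, divergence_metric_types,
                                       "divergence metric_type")
  d$value <- as.numeric(d$value)
  if (any(!is.finite(d$value))) abort("Divergence values must be finite numbers.")
  if (any(d$population_id_a == d$population_id_b)) {
    abort("Divergence records must compare two distinct populations.")
  }
  # canonical orientation-free storage: (a, b) with a < b
  flip <- d$population_id_a > d$population_id_b
  tmp <- d$population_id_a[flip]
  d$population_id_a[flip] <- d$population_id_b[flip]
  d$population_id_b[flip] <- tmp
  d$unit_id <- make_unit_id(d$study_id, d$species)

  dup <- d |>
    dplyr::count(.data$unit_id, .data$population_id_a, .data$population_id_b,
                 .data$metric_type) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "Duplicate divergence (study, pair, metric) key(s): ",
      paste(paste0(dup$unit_id, "/", dup$population_id_a, "-",
                   dup$population_id_b, "/", dup$metric_type), collapse = ", ")
    ))
  }

  oob <- d$metric_type %in% unit_interval_div_metrics & (d$value < 0 | d$value > 1)
  if (any(oob)) {
    warn(sprintf("%d fixation-index value(s) outside [0, 1]; retained verbatim.",
                 sum(oob)))
  }
  if (any(d$metric_type == "migrants" & d$value < 0)) {
    warn("Negative estimated-migrant value(s); retained verbatim.")
  }
  d[c("unit_id", "study_id", "species", "population_id_a", "population_id_b",
      "metric_type", "value")]
}

build_study_index <- function(gd, divergence, roster, taxon_aliases) {
  from_gd <- gd |>
    dplyr::distinct(.data$unit_id, .data$study_id, .data$species,
                    .data$taxon_group, .data$population_id, .data$insular)
  extra <- NULL
  if (!is.null(roster) && nrow(roster) > 0) {
    r <- tibble::as_tibble(roster)
    r$study_id <- as.character(r$study_id)
    r$species <- as.character(r[["species"]] %||% NA_character_)
    r$population_id <- as.character(r$population_id)
    r$insular <- parse_insular(r$insular)
    r$taxon_group <- canonicalize_labels(r$taxon_group, taxon_groups,
                                         "taxon_group", taxon_aliases)
    r$unit_id <- make_unit_id(r$study_id, r$species)
    extra <- r[c("unit_id", "study_id", "species", "taxon_group",
                 "population_id", "insular")]
  }
  idx <- dplyr::bind_rows(from_gd, extra) |>
    dplyr::distinct(.data$unit_id, .data$population_id, .keep_all = TRUE)

  conflict <- idx |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(taxa = dplyr::n_distinct(.data$taxon_group),
                     .groups = "drop") |>
    dplyr::filter(.data$taxa > 1)
  if (nrow(conflict) > 0) {
    abort(paste0("taxon_group must be constant within a study unit; violated by: ",
                 paste(conflict$unit_id, collapse = ", ")))
  }
  flag_conflict <- dplyr::bind_rows(from_gd, extra) |>
    dplyr::distinct(.data$unit_id, .data$population_id, .data$insular) |>
    dplyr::count(.data$unit_id, .data$population_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(flag_conflict) > 0) {
    abort(paste0("Inconsistent insular flag for population(s): ",
                 paste(paste0(flag_conflict$unit_id, "/",
                              flag_conflict$population_id), collapse = ", ")))
  }
  idx
}

#' Read literature records from delimited files
#'
#' Reads the GD and (optionally) divergence CSV files, applies a column-name
#' mapping, collects unparseable rows into a parse report rather than
#' failing, and returns a validated [record_set][as_record_set].
#'
#' @param gd_path Path to the GD measurements CSV (comma-separated, UTF-8,
#'   "." decimal, header row required).
#' @param divergence_path Optional path to the pairwise-divergence CSV.
#' @param schema Named list mapping the canonical column names (e.g.
#'   `study_id`, `value`) to the column names used in the files; see
#'   [default_schema()]. Entries may be omitted when the file already uses
#'   canonical names.
#' @param taxon_aliases Passed to [as_record_set()].
#' @inheritParams as_record_set
#'
#' @return A `record_set`; rows with unparseable numeric values are skipped
#'   and reported in its `parse_log` tibble (file, line, reason). A missing
#'   required column is a fatal configuration error.
#' @export
read_records <- function(gd_path, divergence_path = NULL,
                         schema = default_schema(), roster = NULL,
                         taxon_aliases = default_taxon_aliases()) {
  schema <- utils::modifyList(default_schema(), as.list(schema))

  gd_raw <- read_mapped_csv(gd_path, schema$gd,
                            required = c("study_id", "taxon_group",
                                         "population_id", "insular",
                                         "metric_type", "value"))
  div_raw <- NULL
  if (!is.null(divergence_path)) {
    div_raw <- read_mapped_csv(divergence_path, schema$divergence,
                               required = c("study_id", "population_id_a",
                                            "population_id_b", "metric_type",
                                            "value"))
  }

  rs <- as_record_set(gd_raw$data, div_raw$data, roster = roster,
                      taxon_aliases = taxon_aliases)
  rs$parse_log <- dplyr::bind_rows(gd_raw$log, if (!is.null(div_raw)) div_raw$log)
  rs
}

#' Default column-name schema for [read_records()]
#'
#' @return A list with elements `gd` and `divergence`, each a named character
#'   vector mapping canonical column names to file column names.
#' @export
default_schema <- function() {
  list(
    gd = c(study_id = "study_id", species = "species",
           taxon_group = "taxon_group", habitat = "habitat",
           population_id = "population_id", insular = "insular",
           metric_type = "metric_type", value = "value",
           marker_type = "marker_type"),
    divergence = c(study_id = "study_id", species = "species",
                   population_id_a = "population_id_a",
                   population_id_b = "population_id_b",
                   metric_type = "metric_type", value = "value")
  )
}

read_mapped_csv <- function(path, mapping, required) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(required, names(mapping))
  if (length(missing) > 0) {
    abort(paste0("Schema omits required column mapping(s): ",
                 paste(missing, collapse = ", ")))
  }
  absent <- setdiff(unname(mapping[required]), names(raw))
  if (length(absent) > 0) {
    abort(paste0("File ", path, " lacks required column(s): ",
                 paste(absent, collapse = ", ")))
  }
  present <- mapping[unname(mapping) %in% names(raw)]
  data <- raw[unname(present)]
  names(data) <- names(present)

  value_num <- suppressWarnings(as.numeric(data$value))
  bad <- is.na(value_num)
  log <- tibble::tibble(
    file = rep(basename(path), sum(bad)),
    line = which(bad) + 1L,  # +1 for the header row
    reason = paste0("unparseable numeric value: ",
                    ifelse(is.na(data$value[bad]), "NA", data$value[bad]))
  )
  data$value <- value_num
  list(data = data[!bad, , drop = FALSE], log = log)
}

#' Apply the study-level inclusion criteria
#'
#' Filters a record set to the study units usable for the paired analysis.
#' A unit is retained for the *within* side when its roster has at least
#' three populations, at least one insular and at least two non-insular, and
#' GD measurements exist for both the insular and the non-insular side. It is
#' retained for the *among* side when, additionally to the roster criteria,
#' at least one non-insular/non-insular and one insular/non-insular
#' divergence pair was measured. The two sides are assessed independently: a
#' unit may pass one and fail the other.
#'
#' The operation is idempotent: applying it to its own output changes
#' nothing.
#'
#' @param records A [record_set][as_record_set].
#' @return The filtered `record_set`, with two extra components:
#'   `inclusion` (tibble: unit_id, within, among) and `exclusions`
#'   (tibble: study_id, species, side, reason — one row per failed criterion).
#' @export
validate_inclusion <- function(records) {
  stopifnot(inherits(records, "record_set"))
  if (nrow(records$study_index) == 0) abort("Empty record set.")

  units <- records$study_index |>
    dplyr::group_by(.data$unit_id, .data$study_id, .data$species) |>
    dplyr::summarise(
      n_pop = dplyr::n(),
      n_insular = sum(.data$insular),
      n_non = sum(!.data$insular),
      .groups = "drop"
    )

  gd_cov <- records$gd |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      gd_ins = any(.data$insular),
      gd_non = any(!.data$insular),
      .groups = "drop"
    )

  div_cov <- pair_classes(records) |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      has_nn = any(.data$pair_class == "non_non"),
      has_in = any(.data$pair_class == "ins_non"),
      .groups = "drop"
    )

  units <- units |>
    dplyr::left_join(gd_cov, by = "unit_id") |>
    dplyr::left_join(div_cov, by = "unit_id") |>
    tidyr::replace_na(list(gd_ins = FALSE, gd_non = FALSE,
                           has_nn = FALSE, has_in = FALSE))

  roster_reasons <- function(u) {
    r <- character()
    if (u$n_pop < 3) r <- c(r, "fewer than three populations")
    if (u$n_insular < 1) r <- c(r, "no insular population")
    if (u$n_non < 2) r <- c(r, "fewer than two non-insular populations")
    r
  }

  exclusions <- purrr::map_dfr(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    base <- roster_reasons(u)
    within_r <- c(base,
                  if (!u$gd_non) "no GD measurement for non-insular populations",
                  if (!u$gd_ins) "no GD measurement for insular populations")
    among_r <- c(base,
                 if (!u$has_nn) "no non-insular/non-insular divergence pair",
                 if (!u$has_in) "no insular/non-insular divergence pair")
    dplyr::bind_rows(
      tibble::tibble(study_id = u$study_id, species = u$species,
                     side = "within", reason = within_r),
      tibble::tibble(study_id = u$study_id, species = u$species,
                     side = "among", reason = among_r)
    )
  })

  inclusion <- units |>
    dplyr::transmute(
      .data$unit_id,
      within = .data$n_pop >= 3 & .data$n_insular >= 1 & .data$n_non >= 2 &
        .data$gd_ins & .data$gd_non,
      among = .data$n_pop >= 3 & .data$n_insular >= 1 & .data$n_non >= 2 &
        .data$has_nn & .data$has_in
    )

  if (!any(inclusion$within) && !any(inclusion$among)) {
    abort(paste0(
      "All study units fail the inclusion criteria on both sides. Reasons: ",
      paste(unique(exclusions$reason), collapse = "; ")
    ))
  }

  keep_within <- inclusion$unit_id[inclusion$within]
  keep_among <- inclusion$unit_id[inclusion$among]
  out <- records
  out$gd <- records$gd[records$gd$unit_id %in% keep_within, ]
  out$divergence <- records$divergence[records$divergence$unit_id %in% keep_among, ]
  out$study_index <- records$study_index[
    records$study_index$unit_id %in% union(keep_within, keep_among), ]
  out$inclusion <- inclusion
  out$exclusions <- exclusions
  out
}

# Classify each divergence record by the insular flags of its two populations.
pair_classes <- function(records) {
  if (nrow(records$divergence) == 0) {
    return(tibble::tibble(records$divergence, pair_class = character(0)))
  }
  flags <- records$study_index |>
    dplyr::select("unit_id", "population_id", "insular")
  records$divergence |>
    dplyr::left_join(dplyr::rename(flags, population_id_a = "population_id",
                                   insular_a = "insular"),
                     by = c("unit_id", "population_id_a")) |>
    dplyr::left_join(dplyr::rename(flags, population_id_b = "population_id",
                                   insular_b = "insular"),
                     by = c("unit_id", "population_id_b")) |>
    dplyr::mutate(pair_class = dplyr::case_when(
      !.data$insular_a & !.data$insular_b ~ "non_non",
      .data$insular_a & .data$insular_b ~ "ins_ins",
      TRUE ~ "ins_non"
    ))
}

#' Write a record set to delimited files
#'
#' Writes `gd_records.csv`, `divergence_records.csv` (omitted when there are
#' no divergence records) and, when present, `exclusion_log.tsv` under `dir`.
#' Round trip: [read_records()] on the written files reproduces the record
#' set up to row order.
#'
#' @param records A [record_set][as_record_set].
#' @param dir Output directory; created if absent.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_records <- function(records, dir) {
  stopifnot(inherits(records, "record_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(gd = file.path(dir, "gd_records.csv"))
  readr::write_csv(dplyr::select(records$gd, -"unit_id"), paths[["gd"]])
  if (nrow(records$divergence) > 0) {
    paths[["divergence"]] <- file.path(dir, "divergence_records.csv")
    readr::write_csv(dplyr::select(records$divergence, -"unit_id"),
                     paths[["divergence"]])
  } else {
    inform("No divergence records; divergence_records.csv not written.")
  }
  paths[["roster"]] <- file.path(dir, "study_roster.csv")
  readr::write_csv(dplyr::select(records$study_index, -"unit_id"),
                   paths[["roster"]])
  if (!is.null(records$exclusions) && nrow(records$exclusions) > 0) {
    paths[["exclusions"]] <- file.path(dir, "exclusion_log.tsv")
    readr::write_tsv(records$exclusions, paths[["exclusions"]])
  }
  invisible(paths)
}
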