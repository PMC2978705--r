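# File-format plumbing: FASTA for peptides, CSV schemas for libraries,
# screens, isotherms and sensorgrams (comma-separated, UTF-8, header row,
# molar units in machine files), JSON for landscapes and reports, YAML or
# JSON for run configuration.

#' Read peptides from a FASTA file
#' @param path FASTA file (headers become names).
#' @param linker_length Fixed C-terminal linker length to assume.
#' @return Tibble with columns `name`, `sequence`.
#' @export
read_peptides_fasta <- function(path, linker_length = 3L) {
  set <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    name = names(set),
    sequence = unname(as.character(set)),
    linker_length = as.integer(linker_length)
  )
}

#' Write peptides to a FASTA file
#' @param peptides A [peptide()], a list of them, or a tibble with `name`
#'   and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptides_fasta <- function(peptides, path) {
  if (is_peptide(peptides)) peptides <- list(peptides)
  if (is.list(peptides) && !is.data.frame(peptides)) {
    peptides <- tibble::tibble(
      name = vapply(peptides, function(p) p$name, character(1)),
      sequence = vapply(peptides, function(p) p$residues, character(1))
    )
  }
  set <- Biostrings::AAStringSet(setNames(peptides$sequence, peptides$name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a variant library to CSV
#' @param library An [enumerate_variants()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_library_csv <- function(library, path) {
  readr::write_csv(library, path)
  invisible(path)
}

#' Read an isotherm CSV (columns conc_m, response_ru, replicate)
#' @param path CSV path.
#' @return Tibble with columns `conc`, `response`, `replicate`.
#' @export
read_isotherm_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("conc_m", "response_ru")
  if (!all(need %in% names(d))) {
    abort(sprintf("Isotherm CSV needs columns %s.", paste(need, collapse = ", ")))
  }
  tibble::tibble(
    conc = d$conc_m, response = d$response_ru,
    replicate = if ("replicate" %in% names(d)) d$replicate else 1L
  )
}

#' Write an isotherm CSV
#' @param data Tibble with `conc`, `response`, optionally `replicate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotherm_csv <- function(data, path) {
  readr::write_csv(tibble::tibble(
    conc_m = data$conc, response_ru = data$response,
    replicate = if ("replicate" %in% names(data)) data$replicate else 1L
  ), path)
  invisible(path)
}

#' Read a sensorgram CSV (columns time_s, response_ru, conc_m, phase)
#' @param path CSV path.
#' @return Tibble with columns `time`, `response`, `conc`, `phase`.
#' @export
read_sensorgram_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "response_ru", "conc_m", "phase")
  if (!all(need %in% names(d))) {
    abort(sprintf("Sensorgram CSV needs columns %s.", paste(need, collapse = ", ")))
  }
  if (!all(d$phase %in% c("assoc", "dissoc"))) {
    abort("Sensorgram `phase` must be 'assoc' or 'dissoc'.")
  }
  tibble::tibble(time = d$time_s, response = d$response_ru,
                 conc = d$conc_m, phase = d$phase)
}

#' Write a sensorgram CSV
#' @param data Tibble with `time`, `response`, `conc`, `phase`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensorgram_csv <- function(data, path) {
  readr::write_csv(tibble::tibble(
    time_s = data$time, response_ru = data$response,
    conc_m = data$conc, phase = data$phase
  ), path)
  invisible(path)
}

#' Write a screen table to CSV
#' @param screen A [simulate_screen()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(screen, path) {
  readr::write_csv(screen, path)
  invisible(path)
}

#' Read a screen table from CSV
#' @param path CSV path (schema of [write_screen_csv()]).
#' @return Screen tibble.
#' @export
read_screen_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("variant_code", "position", "sub", "mw_da", "is_lead", "replicate", "response")
  if (!all(need %in% names(d))) {
    abort(sprintf("Screen CSV needs columns %s.", paste(need, collapse = ", ")))
  }
  d
}

#' Serialize an energy landscape to JSON
#' @param landscape An [energy_landscape()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landscape_json <- function(landscape, path) {
  stopifnot(inherits(landscape, "energy_landscape"))
  obj <- list(
    lead = list(
      name = landscape$lead$name,
      residues = landscape$lead$residues,
      linker_length = landscape$lead$linker_length
    ),
    lead_dg = landscape$lead_dg,
    temperature = landscape$temperature,
    contributions = landscape$contributions,
    coupling = landscape$coupling
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an energy landscape from JSON
#' @param path JSON path written by [write_landscape_json()].
#' @return An [energy_landscape()].
#' @export
read_landscape_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  energy_landscape(
    peptide(obj$lead$residues, name = obj$lead$name,
            linker_length = obj$lead$linker_length),
    lead_dg = obj$lead_dg,
    contributions = tibble::as_tibble(obj$contributions),
    coupling = if (length(obj$coupling) && nrow(obj$coupling)) tibble::as_tibble(obj$coupling) else NULL,
    temperature = obj$temperature
  )
}

#' Export a heat map as a TSV matrix plus a long-form CSV
#' @param map A [fold_change_map()] result.
#' @param tsv_path Matrix TSV path (rows labeled wild+position).
#' @param csv_path Optional long-form CSV path.
#' @return `tsv_path`, invisibly.
#' @export
write_heat_map <- function(map, tsv_path, csv_path = NULL) {
  m <- heat_map_matrix(map)
  df <- data.frame(position = rownames(m), m, check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(df), tsv_path)
  if (!is.null(csv_path)) readr::write_csv(map$cells, csv_path)
  invisible(tsv_path)
}

#' Write an additive prediction as a JSON record
#' @param prediction An [combine_additive()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_json <- function(prediction, path) {
  stopifnot(inherits(prediction, "additive_prediction"))
  codes <- prediction$contributions$variant_code %||% character(0)
  obj <- list(
    variant_set = paste(codes, collapse = "+"),
    dg_pred_kcal_mol = prediction$dg_pred,
    se_pred = prediction$se_pred,
    kd_center_m = prediction$kd_center,
    kd_high_m = prediction$kd_high,
    kd_low_m = prediction$kd_low,
    temperature_k = prediction$temperature
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an additivity report as JSON
#' @param report An [assess_additivity()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_additivity_json <- function(report, path) {
  stopifnot(inherits(report, "additivity_report"))
  obj <- list(
    pairs = report$pairs,
    slope_ols = report$slope_ols,
    slope_origin = report$slope_origin,
    deviation_threshold = report$deviation_threshold
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' The file holds any subset of the [optimization_config()] fields plus
#' optionally `lead` (a sequence string or `{name, residues,
#' linker_length}`) and `seed`. Unknown fields are an error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return List with elements `config` ([optimization_config()]), `lead`
#'   (a [peptide()] or `NULL`) and `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file '%s' does not exist.", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  lead <- NULL
  if (!is.null(raw$lead)) {
    lead <- if (is.character(raw$lead) && length(raw$lead) == 1L) {
      if (raw$lead %in% c("TNF1", "TNF4", "TRF26")) lead_peptide(raw$lead)
      else peptide(raw$lead)
    } else {
      peptide(raw$lead$residues, name = raw$lead$name %||% "lead",
              linker_length = raw$lead$linker_length %||% 3L)
    }
  }
  seed <- raw$seed
  cfg_fields <- setdiff(names(raw), c("lead", "seed"))
  known <- names(formals(optimization_config))
  unknown <- setdiff(cfg_fields, known)
  if (length(unknown)) {
    abort(sprintf("Unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  config <- do.call(optimization_config, raw[cfg_fields])
  list(config = config, lead = lead, seed = seed)
}
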