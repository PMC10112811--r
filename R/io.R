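# Canonical dataset schema: columns species, mass_kg, speed_m_s, mode,
# realm; UTF-8 CSV with a header row and "." decimal separator. A
# column_map adapts files with other headers or units onto this schema.

mass_factors <- c(kg = 1, g = 1e-3, mg = 1e-6, t = 1e3, tonne = 1e3, lb = 0.45359237)
speed_factors <- c("m/s" = 1, "m s-1" = 1, "km/h" = 1 / 3.6, "cm/s" = 0.01,
                   "km/d" = 1000 / 86400, "mph" = 0.44704)

#' Map a source file onto the canonical record schema
#'
#' Declares which source columns hold the canonical fields and what units
#' mass and speed are recorded in. `species`, `mass`, `speed` and `mode`
#' are mandatory; `realm` is optional and defaults from the mode.
#'
#' @param species,mass,speed,mode,realm Source column names.
#' @param mass_unit One of `"kg"`, `"g"`, `"mg"`, `"t"`, `"tonne"`, `"lb"`.
#' @param speed_unit One of `"m/s"`, `"m s-1"`, `"km/h"`, `"cm/s"`,
#'   `"km/d"`, `"mph"`.
#' @return A `column_map` object.
#' @export
column_map <- function(species = "species", mass = "mass_kg",
                       speed = "speed_m_s", mode = "mode", realm = "realm",
                       mass_unit = "kg", speed_unit = "m/s") {
  if (!mass_unit %in% names(mass_factors)) {
    abort_config(paste0(
      "Unknown mass unit '", mass_unit, "'; known: ",
      paste(names(mass_factors), collapse = ", "), "."
    ))
  }
  if (!speed_unit %in% names(speed_factors)) {
    abort_config(paste0(
      "Unknown speed unit '", speed_unit, "'; known: ",
      paste(names(speed_factors), collapse = ", "), "."
    ))
  }
  structure(
    list(species = species, mass = mass, speed = speed, mode = mode,
         realm = realm, mass_unit = mass_unit, speed_unit = speed_unit),
    class = "column_map"
  )
}

# validate a data frame of records already on the canonical schema; used by
# the reader, the fitting machinery and the writer
as_speed_records <- function(data, require_species = TRUE) {
  if (!is.data.frame(data)) abort_validation("Records must be a data frame.")
  need <- c(if (require_species) "species", "mass_kg", "speed_m_s", "mode")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort_validation(paste0(
      "Missing mandatory column(s): ", paste(miss, collapse = ", "), "."
    ))
  }
  data <- tibble::as_tibble(data)
  if (!"species" %in% names(data)) data$species <- NA_character_
  if (!"realm" %in% names(data) || all(is.na(data$realm))) {
    data$realm <- default_realm(data$mode)
  } else {
    data$realm <- ifelse(is.na(data$realm), default_realm(data$mode), data$realm)
  }
  probs <- record_problems(data)
  if (nrow(probs)) {
    abort_validation(paste0(
      "Invalid record(s):\n", format_problems(probs)
    ), problems = probs)
  }
  data[c("species", "mass_kg", "speed_m_s", "mode", "realm")]
}

record_problems <- function(data) {
  p <- list()
  bad_mass <- which(!is.finite(data$mass_kg) | data$mass_kg <= 0)
  if (length(bad_mass)) {
    p$mass <- tibble::tibble(
      row = bad_mass, column = "mass_kg",
      value = as.character(data$mass_kg[bad_mass]),
      reason = "mass must be a positive number (kg)"
    )
  }
  bad_speed <- which(!is.finite(data$speed_m_s) | data$speed_m_s <= 0)
  if (length(bad_speed)) {
    p$speed <- tibble::tibble(
      row = bad_speed, column = "speed_m_s",
      value = as.character(data$speed_m_s[bad_speed]),
      reason = "speed must be a positive number (m/s)"
    )
  }
  bad_mode <- which(is.na(data$mode) | !data$mode %in% speed_modes())
  if (length(bad_mode)) {
    p$mode <- tibble::tibble(
      row = bad_mode, column = "mode",
      value = as.character(data$mode[bad_mode]),
      reason = paste0("unknown locomotion mode (expected ",
                      paste(speed_modes(), collapse = "/"), ")")
    )
  }
  bad_realm <- which(!is.na(data$realm) & !data$realm %in% speed_realms())
  if (length(bad_realm)) {
    p$realm <- tibble::tibble(
      row = bad_realm, column = "realm",
      value = as.character(data$realm[bad_realm]),
      reason = paste0("unknown realm (expected ",
                      paste(speed_realms(), collapse = "/"), ")")
    )
  }
  out <- dplyr::bind_rows(p)
  if (!nrow(out)) {
    tibble::tibble(row = integer(), column = character(),
                   value = character(), reason = character())
  } else {
    dplyr::arrange(out, .data$row)
  }
}

format_problems <- function(probs, max_rows = 10) {
  shown <- utils::head(probs, max_rows)
  lines <- sprintf("  row %d, %s = '%s': %s",
                   shown$row, shown$column, shown$value, shown$reason)
  extra <- nrow(probs) - nrow(shown)
  paste(c(lines, if (extra > 0) sprintf("  ... and %d more", extra)),
        collapse = "\n")
}

#' Read a travel-speed dataset from CSV
#'
#' Reads a CSV of species-level speed records, maps it onto the canonical
#' schema via a [column_map()], converts mass and speed to kg and m/s, and
#' validates every row (positive mass and speed, known locomotion mode and
#' realm). Row numbers in diagnostics refer to data rows of the file
#' (excluding the header). Malformed rows either abort with a row-numbered
#' error (`malformed = "error"`, the default) or are dropped with a warning
#' and recorded in the `"problems"` attribute (`malformed = "drop"`), so
#' every input row is accounted for either as a record or as a diagnostic.
#'
#' @param path Path to a CSV file.
#' @param map A [column_map()] describing the file's columns and units.
#' @param malformed `"error"` or `"drop"`.
#' @return A tibble of validated records on the canonical schema.
#' @export
read_speed_data <- function(path, map = column_map(),
                            malformed = c("error", "drop")) {
  malformed <- match.arg(malformed)
  if (!inherits(map, "column_map")) abort_config("`map` must be a `column_map`.")
  if (!file.exists(path)) abort_config(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- unlist(map[c("species", "mass", "speed", "mode")])
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort_validation(paste0(
      "Mapped column(s) absent from ", path, ": ",
      paste(miss, collapse = ", "), "."
    ))
  }
  data <- tibble::tibble(
    species = as.character(raw[[map$species]]),
    mass_kg = suppressWarnings(as.numeric(raw[[map$mass]])) *
      mass_factors[[map$mass_unit]],
    speed_m_s = suppressWarnings(as.numeric(raw[[map$speed]])) *
      speed_factors[[map$speed_unit]],
    mode = tolower(trimws(as.character(raw[[map$mode]]))),
    realm = if (map$realm %in% names(raw)) {
      tolower(trimws(as.character(raw[[map$realm]])))
    } else {
      NA_character_
    }
  )
  data$realm <- ifelse(is.na(data$realm), default_realm(data$mode), data$realm)
  probs <- record_problems(data)
  if (nrow(probs)) {
    if (malformed == "error") {
      abort_validation(paste0(
        "Invalid record(s) in ", path, ":\n", format_problems(probs)
      ), problems = probs)
    }
    warn(paste0(
      nrow(probs), " problem(s) in ", path, "; offending rows dropped:\n",
      format_problems(probs)
    ))
    data <- data[-unique(probs$row), , drop = FALSE]
  }
  attr(data, "problems") <- probs
  data
}

#' Write records to the canonical CSV schema
#'
#' @param data A data frame of speed records.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_speed_data <- function(data, path) {
  data <- as_speed_records(data)
  readr::write_csv(data, path)
  invisible(data)
}

#' Aggregate individual records to species level
#'
#' Collapses within-species replicates to one record per species using the
#' unweighted geometric mean of individual speeds (and of individual masses
#' where present). On the log10 scale the geometric mean is the arithmetic
#' mean, matching the Gaussian log10-speed data model. A species observed
#' under more than one locomotion mode is an error.
#'
#' @param data A data frame of speed records (canonical schema).
#' @return A tibble with one record per species plus an `n_obs` count.
#' @examples
#' aggregate_species(tibble::tibble(
#'   species = c("a", "a"), mass_kg = c(1, 4), speed_m_s = c(2, 8),
#'   mode = "running"
#' ))
#' @export
aggregate_species <- function(data) {
  data <- as_speed_records(data)
  mixed <- data |>
    dplyr::summarise(n_modes = dplyr::n_distinct(.data$mode), .by = "species") |>
    dplyr::filter(.data$n_modes > 1)
  if (nrow(mixed)) {
    abort_config(paste0(
      "Mixed locomotion modes within species: ",
      paste(mixed$species, collapse = ", "), "."
    ))
  }
  data |>
    dplyr::summarise(
      mass_kg = exp(mean(log(.data$mass_kg))),
      speed_m_s = exp(mean(log(.data$speed_m_s))),
      mode = .data$mode[1],
      realm = .data$realm[1],
      n_obs = dplyr::n(),
      .by = "species"
    )
}
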