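# CSV readers/writers for the external interfaces. Everything in this
# domain is small tabular data; plain CSV plus a JSON summary.

.read_csv_checked <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty ", what, " file: ", path)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " file ", path, " missing columns: ",
         paste(miss, collapse = ", "))
  }
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (anyNA(v)) {
      row <- if (length(bad)) bad[1] else which(is.na(v))[1]
      stop("malformed ", what, " file ", path, ": non-numeric or missing '",
           col, "' at row ", row)
    }
    df[[col]] <- v
  }
  df
}

#' Read the pipeline's CSV inputs
#'
#' `read_titration_csv()` expects one row per trap reading with columns
#' `microcosm_id, day, blank_volume_ml, sample_volume_ml, normality`; the
#' pre-converted alternative `read_co2_csv()` expects
#' `microcosm_id, day, co2_mg`. `read_metadata_csv()` expects
#' `microcosm_id, fuel, fuel_mass_mg, soil_mass_g, n_added_mg, setup,
#' replicate, temperature_c`, and `read_endpoint_csv()` expects
#' `microcosm_id, dro_measured_mg, surrogate_recovery, n_final_mg`.
#' Malformed rows raise an error naming the row.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_titration_csv <- function(path) {
  .read_csv_checked(
    path,
    required = c("microcosm_id", "day", "blank_volume_ml",
                 "sample_volume_ml", "normality"),
    numeric_cols = c("day", "blank_volume_ml", "sample_volume_ml",
                     "normality"),
    what = "titration"
  )
}

#' @rdname read_titration_csv
#' @export
read_co2_csv <- function(path) {
  .read_csv_checked(path,
                    required = c("microcosm_id", "day", "co2_mg"),
                    numeric_cols = c("day", "co2_mg"),
                    what = "CO2")
}

#' @rdname read_titration_csv
#' @export
read_metadata_csv <- function(path) {
  df <- .read_csv_checked(
    path,
    required = c("microcosm_id", "fuel", "fuel_mass_mg", "soil_mass_g",
                 "n_added_mg", "setup", "replicate", "temperature_c"),
    numeric_cols = c("fuel_mass_mg", "soil_mass_g", "n_added_mg",
                     "replicate", "temperature_c"),
    what = "metadata"
  )
  bad <- !(toupper(df$fuel) %in% fuel_levels())
  if (any(bad)) {
    stop("metadata file ", path, ": unknown fuel '", df$fuel[which(bad)[1]],
         "' at row ", which(bad)[1])
  }
  bad <- !(toupper(df$setup) %in% setup_levels())
  if (any(bad)) {
    stop("metadata file ", path, ": unknown setup '",
         df$setup[which(bad)[1]], "' at row ", which(bad)[1])
  }
  if (anyDuplicated(df$microcosm_id)) {
    stop("metadata file ", path, ": duplicate microcosm_id '",
         df$microcosm_id[anyDuplicated(df$microcosm_id)], "'")
  }
  df
}

#' @rdname read_titration_csv
#' @export
read_endpoint_csv <- function(path) {
  .read_csv_checked(
    path,
    required = c("microcosm_id", "dro_measured_mg", "surrogate_recovery",
                 "n_final_mg"),
    numeric_cols = c("dro_measured_mg", "surrogate_recovery", "n_final_mg"),
    what = "endpoint"
  )
}

# Accept either a path or an already-read data frame.
.as_table <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else as.data.frame(x)
}
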