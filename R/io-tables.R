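#' Read a labelled-cell table
#'
#' Cells are stored as comma-delimited UTF-8 text with a mandatory header
#' `animal_id, group, tracer, x_um, y_um, z_um`. Coordinates are micrometres
#' in the group standardized space and are taken as read (no rescaling).
#' `group` must be one of `WT`, `P6`, `P12`, `B2KO` and `tracer` one of
#' `red`, `green`; any other value is a parse error naming the offending
#' file line (header = line 1).
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per cell, in file order.
#' @seealso [write_cells()], [read_injections()]
#' @export
read_cells <- function(path) {
  df <- read_delim_checked(path, c("animal_id", "group", "tracer", "x_um", "y_um", "z_um"))
  check_enum(df$group, group_levels(), "group", path)
  check_enum(df$tracer, tracer_levels(), "tracer", path)
  for (col in c("x_um", "y_um", "z_um")) {
    df[[col]] <- check_finite_col(df[[col]], col, path)
  }
  df$animal_id <- as.character(df$animal_id)
  as_tibble(df)
}

#' Write a labelled-cell table
#'
#' Inverse of [read_cells()]; `write_cells()` then [read_cells()] reproduces
#' the table exactly.
#'
#' @param cells Tibble as returned by [read_cells()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path) {
  need <- c("animal_id", "group", "tracer", "x_um", "y_um", "z_um")
  if (!all(need %in% names(cells))) {
    abort(paste0("cells table missing column(s): ",
                 paste(setdiff(need, names(cells)), collapse = ", ")))
  }
  readr::write_csv(cells[need], path)
  invisible(path)
}

#' Read a V1 injection-site table
#'
#' One record per animal with columns `animal_id, ap_mm, ml_mm` and an
#' optional `volume_nl`. Anterior-posterior and medio-lateral positions are
#' millimetres relative to lambda (cortical convention), deliberately a
#' different unit from the micrometre nucleus space.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per animal.
#' @export
read_injections <- function(path) {
  df <- read_delim_checked(path, c("animal_id", "ap_mm", "ml_mm"))
  df$animal_id <- as.character(df$animal_id)
  df$ap_mm <- check_finite_col(df$ap_mm, "ap_mm", path)
  df$ml_mm <- check_finite_col(df$ml_mm, "ml_mm", path)
  if (anyDuplicated(df$animal_id)) {
    dup <- unique(df$animal_id[duplicated(df$animal_id)])
    abort(paste0("duplicate injection record(s) for animal(s): ",
                 paste(dup, collapse = ", ")))
  }
  if (!"volume_nl" %in% names(df)) df$volume_nl <- NA_real_
  as_tibble(df[c("animal_id", "ap_mm", "ml_mm", "volume_nl")])
}

#' Write a V1 injection-site table
#'
#' @param injections Tibble as returned by [read_injections()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_injections <- function(injections, path) {
  need <- c("animal_id", "ap_mm", "ml_mm")
  if (!all(need %in% names(injections))) {
    abort(paste0("injections table missing column(s): ",
                 paste(setdiff(need, names(injections)), collapse = ", ")))
  }
  cols <- c(need, intersect("volume_nl", names(injections)))
  readr::write_csv(injections[cols], path)
  invisible(path)
}

# -- internal parse helpers ---------------------------------------------------

read_delim_checked <- function(path, required) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal"),
    error = function(e) abort(paste0("cannot parse ", path, ": ", conditionMessage(e)))
  )
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("parse error in ", path, ": missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  prob <- readr::problems(df)
  if (nrow(prob)) {
    abort(paste0("parse error in ", path, " at line ", prob$row[1] + 1L,
                 ": expected ", prob$expected[1], ", got '", prob$actual[1], "'"))
  }
  df
}

check_enum <- function(values, levels, col, path) {
  bad <- which(!(values %in% levels))
  if (length(bad)) {
    abort(paste0("parse error in ", path, " at line ", bad[1] + 1L, ": ", col,
                 " '", values[bad[1]], "' is not one of {",
                 paste(levels, collapse = ", "), "}"))
  }
  invisible(TRUE)
}

# Coerces to numeric, flagging the first unparseable or non-finite entry by
# its file line (header is line 1).
check_finite_col <- function(values, col, path) {
  num <- suppressWarnings(as.numeric(values))
  bad <- which(!is.finite(num))
  if (length(bad)) {
    abort(paste0("parse error in ", path, " at line ", bad[1] + 1L,
                 ": non-finite or non-numeric ", col, " '", values[bad[1]], "'"))
  }
  num
}
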