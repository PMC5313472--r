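# Canonical herd-recording schema: one row per cow per test day.
# Units: milk kg/day; fat, protein percent; SCC x1000 cells/mL; dim, dim_p days.

.fapr_schema <- list(
  herd_id     = "character",
  cow_id      = "character",
  test_date   = "Date",
  parity      = "integer",
  dim         = "integer",
  milk_kg     = "double",
  fat_pct     = "double",
  protein_pct = "double",
  scc         = "double",
  pregnant    = "logical",
  dim_p       = "integer",   # day of conception in DIM units, NA when open
  dam_id      = "character"  # optional
)

.fapr_mandatory <- setdiff(names(.fapr_schema), "dam_id")

#' Canonical column names of the herd-recording schema
#'
#' @return Character vector of the canonical column names.
#' @export
herd_record_columns <- function() names(.fapr_schema)

#' Read a herd-recording table
#'
#' Reads a delimited text export of milk-recording data into the canonical
#' schema.  National recording exports differ in column naming; a column
#' mapping (named list or YAML file, `canonical = source` pairs) adapts any
#' delimited file without editing it.  Rows failing type or range validation
#' are not silently dropped: they are collected into a rejects report
#' attached as the `"rejects"` attribute (and optionally written to a
#' side-car file).
#'
#' @param path Path to a delimited text file.
#' @param mapping Optional named list mapping canonical names to source
#'   column names, or path to a YAML file with a `columns:` section.
#' @param delim Field delimiter (default `","`).
#' @param rejects_path Optional path; when given, rejected rows are written
#'   there as CSV with a `reason` column.
#' @return A tibble in the canonical schema, ordered by
#'   (herd_id, cow_id, test_date), with attribute `"rejects"` holding a
#'   tibble of rejected source rows (row number + reason).
#' @export
read_herd_records <- function(path, mapping = NULL, delim = ",",
                              rejects_path = NULL) {
  if (!file.exists(path)) {
    abort(paste0("read_herd_records(): file not found: ", path),
          class = "fapr_config_error")
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  map <- .resolve_mapping(mapping)
  for (canon in names(map)) {
    src <- map[[canon]]
    if (!src %in% names(raw)) {
      abort(paste0("read_herd_records(): mapped source column '", src,
                   "' (for '", canon, "') not present in file."),
            class = "fapr_config_error")
    }
    names(raw)[names(raw) == src] <- canon
  }
  missing <- setdiff(.fapr_mandatory, names(raw))
  if (length(missing) > 0) {
    abort(paste0("read_herd_records(): mandatory column(s) missing: ",
                 paste(missing, collapse = ", ")),
          class = "fapr_config_error")
  }
  if (!"dam_id" %in% names(raw)) raw$dam_id <- NA_character_
  parsed <- .parse_records(raw)
  out <- validate_herd_records(parsed$records)
  rejects <- bind_rows(parsed$rejects, attr(out, "rejects"))
  if (!is.null(rejects_path) && nrow(rejects) > 0) {
    readr::write_csv(rejects, rejects_path)
  }
  attr(out, "rejects") <- rejects
  out
}

.resolve_mapping <- function(mapping) {
  if (is.null(mapping)) return(list())
  if (is.character(mapping) && length(mapping) == 1) {
    cfg <- yaml::read_yaml(mapping)
    mapping <- cfg$columns %||% cfg
  }
  if (!is.list(mapping) || is.null(names(mapping))) {
    abort("read_herd_records(): mapping must be a named list or YAML path.",
          class = "fapr_config_error")
  }
  unknown <- setdiff(names(mapping), names(.fapr_schema))
  if (length(unknown) > 0) {
    abort(paste0("read_herd_records(): unknown canonical column(s) in ",
                 "mapping: ", paste(unknown, collapse = ", ")),
          class = "fapr_config_error")
  }
  mapping
}

.parse_records <- function(raw) {
  suppress_num <- function(x) suppressWarnings(as.numeric(x))
  parsed <- tibble(
    herd_id     = as.character(raw$herd_id),
    cow_id      = as.character(raw$cow_id),
    test_date   = as.Date(raw$test_date),
    parity      = suppressWarnings(as.integer(raw$parity)),
    dim         = suppressWarnings(as.integer(raw$dim)),
    milk_kg     = suppress_num(raw$milk_kg),
    fat_pct     = suppress_num(raw$fat_pct),
    protein_pct = suppress_num(raw$protein_pct),
    scc         = suppress_num(raw$scc),
    pregnant    = as.logical(raw$pregnant),
    dim_p       = suppressWarnings(as.integer(raw$dim_p)),
    dam_id      = as.character(raw$dam_id)
  )
  bad_type <- !complete.cases(parsed[, setdiff(.fapr_mandatory, "dim_p")])
  rejects <- tibble(row = which(bad_type),
                    reason = "unparseable or missing mandatory field")
  list(records = parsed[!bad_type, ], rejects = rejects)
}

#' Validate records against the canonical schema's range rules
#'
#' Range rules: parity >= 1, dim >= 0, milk/fat/protein/scc >= 0,
#' `dim_p <= dim` and present whenever `pregnant`, absent otherwise.  SCC
#' rows without a usable milk weight are rejected (the total-cell model
#' needs both).
#'
#' @param records A tibble in the canonical schema.
#' @return The valid rows, sorted by (herd_id, cow_id, test_date), with a
#'   `"rejects"` attribute listing failed rows and reasons.
#' @export
validate_herd_records <- function(records) {
  r <- records
  reason <- rep(NA_character_, nrow(r))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- flag(r$parity < 1, "parity < 1")
  reason <- flag(r$dim < 0, "negative dim")
  reason <- flag(r$milk_kg < 0 | r$fat_pct < 0 | r$protein_pct < 0 |
                   r$scc < 0, "negative measurement")
  reason <- flag(r$pregnant & (is.na(r$dim_p) | r$dim_p > r$dim),
                 "pregnant without valid dim_p <= dim")
  ok <- is.na(reason)
  rejects <- tibble(row = which(!ok), reason = reason[!ok])
  out <- r[ok, ] %>%
    mutate(dim_p = ifelse(.data$pregnant, .data$dim_p, NA_integer_)) %>%
    arrange(.data$herd_id, .data$cow_id, .data$test_date)
  attr(out, "rejects") <- rejects
  out
}

#' Write a herd-recording table
#'
#' Writes the canonical schema as delimited text; a read of the written file
#' reproduces the records exactly.
#'
#' @param records A tibble in the canonical schema.
#' @param path Output path.
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_herd_records <- function(records, path, delim = ",") {
  readr::write_delim(records[, names(.fapr_schema)], path, delim = delim)
  invisible(path)
}

#' Backdate pregnancy status within each lactation
#'
#' A positive pregnancy test assigns the conception day retroactively (the
#' previous insemination), so in a retrospective training extract every
#' record of the lactation from the conception day onward is known to be
#' pregnant - including test days before the pregnancy was recognised.
#' Used when fitting; prediction-time records keep their as-of-that-day
#' status.
#'
#' @param records Canonical records tibble.
#' @return `records` with `pregnant`/`dim_p` backdated per cow-lactation.
#' @export
backdate_pregnancy <- function(records) {
  records %>%
    group_by(.data$herd_id, .data$cow_id, .data$parity) %>%
    mutate(
      .conc = if (any(.data$pregnant, na.rm = TRUE))
        max(.data$dim_p[.data$pregnant], na.rm = TRUE) else NA_integer_,
      pregnant = !is.na(.data$.conc) & .data$dim >= .data$.conc,
      dim_p = ifelse(.data$pregnant, .data$.conc, NA_integer_)
    ) %>%
    select(-".conc") %>%
    ungroup()
}

#' Flag cow-lactations with enough test days to fit an individual level
#'
#' A per-cow level is only estimated from at least `min_points` milk
#' recordings in the lactation; thinner lactations keep their records but
#' are flagged, and their level defaults to 1 (or a dam-derived value)
#' downstream.  No record is ever dropped here.
#'
#' @param records Canonical records tibble.
#' @param min_points Minimum milk recordings per cow-lactation (default 6).
#' @return `records` with a logical `fittable` column (constant within each
#'   cow-lactation).
#' @export
filter_fittable <- function(records, min_points = 6) {
  if (nrow(records) == 0) {
    return(mutate(records, fittable = logical(0)))
  }
  records %>%
    group_by(.data$herd_id, .data$cow_id, .data$parity) %>%
    mutate(fittable = sum(.data$milk_kg > 0) >= min_points) %>%
    ungroup()
}
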