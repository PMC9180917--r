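# CITES Trade Database CSV dialect:
#   Year, App., Taxon, Class, Order, Family, Genus, Importer, Exporter, Origin,
#   Importer reported quantity, Exporter reported quantity, Term, Unit,
#   Purpose, Source
# Internally records use snake_case names; a blank Unit means whole organisms.

.cites_columns <- c(
  year = "year", taxon = "taxon", class = "taxon_class",
  importer = "importer", exporter = "exporter", origin = "origin",
  importerreportedquantity = "importer_qty",
  exporterreportedquantity = "exporter_qty",
  term = "term", unit = "unit", purpose = "purpose", source = "source")

.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read trade records in the CITES Trade Database CSV dialect
#'
#' Header matching is case-insensitive and whitespace/punctuation tolerant
#' (so `"Importer reported quantity"`, `"importer_reported_quantity"` and
#' `"Importer.reported.quantity"` all match). Blank quantity cells become
#' missing values, never zero. Rows with a non-numeric quantity cell, an
#' unusable year, or no quantity on either side are dropped; the number of
#' dropped rows is reported in a message and stored in the `dropped_rows`
#' attribute.
#'
#' @param path path to a CSV file.
#' @return a `trade_records` data frame with columns `year`, `taxon`,
#'   `taxon_class`, `importer`, `exporter`, `origin`, `importer_qty`,
#'   `exporter_qty`, `term`, `unit`, `purpose`, `source`; attributes
#'   `provenance` (the path) and `dropped_rows`.
#' @export
read_trade_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read trade file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  hdr <- .norm_header(names(raw))
  missing_cols <- setdiff(names(.cites_columns), hdr)
  if (length(missing_cols) > 0L) {
    stop("trade CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    lapply(names(.cites_columns),
                           function(cn) raw[[match(cn, hdr)]]))
  names(out) <- unname(.cites_columns)

  num <- function(x) {
    x <- trimws(x)
    v <- suppressWarnings(as.numeric(x))
    v[x == "" | is.na(x)] <- NA_real_
    list(value = v, malformed = !is.na(x) & x != "" & is.na(v))
  }
  iq <- num(out$importer_qty); eq <- num(out$exporter_qty); yr <- num(out$year)
  out$importer_qty <- iq$value
  out$exporter_qty <- eq$value
  out$year <- as.integer(round(yr$value))
  bad <- iq$malformed | eq$malformed | yr$malformed |
    is.na(out$year) | out$year <= 1900L |
    (is.na(out$importer_qty) & is.na(out$exporter_qty)) |
    (!is.na(out$importer_qty) & out$importer_qty < 0) |
    (!is.na(out$exporter_qty) & out$exporter_qty < 0)
  if (any(bad)) {
    message(sum(bad), " malformed row(s) dropped while reading ", basename(path))
  }
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  for (cc in c("importer", "exporter", "origin")) out[[cc]] <- toupper(trimws(out[[cc]]))
  structure(out, provenance = path, dropped_rows = sum(bad),
            class = c("trade_records", "data.frame"))
}

#' Write trade records in the CITES CSV dialect
#'
#' Inverse of [read_trade_csv()] for well-formed records; the taxonomy columns
#' not carried internally (`App.`, `Order`, `Family`, `Genus`) are emitted as
#' placeholders consistent with a CITES-listed parrot.
#'
#' @param records a `trade_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trade_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- data.frame(
    `Year` = records$year, `App.` = "II", `Taxon` = records$taxon,
    `Class` = records$taxon_class, `Order` = "Psittaciformes",
    `Family` = "Psittacidae", `Genus` = sub(" .*", "", records$taxon),
    `Importer` = records$importer, `Exporter` = records$exporter,
    `Origin` = records$origin,
    `Importer reported quantity` = records$importer_qty,
    `Exporter reported quantity` = records$exporter_qty,
    `Term` = records$term, `Unit` = records$unit,
    `Purpose` = records$purpose, `Source` = records$source,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Keep wild-sourced live whole birds inside a year window
#'
#' Applies the study filter: class Aves, term "live", source "W" (wild
#' caught), blank unit (whole organisms, not kg or parts), and year inside the
#' closed interval `period`. Filtering preserves record order and is
#' idempotent.
#'
#' @param records a `trade_records` data frame.
#' @param period integer length-2, `c(year_lo, year_hi)` closed interval, e.g.
#'   `c(1995, 2005)` for the years before the EU wild-bird ban.
#' @return the filtered `trade_records`, with a `period` attribute.
#' @export
filter_wild_live_birds <- function(records, period) {
  stopifnot(is.data.frame(records), length(period) == 2L, is.numeric(period))
  if (period[1] > period[2]) stop("period lower bound exceeds upper bound", call. = FALSE)
  keep <- tolower(trimws(records$taxon_class)) == "aves" &
    tolower(trimws(records$term)) == "live" &
    toupper(trimws(records$source)) == "W" &
    (is.na(records$unit) | trimws(records$unit) == "") &
    !is.na(records$year) & records$year >= period[1] & records$year <= period[2]
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = attr(records, "provenance"),
            period = as.integer(period),
            class = c("trade_records", "data.frame"))
}

#' Aggregate reconciled per-country trade totals
#'
#' Each record's reconciled quantity is the maximum of the importer- and
#' exporter-reported values (over the values present), a convention that
#' mitigates one-sided under-reporting in CITES data. The reconciled quantity
#' is added to the exporter's `total_exported` and the importer's
#' `total_imported`, except that records with an origin country different
#' from the exporter are treated as re-exports: the re-exporting country gets
#' no supply credit, while the importer is still credited.
#'
#' @param records filtered `trade_records`.
#' @return data frame with columns `country`, `total_exported`,
#'   `total_imported` (zero where a country appears on one side only).
#' @export
aggregate_totals <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    return(data.frame(country = character(), total_exported = numeric(),
                      total_imported = numeric(), stringsAsFactors = FALSE))
  }
  qty <- pmax(records$importer_qty, records$exporter_qty, na.rm = TRUE)
  reexport <- !is.na(records$origin) & trimws(records$origin) != "" &
    records$origin != records$exporter
  countries <- sort(unique(c(records$exporter, records$importer)))
  exp_ok <- !reexport
  te <- rowsum(qty[exp_ok], records$exporter[exp_ok])
  ti <- rowsum(qty, records$importer)
  out <- data.frame(country = countries,
                    total_exported = as.numeric(te[match(countries, rownames(te))]),
                    total_imported = as.numeric(ti[match(countries, rownames(ti))]),
                    stringsAsFactors = FALSE)
  out$total_exported[is.na(out$total_exported)] <- 0
  out$total_imported[is.na(out$total_imported)] <- 0
  out
}

#' Read the country covariate table
#'
#' Expects columns `country`, `period`, `rule_of_law`, `import_tariff`,
#' `export_cost`. Higher `rule_of_law` means stronger enforcement; higher
#' tariff/cost means stronger trade barriers. Duplicate (country, period)
#' keys are a data error.
#'
#' @param path path to a covariate CSV.
#' @return a data frame keyed by (country, period).
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("cannot read covariate file: ", path, call. = FALSE)
  cov <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("country", "period", "rule_of_law", "import_tariff", "export_cost")
  missing_cols <- setdiff(needed, names(cov))
  if (length(missing_cols) > 0L) {
    stop("covariate CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- paste(cov$country, cov$period, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicated (country, period) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  for (cc in c("rule_of_law", "import_tariff", "export_cost")) {
    if (!is.numeric(cov[[cc]]) || any(!is.finite(cov[[cc]]))) {
      stop("covariate column ", cc, " must be finite numeric", call. = FALSE)
    }
  }
  cov$country <- toupper(trimws(cov$country))
  cov[needed]
}

#' Write a covariate table as CSV
#' @param covariates covariate data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariate_csv <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}
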