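# Tabular input/output: OTU count tables, ranked taxonomies, trophic rule
# tables, environmental records, plus date/season handling.
#
# Conventions: all tables are tab-separated UTF-8; dates are ISO-8601
# (YYYY-MM-DD, day resolution); missing values are the literal "NA".
# OTU tables are stored with OTUs as rows and samples as columns (the common
# amplicon convention); a `transpose` flag accommodates the other layout.

#' Construct an OTU count table
#'
#' The central container of the package: a non-negative integer count matrix
#' (OTUs as rows, samples as columns) together with one calendar date per
#' sample. Sample order must follow the dates (non-decreasing).
#'
#' @param counts integer matrix, OTUs x samples, with row and column names.
#' @param sample_dates `Date` vector, one per sample (column), sorted
#'   non-decreasing.
#' @return an object of class `otu_table`: a list with elements `counts`
#'   (integer matrix), `sample_dates` (Date), plus accessors via `$`.
#' @export
#' @examples
#' tab <- otu_table(matrix(c(3L, 1L, 0L, 6L), 2,
#'                         dimnames = list(c("otu1", "otu2"), c("s1", "s2"))),
#'                  as.Date(c("2016-03-18", "2016-03-21")))
#' otu_grand_total(tab)
otu_table <- function(counts, sample_dates) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_validation("counts must have OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop_validation("duplicate OTU ids: ",
                    paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_validation("duplicate sample ids: ",
                    paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop_validation("counts must be numeric with no missing values")
  if (any(counts < 0))
    stop_validation("negative counts are not allowed")
  if (!all(is_wholenumber(counts)))
    stop_validation("counts must be whole numbers")
  storage.mode(counts) <- "integer"
  sample_dates <- as.Date(sample_dates)
  if (length(sample_dates) != ncol(counts) || anyNA(sample_dates))
    stop_validation("need one valid date per sample")
  if (is.unsorted(sample_dates))
    stop_validation("sample columns must be ordered by non-decreasing date")
  if (ncol(counts) > 0 && nrow(counts) > 0 && sum(counts) == 0)
    stop_validation("grand total of a non-empty table must be positive")
  structure(list(counts = counts, sample_dates = sample_dates),
            class = "otu_table")
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
otu_ids <- function(x) rownames(x$counts)

#' @rdname otu_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname otu_table
#' @export
otu_grand_total <- function(x) sum(as.numeric(x$counts))

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(otu_grand_total(x), big.mark = ",")))
  if (ncol(x$counts) > 0)
    cat(sprintf("  dates %s .. %s\n", min(x$sample_dates), max(x$sample_dates)))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Read / write an OTU count table
#'
#' Tab-separated text with a header row. In the default layout the first
#' column holds OTU ids and the remaining columns are samples; `transpose =
#' TRUE` reads the samples-as-rows layout. Sample dates are taken from the
#' sample identifiers when they parse as ISO dates, otherwise they must be
#' supplied via `sample_dates`.
#'
#' @param path file path.
#' @param transpose logical; is the file samples-as-rows?
#' @param sample_dates optional `Date` vector overriding dates parsed from
#'   sample ids.
#' @return `read_otu_table()` returns an [otu_table]; `write_otu_table()`
#'   returns `path` invisibly.
#' @export
read_otu_table <- function(path, transpose = FALSE, sample_dates = NULL) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = character())
  if (ncol(raw) < 2) stop_format("malformed header in ", path,
                                 ": need an id column plus data columns")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop_validation("duplicate ids in first column of ", path, ": ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_format("non-numeric count at row '", ids[bad[1]], "', column '",
                colnames(mat)[bad[2]], "' in ", path)
  }
  dimnames(num) <- list(ids, colnames(mat))
  if (transpose) num <- t(num)
  if (is.null(sample_dates)) {
    sample_dates <- as.Date(colnames(num), format = "%Y-%m-%d")
    if (anyNA(sample_dates))
      stop_format("sample ids in ", path, " are not ISO dates; ",
                  "pass sample_dates explicitly")
  }
  otu_table(num, sample_dates)
}

#' @rdname read_otu_table
#' @param x an [otu_table].
#' @export
write_otu_table <- function(x, path, transpose = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  m <- x$counts
  if (transpose) m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (transpose) "sample_id" else "otu_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# lineages

#' PR2-style rank scheme
#'
#' The eight ranked slots of a PR2 4.x lineage, from most inclusive to most
#' specific. The mapping of slots to rank names changed between PR2 versions,
#' so operations that interpret ranks accept an alternative scheme.
#'
#' @return character vector of 8 rank names.
#' @export
pr2_ranks <- function() {
  c("kingdom", "supergroup", "division", "class",
    "order", "family", "genus", "species")
}

#' Parse a delimited ranked lineage
#'
#' Splits a `;`-delimited lineage string into a fixed 8-slot named vector
#' (trailing slots empty when unassigned). An empty string yields an all-empty
#' lineage; more than 8 fields is a format error.
#'
#' @param lineage character scalar, e.g.
#'   `"Eukaryota;Alveolata;Dinoflagellata;Syndiniales"`.
#' @param ranks rank names for the 8 slots (default [pr2_ranks()]).
#' @param sep field delimiter.
#' @return named character vector of length 8.
#' @export
parse_lineage <- function(lineage, ranks = pr2_ranks(), sep = ";") {
  stopifnot(length(ranks) == 8L)
  if (is.na(lineage)) lineage <- ""
  parts <- if (nzchar(trimws(lineage))) trimws(strsplit(lineage, sep, fixed = TRUE)[[1]])
           else character()
  if (length(parts) > 8L)
    stop_format("lineage has ", length(parts), " fields (max 8): ", lineage)
  out <- character(8L)
  out[seq_along(parts)] <- parts
  names(out) <- ranks
  out
}

#' @rdname parse_lineage
#' @param lineages character vector of lineage strings.
#' @return `parse_lineages()`: character matrix, one row per lineage, 8 rank
#'   columns.
#' @export
parse_lineages <- function(lineages, ranks = pr2_ranks(), sep = ";") {
  m <- t(vapply(lineages, parse_lineage, character(8L),
                ranks = ranks, sep = sep, USE.NAMES = FALSE))
  colnames(m) <- ranks
  m
}

#' Serialize a ranked lineage back to delimited text
#'
#' Drops trailing empty slots; `parse_lineage()` is a left inverse.
#'
#' @param lineage named character vector of 8 slots.
#' @param sep field delimiter.
#' @return character scalar.
#' @export
format_lineage <- function(lineage, sep = ";") {
  filled <- which(nzchar(lineage))
  if (length(filled) == 0L) return("")
  paste(lineage[seq_len(max(filled))], collapse = sep)
}

# ---------------------------------------------------------------------------
# taxonomy table

#' Read / write a taxonomy table
#'
#' Tab-separated with columns `otu_id`, `lineage`, `confidence`. Confidence is
#' the annotation bootstrap value in `[0, 100]` reported by the upstream
#' classifier (the conventional retention cut-off of 80 is applied upstream;
#' it is carried here as metadata only).
#'
#' @param path file path.
#' @param ranks rank scheme passed to [parse_lineages()].
#' @return a `data.frame` with columns `otu_id`, `lineage`, `confidence` and
#'   the 8 parsed rank columns.
#' @export
read_taxonomy <- function(path, ranks = pr2_ranks()) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("otu_id", "lineage", "confidence")
  if (!all(need %in% names(df)))
    stop_format("taxonomy file must have columns ", paste(need, collapse = ", "))
  df$confidence <- as.numeric(df$confidence)
  taxonomy_table(df$otu_id, df$lineage, df$confidence, ranks = ranks)
}

#' @rdname read_taxonomy
#' @param otu_id,lineage,confidence column vectors.
#' @export
taxonomy_table <- function(otu_id, lineage, confidence = NA_real_,
                           ranks = pr2_ranks()) {
  if (anyDuplicated(otu_id))
    stop_validation("duplicate otu_id in taxonomy: ",
                    paste(unique(otu_id[duplicated(otu_id)]), collapse = ", "))
  confidence <- rep_len(as.numeric(confidence), length(otu_id))
  if (any(!is.na(confidence) & (confidence < 0 | confidence > 100)))
    stop_validation("confidence must lie in [0, 100]")
  df <- data.frame(otu_id = as.character(otu_id),
                   lineage = as.character(lineage),
                   confidence = confidence,
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(parse_lineages(df$lineage, ranks = ranks),
                          stringsAsFactors = FALSE))
}

#' @rdname read_taxonomy
#' @param taxonomy a taxonomy `data.frame` as returned by [taxonomy_table()].
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy[, c("otu_id", "lineage", "confidence")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# environmental table

env_columns <- function() {
  c("temperature", "salinity", "secchi_depth", "tide", "sunshine",
    "silicate", "phosphate", "nitrate", "chlorophyll_a")
}

#' Read / write an environmental table
#'
#' One row per sampling date. Numeric columns: `temperature` (degC),
#' `salinity`, `secchi_depth` (m), `sunshine` (h), `silicate`, `phosphate`,
#' `nitrate` (umol/L), `chlorophyll_a` (ug/L); `tide` is categorical
#' (`low`/`high`). Any value may be missing (literal `NA`).
#'
#' @param path file path (TSV).
#' @return `data.frame` with a `date` column (Date) and the columns above.
#' @export
read_env_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "NA")
  if (!"date" %in% names(df)) stop_format("environmental table needs a 'date' column")
  missing_cols <- setdiff(env_columns(), names(df))
  if (length(missing_cols))
    stop_format("environmental table missing columns: ",
                paste(missing_cols, collapse = ", "))
  df$date <- as.Date(df$date)
  validate_env_table(df)
}

validate_env_table <- function(df) {
  if (anyDuplicated(df$date)) stop_validation("duplicate dates in environmental table")
  for (col in c("secchi_depth", "sunshine", "silicate", "phosphate",
                "nitrate", "chlorophyll_a")) {
    v <- df[[col]]
    if (any(!is.na(v) & v < 0))
      stop_validation("negative values in physically non-negative column ", col)
  }
  if (!all(is.na(df$tide) | df$tide %in% c("low", "high")))
    stop_validation("tide must be 'low' or 'high'")
  df[order(df$date), , drop = FALSE]
}

#' @rdname read_env_table
#' @param env environmental `data.frame`.
#' @export
write_env_table <- function(env, path) {
  out <- env
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# ---------------------------------------------------------------------------
# seasons

#' Meteorological season of a date
#'
#' Spring = March-May, Summer = June-August, Autumn = September-November,
#' Winter = December-February. Determined by the month only (year-agnostic);
#' the leap day falls in Winter.
#'
#' @param date `Date` vector (or anything `as.Date()` accepts).
#' @return factor with levels `Spring`, `Summer`, `Autumn`, `Winter`.
#' @export
#' @examples
#' assign_season(as.Date(c("2016-03-18", "2018-12-27", "2016-02-29")))
assign_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  lab <- c("Winter", "Winter", "Spring", "Spring", "Spring", "Summer",
           "Summer", "Summer", "Autumn", "Autumn", "Autumn", "Winter")[m]
  factor(lab, levels = c("Spring", "Summer", "Autumn", "Winter"))
}
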