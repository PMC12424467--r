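# Reading compound tables, writing/reading MCL files.

.precomputed_fields <- c("mw", "xlogp", "tpsa", "hbd", "hba",
                         "mobility_class", "log_ie", "ri")
.count_fields <- c("hbd", "hba")

#' Construct a compound record
#'
#' @param id Unique opaque identifier.
#' @param smiles Canonical SMILES (non-empty).
#' @param inchikey Optional InChIKey.
#' @param precomputed Named list of optional precomputed values: `mw`
#'   (Da), `xlogp`, `tpsa` (A^2), `hbd`, `hba` (counts),
#'   `mobility_class` (1/2/3), `log_ie`, `ri`.
#' @return Object of class `compound_record`.
#' @export
compound_record <- function(id, smiles, inchikey = NULL,
                            precomputed = list()) {
  check_that(is.character(id) && length(id) == 1L && nzchar(id),
             "validation", "id must be a non-empty string")
  check_that(is.character(smiles) && length(smiles) == 1L && nzchar(smiles),
             "validation", sprintf("smiles must be non-empty (id %s)", id),
             id = id)
  check_that(all(names(precomputed) %in% .precomputed_fields), "validation",
             sprintf("unknown precomputed field(s): %s",
                     paste(setdiff(names(precomputed), .precomputed_fields),
                           collapse = ", ")), id = id)
  for (f in .count_fields) {
    v <- precomputed[[f]]
    if (!is.null(v) && !is.na(v)) {
      check_that(v >= 0 && v == floor(v), "validation",
                 sprintf("%s must be a non-negative integer (id %s)", f, id),
                 id = id)
    }
  }
  mc <- precomputed$mobility_class
  if (!is.null(mc) && !is.na(mc)) {
    check_that(mc %in% 1:3, "validation",
               sprintf("mobility_class must be 1, 2 or 3 (id %s)", id),
               id = id)
  }
  structure(list(id = id, smiles = smiles, inchikey = inchikey,
                 precomputed = precomputed), class = "compound_record")
}

#' Map canonical field names to input column headers
#'
#' Fields not mapped are computed or predicted downstream.
#'
#' @param id,smiles Mandatory column headers.
#' @param inchikey,mw,xlogp,tpsa,hbd,hba,mobility_class,log_ie,ri
#'   Optional column headers for precomputed values.
#' @return Object of class `column_map` (named character vector).
#' @export
column_map <- function(id = "id", smiles = "smiles", inchikey = NULL,
                       mw = NULL, xlogp = NULL, tpsa = NULL, hbd = NULL,
                       hba = NULL, mobility_class = NULL, log_ie = NULL,
                       ri = NULL) {
  check_that(is.character(id) && nzchar(id) &&
               is.character(smiles) && nzchar(smiles), "config",
             "id and smiles column mappings are mandatory")
  m <- c(id = id, smiles = smiles, inchikey = inchikey, mw = mw,
         xlogp = xlogp, tpsa = tpsa, hbd = hbd, hba = hba,
         mobility_class = mobility_class, log_ie = log_ie, ri = ri)
  structure(m, class = "column_map")
}

# Auto-detect the delimiter from the header row (comma/tab/semicolon).
detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  counts <- c("," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
              "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
              ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))))
  if (all(counts == 0L)) return(",")
  names(counts)[which.max(counts)]
}

# Parse one character column to numeric with row-accurate errors.
.parse_numeric_column <- function(x, column, path) {
  out <- rep(NA_real_, length(x))
  filled <- !is.na(x) & nzchar(trimws(x))
  vals <- trimws(x[filled])
  dec_comma <- grepl("^-?[0-9]+,[0-9]+$", vals)
  if (any(dec_comma)) {
    row <- which(filled)[which(dec_comma)[1]]
    mcl_stop("validation", sprintf(
      "column %s row %d: %s uses ',' as decimal separator; only '.' is accepted",
      dQuote(column), row, dQuote(vals[which(dec_comma)[1]])),
      column = column, row = row)
  }
  parsed <- suppressWarnings(as.numeric(vals))
  bad <- is.na(parsed)
  if (any(bad)) {
    row <- which(filled)[which(bad)[1]]
    mcl_stop("validation", sprintf(
      "column %s row %d: cannot parse %s as a number",
      dQuote(column), row, dQuote(vals[which(bad)[1]])),
      column = column, row = row)
  }
  out[filled] <- parsed
  out
}

#' Read a delimited compound table
#'
#' The delimiter is auto-detected among comma/tab/semicolon from the
#' header row unless `sep` is given. Blank cells become absent
#' precomputed values; the decimal separator must be `"."`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param colmap A [column_map()] naming at least the id and SMILES
#'   columns.
#' @param sep Optional delimiter override.
#' @return List of `compound_record`s, in row order.
#' @export
read_compound_table <- function(path, colmap = column_map(), sep = NULL) {
  check_that(file.exists(path), "config",
             sprintf("input file not found: %s", path))
  stopifnot(inherits(colmap, "column_map"))
  sep <- sep %||% detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  for (f in c("id", "smiles")) {
    check_that(colmap[[f]] %in% names(df), "config",
               sprintf("mapped %s column %s not found in %s (columns: %s)",
                       f, dQuote(colmap[[f]]), path,
                       paste(names(df), collapse = ", ")))
  }
  ids <- trimws(df[[colmap[["id"]]]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    d <- dup[1]
    rows <- which(ids == d)
    mcl_stop("validation",
             sprintf("duplicate id %s in rows %s", dQuote(d),
                     paste(rows, collapse = " and ")),
             id = d, rows = rows)
  }
  numcols <- intersect(.precomputed_fields, names(colmap))
  parsed <- list()
  for (f in numcols) {
    col <- colmap[[f]]
    if (!is.na(col) && col %in% names(df)) {
      parsed[[f]] <- .parse_numeric_column(df[[col]], col, path)
    }
  }
  lapply(seq_len(nrow(df)), function(i) {
    pre <- lapply(parsed, `[[`, i)
    pre <- pre[!vapply(pre, is.na, logical(1))]
    ik <- if ("inchikey" %in% names(colmap) &&
              colmap[["inchikey"]] %in% names(df))
      df[[colmap[["inchikey"]]]][i] else NULL
    compound_record(ids[i], trimws(df[[colmap[["smiles"]]]][i]),
                    inchikey = ik, precomputed = pre)
  })
}

.mcl_columns <- c("id", "smiles", "polarity", "mobility_class", "log_ie",
                  "predicted_ri", "rplc_class", "cell_index", "rank")

#' Write an MCL (measurable compound list) to delimited text
#'
#' One polarity per file; rows are written in ascending rank order.
#' Numeric fields round-trip to at least 15 significant digits.
#'
#' @param path Output path.
#' @param entries MCL data frame (from [build_mcl()] /
#'   [rank_and_select()]) with columns id, smiles, polarity,
#'   mobility_class, log_ie, predicted_ri, rplc_class, cell_index, rank.
#' @param sep Field delimiter (default comma).
#' @export
write_mcl <- function(path, entries, sep = ",") {
  entries <- as.data.frame(entries)
  if (nrow(entries) > 0L) {
    pol <- unique(entries$polarity)
    check_that(length(pol) == 1L, "validation",
               sprintf("one polarity per output file; got: %s",
                       paste(pol, collapse = ", ")))
    entries <- entries[order(entries$rank), , drop = FALSE]
  }
  missing <- setdiff(.mcl_columns, names(entries))
  check_that(length(missing) == 0L, "validation",
             sprintf("MCL entries missing column(s): %s",
                     paste(missing, collapse = ", ")))
  out <- entries[, .mcl_columns, drop = FALSE]
  for (nc in c("log_ie", "predicted_ri")) {
    out[[nc]] <- ifelse(is.na(out[[nc]]), "",
                        sprintf("%.15g", out[[nc]]))
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an MCL file written by [write_mcl()]
#'
#' @param path Input path.
#' @param sep Optional delimiter override (auto-detected otherwise).
#' @return MCL data frame with typed columns, in file row order.
#' @export
read_mcl <- function(path, sep = NULL) {
  check_that(file.exists(path), "config",
             sprintf("MCL file not found: %s", path))
  sep <- sep %||% detect_delimiter(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  missing <- setdiff(.mcl_columns, names(df))
  check_that(length(missing) == 0L, "validation",
             sprintf("MCL file missing column(s): %s",
                     paste(missing, collapse = ", ")))
  df$mobility_class <- as.integer(df$mobility_class)
  df$log_ie <- suppressWarnings(as.numeric(df$log_ie))
  df$predicted_ri <- suppressWarnings(as.numeric(df$predicted_ri))
  df$rplc_class <- as.integer(df$rplc_class)
  df$rank <- as.integer(df$rank)
  df
}
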