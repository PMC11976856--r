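# Readers and writers for the delimited-text interchange formats: plate
# tables and physchem tables as CSV, ranked lists / result tables as TSV,
# gene sets as GMT, protein matrices as TSV with an id column.

#' @rdname plate_io
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write plate measurement tables
#'
#' Comma-separated with a header row; required columns `particle`,
#' `cell_line`, `assay`, `dose`, `experiment`, `technical_rep`, `cell_free`,
#' `signal`. Schema mismatches are reported with the missing column names.
#'
#' @param plate a `plate_measurements` data frame.
#' @param path file path.
#' @return the table (invisibly, for the writer).
#' @name plate_io
#' @export
read_plate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  .np_check_cols(d, c("particle", "cell_line", "assay", "dose", "experiment",
                      "technical_rep", "cell_free", "signal"),
                 sprintf("plate file '%s'", path))
  d$cell_free <- as.logical(d$cell_free)
  class(d) <- c("plate_measurements", "data.frame")
  d
}

#' Read a physicochemical characterization table
#'
#' CSV with a `particle` column, numeric descriptor columns (blank cells are
#' missing values, excluded pairwise by the correlation screen) and optional
#' subset label columns such as `coating` / `crystal`.
#'
#' @param path file path.
#' @return data frame of class `physchem_table`.
#' @export
read_physchem_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  .np_check_cols(d, "particle", sprintf("physchem file '%s'", path))
  class(d) <- c("physchem_table", "data.frame")
  d
}

#' @rdname physchem_io_write
#' @keywords internal
#' @export
write_physchem_csv <- function(physchem, path) {
  utils::write.csv(physchem, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a result table as tab-separated text
#'
#' UTF-8, header row, no row names; list-columns (e.g. GSEA leading edges)
#' are flattened to comma-joined strings.
#'
#' @param x data frame.
#' @param path file path.
#' @export
write_result_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (nm in names(x)) {
    if (is.list(x[[nm]])) {
      x[[nm]] <- vapply(x[[nm]], paste, character(1), collapse = ",")
    }
  }
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated, one set per line: name, description, then one member id
#' per field. Lines with fewer than 3 fields are hard errors reported with
#' their line numbers; duplicate set names are an error.
#'
#' @param path file path.
#' @return named list of character member vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) .np_stop("GMT file '%s' is empty", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    .np_stop("malformed GMT line(s) (fewer than 3 fields) in '%s': line %s",
             path, paste(short, collapse = ", "))
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    .np_stop("duplicate gene set name(s) in '%s': %s", path,
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2L), nm)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of member-id vectors.
#' @param path file path.
#' @param descriptions optional named character of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) .np_stop("gene sets must be named")
  desc <- descriptions %||% attr(sets, "description") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write protein quantification matrices
#'
#' Tab-separated, first column `protein`, remaining columns one replicate
#' each; empty cells are missing observations.
#'
#' @param path file path.
#' @param mat numeric matrix with protein row names (for the writer).
#' @return numeric matrix with protein row names.
#' @name protein_matrix_io
#' @export
read_protein_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  .np_check_cols(d, "protein", sprintf("protein matrix '%s'", path))
  m <- as.matrix(d[, setdiff(names(d), "protein"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d$protein
  m
}

#' @rdname protein_matrix_io
#' @export
write_protein_matrix <- function(mat, path) {
  d <- data.frame(protein = rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a two-column ranked protein list
#'
#' Tab-separated `protein`, `score`; re-sorted (descending, id tie-break) on
#' read so downstream stages always see a valid ranking.
#'
#' @param ranked a `ranked_proteins` data frame (for the writer).
#' @param path file path.
#' @name ranked_io
#' @export
read_ranked_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  .np_check_cols(d, c("protein", "score"), sprintf("ranked list '%s'", path))
  d <- d[order(-d$score, d$protein), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("ranked_proteins", "data.frame")
  d
}

#' @rdname ranked_io
#' @export
write_ranked_tsv <- function(ranked, path) {
  utils::write.table(ranked[, c("protein", "score")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Bundled reference potency tables
#'
#' Loads the published per-endpoint potency estimates (beta for LDH, ATP,
#' CTB and the printed consensus beta_avg) or the published consensus/rank
#' tables for the silica ("si") and titania ("ti") nanoform panels bundled
#' with the package, as transcribed reference values for validating the
#' consensus and ranking operations.
#'
#' @param panel `"si"` or `"ti"`.
#' @param what `"potency"` (per-endpoint betas, both cell lines wide) or
#'   `"ranks"` (consensus beta_avg with printed ranks).
#' @return data frame.
#' @export
reference_potency_table <- function(panel = c("si", "ti"),
                                    what = c("potency", "ranks")) {
  panel <- match.arg(panel)
  what <- match.arg(what)
  f <- system.file("extdata", sprintf("%s_%s_reference.csv", panel, what),
                   package = "nanopotency", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
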