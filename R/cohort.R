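# Cohort tables are data frames with one row per subject.  Mandatory columns
# are `id` and `class`; the ten analyte columns, `age`, `psa`, `dheas`,
# `coefficient` and the three reported rule columns (`psa_rule`, `dheas_rule`,
# `ratio_rule`) are optional.  Missing values ("ND" cells in clinical tables)
# are NA, which is distinct from a measured zero.

.COHORT_NUMERIC <- c("age", "psa", "dheas", "coefficient")

#' Construct a steroid cohort table
#'
#' Validates a subject-per-row data frame and stamps it with the
#' `steroid_cohort` class.  Subject ids must be unique and any analyte
#' concentration present must be non-negative.
#'
#' @param df Data frame with at least `id` and `class` columns.  `class`
#'   entries must be `"PCa"`, `"BPH"`, `"HC"` or NA (unknown).
#' @param provenance Free-text note on where the table came from.
#' @return The validated data frame, classed `steroid_cohort`.
#' @export
steroid_cohort <- function(df, provenance = NULL) {
  if (!is.data.frame(df)) stop("cohort must be a data frame", call. = FALSE)
  miss <- setdiff(c("id", "class"), names(df))
  if (length(miss))
    stop("cohort is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate subject id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  bad_class <- setdiff(stats::na.omit(unique(df$class)), .CLASSES)
  if (length(bad_class))
    stop("unknown class label(s): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  for (a in intersect(.ANALYTES, names(df))) {
    v <- df[[a]]
    if (!is.numeric(v)) stop("analyte column not numeric: ", a, call. = FALSE)
    if (any(!is.na(v) & v < 0))
      stop("negative concentration in column: ", a, call. = FALSE)
  }
  class(df) <- unique(c("steroid_cohort", class(df)))
  attr(df, "provenance") <- provenance %||% attr(df, "provenance") %||% ""
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort table from delimited text
#'
#' Reads a comma- (default) or tab-delimited file with one header row and
#' one row per subject.  Cells equal to `"ND"` or empty become missing
#' values.  Column names may be remapped through a dialect configuration,
#' either a named list (schema name -> file column name) or the path of a
#' YAML file holding such a mapping.
#'
#' @param path File to read.
#' @param dialect Optional named list or YAML file path remapping columns,
#'   e.g. `list(id = "sample", psa = "total_psa")`.
#' @param sep Field separator; `","` or `"\t"`.
#' @return A [steroid_cohort()] data frame.
#' @export
load_cohort <- function(path, dialect = NULL, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      na.strings = c("ND", "NA", ""), check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e)
      stop("cohort file is empty or has no usable header: ", path,
           call. = FALSE))
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("cohort file is empty or has no usable header: ", path, call. = FALSE)
  if (is.character(dialect)) dialect <- yaml::read_yaml(dialect)
  if (!is.null(dialect)) {
    for (schema_name in names(dialect)) {
      src <- dialect[[schema_name]]
      if (!src %in% names(df))
        stop("dialect maps '", schema_name, "' to absent column '", src, "'",
             call. = FALSE)
      names(df)[names(df) == src] <- schema_name
    }
  }
  for (col in intersect(c(.COHORT_NUMERIC, .ANALYTES), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  steroid_cohort(df, provenance = path)
}

#' Write a cohort table as delimited text
#'
#' Missing values are written as empty cells so that a write/read
#' round-trip preserves them as NA.
#'
#' @param cohort A [steroid_cohort()].
#' @param path Output file.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.table(as.data.frame(cohort), path, sep = sep, na = "",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Embedded clinical cohort fixture
#'
#' The 71-subject clinical table shipped with the package: 20 prostate
#' cancer (PCa), 20 benign prostate hypertrophy (BPH) and 31 healthy
#' control (HC) subjects with age, total PSA (ng/mL; two subjects have no
#' PSA measurement), DHEAS (ng/mL), the reported 1-100 ratio-relationship
#' discriminating coefficient, and the three reported classification
#' columns (PSA threshold rule, DHEAS threshold rule, ratio-coefficient
#' band rule).  Full 10-steroid panels are not part of this table.
#'
#' @return A [steroid_cohort()] with 71 rows.
#' @export
#' @examples
#' tab <- builtin_table1()
#' table(tab$class)
builtin_table1 <- function() {
  load_cohort(.extdata("cohort_table1.csv"))
}

#' Embedded MRM transition table
#'
#' The tandem-MS multiple-reaction-monitoring transitions of the ten panel
#' steroids: two parent -> fragment transitions per analyte, with retention
#' times where known.  DHEA and DHEAS share parent m/z 271.2 (DHEAS loses
#' its sulfate in the source) and are distinguished chromatographically.
#'
#' @return Data frame classed `transition_table`, 20 rows.
#' @export
builtin_transitions <- function() {
  df <- utils::read.csv(.extdata("transitions_table2.csv"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(df$parent_mz > 0), all(df$fragment_mz > 0))
  class(df) <- c("transition_table", class(df))
  df
}

#' Parent m/z for panel analytes
#'
#' @param analyte Character vector of analyte names.
#' @param transitions A transition table, by default the embedded one.
#' @return Numeric vector of parent m/z values.
#' @export
parent_mz <- function(analyte, transitions = builtin_transitions()) {
  idx <- match(analyte, transitions$analyte)
  if (anyNA(idx))
    stop("unknown analyte(s): ", paste(analyte[is.na(idx)], collapse = ", "),
         call. = FALSE)
  transitions$parent_mz[idx]
}

#' Per-class subject counts of a cohort
#'
#' @param cohort A [steroid_cohort()].
#' @return Named integer vector over the class labels present.
#' @export
class_counts <- function(cohort) {
  table(factor(cohort$class, levels = .CLASSES))
}

#' Extract the panel matrix of a cohort
#'
#' @param cohort A [steroid_cohort()] whose analyte columns are present.
#' @return Numeric matrix, one row per subject (rownames = ids), columns in
#'   canonical analyte order.
#' @export
cohort_panels <- function(cohort) {
  miss <- setdiff(.ANALYTES, names(cohort))
  if (length(miss))
    stop("cohort has no panel columns for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(as.data.frame(cohort)[, .ANALYTES])
  rownames(m) <- cohort$id
  incomplete <- rownames(m)[!stats::complete.cases(m)]
  if (length(incomplete))
    stop("subject(s) with incomplete panels: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  m
}
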