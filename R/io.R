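#' Write / read a cohort as CSV
#'
#' One row per case, columns named per the schema; "unknown" is spelled
#' `unknown` (the spreadsheet dialect of the study's supplementary data).
#'
#' @param cases Cohort data.frame.
#' @param path Output file.
#' @export
write_cases <- function(cases, path) {
  out <- cases
  schema <- copd_schema()
  for (nm in intersect(schema$name, names(out))) {
    if (schema_row(schema, nm)$kind == "continuous") {
      v <- as.character(out[[nm]])
      v[is.na(out[[nm]])] <- UNKNOWN_TOKEN
      out[[nm]] <- v
    } else {
      out[[nm]][is.na(out[[nm]])] <- UNKNOWN_TOKEN
    }
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE)
}

#' @rdname write_cases
#' @param validate Validate every case after reading (default TRUE).
#' @return `read_cases`: cohort data.frame (continuous columns numeric with
#'   `NA` for unknown; categorical columns character).
#' @export
read_cases <- function(path, validate = TRUE) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  schema <- copd_schema()
  missing_v <- setdiff(schema$name, names(raw))
  if (length(missing_v))
    stop("incomplete case file: missing column(s) ",
         paste(missing_v, collapse = ", "))
  for (nm in schema$name) {
    if (schema_row(schema, nm)$kind == "continuous") {
      v <- raw[[nm]]
      v[v == UNKNOWN_TOKEN] <- NA
      raw[[nm]] <- as.numeric(v)
    }
  }
  if (validate) {
    ok <- validate_cohort(raw, schema)
    if (!all(ok)) {
      bad <- which(!ok)
      stop("invalid cases at row(s) ", paste(head(bad, 10), collapse = ", "),
           ": ", paste(unlist(attr(ok, "violations")[1]), collapse = "; "))
    }
  }
  raw
}

#' Write a label matrix as a per-rater wide CSV
#'
#' Layout mirrors the study's label spreadsheets: one row per case, four
#' columns per rater (`<id>_triage`, `<id>_exacerbation`,
#' `<id>_triage_conf`, `<id>_exac_conf`).
#'
#' @param labels A `copd_labels` data.frame.
#' @param path Output file.
#' @export
write_labels <- function(labels, path) {
  raters <- unique(labels$rater_id)
  cases <- unique(labels$case_id)
  out <- data.frame(case_id = cases, stringsAsFactors = FALSE)
  for (r in raters) {
    sub <- labels[labels$rater_id == r, ]
    i <- match(cases, sub$case_id)
    out[[paste0(r, "_triage")]] <- sub$triage[i]
    out[[paste0(r, "_exacerbation")]] <- sub$exacerbation[i]
    out[[paste0(r, "_triage_conf")]] <- sub$triage_conf[i]
    out[[paste0(r, "_exac_conf")]] <- sub$exac_conf[i]
  }
  write.csv(out, path, row.names = FALSE)
}

#' Read labels from a file
#'
#' Two dialects: `"csv"` reads the package's wide per-rater CSV layout
#' (see [write_labels()]); `"s1"` reads a spreadsheet workbook (or an
#' equivalently laid out CSV) in the style of the study's supplementary
#' label sheets — one row per case with per-physician triage/exacerbation
#' columns — using `readxl` for `.xlsx` input. Rows with out-of-range
#' categories are rejected with line-number diagnostics; with
#' `fail_fast = FALSE` the offending rows are dropped and reported in the
#' `"rejected"` attribute.
#'
#' @param path Input file.
#' @param dialect `"csv"` or `"s1"`.
#' @param fail_fast Stop on the first malformed row (default TRUE).
#' @return A `copd_labels` data.frame.
#' @export
read_labels <- function(path, dialect = c("csv", "s1"), fail_fast = TRUE) {
  dialect <- match.arg(dialect)
  raw <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the readxl package")
    as.data.frame(readxl::read_excel(path))
  } else {
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (dialect == "s1") names(raw) <- normalize_s1_names(names(raw))
  id_col <- intersect(c("case_id", "case", "Case", "ID"), names(raw))[1]
  if (is.na(id_col)) stop("unknown dialect: no case id column found")
  tri_cols <- grep("_triage$", names(raw), value = TRUE)
  if (length(tri_cols) == 0) stop("unknown dialect: no *_triage columns found")
  raters <- sub("_triage$", "", tri_cols)
  out <- list(); errors <- character(0)
  for (r in raters) {
    tri <- suppressWarnings(as.integer(raw[[paste0(r, "_triage")]]))
    exa <- suppressWarnings(as.integer(raw[[paste0(r, "_exacerbation")]]))
    tcf <- if (paste0(r, "_triage_conf") %in% names(raw))
      suppressWarnings(as.numeric(raw[[paste0(r, "_triage_conf")]])) else NA_real_
    ecf <- if (paste0(r, "_exac_conf") %in% names(raw))
      suppressWarnings(as.numeric(raw[[paste0(r, "_exac_conf")]])) else NA_real_
    bad <- is.na(tri) | !tri %in% 1:4 | is.na(exa) | !exa %in% 0:1 |
      (!is.na(tcf) & (tcf < 0 | tcf > 100)) | (!is.na(ecf) & (ecf < 0 | ecf > 100))
    if (any(bad)) {
      msg <- sprintf("rater %s: invalid label at data row(s) %s", r,
                     paste(which(bad), collapse = ", "))
      if (fail_fast) stop(msg)
      errors <- c(errors, msg)
    }
    out[[r]] <- data.frame(rater_id = r, case_id = as.character(raw[[id_col]]),
                           triage = tri, exacerbation = exa,
                           triage_conf = tcf, exac_conf = ecf,
                           stringsAsFactors = FALSE)[!bad, ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "rejected") <- errors
  class(res) <- c("copd_labels", "data.frame")
  res
}

# map S1-style physician column headers onto the package layout
normalize_s1_names <- function(nms) {
  n <- tolower(nms)
  n <- gsub("[ .]+", "_", n)
  n <- sub("^(dr|doctor|physician)[_]?([0-9]+)", "dr\\2", n)
  n <- sub("_exac(erbation)?_?conf(idence)?$", "_exac_conf", n)
  n <- sub("_triage_?conf(idence)?$", "_triage_conf", n)
  n <- sub("_exac$", "_exacerbation", n)
  n
}

#' Write a consensus table as CSV
#'
#' @param consensus data.frame from [consensus_labels()].
#' @param scenario Scenario string recorded alongside each row.
#' @param path Output file.
#' @export
write_consensus <- function(consensus, scenario, path) {
  out <- cbind(consensus[, "case_id", drop = FALSE], scenario = scenario,
               consensus_triage = consensus$triage,
               consensus_exacerbation = consensus$exacerbation)
  write.csv(out, path, row.names = FALSE)
}
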