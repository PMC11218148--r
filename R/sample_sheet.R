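#' Sample sheets
#'
#' A sample sheet annotates the columns of a beta matrix: one row per sample,
#' with the passage number (the clock's response variable) plus cohort
#' metadata. It is a plain `data.frame` with required columns `sample_id`
#' (unique character) and `passage` (non-negative integer), and optional
#' columns `cell_type`, `donor_id`, `treatment`, `dose`, `cumulative_pd` and
#' `cohort`. On disk it is a CSV with a header row.
#'
#' @param sheet a data.frame to validate.
#' @param require_passage if `TRUE` (default) every sample must carry a
#'   passage; set `FALSE` for prediction-only sheets.
#' @return the validated data.frame.
#' @export
as_sample_sheet <- function(sheet, require_passage = TRUE) {
  if (!is.data.frame(sheet))
    stop("sample sheet must be a data.frame", call. = FALSE)
  need <- c("sample_id", "passage")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0)
    stop("sample sheet lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sheet$sample_id <- as.character(sheet$sample_id)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "), call. = FALSE)
  p <- sheet$passage
  if (!is.numeric(p)) {
    pc <- suppressWarnings(as.numeric(as.character(p)))
    if (any(is.na(pc) & !is.na(p)))
      stop("non-numeric passage value(s) in sample sheet", call. = FALSE)
    p <- pc
  }
  if (any(!is.na(p) & (p < 0 | p != round(p))))
    stop("passage must be a non-negative integer", call. = FALSE)
  if (require_passage && anyNA(p))
    stop("passage missing for sample(s): ",
         paste(sheet$sample_id[is.na(p)], collapse = ", "), call. = FALSE)
  sheet$passage <- as.integer(p)
  if ("cumulative_pd" %in% names(sheet))
    sheet$cumulative_pd <- as.numeric(sheet$cumulative_pd)
  rownames(sheet) <- NULL
  sheet
}

#' @rdname as_sample_sheet
#' @param path CSV file path.
#' @export
read_sample_sheet <- function(path, require_passage = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, na.strings = c("", "NA"))
  as_sample_sheet(tab, require_passage = require_passage)
}

#' @rdname as_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- as_sample_sheet(sheet, require_passage = FALSE)
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# align a sheet to the columns of a beta matrix, erroring on gaps
match_sheet <- function(beta, sheet) {
  miss <- setdiff(colnames(beta), sheet$sample_id)
  if (length(miss) > 0)
    stop("samples in beta matrix absent from sample sheet: ",
         paste(miss, collapse = ", "), call. = FALSE)
  sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
}
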