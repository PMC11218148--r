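#' Serialise a passage clock to structured text
#'
#' A fitted `passage_clock` is stored as a JSON document with fields
#' `schema_version`, `intercept`, `weights` (probe -> coefficient map, only
#' non-zero entries) and `training_meta`. Numbers are written with enough
#' decimal digits to round-trip the underlying doubles bit-exactly, so
#' `read_clock_model(write_clock_model(m, f))` reproduces `m`.
#'
#' @param model a `passage_clock` (or a list with `intercept`, `weights`,
#'   `training_meta`).
#' @param path output file path.
#' @return `write_clock_model()` returns `path` invisibly;
#'   `read_clock_model()` returns a `passage_clock`.
#' @export
write_clock_model <- function(model, path) {
  if (!all(c("intercept", "weights") %in% names(model)))
    stop("not a clock model (needs intercept and weights)", call. = FALSE)
  w <- model$weights
  if (any(w == 0))
    stop("clock model contains zero-valued weights; store only selected CpGs",
         call. = FALSE)
  if (length(w) > 0 && is.null(names(w)))
    stop("weights must be named by probe ID", call. = FALSE)
  doc <- list(schema_version = 1L,
              intercept = model$intercept,
              weights = as.list(w),
              training_meta = model$training_meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version != 1)
    stop("unknown clock model schema version: ",
         if (is.null(doc$schema_version)) "(none)" else doc$schema_version,
         call. = FALSE)
  w <- vapply(doc$weights, as.numeric, numeric(1))
  meta <- lapply(doc$training_meta, function(v) {
    if (is.null(v)) NA_real_
    else if (is.list(v)) unlist(v)
    else v
  })
  structure(list(intercept = as.numeric(doc$intercept),
                 weights = w,
                 cv = NULL,
                 training_meta = meta),
            class = "passage_clock")
}
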