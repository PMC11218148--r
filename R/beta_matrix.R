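#' Beta-value matrices
#'
#' A beta matrix is the substrate of every computation in this package: a
#' numeric matrix of methylation fractions (beta values, in \[0, 1\]) with CpG
#' probes as rows and samples as columns. Probe IDs live in `rownames()`,
#' sample IDs in `colnames()`, and missing measurements are `NA`. These
#' functions validate, read and write that representation.
#'
#' On disk a beta matrix is tab-separated text: the header row is
#' `probe_id` followed by the sample IDs, and each subsequent row is one CpG.
#' Empty fields encode missing values.
#'
#' @param x numeric matrix with unique, non-empty `rownames` (probe IDs) and
#'   `colnames` (sample IDs); all non-missing values in \[0, 1\].
#' @return `as_beta_matrix()` returns the validated matrix (invisibly
#'   unchanged); `read_beta_matrix()` returns such a matrix.
#' @examples
#' b <- matrix(c(0.1, 0.9, 0.5, 0.4), 2, 2,
#'             dimnames = list(c("cg01", "cg02"), c("S1", "S2")))
#' as_beta_matrix(b)
#' @export
as_beta_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("beta matrix must be a numeric matrix", call. = FALSE)
  pid <- rownames(x)
  sid <- colnames(x)
  if (is.null(pid) || is.null(sid) || any(!nzchar(pid)) || any(!nzchar(sid)))
    stop("beta matrix needs non-empty probe (row) and sample (column) names",
         call. = FALSE)
  if (anyDuplicated(pid))
    stop("duplicate probe IDs: ", paste(unique(pid[duplicated(pid)]),
         collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample IDs: ", paste(unique(sid[duplicated(sid)]),
         collapse = ", "), call. = FALSE)
  bad <- which(!is.na(x) & (x < 0 | x > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
      pid[bad[1, 1]], sid[bad[1, 2]], x[bad[1, , drop = FALSE]]),
      call. = FALSE)
  }
  x
}

#' @rdname as_beta_matrix
#' @param path file path of a tab-separated beta matrix.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(hdr[-1]))
    stop("duplicate sample IDs in header: ",
         paste(unique(hdr[-1][duplicated(hdr[-1])]), collapse = ", "),
         call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = "")
  colnames(tab) <- hdr
  if (ncol(tab) < 2)
    stop("beta matrix file needs a probe_id column plus >= 1 sample column",
         call. = FALSE)
  probes <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  unparseable <- !is.na(vals) & is.na(num)
  if (any(unparseable)) {
    w <- which(unparseable, arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable beta value '%s' at probe '%s', sample '%s'",
                 vals[w[1], w[2]], probes[w[1]], colnames(vals)[w[2]]),
         call. = FALSE)
  }
  dimnames(num) <- list(probes, colnames(vals))
  as_beta_matrix(num)
}

#' @rdname as_beta_matrix
#' @param beta a validated beta matrix.
#' @export
write_beta_matrix <- function(beta, path) {
  beta <- as_beta_matrix(beta)
  chr <- matrix(fmt_num(beta), nrow = nrow(beta))
  chr[is.na(beta)] <- ""
  out <- cbind(probe_id = rownames(beta), chr)
  colnames(out) <- c("probe_id", colnames(beta))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# shortest decimal strings that round-trip doubles exactly
fmt_num <- function(x) {
  out <- rep(NA_character_, length(x))
  nok <- which(!is.na(x))
  if (length(nok) == 0) return(out)
  full <- format(x[nok], digits = 17, scientific = FALSE, trim = TRUE)
  short <- format(x[nok], digits = 15, scientific = FALSE, trim = TRUE)
  use_short <- as.numeric(short) == x[nok]
  full[use_short] <- short[use_short]
  out[nok] <- full
  out
}
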