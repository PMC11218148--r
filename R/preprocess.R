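#' Probe-level quality filtering
#'
#' Methylation-array pre-processing gate applied before screening: compute
#' beta values from methylated/unmethylated intensity pairs, drop probes that
#' fail the detection p-value cut-off, remove cross-hybridising probes from a
#' blocklist, and drop probes with missing values. Inputs are assumed already
#' background-corrected and normalised; none of these filters ever removes a
#' sample, only probes.
#'
#' @param methylated,unmethylated non-negative numeric matrices of
#'   fluorescence intensities with identical dimnames (probes x samples).
#' @param offset non-negative stabilising constant added to the denominator
#'   (platform convention; default 100).
#' @return `compute_beta()` returns a beta matrix
#'   `M / (M + U + offset)` with values in \[0, 1).
#' @examples
#' m <- matrix(900, 1, 1, dimnames = list("cg01", "S1"))
#' u <- matrix(0,   1, 1, dimnames = list("cg01", "S1"))
#' compute_beta(m, u)  # 0.9
#' @export
compute_beta <- function(methylated, unmethylated, offset = 100) {
  stopifnot(is.matrix(methylated), is.matrix(unmethylated),
            identical(dim(methylated), dim(unmethylated)))
  if (offset < 0) stop("offset must be >= 0", call. = FALSE)
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE))
    stop("negative intensity value", call. = FALSE)
  beta <- methylated / (methylated + unmethylated + offset)
  beta[is.na(methylated) | is.na(unmethylated)] <- NA_real_
  dimnames(beta) <- dimnames(methylated)
  as_beta_matrix(beta)
}

#' @rdname compute_beta
#' @param beta a beta matrix (probes x samples).
#' @param detp matrix of detection p-values covering every probe and sample
#'   of `beta`.
#' @param cutoff detection p-value cut-off; a probe fails where p > cutoff.
#' @param rule `"any-sample"` (default) drops a probe failing in at least one
#'   sample; `"mean"` drops a probe whose mean detection p exceeds the cutoff.
#' @export
filter_by_detection <- function(beta, detp, cutoff = 0.01,
                                rule = c("any-sample", "mean")) {
  rule <- match.arg(rule)
  beta <- as_beta_matrix(beta)
  miss_p <- setdiff(rownames(beta), rownames(detp))
  if (length(miss_p) > 0)
    stop("probes missing from detection p matrix: ",
         paste(utils::head(miss_p, 5), collapse = ", "), call. = FALSE)
  miss_s <- setdiff(colnames(beta), colnames(detp))
  if (length(miss_s) > 0)
    stop("samples missing from detection p matrix: ",
         paste(miss_s, collapse = ", "), call. = FALSE)
  d <- detp[rownames(beta), colnames(beta), drop = FALSE]
  fail <- switch(rule,
    "any-sample" = apply(d > cutoff, 1, any),
    "mean"       = rowMeans(d) > cutoff)
  keep <- !fail
  message(sprintf("detection filter (%s, cutoff %g): %d of %d probes dropped",
                  rule, cutoff, sum(fail), nrow(beta)))
  beta[keep, , drop = FALSE]
}

#' @rdname compute_beta
#' @param blocklist character vector of probe IDs to remove (e.g. a published
#'   cross-hybridising probe list).
#' @export
remove_blocklist <- function(beta, blocklist) {
  beta <- as_beta_matrix(beta)
  present <- intersect(blocklist, rownames(beta))
  absent <- length(unique(blocklist)) - length(present)
  if (absent > 0)
    message(sprintf("blocklist: %d ID(s) not found in matrix", absent))
  out <- beta[!(rownames(beta) %in% present), , drop = FALSE]
  message(sprintf("blocklist: removed %d of %d probes",
                  length(present), nrow(beta)))
  if (nrow(out) == 0) warning("blocklist removed every probe", call. = FALSE)
  out
}

#' @rdname compute_beta
#' @export
drop_incomplete_probes <- function(beta) {
  beta <- as_beta_matrix(beta)
  keep <- rowSums(is.na(beta)) == 0
  if (sum(!keep) > 0)
    message(sprintf("dropping %d probe(s) with missing values", sum(!keep)))
  out <- beta[keep, , drop = FALSE]
  if (nrow(out) == 0)
    warning("no complete probes remain", call. = FALSE)
  out
}

#' @rdname compute_beta
#' @param path blocklist file: one probe ID per line, `#` comments and blank
#'   lines ignored.
#' @export
read_blocklist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}
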