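`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
as_dna_set <- function(x) {
  if (inherits(x, "cds_set")) return(x$seqs)
  if (methods::is(x, "DNAStringSet")) return(x)
  if (methods::is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is.character(x)) return(Biostrings::DNAStringSet(toupper(x)))
  stop("cannot interpret input as DNA sequences", call. = FALSE)
}

#' Format a p-value the way assay reports print it
#'
#' Values below the reporting precision are printed as an upper bound
#' (e.g. "p < 0.001"), full precision being retained in machine-readable
#' output.
#'
#' @param p p-value in \[0, 1\].
#' @param digits number of decimal places of the reporting precision.
#' @return A character scalar such as `"p = 0.074"` or `"p < 0.001"`.
#' @export
#' @examples
#' format_p_value(0.0742)
#' format_p_value(3e-7)
format_p_value <- function(p, digits = 3) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  cutoff <- 10^(-digits)
  if (p < cutoff) {
    sprintf("p < %s", format(cutoff, scientific = FALSE))
  } else {
    sprintf("p = %.*f", digits, p)
  }
}

#' @noRd
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
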