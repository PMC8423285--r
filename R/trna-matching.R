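# Cross-referencing over-represented phage codons against the phage's tRNA
# anticodon complement. A phage that over-uses a codon relative to its host
# sometimes carries its own tRNA for that codon; whether it does is read off
# the anticodon list produced upstream by a tRNA predictor.

#' Anticodon corresponding to a codon
#'
#' The anticodon is the reverse complement of the codon, reported 5'-to-3'
#' in the DNA alphabet (T, not U), matching the output convention of common
#' tRNA predictors.
#'
#' @param codon character vector of unambiguous ACGT triplets.
#' @return Character vector of anticodon triplets.
#' @export
#' @examples
#' codon_to_anticodon("ACT")
codon_to_anticodon <- function(codon) {
  codon <- toupper(as.character(codon))
  if (length(codon) == 0L || any(!grepl("^[ACGT]{3}$", codon))) {
    stop("codons must be unambiguous ACGT triplets", call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(codon)))
}

# Third-position pairing rules, keyed by the codon's third base; values are
# the anticodon first (wobble, position 34) bases that can read it. The
# Watson-Crick partner is always included; the extras are G:U pairing and
# inosine-like reading (A34 treated as I, reading U/C/A).
wobble_rules <- function() {
  list(
    A = c("T", "A"),
    C = c("G", "A"),
    G = c("C", "T"),
    T = c("A", "G")
  )
}

#' Read a tRNA anticodon list
#'
#' Accepts either a two-column TSV (`anticodon`, `amino_acid`; header
#' optional) or free text in the style of tRNA predictor reports, from which
#' entries like `tRNA-Thr(agt)` are collected. U is mapped to T.
#'
#' @param path input file path.
#' @param format `"auto"` (default), `"tsv"` or `"predictor"`.
#' @return Data frame with columns `anticodon` and `amino_acid` (3-letter
#'   code or `"?"`); zero rows when the input lists no tRNAs.
#' @export
read_anticodons <- function(path, format = c("auto", "tsv", "predictor")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("anticodon list not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (format == "auto") {
    first <- if (length(lines)) strsplit(lines[[1L]], "\t")[[1L]][1L] else ""
    format <- if (length(lines) == 0L ||
                  grepl("^[ACGTUacgtu]{3}$", trimws(first)) ||
                  grepl("anticodon", lines[[1L]], ignore.case = TRUE)) {
      "tsv"
    } else {
      "predictor"
    }
  }
  if (format == "tsv") {
    if (length(lines) == 0L) {
      return(data.frame(anticodon = character(0), amino_acid = character(0),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(lines, "\t")
    if (grepl("anticodon", lines[[1L]], ignore.case = TRUE)) parts <- parts[-1L]
    ac <- chartr("U", "T", toupper(vapply(parts, `[`, "", 1L)))
    aa <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "?", "")
    ok <- grepl("^[ACGT]{3}$", ac)
    if (any(!ok)) {
      stop("invalid anticodon entries: ",
           paste(ac[!ok], collapse = ", "), call. = FALSE)
    }
    data.frame(anticodon = ac, amino_acid = aa, stringsAsFactors = FALSE)
  } else {
    m <- regmatches(lines, regexpr("tRNA-([A-Za-z?]{1,3})\\(([ACGTUacgtu]{3})\\)", lines))
    aa <- sub("^tRNA-([A-Za-z?]{1,3})\\(.*$", "\\1", m)
    ac <- chartr("U", "T", toupper(sub("^.*\\(([ACGTUacgtu]{3})\\)$", "\\1", m)))
    data.frame(anticodon = ac, amino_acid = aa, stringsAsFactors = FALSE)
  }
}

#' Match over-represented codons against a tRNA anticodon set
#'
#' For every defined codon whose usage ratio is at least `min_ratio`,
#' reports whether the anticodon complement contains a cognate tRNA. With
#' `wobble = FALSE` (default) cognate means the exact reverse-complement
#' anticodon; with `wobble = TRUE` third-position pairings (G:U, and
#' inosine-like reading of A at position 34) also count, so wobble matches
#' are always a superset of exact matches.
#'
#' An empty anticodon set (a phage encoding no tRNAs at all) yields
#' `has_cognate_trna = FALSE` for every row.
#'
#' @param ratios a `codon_ratio_table` from [usage_ratio()].
#' @param trnas data frame from [read_anticodons()], or a character vector
#'   of anticodon triplets; may be empty.
#' @param min_ratio ratio threshold selecting over-represented codons
#'   (default 1.1, the `higher` bin boundary).
#' @param wobble apply third-position wobble pairing rules (default FALSE).
#' @return An `adaptation_report` data frame with columns `codon`,
#'   `amino_acid`, `ratio`, `has_cognate_trna`, `matched_anticodons`
#'   (comma-separated, `""` when none), ordered by decreasing ratio;
#'   attributes `threshold_used` and `wobble`.
#' @export
match_overrepresented <- function(ratios, trnas, min_ratio = 1.1,
                                  wobble = FALSE) {
  stopifnot(is.data.frame(ratios), min_ratio > 0)
  acs <- if (is.data.frame(trnas)) trnas$anticodon else as.character(trnas)
  acs <- chartr("U", "T", toupper(acs))
  if (length(acs) && any(!grepl("^[ACGT]{3}$", acs))) {
    stop("anticodons must be unambiguous ACGT triplets", call. = FALSE)
  }
  d <- ratios[!is.na(ratios$ratio) & ratios$ratio >= min_ratio, , drop = FALSE]
  d <- d[order(-d$ratio, d$codon), , drop = FALSE]
  rules <- wobble_rules()
  matched <- vapply(d$codon, function(codon) {
    exact <- codon_to_anticodon(codon)
    hits <- if (wobble) {
      third <- substr(codon, 3L, 3L)
      acs[substr(acs, 2L, 3L) == substr(exact, 2L, 3L) &
            substr(acs, 1L, 1L) %in% rules[[third]]]
    } else {
      acs[acs == exact]
    }
    paste(unique(hits), collapse = ",")
  }, character(1))
  out <- data.frame(
    codon = d$codon,
    amino_acid = if ("amino_acid" %in% names(d)) d$amino_acid else
      unname(Biostrings::GENETIC_CODE[d$codon]),
    ratio = d$ratio,
    has_cognate_trna = nzchar(matched),
    matched_anticodons = unname(matched),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "threshold_used") <- min_ratio
  attr(out, "wobble") <- wobble
  class(out) <- c("adaptation_report", "data.frame")
  out
}

#' @export
print.adaptation_report <- function(x, ...) {
  cat(sprintf(
    "<adaptation_report> %d codon(s) with ratio >= %.2f (wobble %s); %d with cognate tRNA\n",
    nrow(x), attr(x, "threshold_used"),
    if (isTRUE(attr(x, "wobble"))) "on" else "off",
    sum(x$has_cognate_trna)
  ))
  print(as.data.frame(x))
  invisible(x)
}
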