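# Codon counting, relative codon frequencies f_i, phage:host usage ratios
# r_i, their three-bin classification, and GC content.
#
# The central statistic: for each of the 64 codons,
#   f_i = (count of codon i) / (total codon count over all analyzed CDS)
#   r_i = f_i(phage) / f_i(host)
# with r_i >= 1.1 read as the phage over-using codon i, r_i in [0.9, 1.1)
# as similar usage, and r_i < 0.9 as the host over-using it. Counting is
# pooled over all CDS of an organism, after removal of start codons.

codon_alphabet <- function() sort(names(Biostrings::GENETIC_CODE))

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Remove the start codon from every CDS
#'
#' Codon-usage comparisons exclude start codons, whose choice is constrained
#' by initiation rather than by synonymous-codon preference. Each sequence
#' is shortened by exactly its first three bases.
#'
#' @param cds a `cds_set`, DNAStringSet or character vector; every sequence
#'   must be at least 6 bases and a multiple of 3.
#' @return An object of the same kind with the first codon removed from each
#'   sequence.
#' @export
#' @examples
#' strip_start_codons(c(g1 = "ATGAAATTTTGA"))
strip_start_codons <- function(cds) {
  seqs <- as_dna_set(cds)
  w <- Biostrings::width(seqs)
  if (any(w < 6L)) {
    stop("sequence shorter than 6 bases: removing the start codon would ",
         "leave less than one codon", call. = FALSE)
  }
  if (any(w %% 3L != 0L)) {
    stop("sequence length not a multiple of 3", call. = FALSE)
  }
  out <- Biostrings::subseq(seqs, start = 4L)
  if (inherits(cds, "cds_set")) {
    cds$seqs <- out
    cds
  } else if (is.character(cds)) {
    stats::setNames(as.character(out), names(cds))
  } else {
    out
  }
}

#' Count codons pooled over a set of CDS
#'
#' Counts non-overlapping triplets read from position 1 of each sequence,
#' pooled across all CDS of the set (one count table per organism, matching
#' the definition of f_i as a genome-wide proportion).
#'
#' @param cds a `cds_set`, DNAStringSet or character vector of ACGT
#'   sequences with lengths divisible by 3.
#' @return Named numeric vector of length 64 (codons in alphabetical order);
#'   `sum()` of it is the total codon count.
#' @export
#' @examples
#' count_codons("AAATTTTGA")
count_codons <- function(cds) {
  seqs <- as_dna_set(cds)
  if (length(seqs) == 0L || sum(Biostrings::width(seqs)) == 0L) {
    stop("no valid CDS", call. = FALSE)
  }
  w <- Biostrings::width(seqs)
  if (any(w %% 3L != 0L)) {
    i <- which(w %% 3L != 0L)[1L]
    stop("sequence length not a multiple of 3: ",
         names(seqs)[i] %||% i, call. = FALSE)
  }
  ch <- as.character(seqs)
  bad <- regexpr("[^ACGT]", ch)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "non-ACGT character in sequence '%s' at codon %d",
      if (!is.null(names(seqs))) names(seqs)[i] else as.character(i),
      (bad[i] - 1L) %/% 3L + 1L
    ), call. = FALSE)
  }
  m <- Biostrings::oligonucleotideFrequency(seqs, width = 3, step = 3)
  counts <- colSums(m)
  counts[codon_alphabet()]
}

#' Relative codon frequencies
#'
#' f_i = count of codon i / total codon count. Frequencies sum to 1.
#'
#' @param counts named numeric vector over the 64 codons (from
#'   [count_codons()]).
#' @return Named numeric vector of frequencies in \[0, 1\].
#' @export
relative_frequencies <- function(counts) {
  codons <- codon_alphabet()
  if (is.null(names(counts)) || !all(codons %in% names(counts))) {
    stop("counts must be named by the 64 codons", call. = FALSE)
  }
  counts <- counts[codons]
  if (any(counts < 0)) stop("negative codon count", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("total codon count is zero", call. = FALSE)
  counts / total
}

#' Classify a codon usage ratio into bins
#'
#' `higher` iff r >= hi, `similar` iff lo <= r < hi, `lower` iff r < lo.
#' The lower boundary is inclusive for `similar` so that the three bins
#' partition cleanly; undefined ratios (host frequency 0) map to
#' `undefined`.
#'
#' @param r numeric vector of ratios (NA for undefined).
#' @param lo,hi bin thresholds (defaults 0.9 and 1.1).
#' @return Factor with levels `higher`, `similar`, `lower`, `undefined`.
#' @export
#' @examples
#' classify_ratio(c(1.1, 0.9, 0.89, 3))
classify_ratio <- function(r, lo = 0.9, hi = 1.1) {
  stopifnot(lo > 0, hi > lo)
  if (any(r < 0, na.rm = TRUE)) stop("negative ratio", call. = FALSE)
  out <- ifelse(is.na(r), "undefined",
         ifelse(r >= hi, "higher",
         ifelse(r >= lo, "similar", "lower")))
  factor(out, levels = c("higher", "similar", "lower", "undefined"))
}

#' Phage-to-host codon usage ratio table
#'
#' Computes r_i = f_i(phage) / f_i(host) for all 64 codons and assigns each
#' defined ratio to a bin (see [classify_ratio()]). Codons the host never
#' uses (f_host = 0) are flagged `undefined` rather than infinite and are
#' excluded from rankings.
#'
#' @param phage,host named numeric vectors over the 64 codons: either raw
#'   counts (from [count_codons()]) or frequencies summing to 1.
#' @param lo,hi bin thresholds (defaults 0.9 and 1.1).
#' @return A `codon_ratio_table` data frame with columns `codon`,
#'   `amino_acid`, (`count_phage`, `count_host` when counts were supplied),
#'   `f_phage`, `f_host`, `ratio`, `bin`; thresholds stored as attributes
#'   `lo` and `hi`.
#' @export
usage_ratio <- function(phage, host, lo = 0.9, hi = 1.1) {
  codons <- codon_alphabet()
  is_counts <- function(x) sum(x) > 1 + 1e-9
  cp <- if (is_counts(phage)) phage[codons] else NULL
  ch <- if (is_counts(host)) host[codons] else NULL
  f_p <- relative_frequencies(phage)
  f_h <- relative_frequencies(host)
  ratio <- ifelse(f_h > 0, f_p / f_h, NA_real_)
  df <- data.frame(
    codon = codons,
    amino_acid = unname(Biostrings::GENETIC_CODE[codons]),
    stringsAsFactors = FALSE
  )
  if (!is.null(cp)) df$count_phage <- unname(cp)
  if (!is.null(ch)) df$count_host <- unname(ch)
  df$f_phage <- unname(f_p)
  df$f_host <- unname(f_h)
  df$ratio <- unname(ratio)
  df$bin <- classify_ratio(df$ratio, lo = lo, hi = hi)
  attr(df, "lo") <- lo
  attr(df, "hi") <- hi
  class(df) <- c("codon_ratio_table", "data.frame")
  df
}

#' Top and bottom codons by usage ratio
#'
#' The k largest and k smallest defined ratios, the usual way a phage-host
#' codon comparison is displayed. Ties are broken by codon alphabetical
#' order; undefined ratios are excluded.
#'
#' @param ratios a `codon_ratio_table` from [usage_ratio()].
#' @param k how many codons per list (default 10).
#' @return List with data frames `top` (descending ratio) and `bottom`
#'   (ascending ratio), each with columns `codon`, `amino_acid`, `ratio`.
#' @export
top_bottom_codons <- function(ratios, k = 10) {
  stopifnot(is.data.frame(ratios), k >= 1)
  d <- as.data.frame(ratios)[!is.na(ratios$ratio), , drop = FALSE]
  if (nrow(d) < k) {
    stop("fewer than k defined ratios (", nrow(d), " < ", k, ")",
         call. = FALSE)
  }
  cols <- intersect(c("codon", "amino_acid", "ratio"), names(d))
  top <- d[order(-d$ratio, d$codon), cols][seq_len(k), , drop = FALSE]
  bottom <- d[order(d$ratio, d$codon), cols][seq_len(k), , drop = FALSE]
  rownames(top) <- rownames(bottom) <- NULL
  list(top = top, bottom = bottom)
}

#' GC content of a sequence or sequence set
#'
#' (G + C) / (A + C + G + T); ambiguity codes are excluded from both
#' numerator and denominator. For a multi-record set (e.g. a draft genome in
#' contigs) counts are pooled over records.
#'
#' @param seq character, DNAString(Set) or `cds_set`.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' gc_content("GATC")
gc_content <- function(seq) {
  seqs <- as_dna_set(seq)
  lf <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  cs <- colSums(lf)
  den <- sum(cs)
  if (den == 0) stop("sequence has no unambiguous bases", call. = FALSE)
  unname((cs[["C"]] + cs[["G"]]) / den)
}

#' Write a codon ratio table as TSV
#'
#' @param ratios a `codon_ratio_table`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_codon_table <- function(ratios, path) {
  stopifnot(is.data.frame(ratios))
  utils::write.table(as.data.frame(ratios), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.codon_ratio_table <- function(x, ...) {
  cat(sprintf(
    "<codon_ratio_table> thresholds [%.2f, %.2f); bins: %s\n",
    attr(x, "lo"), attr(x, "hi"),
    paste(sprintf("%s=%d", levels(x$bin), tabulate(x$bin, 4L)),
          collapse = " ")
  ))
  print(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat("...", nrow(x) - 8L, "more rows\n")
  invisible(x)
}
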