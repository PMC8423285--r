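# Reading genomes and annotations, and extracting validated coding sequences.
#
# Coordinates are GFF3-style (1-based, inclusive) at the interface; slicing
# is delegated to Biostrings, which removes any chance of off-by-one drift
# between the two conventions.

#' Read a nucleotide FASTA file
#'
#' Reads a multi-record FASTA file, concatenating wrapped sequence lines,
#' stripping internal whitespace and upper-casing. Record ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] with one element per record, in
#'   file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 a genome", "ACGT", "ACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("genome not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0L) stop("no records in ", path, call. = FALSE)
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("no records in ", path, " (", conditionMessage(e), ")",
           call. = FALSE)
    }
  )
  if (length(raw) == 0L) stop("no records in ", path, call. = FALSE)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(raw)))
  ids <- sub("\\s.*$", "", names(raw))
  iupac <- paste0(names(Biostrings::IUPAC_CODE_MAP), collapse = "")
  bad <- regexpr(sprintf("[^%s]", iupac), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "invalid character '%s' in record '%s' at position %d",
      substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]
    ), call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Read CDS features from a GFF3 annotation
#'
#' Parses a GFF3 file and returns only the CDS rows, as 1-based inclusive
#' coordinates with strand. Multi-segment CDS (rows sharing an `ID`) are kept
#' as one row per segment under the same `feature_id`; [extract_cds()] joins
#' them in coordinate order.
#'
#' @param path path to a GFF3 file.
#' @param seq_id_filter optional character vector; keep only features on
#'   these seqids.
#' @return A [GenomicRanges::GRanges] with metadata columns `feature_id` and
#'   `phase`.
#' @export
read_gff_cds <- function(path, seq_id_filter = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("annotation not found: ", path, call. = FALSE)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) {
      stop("invalid GFF3 in ", path, " (possibly start > end): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  cds <- gr[as.character(gr$type) == "CDS"]
  if (!is.null(seq_id_filter)) {
    cds <- cds[as.character(GenomicRanges::seqnames(cds)) %in% seq_id_filter]
  }
  strand_chr <- as.character(BiocGenerics::strand(cds))
  if (any(!strand_chr %in% c("+", "-"))) {
    stop("strand not in {+,-} for one or more CDS features", call. = FALSE)
  }
  fid <- if (!is.null(cds$ID)) as.character(cds$ID) else rep(NA_character_, length(cds))
  if (anyNA(fid) && !is.null(cds$Name)) {
    fid[is.na(fid)] <- as.character(cds$Name)[is.na(fid)]
  }
  fid[is.na(fid)] <- sprintf("cds_%05d", which(is.na(fid)))
  phase <- if (!is.null(cds$phase)) as.integer(cds$phase) else rep(0L, length(cds))
  phase[is.na(phase)] <- 0L
  S4Vectors::mcols(cds) <- S4Vectors::DataFrame(feature_id = fid, phase = phase)
  cds
}

#' @noRd
new_cds_set <- function(genome_id, seqs, dropped) {
  structure(
    list(genome_id = genome_id, seqs = seqs, dropped = dropped),
    class = "cds_set"
  )
}

#' @export
print.cds_set <- function(x, ...) {
  cat(sprintf(
    "<cds_set> genome '%s': %d CDS retained, %d dropped\n",
    x$genome_id, length(x$seqs), nrow(x$dropped)
  ))
  invisible(x)
}

#' @export
length.cds_set <- function(x) length(x$seqs)

#' Extract validated coding sequences from a genome
#'
#' Slices each CDS feature out of the genome (reverse-complementing
#' minus-strand features), joins multi-segment features sharing a
#' `feature_id` in ascending coordinate order, and applies a validation
#' policy. Sequences failing validation are dropped and recorded with a
#' reason, never silently discarded.
#'
#' Validation reasons are: `nonzero_phase` (partial CDS, unless
#' `include_partial`), `ambiguous_bases` (non-ACGT letters, unless
#' `drop_ambiguous = FALSE` in which case codon counting will refuse them
#' later), `length_not_multiple_of_3`, `too_short` (< 6 bases, i.e. fewer
#' than one codon once the start codon is removed), and `internal_stop`
#' (in-frame stop before the final codon, unless
#' `drop_internal_stop = FALSE`).
#'
#' @param genome a named [Biostrings::DNAStringSet] (or character vector) of
#'   genome records.
#' @param features a [GenomicRanges::GRanges] from [read_gff_cds()], or any
#'   GRanges with `feature_id` metadata.
#' @param genome_id identifier for the resulting set; defaults to the first
#'   genome record's name.
#' @param drop_internal_stop drop CDS with an in-frame stop codon before the
#'   final codon (default `TRUE`).
#' @param drop_ambiguous drop CDS containing non-ACGT characters (default
#'   `TRUE`; codon counting is ill-defined on ambiguity codes).
#' @param drop_final_stop remove a trailing stop codon from each retained
#'   CDS (default `FALSE`: the final stop stays in, only start codons are
#'   removed downstream by [strip_start_codons()]).
#' @param include_partial keep CDS whose GFF phase is non-zero (default
#'   `FALSE`).
#' @param verbose emit one `DROPPED <feature_id> <reason>` message per
#'   dropped feature.
#' @return A `cds_set`: list with `genome_id`, `seqs` (named DNAStringSet)
#'   and `dropped` (data frame of `feature_id`, `reason`).
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "AAATGCATTT"))
#' f <- GenomicRanges::GRanges("chr", IRanges::IRanges(3, 8), strand = "+",
#'                             feature_id = "c1", phase = 0L)
#' extract_cds(g, f)
extract_cds <- function(genome, features, genome_id = NULL,
                        drop_internal_stop = TRUE, drop_ambiguous = TRUE,
                        drop_final_stop = FALSE, include_partial = FALSE,
                        verbose = FALSE) {
  genome <- as_dna_set(genome)
  sn <- as.character(GenomicRanges::seqnames(features))
  if (is.null(names(genome))) {
    if (length(genome) == 1L && length(unique(sn)) <= 1L) {
      names(genome) <- unique(sn)
    } else {
      stop("genome records must be named", call. = FALSE)
    }
  }
  if (!all(sn %in% names(genome))) {
    stop("features reference unknown genome record(s): ",
         paste(setdiff(unique(sn), names(genome)), collapse = ", "),
         call. = FALSE)
  }
  st <- BiocGenerics::start(features)
  en <- BiocGenerics::end(features)
  if (any(st < 1L) || any(en > Biostrings::width(genome)[match(sn, names(genome))])) {
    stop("feature out of bounds of its genome record", call. = FALSE)
  }
  strand_chr <- as.character(BiocGenerics::strand(features))
  if (any(!strand_chr %in% c("+", "-"))) {
    stop("strand not in {+,-}", call. = FALSE)
  }
  mc <- S4Vectors::mcols(features)
  fid <- if ("feature_id" %in% names(mc)) as.character(mc$feature_id) else sprintf("cds_%05d", seq_along(features))
  phase <- if ("phase" %in% names(mc)) as.integer(mc$phase) else rep(0L, length(features))
  phase[is.na(phase)] <- 0L

  stops <- c("TAA", "TAG", "TGA")
  kept <- character(0)
  drop_id <- character(0)
  drop_reason <- character(0)
  note_drop <- function(id, reason) {
    if (verbose) message("DROPPED ", id, " ", reason)
    drop_id <<- c(drop_id, id)
    drop_reason <<- c(drop_reason, reason)
  }

  for (id in unique(fid)) {
    idx <- which(fid == id)
    idx <- idx[order(st[idx])]
    str <- unique(strand_chr[idx])
    if (length(str) != 1L) {
      note_drop(id, "mixed_strand")
      next
    }
    if (!include_partial && any(phase[idx] != 0L)) {
      note_drop(id, "nonzero_phase")
      next
    }
    pieces <- vapply(idx, function(i) {
      as.character(Biostrings::subseq(genome[[sn[i]]], st[i], en[i]))
    }, character(1))
    s <- paste(pieces, collapse = "")
    if (str == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    if (drop_ambiguous && grepl("[^ACGT]", s)) {
      note_drop(id, "ambiguous_bases")
      next
    }
    if (nchar(s) %% 3L != 0L) {
      note_drop(id, "length_not_multiple_of_3")
      next
    }
    if (drop_final_stop && nchar(s) >= 3L &&
        substr(s, nchar(s) - 2L, nchar(s)) %in% stops) {
      s <- substr(s, 1L, nchar(s) - 3L)
    }
    if (nchar(s) < 6L) {
      note_drop(id, "too_short")
      next
    }
    if (drop_internal_stop) {
      starts <- seq(1L, nchar(s) - 2L, by = 3L)
      internal <- substring(s, starts, starts + 2L)[-length(starts)]
      if (any(internal %in% stops)) {
        note_drop(id, "internal_stop")
        next
      }
    }
    kept[id] <- s
  }

  if (length(kept) == 0L) stop("no valid CDS", call. = FALSE)
  seqs <- Biostrings::DNAStringSet(kept)
  new_cds_set(
    genome_id = genome_id %||% names(genome)[1L],
    seqs = seqs,
    dropped = data.frame(feature_id = drop_id, reason = drop_reason,
                         stringsAsFactors = FALSE)
  )
}

#' Write a CDS set to FASTA
#'
#' @param cds a `cds_set` (or DNAStringSet).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  Biostrings::writeXStringSet(as_dna_set(cds), path)
  invisible(path)
}
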