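# Pipeline entry points tying the stages together: codon-usage comparison
# from genome + annotation files, and phenotype analyses (growth kinetics,
# efficiency of plating, biofilm statistics) from assay tables. Every run
# writes a machine-readable provenance block next to its results; the same
# inputs and configuration always produce identical output files.

provenance_block <- function(inputs, params) {
  list(
    tool = "phagekit",
    version = as.character(utils::packageVersion("phagekit")),
    inputs = inputs,
    parameters = params
  )
}

#' Run the phage-vs-host codon usage comparison
#'
#' Chains the full codon-usage pipeline: read both genomes and annotations,
#' extract and validate CDS, remove start codons, count codons, compute
#' relative frequencies and phage:host ratios, rank top/bottom codons, and
#' summarize GC content. If an anticodon list is supplied, over-represented
#' codons are cross-referenced against it.
#'
#' Writes into `out_dir`: `codon_usage.tsv`, `top_bottom_codons.json`,
#' `gc_summary.json`, `provenance.json`, and (with anticodons)
#' `adaptation_report.tsv`.
#'
#' @param phage_fasta,phage_gff,host_fasta,host_gff input file paths.
#' @param out_dir output directory (created if needed).
#' @param anticodons optional: path to an anticodon list (see
#'   [read_anticodons()]), a data frame, or a character vector of
#'   anticodons. An empty vector models a phage with no tRNA genes.
#' @param lo,hi ratio bin thresholds (defaults 0.9, 1.1).
#' @param k size of the top/bottom codon lists (default 10).
#' @param min_ratio threshold for the tRNA cross-reference (default 1.1).
#' @param wobble apply wobble pairing in the cross-reference.
#' @param drop_final_stop,include_partial CDS validation policy, see
#'   [extract_cds()].
#' @param verbose log dropped CDS features.
#' @return Invisibly, a list with `ratio_table`, `top_bottom`, `gc`,
#'   `adaptation` (or NULL) and `files`.
#' @export
run_codon_usage <- function(phage_fasta, phage_gff, host_fasta, host_gff,
                            out_dir = ".", anticodons = NULL,
                            lo = 0.9, hi = 1.1, k = 10, min_ratio = 1.1,
                            wobble = FALSE, drop_final_stop = FALSE,
                            include_partial = FALSE, verbose = FALSE) {
  read_side <- function(fasta, gff) {
    genome <- read_fasta(fasta)
    feats <- read_gff_cds(gff)
    cds <- extract_cds(genome, feats, drop_final_stop = drop_final_stop,
                       include_partial = include_partial, verbose = verbose)
    counts <- count_codons(strip_start_codons(cds))
    list(genome = genome, cds = cds, counts = counts)
  }
  phage <- read_side(phage_fasta, phage_gff)
  host <- read_side(host_fasta, host_gff)

  ratio <- usage_ratio(phage$counts, host$counts, lo = lo, hi = hi)
  tb <- top_bottom_codons(ratio, k = k)
  gc <- list(
    phage = list(id = names(phage$genome)[1L],
                 length_bp = sum(Biostrings::width(phage$genome)),
                 n_cds = length(phage$cds),
                 gc_percent = 100 * gc_content(phage$genome)),
    host = list(id = names(host$genome)[1L],
                length_bp = sum(Biostrings::width(host$genome)),
                n_cds = length(host$cds),
                gc_percent = 100 * gc_content(host$genome))
  )
  adaptation <- NULL
  if (!is.null(anticodons)) {
    trnas <- if (is.character(anticodons) && length(anticodons) == 1L &&
                 file.exists(anticodons)) {
      read_anticodons(anticodons)
    } else {
      anticodons
    }
    adaptation <- match_overrepresented(ratio, trnas, min_ratio = min_ratio,
                                        wobble = wobble)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    codon_tsv = file.path(out_dir, "codon_usage.tsv"),
    top_bottom = file.path(out_dir, "top_bottom_codons.json"),
    gc_summary = file.path(out_dir, "gc_summary.json"),
    provenance = file.path(out_dir, "provenance.json")
  )
  write_codon_table(ratio, files[["codon_tsv"]])
  write_json_report(
    list(thresholds = list(lo = lo, hi = hi), k = k,
         top = tb$top, bottom = tb$bottom),
    files[["top_bottom"]]
  )
  write_json_report(gc, files[["gc_summary"]])
  if (!is.null(adaptation)) {
    files[["adaptation"]] <- file.path(out_dir, "adaptation_report.tsv")
    utils::write.table(as.data.frame(adaptation), files[["adaptation"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_json_report(
    provenance_block(
      inputs = list(phage_fasta = phage_fasta, phage_gff = phage_gff,
                    host_fasta = host_fasta, host_gff = host_gff),
      params = list(lo = lo, hi = hi, k = k, min_ratio = min_ratio,
                    wobble = wobble, drop_final_stop = drop_final_stop,
                    include_partial = include_partial)
    ),
    files[["provenance"]]
  )
  invisible(list(ratio_table = ratio, top_bottom = tb, gc = gc,
                 adaptation = adaptation, files = files))
}

#' Run phenotype analyses from assay tables
#'
#' Dispatches on whichever inputs are given: a one-step growth table (see
#' [read_growth_tsv()]) yields a kinetics estimate; a spot-count or titer
#' table (see [read_spot_titers_tsv()], [read_titers_tsv()]) yields an
#' efficiency-of-plating table; a two-group measurement table (see
#' [read_two_group_tsv()]) yields a normality-gated test report. JSON
#' reports (plus `eop.tsv` with 2-significant-figure percentages) and a
#' provenance block are written to `out_dir`; a one-line human-readable
#' summary per analysis is printed unless `quiet`.
#'
#' @param growth_tsv,spots_tsv,titers_tsv,biofilm_tsv input file paths
#'   (any subset).
#' @param out_dir output directory.
#' @param rise_factor,plateau_tol kinetics extraction parameters, see
#'   [estimate_kinetics()].
#' @param countable_min,countable_max,spot_volume spot counting rules, see
#'   [titer_from_spots()].
#' @param paired is the biofilm comparison paired?
#' @param alpha significance level (default 0.05).
#' @param quiet suppress printed summaries.
#' @return Invisibly, a list with `kinetics`, `eop`, `biofilm` (NULL when
#'   not run) and `files`.
#' @export
run_phenotype <- function(growth_tsv = NULL, spots_tsv = NULL,
                          titers_tsv = NULL, biofilm_tsv = NULL,
                          out_dir = ".", rise_factor = 2, plateau_tol = 0.1,
                          countable_min = 3, countable_max = 100,
                          spot_volume = 0.01, paired = FALSE, alpha = 0.05,
                          quiet = FALSE) {
  if (is.null(growth_tsv) && is.null(spots_tsv) && is.null(titers_tsv) &&
      is.null(biofilm_tsv)) {
    stop("no input table given", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(provenance = file.path(out_dir, "provenance.json"))
  say <- function(...) if (!quiet) cat(..., "\n", sep = "")
  kinetics <- eop <- biofilm <- NULL

  if (!is.null(growth_tsv)) {
    kinetics <- estimate_kinetics(read_growth_tsv(growth_tsv),
                                  rise_factor = rise_factor,
                                  plateau_tol = plateau_tol)
    files[["kinetics"]] <- file.path(out_dir, "kinetics.json")
    write_json_report(
      list(latent_min = kinetics$latent_min, rise_min = kinetics$rise_min,
           burst_size = kinetics$burst_size, burst_se = kinetics$burst_se,
           n_replicates = kinetics$n_replicates),
      files[["kinetics"]]
    )
    say(sprintf(
      "growth: latent %g min, rise %g min, burst size %.3g PFU/infected cell",
      kinetics$latent_min, kinetics$rise_min, kinetics$burst_size
    ))
  }

  if (!is.null(spots_tsv) || !is.null(titers_tsv)) {
    titers <- if (!is.null(spots_tsv)) {
      read_spot_titers_tsv(spots_tsv, countable_min, countable_max,
                           spot_volume)
    } else {
      read_titers_tsv(titers_tsv)
    }
    eop <- efficiency_of_plating(titers)
    files[["eop_json"]] <- file.path(out_dir, "eop.json")
    files[["eop_tsv"]] <- file.path(out_dir, "eop.tsv")
    write_json_report(
      list(reference_strain = attr(eop, "reference_strain"),
           rows = as.data.frame(eop)),
      files[["eop_json"]]
    )
    rounded <- as.data.frame(eop)
    rounded$eop_percent <- signif(rounded$eop_percent, 2)
    utils::write.table(rounded, files[["eop_tsv"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    say(sprintf(
      "eop: %s",
      paste(sprintf("%s: %.2g%%", eop$strain_id, eop$eop_percent),
            collapse = "; ")
    ))
  }

  if (!is.null(biofilm_tsv)) {
    dat <- read_two_group_tsv(biofilm_tsv)
    biofilm <- gated_compare(dat$group_a, dat$group_b, paired = paired,
                             labels = dat$labels, alpha = alpha)
    files[["biofilm"]] <- file.path(out_dir, "biofilm_test.json")
    write_json_report(
      list(labels = biofilm$labels, n = biofilm$n, paired = biofilm$paired,
           normality_p = as.list(biofilm$normality_p),
           test_used = biofilm$test_used, statistic = biofilm$statistic,
           p_value = biofilm$p_value, significant = biofilm$significant,
           alpha = biofilm$alpha),
      files[["biofilm"]]
    )
    say(sprintf("biofilm: %s, %s%s", biofilm$test_used,
                format_p_value(biofilm$p_value),
                if (biofilm$significant) " (significant)" else ""))
  }

  write_json_report(
    provenance_block(
      inputs = list(growth_tsv = growth_tsv, spots_tsv = spots_tsv,
                    titers_tsv = titers_tsv, biofilm_tsv = biofilm_tsv),
      params = list(rise_factor = rise_factor, plateau_tol = plateau_tol,
                    countable_min = countable_min,
                    countable_max = countable_max,
                    spot_volume = spot_volume, paired = paired,
                    alpha = alpha)
    ),
    files[["provenance"]]
  )
  invisible(list(kinetics = kinetics, eop = eop, biofilm = biofilm,
                 files = files))
}
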