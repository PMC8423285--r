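# Synthetic-data generators: coding genome pairs with controlled per-amino-
# acid codon bias, one-step growth curves, spot dilution series, and
# two-group biofilm datasets. Every generator is a pure function of its
# parameters and a single integer seed (bit-reproducible), and returns the
# generating ground truth alongside the data so estimators can be checked
# against what was simulated.

#' Uniform synonymous codon weights
#'
#' One weight vector per amino acid (stop excluded), uniform over the
#' synonymous codons of the standard genetic code.
#'
#' @return Named list: per amino acid (one-letter code), a named numeric
#'   vector over its codons summing to 1.
#' @export
uniform_codon_weights <- function() {
  gc_map <- Biostrings::GENETIC_CODE
  fams <- split(names(gc_map), unname(gc_map))
  fams <- fams[setdiff(names(fams), "*")]
  lapply(fams, function(cs) {
    cs <- sort(cs)
    stats::setNames(rep(1 / length(cs), length(cs)), cs)
  })
}

#' Codon weights with chosen fold-biases relative to uniform
#'
#' Starts from [uniform_codon_weights()] and up-weights chosen codons so
#' that, within each synonymous family, the chosen codon's weight is `fold`
#' times the uniform weight; the remaining family weight is split equally
#' over the unchosen codons. Because the phage:host usage ratio of a codon
#' equals the ratio of its weights when both genomes share the same gene
#' structure, a genome pair built from these weights against uniform host
#' weights has true usage ratio `fold` at each chosen codon.
#'
#' @param fold named numeric vector, e.g. `c(ACT = 3)`; names are codons,
#'   values the desired fold over uniform. `fold / family_size` must stay
#'   below 1.
#' @return Weight list as in [uniform_codon_weights()].
#' @export
#' @examples
#' w <- biased_codon_weights(c(ACT = 3))
#' w$T["ACT"]
biased_codon_weights <- function(fold) {
  stopifnot(is.numeric(fold), length(fold) >= 1, !is.null(names(fold)))
  w <- uniform_codon_weights()
  gc_map <- Biostrings::GENETIC_CODE
  if (any(!names(fold) %in% names(gc_map))) {
    stop("unknown codon(s): ",
         paste(setdiff(names(fold), names(gc_map)), collapse = ", "),
         call. = FALSE)
  }
  aa_of <- unname(gc_map[names(fold)])
  if (any(aa_of == "*")) stop("cannot bias a stop codon", call. = FALSE)
  for (aa in unique(aa_of)) {
    fam <- w[[aa]]
    f <- fold[names(fold)[aa_of == aa]]
    target <- f / length(fam)
    if (sum(target) >= 1) {
      stop("fold too large for the ", aa, " family", call. = FALSE)
    }
    rest <- setdiff(names(fam), names(f))
    if (length(rest) == 0L) {
      stop("cannot bias every codon of the ", aa, " family", call. = FALSE)
    }
    fam[names(f)] <- target
    fam[rest] <- (1 - sum(target)) / length(rest)
    w[[aa]] <- fam
  }
  w
}

#' KMI8-like phage codon bias preset
#'
#' Emulates the codon-usage structure observed for phage KMI8 against its
#' *K. michiganensis* host: five codons over-used at least 2.5-fold, the
#' strongest being ACT (threonine) at over 3-fold.
#'
#' @return Weight list as in [uniform_codon_weights()].
#' @export
kmi8_like_codon_bias <- function() {
  biased_codon_weights(
    c(ACT = 3.2, GGT = 2.95, CCG = 2.9, GTT = 2.85, TCT = 2.75)
  )
}

#' Specification of a synthetic coding genome
#'
#' @param n_genes number of genes (default 78, a typical phage gene count).
#' @param gene_length_codons integer range `c(min, max)` of body codons per
#'   gene, drawn uniformly (default 100 to 350, giving phage-typical ~0.3
#'   to 1 kb genes).
#' @param weights per-amino-acid synonymous codon weights, as returned by
#'   [uniform_codon_weights()] or [biased_codon_weights()].
#' @return A `codon_bias_spec` object.
#' @export
codon_bias_spec <- function(n_genes = 78, gene_length_codons = c(100, 350),
                            weights = uniform_codon_weights()) {
  stopifnot(
    n_genes >= 1,
    length(gene_length_codons) == 2L,
    gene_length_codons[1L] >= 1,
    gene_length_codons[2L] >= gene_length_codons[1L]
  )
  sums <- vapply(weights, sum, numeric(1))
  if (any(abs(sums - 1) > 1e-9) || any(unlist(weights) < 0)) {
    stop("weights must be non-negative and sum to 1 per amino acid",
         call. = FALSE)
  }
  if (any(vapply(weights, function(x) all(x == 0), logical(1)))) {
    stop("an amino acid has an all-zero weight vector", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes),
         gene_length_codons = as.integer(gene_length_codons),
         weights = weights),
    class = "codon_bias_spec"
  )
}

#' Generating codon frequency profile of a spec
#'
#' The expected post-start-stripping relative codon frequency of a genome
#' drawn from the spec: body codons are an equal mixture over amino acids
#' times the synonymous weights, plus exactly one TAA stop per gene.
#'
#' @param spec a [codon_bias_spec()].
#' @return Named numeric vector over the 64 codons summing to 1.
#' @export
true_codon_profile <- function(spec) {
  stopifnot(inherits(spec, "codon_bias_spec"))
  m <- mean(spec$gene_length_codons)  # expected body codons per gene
  f <- stats::setNames(numeric(64L), codon_alphabet())
  p_aa <- 1 / length(spec$weights)
  for (aa in names(spec$weights)) {
    wts <- spec$weights[[aa]]
    f[names(wts)] <- f[names(wts)] + m * p_aa * wts
  }
  f["TAA"] <- f["TAA"] + 1
  f / (m + 1)
}

# Draw the gene sequences of one genome (body codons per spec weights,
# framed by ATG and TAA), then assemble them with random spacers on
# alternating strands and emit the annotation.
synth_genome <- function(spec, genome_id, spacer_length) {
  lens <- sample(seq(spec$gene_length_codons[1L], spec$gene_length_codons[2L]),
                 spec$n_genes, replace = TRUE)
  aas <- sample(names(spec$weights), sum(lens), replace = TRUE)
  codons <- character(length(aas))
  for (aa in unique(aas)) {
    idx <- which(aas == aa)
    wts <- spec$weights[[aa]]
    codons[idx] <- sample(names(wts), length(idx), replace = TRUE, prob = wts)
  }
  gene_of <- factor(rep(seq_along(lens), lens), levels = seq_along(lens))
  bodies <- vapply(split(codons, gene_of), paste, character(1), collapse = "")
  genes <- paste0("ATG", bodies, "TAA")

  spacers <- vapply(seq_len(spec$n_genes + 1L), function(i) {
    paste(sample(c("A", "C", "G", "T"), spacer_length, replace = TRUE),
          collapse = "")
  }, character(1))
  strands <- rep(c("+", "-"), length.out = spec$n_genes)
  placed <- ifelse(strands == "-",
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAStringSet(genes))),
                   genes)
  chunks <- character(2L * spec$n_genes + 1L)
  chunks[seq(1L, length(chunks), by = 2L)] <- spacers
  chunks[seq(2L, length(chunks), by = 2L)] <- placed
  full <- paste(chunks, collapse = "")

  gene_w <- nchar(genes)
  starts <- spacer_length + 1L +
    cumsum(c(0L, utils::head(gene_w + spacer_length, -1L)))
  ends <- starts + gene_w - 1L
  features <- GenomicRanges::GRanges(
    seqnames = genome_id,
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = strands,
    type = "CDS",
    ID = sprintf("gene_%04d", seq_len(spec$n_genes)),
    phase = 0L
  )
  genome <- Biostrings::DNAStringSet(stats::setNames(full, genome_id))
  list(genome = genome, features = features, gene_seqs = genes)
}

#' Generate a host/phage genome pair with known codon-usage truth
#'
#' Builds two synthetic coding genomes (each gene is ATG + body codons drawn
#' per the spec's weights + TAA, genes alternating between strands with
#' random spacer sequence) and returns, alongside the sequences and
#' annotations, the generating relative codon frequencies and their
#' phage:host ratios. With `out_dir` set, FASTA and GFF3 files plus a JSON
#' manifest of the specs and seed are written; outputs are byte-identical
#' across reruns with the same arguments.
#'
#' @param host_bias,phage_bias [codon_bias_spec()] objects.
#' @param seed integer seed for the single pseudo-random stream used.
#' @param out_dir optional directory to write `host.fasta`, `host.gff3`,
#'   `phage.fasta`, `phage.gff3` and `manifest.json` into.
#' @param spacer_length intergenic spacer length in bases (default 30).
#' @return List with elements `host` and `phage` (each: `genome`
#'   DNAStringSet, `features` GRanges), `truth` (data frame `codon`,
#'   `f_host`, `f_phage`, `r`) and `files` (named paths or NULL).
#' @export
generate_genome_pair <- function(host_bias, phage_bias, seed = 1,
                                 out_dir = NULL, spacer_length = 30) {
  stopifnot(inherits(host_bias, "codon_bias_spec"),
            inherits(phage_bias, "codon_bias_spec"))
  res <- withr::with_seed(as.integer(seed), {
    list(
      host = synth_genome(host_bias, "host_synthetic", spacer_length),
      phage = synth_genome(phage_bias, "phage_synthetic", spacer_length)
    )
  })
  f_host <- true_codon_profile(host_bias)
  f_phage <- true_codon_profile(phage_bias)
  truth <- data.frame(
    codon = codon_alphabet(),
    f_host = unname(f_host),
    f_phage = unname(f_phage),
    r = unname(ifelse(f_host > 0, f_phage / f_host, NA_real_)),
    stringsAsFactors = FALSE
  )
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      host_fasta = file.path(out_dir, "host.fasta"),
      host_gff = file.path(out_dir, "host.gff3"),
      phage_fasta = file.path(out_dir, "phage.fasta"),
      phage_gff = file.path(out_dir, "phage.gff3"),
      manifest = file.path(out_dir, "manifest.json")
    )
    Biostrings::writeXStringSet(res$host$genome, files[["host_fasta"]])
    rtracklayer::export(res$host$features, files[["host_gff"]], format = "gff3")
    Biostrings::writeXStringSet(res$phage$genome, files[["phage_fasta"]])
    rtracklayer::export(res$phage$features, files[["phage_gff"]], format = "gff3")
    spec_json <- function(s) {
      list(n_genes = s$n_genes, gene_length_codons = s$gene_length_codons,
           weights = s$weights)
    }
    write_json_report(
      list(generator = "generate_genome_pair", seed = as.integer(seed),
           spacer_length = spacer_length,
           host = spec_json(host_bias), phage = spec_json(phage_bias)),
      files[["manifest"]]
    )
  }
  list(host = res$host, phage = res$phage, truth = truth, files = files)
}

#' Generate one-step growth curves with known kinetics
#'
#' Deterministic piecewise log-linear template -- baseline titer until the
#' latent period ends, log-linear rise to `baseline * burst` over the rise
#' period, then plateau -- sampled every `sample_interval` minutes, with
#' multiplicative log-normal noise per point.
#'
#' @param latent_min latent period in minutes (default 20).
#' @param rise_min rise period in minutes (default 30).
#' @param burst burst size, plateau-to-baseline titer ratio (default 12).
#' @param baseline_titer pre-burst titer in PFU/mL (default 1e4).
#' @param sample_interval sampling interval in minutes (default 10).
#' @param horizon_min last sampled time (default 90); must be at least
#'   `latent_min + rise_min`.
#' @param noise_sigma_log10 SD of the log10 multiplicative noise (default
#'   0.02).
#' @param n_replicates number of replicate curves (default 3).
#' @param seed integer seed.
#' @return Long data frame `replicate`, `time_min`, `pfu_per_ml`.
#' @export
#' @examples
#' estimate_kinetics(generate_growth_curves(noise_sigma_log10 = 0))
generate_growth_curves <- function(latent_min = 20, rise_min = 30, burst = 12,
                                   baseline_titer = 1e4, sample_interval = 10,
                                   horizon_min = 90, noise_sigma_log10 = 0.02,
                                   n_replicates = 3, seed = 1) {
  stopifnot(latent_min >= 0, rise_min > 0, burst > 1, baseline_titer > 0,
            sample_interval > 0, noise_sigma_log10 >= 0, n_replicates >= 1)
  if (horizon_min < latent_min + rise_min) {
    stop("horizon shorter than latent + rise", call. = FALSE)
  }
  times <- seq(0, horizon_min, by = sample_interval)
  template <- ifelse(
    times <= latent_min, baseline_titer,
    ifelse(times < latent_min + rise_min,
           baseline_titer * burst^((times - latent_min) / rise_min),
           baseline_titer * burst)
  )
  withr::with_seed(as.integer(seed), {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      noise <- 10^stats::rnorm(length(times), 0, noise_sigma_log10)
      data.frame(
        replicate = sprintf("rep%d", r),
        time_min = times,
        pfu_per_ml = template * noise,
        stringsAsFactors = FALSE
      )
    }))
  })
}

#' Generate a spot dilution series with Poisson plaque counts
#'
#' Plaque counts per spot are Poisson with mean
#' `true_titer * spot_volume * 10^(-exponent)`.
#'
#' @param true_titer true stock titer in PFU/mL.
#' @param dilution_exponents 10-fold dilution steps (default 4:8).
#' @param spot_volume spotted volume in mL (default 0.01).
#' @param seed integer seed.
#' @return A [spot_series()].
#' @export
generate_spot_series <- function(true_titer, dilution_exponents = 4:8,
                                 spot_volume = 0.01, seed = 1) {
  stopifnot(true_titer > 0)
  counts <- withr::with_seed(as.integer(seed), {
    stats::rpois(length(dilution_exponents),
                 true_titer * spot_volume * 10^(-dilution_exponents))
  })
  spot_series(dilution_exponents, counts, spot_volume)
}

#' Generate two-group biofilm data with a known effect
#'
#' Control measurements are drawn around a baseline mean; treated
#' measurements around the baseline shifted down by the effect preset
#' (`none`: 0%; `strong_reduction`: 60% mean decrease, the scale of
#' reduction a strongly lytic phage produces). Noise is either normal or
#' right-skewed log-normal, both parameterized by a coefficient of
#' variation so presets are scale-free. The default n of 42 mirrors a
#' confocal counting design of 14 fields across triplicate experiments.
#'
#' @param n observations per group (default 42 = 14 x 3).
#' @param effect `"none"` or `"strong_reduction"`.
#' @param noise `"normal"` or `"lognormal"`.
#' @param paired paired design flag carried into the returned object
#'   (absorbance-style data are paired; count-style, the default, are not).
#' @param baseline_mean control-group mean (default 1, e.g. absorbance AU).
#' @param cv coefficient of variation of the noise (default 0.1).
#' @param seed integer seed.
#' @return A `two_group_data`: list with `group_a` (control), `group_b`
#'   (treated), `paired`, `labels`, `effect`, `noise`.
#' @export
generate_biofilm_data <- function(n = 42, effect = c("none", "strong_reduction"),
                                  noise = c("normal", "lognormal"),
                                  paired = FALSE, baseline_mean = 1, cv = 0.1,
                                  seed = 1) {
  effect <- match.arg(effect)
  noise <- match.arg(noise)
  stopifnot(n >= 3, baseline_mean > 0, cv > 0)
  reduction <- c(none = 0, strong_reduction = 0.6)[[effect]]
  draw <- function(k, mu) {
    if (noise == "normal") {
      stats::rnorm(k, mean = mu, sd = cv * mu)
    } else {
      sdlog <- sqrt(log1p(cv^2))
      stats::rlnorm(k, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    }
  }
  groups <- withr::with_seed(as.integer(seed), {
    list(a = draw(n, baseline_mean),
         b = draw(n, baseline_mean * (1 - reduction)))
  })
  structure(
    list(group_a = groups$a, group_b = groups$b, paired = paired,
         labels = c("control", "phage_treated"),
         effect = effect, noise = noise),
    class = "two_group_data"
  )
}

#' @export
print.two_group_data <- function(x, ...) {
  cat(sprintf(
    "<two_group_data> %s (n=%d, mean %.3g) vs %s (n=%d, mean %.3g); %s, %s noise, effect '%s'\n",
    x$labels[1L], length(x$group_a), mean(x$group_a),
    x$labels[2L], length(x$group_b), mean(x$group_b),
    if (x$paired) "paired" else "independent", x$noise, x$effect
  ))
  invisible(x)
}
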