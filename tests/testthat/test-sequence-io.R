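test_that("read_fasta concatenates wrapped lines, strips whitespace, upper-cases", {
  fa <- local_fasta(c(">g1 some description", "ACGT", "ACGT",
                      ">g2", "AC GT", ">g3", "acgtn"))
  x <- read_fasta(fa)
  expect_s4_class(x, "DNAStringSet")
  expect_equal(names(x), c("g1", "g2", "g3"))
  expect_equal(as.character(x[["g1"]]), "ACGTACGT")
  expect_equal(Biostrings::width(x)[1], 8L)
  expect_equal(as.character(x[["g2"]]), "ACGT")
  expect_equal(as.character(x[["g3"]]), "ACGTN")
})

test_that("read_fasta rejects empty files and non-IUPAC characters with position", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta(empty), "no records")
  expect_error(read_fasta(withr::local_tempfile()), "not found")
  bad <- local_fasta(c(">g1", "ACZT"))
  expect_error(read_fasta(bad), "'Z' in record 'g1' at position 3")
})

test_that("read_gff_cds keeps only CDS rows, preserving coordinates and strand", {
  gff <- local_gff(c(
    "chr1\t.\tgene\t1\t20\t.\t+\t.\tID=g1",
    "chr1\t.\tCDS\t3\t8\t.\t+\t0\tID=c1",
    "chr1\t.\tCDS\t10\t15\t.\t-\t0\tID=c2",
    "chr1\t.\texon\t3\t8\t.\t+\t.\tID=e1",
    "chr2\t.\tCDS\t1\t6\t.\t+\t0\tID=c3"
  ))
  f <- read_gff_cds(gff)
  expect_length(f, 3L)
  expect_equal(f$feature_id, c("c1", "c2", "c3"))
  expect_equal(BiocGenerics::start(f), c(3L, 10L, 1L))
  expect_equal(BiocGenerics::end(f), c(8L, 15L, 6L))
  expect_equal(as.character(BiocGenerics::strand(f)), c("+", "-", "+"))
  # seq_id filter
  expect_length(read_gff_cds(gff, seq_id_filter = "chr2"), 1L)
  # strandless CDS rejected
  bad <- local_gff("chr1\t.\tCDS\t3\t8\t.\t.\t0\tID=c1")
  expect_error(read_gff_cds(bad), "strand")
  # start > end rejected
  rev <- local_gff("chr1\t.\tCDS\t8\t3\t.\t+\t0\tID=c1")
  expect_error(read_gff_cds(rev))
})

test_that("extract_cds slices 1-based inclusive coordinates on both strands", {
  g <- Biostrings::DNAStringSet(c(chr = "AAATGCATTT"))
  plus <- GenomicRanges::GRanges("chr", IRanges::IRanges(3, 8), strand = "+",
                                 feature_id = "c1", phase = 0L)
  minus <- GenomicRanges::GRanges("chr", IRanges::IRanges(3, 8), strand = "-",
                                  feature_id = "c1", phase = 0L)
  expect_equal(as.character(extract_cds(g, plus)$seqs[["c1"]]), "ATGCAT")
  expect_equal(
    as.character(extract_cds(g, minus, drop_internal_stop = FALSE)$seqs[["c1"]]),
    revcomp_oracle("ATGCAT")
  )
})

test_that("multi-segment CDS sharing an ID are joined in coordinate order", {
  s <- "ATGAAACCCGGGTTTAAA"
  g <- Biostrings::DNAStringSet(c(chr = s))
  f <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(start = c(1, 10), end = c(6, 15)),
    strand = "+", feature_id = c("c1", "c1"), phase = 0L
  )
  got <- extract_cds(g, f)$seqs[["c1"]]
  expect_equal(as.character(got), paste0(substr(s, 1, 6), substr(s, 10, 15)))
  expect_equal(nchar(as.character(got)), 12L)
  # minus-strand join: reverse complement of the ascending concatenation
  fm <- GenomicRanges::GRanges(
    "chr", IRanges::IRanges(start = c(1, 10), end = c(6, 15)),
    strand = "-", feature_id = c("c1", "c1"), phase = 0L
  )
  expect_equal(
    as.character(extract_cds(g, fm, drop_internal_stop = FALSE)$seqs[["c1"]]),
    revcomp_oracle(paste0(substr(s, 1, 6), substr(s, 10, 15)))
  )
})

test_that("validation drops and logs bad CDS; counts are conserved", {
  g <- Biostrings::DNAStringSet(c(chr = "ATGAAATAAATGTAACCCTTTATGCCCNNNTAAAT"))
  f <- GenomicRanges::GRanges(
    "chr",
    IRanges::IRanges(start = c(1, 1, 13, 24, 1), end = c(9, 4, 24, 32, 9)),
    strand = "+",
    feature_id = c("ok", "len4", "stopin", "ambig", "dup_ok"), phase = 0L
  )
  expect_message(
    res <- extract_cds(g, f, verbose = TRUE),
    "DROPPED len4 length_not_multiple_of_3"
  )
  expect_setequal(names(res$seqs), c("ok", "dup_ok"))
  expect_setequal(res$dropped$feature_id, c("len4", "stopin", "ambig"))
  expect_equal(res$dropped$reason[res$dropped$feature_id == "stopin"],
               "internal_stop")
  expect_equal(res$dropped$reason[res$dropped$feature_id == "ambig"],
               "ambiguous_bases")
  # retained + dropped == distinct input features
  expect_equal(length(res$seqs) + nrow(res$dropped), length(unique(f$feature_id)))
  # internal stops kept when the policy allows them
  lax <- extract_cds(g, f[3], drop_internal_stop = FALSE)
  expect_equal(length(lax$seqs), 1L)
})

test_that("extract_cds honors phase, final-stop and bounds policies", {
  g <- Biostrings::DNAStringSet(c(chr = "ATGAAACCCTAAGG"))
  f <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 12), strand = "+",
                              feature_id = "c1", phase = 0L)
  expect_equal(as.character(extract_cds(g, f)$seqs[["c1"]]), "ATGAAACCCTAA")
  expect_equal(
    as.character(extract_cds(g, f, drop_final_stop = TRUE)$seqs[["c1"]]),
    "ATGAAACCC"
  )
  partial <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 12),
                                    strand = "+", feature_id = "c1",
                                    phase = 1L)
  expect_error(extract_cds(g, partial), "no valid CDS")
  expect_equal(length(extract_cds(g, partial, include_partial = TRUE)), 1L)
  oob <- GenomicRanges::GRanges("chr", IRanges::IRanges(10, 99), strand = "+",
                                feature_id = "c1", phase = 0L)
  expect_error(extract_cds(g, oob), "out of bounds")
})

test_that("minus-strand extraction equals reverse complement of plus-strand slice", {
  withr::with_seed(401, {
    for (i in 1:20) {
      g <- Biostrings::DNAStringSet(c(chr = random_dna(300)))
      start <- sample(1:250, 1)
      len <- 3 * sample(2:15, 1)
      mk <- function(strand) {
        GenomicRanges::GRanges("chr",
                               IRanges::IRanges(start, start + len - 1),
                               strand = strand, feature_id = "x", phase = 0L)
      }
      plus <- extract_cds(g, mk("+"), drop_internal_stop = FALSE)
      minus <- extract_cds(g, mk("-"), drop_internal_stop = FALSE)
      expect_equal(as.character(minus$seqs[["x"]]),
                   revcomp_oracle(as.character(plus$seqs[["x"]])))
    }
  })
})

test_that("CDS sets round-trip through FASTA", {
  withr::with_seed(402, {
    g <- Biostrings::DNAStringSet(c(chr = random_dna(200)))
    f <- GenomicRanges::GRanges(
      "chr", IRanges::IRanges(start = c(2, 50, 101), end = c(31, 91, 160)),
      strand = c("+", "-", "+"),
      feature_id = c("a", "b", "c"), phase = 0L
    )
    cds <- extract_cds(g, f, drop_internal_stop = FALSE)
    path <- withr::local_tempfile(fileext = ".fasta")
    write_cds_fasta(cds, path)
    back <- read_fasta(path)
    expect_equal(as.character(back), as.character(cds$seqs))
  })
})
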