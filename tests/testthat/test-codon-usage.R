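test_that("strip_start_codons removes exactly the first codon of every CDS", {
  expect_equal(unname(strip_start_codons(c(g = "ATGAAATTTTGA"))), "AAATTTTGA")
  expect_equal(unname(strip_start_codons(c(g = "ATGTAA"))), "TAA")
  withr::with_seed(403, {
    seqs <- vapply(1:10, function(i) random_dna(3 * sample(2:30, 1)),
                   character(1))
    names(seqs) <- paste0("g", 1:10)
    stripped <- strip_start_codons(seqs)
    expect_equal(sum(nchar(stripped)), sum(nchar(seqs)) - 30L)
    expect_equal(names(stripped), names(seqs))
  })
  expect_error(strip_start_codons("ATG"), "shorter than 6")
})

test_that("count_codons pools non-overlapping triplets across a set", {
  counts <- count_codons("AAATTTTGA")
  expect_equal(sum(counts), 3)
  expect_equal(unname(counts[c("AAA", "TTT", "TGA")]), c(1, 1, 1))
  expect_equal(length(counts), 64L)
  expect_equal(names(counts), sort(names(counts)))
  counts2 <- count_codons(c("AAAAAA", "AAA"))
  expect_equal(unname(counts2[["AAA"]]), 3)
  expect_equal(sum(counts2), 3)
  expect_error(count_codons(character(0)), "no valid CDS")
  expect_error(count_codons(c(x = "AANTTT")), "non-ACGT.*'x'.*codon 1")
})

test_that("count_codons agrees with a substring-walking oracle", {
  withr::with_seed(404, {
    seqs <- vapply(1:8, function(i) random_dna(3 * sample(5:40, 1)),
                   character(1))
    counts <- count_codons(seqs)
    oracle <- codon_counts_oracle(seqs)
    expect_equal(counts[names(oracle)], oracle[names(oracle)],
                 ignore_attr = TRUE)
    expect_equal(sum(counts), sum(nchar(seqs)) / 3)
  })
})

test_that("relative frequencies divide by the total and sum to one", {
  counts <- count_codons("AAATTTTGA")
  f <- relative_frequencies(counts)
  expect_equal(unname(f[["AAA"]]), 1 / 3)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  single <- stats::setNames(numeric(64), names(counts))
  single["ACT"] <- 5
  fs <- relative_frequencies(single)
  expect_equal(unname(fs[["ACT"]]), 1)
  expect_equal(sum(fs == 0), 63L)
  expect_error(relative_frequencies(single * 0), "zero")
})

test_that("codon-count conservation holds after start stripping", {
  withr::with_seed(405, {
    seqs <- vapply(1:12, function(i) random_dna(3 * sample(3:50, 1)),
                   character(1))
    stripped <- strip_start_codons(seqs)
    expect_equal(sum(count_codons(stripped)), sum(nchar(stripped)) / 3)
    expect_equal(sum(count_codons(stripped)),
                 sum(nchar(seqs) / 3) - length(seqs))
  })
})

test_that("usage_ratio computes r_i with undefined host-zero codons excluded", {
  counts <- count_codons(c(random_dna(300)))
  same <- usage_ratio(counts, counts)
  defined <- !is.na(same$ratio)
  expect_true(all(same$ratio[defined] == 1))
  expect_true(all(same$bin[defined] == "similar"))
  expect_true(all(same$bin[!defined] == "undefined"))

  # a 3x frequency excess lands in the "higher" bin
  f_host <- stats::setNames(rep(1 / 64, 64), codon_names <- same$codon)
  f_phage <- f_host
  f_phage["ACT"] <- 0.03
  f_host["ACT"] <- 0.01
  f_phage <- f_phage / sum(f_phage)
  f_host <- f_host / sum(f_host)
  rt <- usage_ratio(f_phage, f_host)
  ract <- rt$ratio[rt$codon == "ACT"]
  expect_gt(ract, 2.9)
  expect_equal(as.character(rt$bin[rt$codon == "ACT"]), "higher")

  # host zero -> undefined, excluded from rankings
  f_h0 <- f_host
  f_h0["GGG"] <- 0
  f_h0 <- f_h0 / sum(f_h0)
  rt0 <- usage_ratio(f_phage, f_h0)
  expect_true(is.na(rt0$ratio[rt0$codon == "GGG"]))
  expect_equal(as.character(rt0$bin[rt0$codon == "GGG"]), "undefined")
  tb <- top_bottom_codons(rt0, 10)
  expect_false("GGG" %in% c(tb$top$codon, tb$bottom$codon))
})

test_that("ratio reciprocity: r(A,B) * r(B,A) = 1 for defined codons", {
  withr::with_seed(406, {
    for (i in 1:5) {
      ca <- count_codons(random_dna(3 * 2000))
      cb <- count_codons(random_dna(3 * 2000))
      ab <- usage_ratio(ca, cb)$ratio
      ba <- usage_ratio(cb, ca)$ratio
      both <- !is.na(ab) & !is.na(ba) & ab > 0
      expect_true(all(abs(ab[both] * ba[both] - 1) < 1e-9))
    }
  })
})

test_that("classify_ratio bins partition at exactly 0.9 and 1.1", {
  expect_equal(as.character(classify_ratio(1.1)), "higher")
  expect_equal(as.character(classify_ratio(0.9)), "similar")
  expect_equal(as.character(classify_ratio(0.89)), "lower")
  expect_equal(as.character(classify_ratio(c(3, 1.0999, 0.0))),
               c("higher", "similar", "lower"))
  expect_error(classify_ratio(-0.1), "negative")
  # every defined ratio falls in exactly one bin
  withr::with_seed(407, {
    r <- runif(500, 0, 3)
    bins <- classify_ratio(r)
    expect_false(anyNA(bins))
    expect_equal(as.vector(table(bins)[c("higher", "similar", "lower")]),
                 c(sum(r >= 1.1), sum(r >= 0.9 & r < 1.1), sum(r < 0.9)))
  })
})

test_that("top_bottom_codons matches a full sort with alphabetical tie-break", {
  counts <- count_codons(random_dna(3 * 500))
  all_one <- usage_ratio(counts, counts)
  tb <- top_bottom_codons(all_one, 3)
  first3 <- sort(all_one$codon[!is.na(all_one$ratio)])[1:3]
  expect_equal(tb$top$codon, first3)
  expect_equal(tb$bottom$codon, first3)

  withr::with_seed(408, {
    ca <- count_codons(random_dna(3 * 3000))
    cb <- count_codons(random_dna(3 * 3000))
    rt <- usage_ratio(ca, cb)
    tb <- top_bottom_codons(rt, 10)
    d <- rt[!is.na(rt$ratio), ]
    ord <- d[order(-d$ratio, d$codon), ]
    ordb <- d[order(d$ratio, d$codon), ]
    expect_equal(tb$top$codon, ord$codon[1:10])
    expect_equal(tb$bottom$codon, ordb$codon[1:10])
    expect_equal(nrow(tb$top), 10L)
  })
  expect_error(top_bottom_codons(all_one, 100), "fewer than k")
})

test_that("gc_content counts unambiguous bases only and is strand-symmetric", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("GATC"), 0.5)
  expect_equal(gc_content("GCNNNNAT"), 0.5)  # ambiguity excluded both sides
  expect_error(gc_content("NNN"), "no unambiguous")
  withr::with_seed(409, {
    for (i in 1:10) {
      s <- random_dna(sample(50:500, 1))
      expect_equal(gc_content(s), gc_content(revcomp_oracle(s)))
    }
  })
})
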