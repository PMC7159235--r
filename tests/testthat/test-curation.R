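make_del <- function(chrom, start, end, hom = list(character()),
                     het = list(character()), samples = c("S1", "S2")) {
  d <- tibble::tibble(id = sprintf("d%d", seq_along(start)),
                      chrom = chrom, start = as.integer(start),
                      end = as.integer(end),
                      length = as.integer(end - start),
                      af = 0.1, n_hom = lengths(hom), n_het = lengths(het),
                      hom_samples = hom, het_samples = het,
                      filter = "PASS")
  attr(d, "samples") <- samples
  d
}

make_enh <- function(chrom, start, end) {
  tibble::tibble(id = enhancer_id(chrom, start, end), chrom = chrom,
                 start = as.integer(start), end = as.integer(end))
}

test_that("homozygous filter keeps hom carriers and drops exon overlap", {
  dels <- make_del(rep("chr1", 3), c(100, 400, 700), c(300, 600, 900),
                   hom = list("S1", character(), "S1"),
                   het = list(character(), c("S1", "S2"), character()))
  # exon shares exactly 1 bp with the third deletion: [899, 950) vs [700, 900)
  exons <- interval_table("chr1", 899, 950)
  # brute-force oracle: pairwise intersection widths
  ov <- sapply(seq_len(3), function(i)
    max(0, min(dels$end[i], 950) - max(dels$start[i], 899)))
  expect_equal(ov, c(0, 0, 1))
  kept <- homozygous_noncoding_deletions(dels, exons)
  expect_equal(kept$id, "d1")  # d2 het-only, d3 touches the exon
})

test_that("LoF tolerance requires full containment, boundaries included", {
  enh <- make_enh("chr1", 100, 200)
  expect_equal(call_lof_tolerant(enh, make_del("chr1", 50, 300,
                                               hom = list("S1"))),
               enh$id)                                   # strict superset
  expect_equal(call_lof_tolerant(enh, make_del("chr1", 150, 300,
                                               hom = list("S1"))),
               character())                              # partial deletion
  expect_equal(call_lof_tolerant(enh, make_del("chr1", 100, 200,
                                               hom = list("S1"))),
               enh$id)                                   # boundary equality
})

test_that("tolerant calls are order-invariant, duplication-invariant, monotone", {
  set.seed(5)
  enh <- make_enh("chr1", seq(0, 9000, by = 1000),
                  seq(0, 9000, by = 1000) + sample(200:800, 10))
  dels <- make_del("chr1", sample(0:9000, 20), NA, hom = rep(list("S1"), 20))
  dels$end <- dels$start + sample(100:2000, 20)
  dels$length <- dels$end - dels$start
  base <- call_lof_tolerant(enh, dels)
  shuffled <- dels[sample(nrow(dels)), ]
  expect_equal(call_lof_tolerant(enh, shuffled), base)
  expect_equal(call_lof_tolerant(enh, rbind(dels, dels)), base)
  # adding a deletion can only grow the called set
  extra <- rbind(dels, make_del("chr1", 0, 10000, hom = list("S2")))
  expect_true(all(base %in% call_lof_tolerant(enh, extra)))
})

test_that("low tolerance needs strict >50% reciprocal overlap", {
  e <- make_enh("chr1", 0, 100)
  # overlap 60 bp -> 0.6 of each: called
  expect_equal(call_low_tolerance(e, interval_table("chr1", 40, 140)), e$id)
  # overlap 100 -> 1.0 of enhancer but 100/300 of element: not called
  expect_equal(call_low_tolerance(e, interval_table("chr1", 0, 300)),
               character())
  # identical intervals: called
  expect_equal(call_low_tolerance(e, interval_table("chr1", 0, 100)), e$id)
  # exactly 50% both ways is NOT enough (strict inequality)
  e2 <- make_enh("chr1", 0, 100)
  expect_equal(call_low_tolerance(e2, interval_table("chr1", 50, 150)),
               character())
})

test_that("label sets are disjoint; conflicts drop from both classes", {
  expect_message(ls_ <- label_set(c("a", "b"), c("b", "c")), "both labels")
  expect_equal(ls_$lof_tolerant, "a")
  expect_equal(ls_$low_tolerance, "c")
  expect_equal(ls_$conflicts, "b")
  expect_error(label_set("a", "b", known_ids = "a"), "outside")
})

test_that("per-individual counts count distinct fully deleted enhancers", {
  enh <- make_enh("chr1", c(100, 300, 1000), c(200, 400, 1100))
  # one deletion spans the first two enhancers; S1 hom
  dels <- make_del("chr1", c(50, 950, 80), c(450, 1200, 450),
                   hom = list("S1", character(), "S1"),
                   het = list(character(), c("S2"), character()))
  res <- per_individual_counts(enh, dels)
  counts <- setNames(res$counts$n, res$counts$sample)
  expect_equal(counts[["S1"]], 2)  # two distinct despite two covering dels
  expect_equal(counts[["S2"]], 0)  # het only
  expect_equal(res$max, 2)
})

test_that("allele-frequency summary compares deleting vs all deletions", {
  enh <- make_enh("chr1", c(100, 500), c(200, 600))
  dels <- make_del("chr1", c(50, 450, 900, 1300), c(300, 700, 1000, 1400),
                   hom = rep(list("S1"), 4))
  dels$af <- c(0.4, 0.5, 0.1, 0.2)
  res <- allele_frequency_summary(dels, enh)
  expect_equal(sort(res$af$all.deleting), c(0.4, 0.5))
  expect_equal(length(res$af$all.all), 4)
  expect_true(res$comparisons$D[1] > 0)
  # identical sets give D = 0
  res0 <- allele_frequency_summary(dels,
                                   make_enh("chr1", c(60, 460, 910, 1310),
                                            c(290, 690, 990, 1390)))
  expect_equal(res0$comparisons$D[1], 0)
  # single observation per group -> skipped with note
  one <- allele_frequency_summary(dels[3, ], enh)
  expect_match(one$comparisons$note[1], "skipped")
})

test_that("curation recovers the synthetic ground truth on the small universe", {
  u <- small_universe()
  man <- u$manifest
  dels <- homozygous_noncoding_deletions(u$deletions, u$exons)
  expect_setequal(call_lof_tolerant(u$enhancers, dels),
                  man$id[man$class == "tolerant"])
  expect_setequal(call_low_tolerance(u$enhancers, u$conserved),
                  man$id[man$class == "low"])
  # every trap configuration stays out of the label sets
  traps <- man$id[man$trap != ""]
  lab <- small_labels()
  expect_length(intersect(traps, c(lab$lof_tolerant, lab$low_tolerance)), 0)
})
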