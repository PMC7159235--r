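test_that("region ids parse, including compound network keys", {
  p <- parse_region_id(c("chr1:100-200", "chr2:5-9$GENE1"))
  expect_equal(p$chrom, c("chr1", "chr2"))
  expect_equal(p$start, c(100L, 5L))
  expect_equal(p$end, c(200L, 9L))
  expect_equal(p$gene, c(NA, "GENE1"))
  expect_equal(p$id, c("chr1:100-200", "chr2:5-9"))
  expect_error(parse_region_id("chr1:banana"), "cannot parse")
})

test_that("interval construction enforces the coordinate invariants", {
  expect_silent(interval_table("chr1", 0, 1))
  expect_error(interval_table("chr1", 200, 100), "invalid interval")
  expect_error(interval_table("chr1", -5, 10), "invalid interval")
  df <- interval_table(c("chr1", "chr1"), c(100, 300), c(200, 400),
                       name = c("a", "b"))
  expect_equal(df$end - df$start, c(100L, 100L))
})

test_that("enhancer network rows merge into tissue-unioned edges", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("enhancer\tgene\ttissue",
               "chr1:100-200\tG1\ttissueA",
               "chr1:100-200\tG1\ttissueB",
               "chr1:100-200\tG2\ttissueC"), path)
  tm <- setNames(c("A", "B", "C"), c("tissueA", "tissueB", "tissueC"))
  nw <- read_enhancer_network(path, tm)
  expect_equal(nrow(nw$edges), 2)
  expect_equal(nw$edges$tissues[[1]], c("A", "B"))
  expect_equal(nw$edges$tissues[[2]], "C")
  expect_equal(nw$edges$weight, c(2L, 1L))
  expect_equal(nrow(nw$enhancers), 1)
  expect_equal(nw$n_discarded, 0)
})

test_that("single-row network yields one edge; unmapped tissues are dropped", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("enhancer\tgene\ttissue", "chr1:10-20\tG1\tliver"), path)
  nw <- read_enhancer_network(path, c(liver = "Liver"))
  expect_equal(nrow(nw$edges), 1)
  expect_equal(nw$edges$tissues[[1]], "Liver")

  nw2 <- read_enhancer_network(path, c(kidney = "Kidney"))
  expect_equal(nrow(nw2$edges), 0)
  expect_equal(nw2$n_discarded, 1)

  empty <- tempfile(fileext = ".tsv")
  writeLines("enhancer\tgene\ttissue", empty)
  expect_error(read_enhancer_network(empty), "empty")
})

test_that("symbolic <DEL> coordinates convert 1-based inclusive to 0-based", {
  path <- write_test_vcf(paste(
    c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "S1", "S2"), collapse = "\t"))
  cat("chr1\t101\td1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=200\tGT\t1|1\t0/1\n",
      file = path, append = TRUE)
  d <- read_deletions(path)
  expect_equal(d$start, 100L)
  expect_equal(d$end, 200L)
  expect_equal(d$length, 100L)
  expect_equal(d$hom_samples[[1]], "S1")   # 1|1 normalized to hom
  expect_equal(d$het_samples[[1]], "S2")
  expect_equal(d$af, (2 * 1 + 1) / (2 * 2))
})

test_that("explicit REF/ALT deletions left-align to the REF suffix", {
  # REF=ACGT ALT=A at POS=10: deleted bases are CGT = [10, 13) 0-based,
  # checked against manual left-alignment of the 3-bp deletion
  path <- write_test_vcf(paste(
    c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "S1"), collapse = "\t"))
  cat("chr1\t10\td2\tACGT\tA\t.\tPASS\t.\tGT\t0/1\n",
      file = path, append = TRUE)
  d <- read_deletions(path)
  expect_equal(d$start, 10L)
  expect_equal(d$end, 13L)
  expect_equal(d$length, 3L)
})

test_that("multi-allelic deletions split; other-allele carriers are non-carriers", {
  path <- write_test_vcf(paste(
    c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "S1", "S2", "S3"), collapse = "\t"))
  cat("chr1\t10\tm1\tACGTA\tA,AC\t.\tPASS\t.\tGT\t1/1\t2/2\t1/2\n",
      file = path, append = TRUE)
  d <- read_deletions(path)
  expect_equal(nrow(d), 2)
  expect_equal(d$id, c("m1_1", "m1_2"))
  expect_equal(d$hom_samples[[1]], "S1")      # allele 1: S2 is non-carrier
  expect_equal(d$het_samples[[1]], "S3")
  expect_equal(d$hom_samples[[2]], "S2")
  expect_equal(d$het_samples[[2]], "S3")
})

test_that("records without resolvable END are skipped with a warning", {
  path <- write_test_vcf(paste(
    c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "S1"), collapse = "\t"))
  cat("chr1\t10\tok\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=50\tGT\t1/1\n",
      "chr1\t100\tbad\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL\tGT\t1/1\n",
      sep = "", file = path, append = TRUE)
  expect_warning(d <- read_deletions(path), "skipped")
  expect_equal(nrow(d), 1)
  expect_equal(d$id, "ok")
})

test_that("BED parsing validates coordinates and keeps names", {
  ok <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr2\t5\t10\tfeat"), ok)
  b <- read_bed(ok)
  expect_equal(b$start, c(100L, 5L))
  expect_equal(b$name, c(NA, "feat"))

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), bad)
  expect_error(read_bed(bad), "line 2")
})

test_that("BED and scalar tables round-trip exactly", {
  df <- interval_table(c("chr1", "chr2"), c(0, 500), c(100, 900),
                       name = c("x", "y"))
  p <- tempfile(fileext = ".bed")
  write_bed(df, p)
  expect_equal(read_bed(p), df)

  x <- c(G1 = 0.62, G2 = 0.125)  # realistic indispensability values
  p2 <- tempfile(fileext = ".tsv")
  write_scalar_table(x, p2)
  expect_equal(read_scalar_table(p2), x)
})

test_that("scalar tables reject duplicates and non-numeric values", {
  p <- tempfile()
  writeLines(c("G1\t0.62"), p)
  expect_equal(read_scalar_table(p), c(G1 = 0.62))

  writeLines(character(), p)
  expect_length(read_scalar_table(p), 0)

  writeLines(c("G1\t0.1", "G1\t0.2"), p)
  expect_error(read_scalar_table(p), "duplicated key 'G1'")

  writeLines(c("G1\t0.1", "G2\tnot_a_number"), p)
  expect_error(read_scalar_table(p), "G2")
})

test_that("JASPAR motif text parses to count matrices", {
  p <- tempfile()
  writeLines(c(">MA0001.1 TEST",
               "A  [ 1 2 17 ]",
               "C  [ 0 1 1 ]",
               "G  [ 2 0 1 ]",
               "T  [ 1 1 1 ]"), p)
  pw <- read_jaspar_pwms(p)
  expect_named(pw, "MA0001.1")
  expect_equal(dim(pw[[1]]), c(4L, 3L))
  expect_equal(unname(pw[[1]]["A", 3]), 17)

  writeLines(c(">BAD", "A 0", "C 0", "G 0", "T 0"), p)
  expect_error(read_jaspar_pwms(p), "zero column sum")
})

test_that("the generated VCF round-trips through the reader", {
  u <- small_universe()
  dir <- tempfile()
  files <- write_universe(u, dir)
  d <- read_deletions(files[["deletions.vcf"]])
  m <- match(d$id, u$deletions$id)
  expect_false(anyNA(m))
  expect_equal(d$start, u$deletions$start[m])
  expect_equal(d$end, u$deletions$end[m])
  expect_true(all(mapply(setequal, d$hom_samples, u$deletions$hom_samples[m])))
  expect_true(all(mapply(setequal, d$het_samples, u$deletions$het_samples[m])))
  expect_equal(attr(d, "samples"), u$samples)
})
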