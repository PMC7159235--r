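test_that("tissue enrichment builds the right 2x2 tables", {
  # distinct counting engineered to give a=8,b=2,c=2,d=8
  ids <- sprintf("e%02d", 1:20)
  tis <- c(rep(list("T"), 8), rep(list("U"), 2),   # class: 8 in T, 2 not
           rep(list("T"), 2), rep(list("U"), 8))   # non-class: 2 in T
  names(tis) <- ids
  lab <- label_set(ids[1:10], character())
  res <- tissue_enrichment(lab, tis, "tolerant", counting = "distinct")
  rT <- res[res$tissue == "T", ]
  expect_equal(unlist(rT[c("a", "b", "c", "d")], use.names = FALSE),
               c(8, 2, 2, 8))
  expect_equal(rT$odds_ratio, 16)
  # Fisher p matches exhaustive hypergeometric enumeration
  expect_equal(rT$p_value, fisher_oracle_p(8, 2, 2, 8), tolerance = 1e-12)

  # balanced table: no association
  tis2 <- c(rep(list("T"), 10), rep(list("U"), 10),
            rep(list("T"), 10), rep(list("U"), 10))
  names(tis2) <- sprintf("x%02d", 1:40)
  lab2 <- label_set(sprintf("x%02d", 1:20), character())
  res2 <- tissue_enrichment(lab2, tis2, "tolerant", counting = "distinct")
  expect_equal(res2$odds_ratio[res2$tissue == "T"], 1.0)
  expect_equal(res2$p_value[res2$tissue == "T"], 1.0)
})

test_that("zero cells get the Haldane-Anscombe correction and a flag", {
  ids <- sprintf("e%02d", 1:20)
  tis <- c(rep(list("U"), 5), rep(list(c("T", "U")), 15))
  names(tis) <- ids
  lab <- label_set(ids[1:5], character())    # class never in tissue T
  res <- tissue_enrichment(lab, tis, "tolerant")
  rT <- res[res$tissue == "T", ]
  expect_true(rT$flagged)
  expect_lt(rT$odds_ratio, 1)
})

test_that("Fisher p-values match hypergeometric enumeration on random tables", {
  set.seed(33)
  for (i in 1:25) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    p_pkg <- stats::fisher.test(matrix(c(a, b, c_, d), 2,
                                       byrow = TRUE))$p.value
    expect_equal(p_pkg, fisher_oracle_p(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("KS comparison: degenerate cases and oracle equivalence", {
  same <- ks_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$D, 0)
  far <- ks_compare(runif(30, 0, 0.1), runif(30, 0.9, 1))
  expect_equal(far$D, 1)
  set.seed(8)
  a <- rnorm(100); b <- rnorm(100, 0.4)
  res <- ks_compare(a, b)
  expect_equal(res$D, ks_oracle_D(a, b), tolerance = 1e-12)
  expect_true(all(c("x", "cdf_a", "cdf_b") %in% names(res$ecdf)))
  expect_error(ks_compare(1, c(1, 2)), "at least 2")
})

test_that("group comparisons report Wilcoxon p and Cohen's d", {
  set.seed(12)
  n <- 1100
  ids <- sprintf("e%04d", 1:n)
  m <- tibble::tibble(enhancer = ids,
                      feat = c(rnorm(500), rnorm(500, 1), rnorm(100)))
  lab <- label_set(ids[1:500], ids[501:1000])
  res <- group_comparison(m, lab, "feat")
  expect_equal(nrow(res), 3)
  d_tl <- res$cohens_d[res$comparison == "tolerant vs low"]
  expect_equal(d_tl, -1, tolerance = 0.15)  # N(0,1) vs N(1,1), n=500 each
  expect_lt(res$p_value[res$comparison == "tolerant vs low"], 1e-10)

  # identical groups: d = 0
  m2 <- m
  m2$feat[1:100] <- seq(0, 1, length.out = 100)
  m2$feat[101:200] <- seq(0, 1, length.out = 100)
  lab_same <- label_set(ids[1:100], ids[101:200])
  res2 <- group_comparison(m2, lab_same, "feat")
  expect_equal(res2$cohens_d[res2$comparison == "tolerant vs low"], 0)

  # constant feature: pooled sd 0 -> flagged
  m3 <- m; m3$feat <- 1
  res3 <- group_comparison(m3, lab, "feat")
  expect_true(all(res3$flagged))
  expect_error(group_comparison(m, lab, "nope"), "not in matrix")
})

test_that("discovery curve is monotone over nested genome subsets", {
  u <- small_universe()
  dels <- homozygous_noncoding_deletions(u$deletions, u$exons)
  lab <- small_labels()
  enh <- u$enhancers[u$enhancers$id %in% lab$lof_tolerant, ]
  curve <- discovery_curve(enh, dels, step = 5, seed = 3, n_draws = 2)
  for (d in unique(curve$draw)) {
    v <- curve$n_discovered[curve$draw == d]
    expect_true(all(diff(v) >= 0))
  }
  # all genomes recover the full tolerant set
  expect_equal(max(curve$n_discovered), length(lab$lof_tolerant))
  # step larger than the panel: a single point at the full panel
  one <- discovery_curve(enh, dels, step = 1000, seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_genomes, length(u$samples))
})

test_that("disease enhancers match by overlap, then proximity, then target", {
  enh <- tibble::tibble(id = c("chr1:100-200", "chr1:300-400",
                               "chr1:600-700"),
                        chrom = "chr1", start = c(100L, 300L, 600L),
                        end = c(200L, 400L, 700L))
  reg <- tibble::tibble(enhancer = c("chr1:100-200", "chr1:300-400",
                                     "chr1:600-700"),
                        gene = c("G1", "G2", "G3"))
  dt <- tibble::tibble(
    id = c("D1", "D2", "D3", "D4", "D5"),
    chrom = "chr1",
    start = c(120L, 120L, 480L, 250L, 10L),
    end = c(180L, 180L, 520L, 260L, 20L),
    target_gene = c("G1", "G9", "G2", "G2", "G1"),
    disease = c("neuro", "neuro", "neuro", "breast cancer", "immune"))
  res <- match_disease_enhancers(dt, enh, reg)
  expect_true(res$matched[res$disease_id == "D1"])   # overlap + target
  expect_false(res$matched[res$disease_id == "D2"])  # target not regulated
  # D3 sits equidistant (80 bp) between chr1:300-400 and chr1:600-700:
  # smaller start wins, and its target G2 matches
  expect_equal(res$matched_enhancer[res$disease_id == "D3"], "chr1:300-400")
  expect_true(res$matched[res$disease_id == "D3"])
  # cancer rows are excluded up front
  expect_false(res$matched[res$disease_id == "D4"])
  expect_match(res$reason[res$disease_id == "D4"], "excluded")
  # nearest on the same chromosome when no overlap exists
  expect_equal(res$matched_enhancer[res$disease_id == "D5"], "chr1:100-200")

  dt2 <- dt[1, ]; dt2$chrom <- "chrX"
  res2 <- match_disease_enhancers(dt2, enh, reg)
  expect_match(res2$reason, "chromosome absent")
})

test_that("motif presence matches the exhaustive window-scan oracle", {
  pwms <- enhtol:::synthetic_pwms()[1:2]
  consensus <- vapply(pwms, function(p)
    paste(rownames(p)[apply(p, 2, which.max)], collapse = ""), character(1))
  set.seed(6)
  base <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  seqs <- c(
    hit1 = paste0(base(30), consensus[1], base(30)),       # planted forward
    hit2 = paste0(base(10),
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(consensus[2]))), base(10)),
    blank = base(80),
    allN = strrep("N", 60),
    short = "ACG")
  lab <- label_set("hit1", "blank")
  res <- motif_enrichment(seqs, pwms, lab)
  frac <- res$presence
  # planted consensus is found; all-N and too-short sequences never match
  expect_equal(frac$fraction[frac$motif == names(pwms)[1] &
                               frac$class == "tolerant"], 1)
  counts <- setNames(res$counts$n_motifs, res$counts$enhancer)
  expect_equal(unname(counts[c("allN", "short")]), c(0, 0))
  expect_gte(counts[["hit2"]], 1)  # reverse-strand hit
  # oracle equivalence over every sequence x motif
  for (mn in names(pwms)) {
    oracle <- vapply(seqs, motif_present_oracle, logical(1), pwm = pwms[[mn]])
    got <- vapply(names(seqs), function(id)
      res$counts$n_motifs[res$counts$enhancer == id] >= 1 &&
        TRUE, logical(1))
    # recompute per-motif presence through the package scanner
    lo <- enhtol:::pwm_log_odds(pwms[[mn]])
    thr <- 0.8 * sum(apply(lo, 2, max))
    pkg <- vapply(seqs, function(s)
      enhtol:::best_pwm_score(s, lo) >= thr, logical(1))
    expect_equal(unname(pkg), unname(oracle))
  }
  # BH-adjusted Fisher enrichment columns are present and valid
  expect_true(all(res$enrichment$p_adjusted >= res$enrichment$p_value - 1e-12))
})

test_that("BH adjustment matches the manual step-up on the printed triple", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(14)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # monotone in input ranks
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})
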