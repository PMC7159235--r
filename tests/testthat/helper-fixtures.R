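# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small universe for unit tests: enough labeled enhancers to train on
small_spec <- function(seed = 7) {
  fixture_spec(n_enhancers = 400, n_genes = 150, n_tissues = 6,
               n_samples = 24, chrom_length = 3e6, seed = seed,
               class_fractions = c(tolerant = 0.2, low = 0.13))
}

small_universe <- function() cached("small_universe", {
  generate_universe(small_spec())
})

# the default-scale universe: the study conditions used by the acceptance
# checks (2,000 enhancers, 600 genes, 15 tissues, 60 samples, signal 3)
default_universe <- function() cached("default_universe", {
  generate_universe(fixture_spec(seed = 1))
})

merge_network <- function(network) {
  network |>
    dplyr::group_by(.data$enhancer, .data$gene) |>
    dplyr::summarise(tissues = list(sort(unique(.data$tissue))),
                     .groups = "drop")
}

universe_net <- function(u, key = NULL) {
  build <- function() build_meganet(merge_network(u$network), u$interactions)
  if (is.null(key)) build() else cached(key, build())
}

small_net <- function() universe_net(small_universe(), "small_net")

small_features <- function() cached("small_features", {
  u <- small_universe()
  f <- compute_enhancer_features(small_net(), gis = u$gis,
                                 conservation = u$conservation)
  impute_missing(prune_correlated_features(f, 0.9), "median")
})

small_labels <- function() cached("small_labels", {
  u <- small_universe()
  dels <- homozygous_noncoding_deletions(u$deletions, u$exons)
  label_set(call_lof_tolerant(u$enhancers, dels),
            call_low_tolerance(u$enhancers, u$conserved),
            known_ids = u$enhancers$id)
})

# strongly separated classification fixture: 5 informative columns
# (positives N(0,1), negatives N(3,1)) plus noise columns
separable_matrix <- function(n_pos = 120, n_neg = 49, n_noise = 200,
                             seed = 3, shift = 3) {
  set.seed(seed)
  n <- n_pos + n_neg
  ids <- sprintf("chr1:%d-%d", seq_len(n) * 1000, seq_len(n) * 1000 + 500)
  inform <- rbind(matrix(stats::rnorm(n_pos * 5), n_pos),
                  matrix(stats::rnorm(n_neg * 5, mean = shift), n_neg))
  noise <- matrix(stats::rnorm(n * n_noise), n)
  m <- tibble::as_tibble(cbind(inform, noise),
                         .name_repair = ~ c(sprintf("inform_%d", 1:5),
                                            sprintf("noise_%03d",
                                                    seq_len(n_noise))))
  m <- tibble::add_column(m, enhancer = ids, .before = 1)
  labels <- label_set(ids[seq_len(n_pos)], ids[n_pos + seq_len(n_neg)])
  list(matrix = m, labels = labels,
       pos_ids = ids[seq_len(n_pos)], neg_ids = ids[n_pos + seq_len(n_neg)])
}

# tiny VCF writer for io tests
write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"t\">",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"t\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"t\">",
               lines), path)
  path
}
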