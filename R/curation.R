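#' Keep homozygous, non-coding deletions
#'
#' The first curation step: a deletion can only evidence enhancer LoF
#' tolerance if (a) at least one individual carries it in a homozygous state
#' and (b) it does not touch any coding exon (any >= 1 bp overlap disqualifies
#' it, the most conservative reading). Input order is preserved.
#'
#' @param deletions deletion tibble from [read_deletions()].
#' @param exons interval tibble of coding exons.
#' @return the filtered deletion tibble.
#' @export
homozygous_noncoding_deletions <- function(deletions, exons) {
  if (nrow(deletions) == 0) return(deletions)
  hom <- deletions$n_hom >= 1
  coding <- overlaps_any(deletions, exons)
  deletions[hom & !coding, , drop = FALSE]
}

#' Call LoF-tolerant enhancers
#'
#' An enhancer is LoF-tolerant when its interval is fully contained
#' (boundary equality included) in at least one deletion: only enhancers that
#' are 100% deleted count, partial deletion is not evidence of tolerated loss.
#' `deletions` is expected to be pre-filtered by
#' [homozygous_noncoding_deletions()].
#'
#' @param enhancers enhancer tibble (`id`, `chrom`, `start`, `end`).
#' @param deletions deletion tibble.
#' @return character vector of LoF-tolerant enhancer ids (sorted).
#' @export
call_lof_tolerant <- function(enhancers, deletions) {
  if (nrow(enhancers) == 0 || nrow(deletions) == 0) return(character())
  hit <- contained_in_any(enhancers, deletions)
  sort(unique(enhancers$id[hit]))
}

#' Call low-LoF-tolerance enhancers
#'
#' An enhancer has low LoF tolerance when it shows strict >50% reciprocal
#' overlap with an ultraconserved, reporter-validated element: the shared span
#' must exceed half the enhancer's length AND half the element's length.
#'
#' @param enhancers enhancer tibble.
#' @param conserved_elements interval tibble of conserved elements.
#' @param min_reciprocal reciprocal-overlap cutoff, default 0.5 (strict `>`).
#' @return character vector of low-LoF-tolerance enhancer ids (sorted).
#' @export
call_low_tolerance <- function(enhancers, conserved_elements,
                               min_reciprocal = 0.5) {
  if (nrow(enhancers) == 0 || nrow(conserved_elements) == 0) return(character())
  hit <- reciprocal_overlap_any(enhancers, conserved_elements,
                                frac = min_reciprocal)
  sort(unique(enhancers$id[hit]))
}

#' Construct a disjoint training label set
#'
#' Training labels must be disjoint. An enhancer qualifying for both classes
#' (possible only on adversarial input) is excluded from both and reported.
#'
#' @param lof_tolerant,low_tolerance character vectors of enhancer ids.
#' @param known_ids optional universe of valid enhancer ids; labels outside it
#'   raise an error.
#' @return object of class `label_set`: list with sorted unique `lof_tolerant`
#'   and `low_tolerance` id vectors plus `conflicts`.
#' @export
label_set <- function(lof_tolerant, low_tolerance, known_ids = NULL) {
  lof_tolerant <- sort(unique(as.character(lof_tolerant)))
  low_tolerance <- sort(unique(as.character(low_tolerance)))
  if (!is.null(known_ids)) {
    unknown <- setdiff(c(lof_tolerant, low_tolerance), known_ids)
    if (length(unknown) > 0) {
      stop("label(s) outside the known enhancer universe: ",
           paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
    }
  }
  conflicts <- intersect(lof_tolerant, low_tolerance)
  if (length(conflicts) > 0) {
    message(length(conflicts),
            " enhancer(s) qualified for both labels; excluded from both")
    lof_tolerant <- setdiff(lof_tolerant, conflicts)
    low_tolerance <- setdiff(low_tolerance, conflicts)
  }
  structure(list(lof_tolerant = lof_tolerant, low_tolerance = low_tolerance,
                 conflicts = conflicts),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat("<label_set> ", length(x$lof_tolerant), " LoF-tolerant, ",
      length(x$low_tolerance), " low-LoF-tolerance",
      if (length(x$conflicts) > 0) paste0(" (", length(x$conflicts),
                                          " conflicts dropped)"), "\n",
      sep = "")
  invisible(x)
}

#' Per-individual counts of homozygously deleted enhancers
#'
#' For each sample, counts the distinct LoF-tolerant enhancers fully contained
#' in a deletion that the sample carries homozygously — the per-genome LoF
#' burden summarized in the curation analyses.
#'
#' @param enhancers enhancer tibble.
#' @param deletions deletion tibble (pre-filtered to homozygous non-coding
#'   calls).
#' @param labels optional `label_set`; when given, only enhancers in
#'   `labels$lof_tolerant` are counted.
#' @return list with `counts` (tibble `sample`, `n`), and scalars `mean`,
#'   `min`, `max`.
#' @export
per_individual_counts <- function(enhancers, deletions, labels = NULL) {
  samples <- attr(deletions, "samples")
  if (is.null(samples)) {
    samples <- sort(unique(unlist(deletions$hom_samples)))
  }
  if (!is.null(labels)) {
    enhancers <- enhancers[enhancers$id %in% labels$lof_tolerant, ,
                           drop = FALSE]
  }
  per_sample <- stats::setNames(vector("list", length(samples)), samples)
  if (nrow(enhancers) > 0 && nrow(deletions) > 0) {
    ge <- as_granges0(enhancers)
    gd <- as_granges0(deletions)
    hits <- GenomicRanges::findOverlaps(ge, gd, type = "within")
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    for (k in seq_along(qi)) {
      for (s in deletions$hom_samples[[si[k]]]) {
        per_sample[[s]] <- c(per_sample[[s]], enhancers$id[qi[k]])
      }
    }
  }
  counts <- tibble::tibble(
    sample = samples,
    n = vapply(per_sample, function(x) length(unique(x)), integer(1))
  )
  list(counts = counts,
       mean = if (nrow(counts) > 0) mean(counts$n) else NA_real_,
       min = if (nrow(counts) > 0) min(counts$n) else NA_integer_,
       max = if (nrow(counts) > 0) max(counts$n) else NA_integer_)
}

#' Allele-frequency summary of enhancer-deleting deletions
#'
#' Compares the allele-frequency distribution of deletions that fully delete
#' an enhancer against all deletions, overall and within population groups,
#' using the two-sample Kolmogorov-Smirnov test.
#'
#' @param deletions deletion tibble with `af` available.
#' @param enhancers enhancer tibble defining which deletions are
#'   enhancer-deleting (full containment of at least one enhancer).
#' @param grouping optional named character vector sample -> population group;
#'   when given, per-group comparisons restrict allele frequencies recomputed
#'   over that group's genotype carriers.
#' @return list with `af` (named list of numeric AF vectors), and
#'   `comparisons` (tibble `group`, `n_deleting`, `n_all`, `D`, `p_value`,
#'   `note`).
#' @export
allele_frequency_summary <- function(deletions, enhancers, grouping = NULL) {
  # which deletions contain at least one enhancer entirely
  deleting <- rep(FALSE, nrow(deletions))
  if (nrow(enhancers) > 0 && nrow(deletions) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges0(enhancers),
                                        as_granges0(deletions),
                                        type = "within")
    deleting <- seq_len(nrow(deletions)) %in% S4Vectors::subjectHits(hits)
  }
  group_af <- function(rows, samples_in_group = NULL) {
    d <- deletions[rows, , drop = FALSE]
    if (is.null(samples_in_group)) return(d$af[!is.na(d$af)])
    n <- length(samples_in_group)
    if (n == 0) return(numeric())
    hom <- vapply(d$hom_samples, function(s)
      sum(s %in% samples_in_group), integer(1))
    het <- vapply(d$het_samples, function(s)
      sum(s %in% samples_in_group), integer(1))
    (2 * hom + het) / (2 * n)
  }
  groups <- list(all = NULL)
  if (!is.null(grouping)) {
    for (g in sort(unique(unname(grouping)))) {
      groups[[g]] <- names(grouping)[unname(grouping) == g]
    }
  }
  af <- list()
  comp <- list()
  for (g in names(groups)) {
    a <- group_af(deleting, groups[[g]])
    b <- group_af(rep(TRUE, nrow(deletions)), groups[[g]])
    af[[paste0(g, ".deleting")]] <- a
    af[[paste0(g, ".all")]] <- b
    if (length(a) < 2 || length(b) < 2) {
      comp[[g]] <- tibble::tibble(group = g, n_deleting = length(a),
                                  n_all = length(b), D = NA_real_,
                                  p_value = NA_real_,
                                  note = "skipped: <2 observations")
    } else {
      ks <- ks_compare(a, b)
      comp[[g]] <- tibble::tibble(group = g, n_deleting = length(a),
                                  n_all = length(b), D = ks$D,
                                  p_value = ks$p_value, note = "")
    }
  }
  list(af = af, comparisons = dplyr::bind_rows(comp))
}
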