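#' Tissue enrichment of a label class
#'
#' For each tissue, builds the 2x2 table (class vs non-class) x (memberships
#' in this tissue vs memberships in all other tissues) and reports the odds
#' ratio with Fisher's exact p-value. The default counting unit is the
#' enhancer-tissue membership: an enhancer active in k tissues contributes k
#' memberships; `counting = "distinct"` counts each enhancer once per tissue
#' and once in the complement.
#'
#' Zero cells get the Haldane-Anscombe +0.5 correction for the odds ratio
#' (flagged); the p-value is always computed on the uncorrected counts.
#'
#' @param labels a `label_set`.
#' @param enhancer_tissues named list enhancer id -> character vector of
#'   tissue groups.
#' @param label_class `"tolerant"` or `"low"` — which label class to test
#'   against all remaining enhancers.
#' @param counting `"membership"` (default) or `"distinct"`.
#' @return tibble `tissue`, `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`,
#'   `flagged`.
#' @export
tissue_enrichment <- function(labels, enhancer_tissues,
                              label_class = c("tolerant", "low"),
                              counting = c("membership", "distinct")) {
  stopifnot(inherits(labels, "label_set"))
  label_class <- match.arg(label_class)
  counting <- match.arg(counting)
  class_ids <- if (label_class == "tolerant") labels$lof_tolerant else
    labels$low_tolerance
  ids <- names(enhancer_tissues)
  in_class <- ids %in% class_ids
  tissues <- sort(unique(unlist(enhancer_tissues)))
  nt <- lengths(enhancer_tissues)
  out <- lapply(tissues, function(t) {
    has_t <- vapply(enhancer_tissues, function(x) t %in% x, logical(1))
    if (counting == "membership") {
      a <- sum(has_t & in_class)
      b <- sum(nt[in_class]) - a          # class memberships elsewhere
      cc <- sum(has_t & !in_class)
      d <- sum(nt[!in_class]) - cc
    } else {
      a <- sum(has_t & in_class)
      b <- sum(!has_t & in_class)
      cc <- sum(has_t & !in_class)
      d <- sum(!has_t & !in_class)
    }
    tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
    zero <- any(tab == 0)
    orr <- if (zero) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else (a * d) / (b * cc)
    tibble::tibble(tissue = t, a = a, b = b, c = cc, d = d,
                   odds_ratio = orr, p_value = p, flagged = zero)
  })
  dplyr::bind_rows(out)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the maximum gap between the two empirical CDFs; the p-value is the
#' asymptotic two-sided approximation. Also returns the pooled-grid CDF pair
#' for plotting.
#'
#' @param scores_a,scores_b numeric vectors, each with at least 2 values.
#' @return list `D`, `p_value`, `ecdf` (tibble `x`, `cdf_a`, `cdf_b`).
#' @export
ks_compare <- function(scores_a, scores_b) {
  if (length(scores_a) < 2 || length(scores_b) < 2) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(scores_a, scores_b, exact = FALSE))
  grid <- sort(unique(c(scores_a, scores_b)))
  fa <- stats::ecdf(scores_a)
  fb <- stats::ecdf(scores_b)
  list(D = unname(kt$statistic), p_value = kt$p.value,
       ecdf = tibble::tibble(x = grid, cdf_a = fa(grid), cdf_b = fb(grid)))
}

# Cohen's d with pooled standard deviation; positive = first group higher.
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Three-way group comparison of one feature
#'
#' Compares a feature between LoF-tolerant, low-LoF-tolerance and genome-wide
#' (GW = all enhancers in neither label set) groups: Wilcoxon rank-sum
#' p-value and Cohen's d (positive = first-named group higher) for each of
#' the pairs tolerant-vs-GW, tolerant-vs-low, low-vs-GW.
#'
#' @param m feature tibble with `enhancer` id column.
#' @param labels a `label_set`.
#' @param feature feature column name.
#' @return tibble `comparison`, `n1`, `n2`, `p_value`, `cohens_d`, `flagged`
#'   (TRUE when d is undefined, e.g. zero pooled sd, or a group has < 2
#'   observations).
#' @export
group_comparison <- function(m, labels, feature) {
  stopifnot(inherits(labels, "label_set"))
  if (!feature %in% names(m)) stop("feature '", feature, "' not in matrix",
                                   call. = FALSE)
  x <- stats::setNames(m[[feature]], m$enhancer)
  g <- list(
    tolerant = x[names(x) %in% labels$lof_tolerant],
    low = x[names(x) %in% labels$low_tolerance],
    GW = x[!names(x) %in% c(labels$lof_tolerant, labels$low_tolerance)]
  )
  pairs <- list(c("tolerant", "GW"), c("tolerant", "low"), c("low", "GW"))
  out <- lapply(pairs, function(pr) {
    a <- g[[pr[1]]]; b <- g[[pr[2]]]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble::tibble(comparison = paste(pr, collapse = " vs "),
                            n1 = length(a), n2 = length(b),
                            p_value = NA_real_, cohens_d = NA_real_,
                            flagged = TRUE))
    }
    p <- suppressWarnings(stats::wilcox.test(a, b,
                                             exact = length(a) <= 20 &&
                                               length(b) <= 20)$p.value)
    d <- cohens_d(a, b)
    tibble::tibble(comparison = paste(pr, collapse = " vs "),
                   n1 = length(a), n2 = length(b), p_value = p,
                   cohens_d = d, flagged = is.na(d))
  })
  dplyr::bind_rows(out)
}

#' Discovery curve of LoF-tolerant enhancers vs genomes sampled
#'
#' Randomly orders the sample panel and reports, at nested prefixes growing
#' in steps of `step` genomes, how many distinct enhancers are fully
#' contained in a deletion carried homozygously by at least one sampled
#' genome. Counts are monotone non-decreasing by construction; `n_draws`
#' repeated orderings give a sampling band.
#'
#' @param enhancers enhancer tibble.
#' @param deletions deletion tibble (homozygous non-coding calls).
#' @param sample_ids character panel of genome ids; default: the deletion
#'   table's sample attribute.
#' @param step genomes added per point.
#' @param seed RNG seed for the orderings.
#' @param n_draws number of independent orderings.
#' @return tibble `draw`, `n_genomes`, `n_discovered`.
#' @export
discovery_curve <- function(enhancers, deletions,
                            sample_ids = attr(deletions, "samples"),
                            step = 100, seed = 1, n_draws = 1) {
  if (is.null(sample_ids)) {
    sample_ids <- sort(unique(unlist(deletions$hom_samples)))
  }
  # enhancer -> set of samples homozygously deleting it entirely
  enh_samples <- rep(list(character()), nrow(enhancers))
  if (nrow(enhancers) > 0 && nrow(deletions) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges0(enhancers),
                                        as_granges0(deletions),
                                        type = "within")
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    for (k in seq_along(qi)) {
      enh_samples[[qi[k]]] <- union(enh_samples[[qi[k]]],
                                    deletions$hom_samples[[si[k]]])
    }
  }
  sizes <- unique(c(seq(min(step, length(sample_ids)), length(sample_ids),
                        by = step), length(sample_ids)))
  set.seed(seed)
  out <- list()
  for (d in seq_len(n_draws)) {
    ord <- sample(sample_ids)
    for (ns in sizes) {
      sub <- ord[seq_len(ns)]
      n_found <- sum(vapply(enh_samples, function(s) any(s %in% sub),
                            logical(1)))
      out[[length(out) + 1L]] <- tibble::tibble(
        draw = d, n_genomes = ns, n_discovered = n_found)
    }
  }
  dplyr::bind_rows(out)
}

#' Match disease enhancers to the enhancer catalog
#'
#' For each disease-enhancer interval: take the overlapping catalog enhancer
#' (largest overlap; ties to the smaller start); if none overlaps, take the
#' nearest enhancer on the same chromosome (edge-to-edge gap; ties to the
#' smaller start). A match is retained only when the disease record's
#' reported target gene is among the matched enhancer's regulated genes.
#' Records whose disease type matches `exclude_types` (case-insensitive
#' substring, e.g. cancer rows, which reflect somatic variation) are
#' excluded.
#'
#' @param disease_table tibble `chrom`, `start`, `end`, `target_gene`,
#'   `disease` (type label), and optionally `id`.
#' @param enhancers enhancer tibble.
#' @param reg_edges regulation-edge tibble (`enhancer`, `gene`).
#' @param exclude_types character vector of disease-type substrings to drop.
#' @return tibble `disease_id`, `disease`, `target_gene`,
#'   `matched_enhancer`, `matched` (logical), `reason`.
#' @export
match_disease_enhancers <- function(disease_table, enhancers, reg_edges,
                                    exclude_types = "cancer") {
  disease_table <- validate_intervals(disease_table, "disease table")
  if (!"id" %in% names(disease_table)) {
    disease_table$id <- enhancer_id(disease_table$chrom, disease_table$start,
                                    disease_table$end)
  }
  excl <- rep(FALSE, nrow(disease_table))
  for (pat in exclude_types) {
    excl <- excl | grepl(pat, disease_table$disease, ignore.case = TRUE)
  }
  targets_of <- split(reg_edges$gene, reg_edges$enhancer)
  out <- lapply(seq_len(nrow(disease_table)), function(i) {
    row <- disease_table[i, ]
    base <- tibble::tibble(disease_id = row$id, disease = row$disease,
                           target_gene = row$target_gene,
                           matched_enhancer = NA_character_,
                           matched = FALSE, reason = "")
    if (excl[i]) { base$reason <- "excluded disease type"; return(base) }
    cand <- enhancers[enhancers$chrom == row$chrom, , drop = FALSE]
    if (nrow(cand) == 0) { base$reason <- "chromosome absent"; return(base) }
    ov <- overlap_width(row$start, row$end, cand$start, cand$end)
    if (any(ov > 0)) {
      sel <- which(ov == max(ov))
    } else {
      gap <- pmax(cand$start - row$end, row$start - cand$end)
      sel <- which(gap == min(gap))
    }
    sel <- sel[order(cand$start[sel])][1]  # tie -> smaller start
    hit <- cand$id[sel]
    if (row$target_gene %in% targets_of[[hit]]) {
      base$matched_enhancer <- hit
      base$matched <- TRUE
    } else {
      base$matched_enhancer <- hit
      base$reason <- "target gene not regulated by matched enhancer"
    }
    base
  })
  dplyr::bind_rows(out)
}

# Log-odds matrix from a PWM count matrix: pseudocounted column-stochastic
# probabilities against a uniform background.
pwm_log_odds <- function(pwm, pseudocount = 0.5, background = 0.25) {
  if (any(colSums(pwm) <= 0)) stop("PWM has a zero column sum", call. = FALSE)
  prob <- sweep(pwm + pseudocount, 2, colSums(pwm + pseudocount), "/")
  log2(prob / background)
}

# Scan one sequence (character string over ACGTN) with a log-odds matrix on
# both strands; windows containing N score -Inf. Returns the best score, or
# -Inf when the sequence is shorter than the motif.
best_pwm_score <- function(seq, lo) {
  w <- ncol(lo)
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  if (L < w) return(-Inf)
  idx <- match(chars, c("A", "C", "G", "T"))
  score_one <- function(index, mat) {
    W <- length(index) - w + 1L
    s <- numeric(W)
    for (k in seq_len(w)) {
      col <- mat[, k]
      v <- col[index[k:(k + W - 1L)]]
      v[is.na(v)] <- -Inf  # N or other ambiguity code
      s <- s + v
    }
    max(s)
  }
  fwd <- score_one(idx, lo)
  # reverse complement: complement indices (A<->T, C<->G), reversed order
  rc_idx <- rev(5L - idx)
  rev_ <- score_one(rc_idx, lo)
  max(fwd, rev_)
}

#' Motif presence and enrichment across label classes
#'
#' A motif is "present" in an enhancer when some window on either strand
#' scores at least `threshold_frac` of the motif's maximum achievable
#' log-odds score (pseudocounted, uniform background). Per class (tolerant,
#' low, GW) the presence fraction is the share of enhancers containing the
#' motif; enrichment of each labeled class against GW is tested per motif
#' with Fisher's exact test and Benjamini-Hochberg adjustment. Per-enhancer
#' motif counts support class-level count comparisons.
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet] of
#'   enhancer sequences (names are enhancer ids).
#' @param pwms named list of 4 x L count matrices (rows A, C, G, T).
#' @param labels a `label_set`.
#' @param threshold_frac fraction of the maximum log-odds score required for
#'   a match.
#' @return list:
#'   \describe{
#'     \item{presence}{tibble `motif`, `class`, `n_present`, `n_total`,
#'       `fraction`}
#'     \item{enrichment}{tibble `motif`, `class`, `odds_ratio`, `p_value`,
#'       `p_adjusted` (BH within class)}
#'     \item{counts}{tibble `enhancer`, `class`, `n_motifs`}
#'   }
#' @export
motif_enrichment <- function(sequences, pwms, labels, threshold_frac = 0.8) {
  stopifnot(inherits(labels, "label_set"))
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  ids <- names(sequences)
  cls <- ifelse(ids %in% labels$lof_tolerant, "tolerant",
                ifelse(ids %in% labels$low_tolerance, "low", "GW"))
  present <- matrix(FALSE, nrow = length(ids), ncol = length(pwms),
                    dimnames = list(ids, names(pwms)))
  for (mname in names(pwms)) {
    lo <- pwm_log_odds(pwms[[mname]])
    thr <- threshold_frac * sum(apply(lo, 2, max))
    present[, mname] <- vapply(sequences, function(s)
      best_pwm_score(s, lo) >= thr, logical(1))
  }
  classes <- c("tolerant", "low", "GW")
  presence <- dplyr::bind_rows(lapply(names(pwms), function(mn) {
    dplyr::bind_rows(lapply(classes, function(cl) {
      n_tot <- sum(cls == cl)
      tibble::tibble(motif = mn, class = cl,
                     n_present = sum(present[cls == cl, mn]),
                     n_total = n_tot,
                     fraction = if (n_tot > 0)
                       sum(present[cls == cl, mn]) / n_tot else NA_real_)
    }))
  }))
  enr <- dplyr::bind_rows(lapply(c("tolerant", "low"), function(cl) {
    dplyr::bind_rows(lapply(names(pwms), function(mn) {
      a <- sum(present[cls == cl, mn]); b <- sum(cls == cl) - a
      cc <- sum(present[cls == "GW", mn]); d <- sum(cls == "GW") - cc
      ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))
      tibble::tibble(motif = mn, class = cl,
                     odds_ratio = unname(ft$estimate),
                     p_value = ft$p.value)
    }))
  }))
  enr <- enr |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(p_adjusted = bh_adjust(.data$p_value)) |>
    dplyr::ungroup()
  counts <- tibble::tibble(enhancer = ids, class = cls,
                           n_motifs = rowSums(present))
  list(presence = presence, enrichment = enr, counts = counts)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone, capped at 1, never
#' smaller than the raw p-value.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}
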