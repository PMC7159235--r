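#' Specification for a synthetic input universe
#'
#' Defines the miniature study conditions emulated by the generator: a
#' two-chromosome genome carrying enhancers, coding exons, conserved
#' elements, a tissue-annotated enhancer-target network, gene-gene
#' interactions, a deletion VCF with per-sample genotypes, gene
#' indispensability and conservation scores, enhancer sequences and a
#' disease-enhancer table.
#'
#' `signal_strength` controls the separation of the class-conditional
#' distributions (0 = classes indistinguishable except for the deletion /
#' conservation geometry that defines them; 3 = the default, clearly
#' separated classes whose feature directions mirror the reported biology:
#' tolerant-like enhancers are tissue-specific, regulate few, dispensable,
#' redundantly-regulated genes; low-like enhancers are broadly active,
#' regulate many indispensable genes and are highly conserved).
#'
#' @param n_enhancers,n_genes,n_tissues,n_samples counts.
#' @param class_fractions named numeric `c(tolerant=, low=)`; the remainder
#'   is background.
#' @param signal_strength non-negative real.
#' @param deletion_rate background (non-enhancer-deleting) deletions per
#'   enhancer slot.
#' @param hom_rate mean number of extra homozygous carriers per
#'   enhancer-deleting deletion (each has at least one).
#' @param n_chroms,chrom_length genome geometry in bp.
#' @param seed master seed for the whole bundle.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_enhancers = 2000, n_genes = 600, n_tissues = 15,
                         n_samples = 60,
                         class_fractions = c(tolerant = 0.08, low = 0.0245),
                         signal_strength = 3, deletion_rate = 0.1,
                         hom_rate = 1.5, n_chroms = 2,
                         chrom_length = 10e6, seed = 1) {
  stopifnot(n_enhancers >= 1, n_genes >= 1, n_tissues >= 1, n_samples >= 1,
            signal_strength >= 0, sum(class_fractions) <= 1,
            all(class_fractions >= 0))
  slots_per_chrom <- ceiling(n_enhancers / n_chroms)
  slot_size <- floor(0.8 * chrom_length / slots_per_chrom)
  if (slot_size < 6000) {
    stop("geometrically unsatisfiable spec: ", n_enhancers,
         " enhancers do not fit ", n_chroms, " x ", chrom_length,
         " bp (need >= 6 kb per enhancer slot, have ", slot_size, ")",
         call. = FALSE)
  }
  genes_per_chrom <- ceiling(n_genes / n_chroms)
  if (genes_per_chrom * 2000 > 0.2 * chrom_length) {
    stop("geometrically unsatisfiable spec: exon region too small for ",
         n_genes, " genes", call. = FALSE)
  }
  structure(list(n_enhancers = n_enhancers, n_genes = n_genes,
                 n_tissues = n_tissues, n_samples = n_samples,
                 class_fractions = class_fractions,
                 signal_strength = signal_strength,
                 deletion_rate = deletion_rate, hom_rate = hom_rate,
                 n_chroms = n_chroms, chrom_length = chrom_length,
                 slot_size = slot_size, slots_per_chrom = slots_per_chrom,
                 seed = seed),
            class = "fixture_spec")
}

# tissue-group panel; the first pair is immune-like, the next pair
# brain/kidney-like — classes are steered toward them so tissue-enrichment
# analyses have structure to find
fixture_tissues <- function(n) {
  pool <- c("HSC_Bcell", "Tcell", "Brain_NSC", "Kidney", "Liver", "Heart",
            "Lung", "Muscle", "Adipose", "Skin", "Pancreas", "Thymus",
            "ESC", "iPSC", "Lymphoblastoid", "Digestive", "Mesench",
            "Myosat", "Epithelial")
  if (n <= length(pool)) pool[seq_len(n)] else
    c(pool, sprintf("Tissue%02d", seq_len(n - length(pool))))
}

#' Generate a complete synthetic input universe
#'
#' Builds, from the seed and parameters of a [fixture_spec()], every input
#' the scoring pipeline consumes, together with a ground-truth manifest.
#' Geometry guarantees by construction:
#' \itemize{
#'   \item every tolerant-like enhancer is fully covered by a deletion
#'     carried homozygously by at least one sample, and no exon overlaps it;
#'   \item every low-like enhancer has strict >50% reciprocal overlap with a
#'     conserved element and a high conservation score;
#'   \item background enhancers never qualify for either label, but several
#'     "trap" configurations sit just outside the rules (het-only full
#'     deletions, partial homozygous deletions, homozygous deletions that
#'     also clip an exon, sub-threshold or oversized conserved elements) to
#'     exercise the curation filters.
#' }
#' Regeneration from the same spec is deterministic; writing the bundle via
#' [write_universe()] is byte-identical across runs.
#'
#' @param spec a `fixture_spec`.
#' @param out_dir optional directory; when given the bundle is written there
#'   via [write_universe()].
#' @return list of class `synthetic_universe` with elements `spec`,
#'   `enhancers`, `network` (long tibble enhancer/gene/tissue), `edges`
#'   (merged regulatory edges), `interactions`, `deletions`, `exons`,
#'   `conserved`, `gis`, `conservation`, `sequences`, `pwms`, `disease`,
#'   `manifest`, `samples`, `tissue_map`.
#' @export
generate_universe <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  s <- spec$signal_strength
  tissues <- fixture_tissues(spec$n_tissues)
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  chroms <- sprintf("chr%d", seq_len(spec$n_chroms))

  ## ---- enhancer geometry: one slot per enhancer -------------------------
  n <- spec$n_enhancers
  slot_chrom <- chroms[((seq_len(n) - 1) %/% spec$slots_per_chrom) + 1]
  slot_index <- (seq_len(n) - 1) %% spec$slots_per_chrom
  slot_start <- slot_index * spec$slot_size
  enh_len <- sample(600:2000, n, replace = TRUE)
  enh_start <- slot_start + 2000L
  enh_end <- enh_start + enh_len
  enh_ids <- enhancer_id(slot_chrom, enh_start, enh_end)

  ## ---- class assignment and traps ---------------------------------------
  n_tol <- round(spec$class_fractions[["tolerant"]] * n)
  n_low <- round(spec$class_fractions[["low"]] * n)
  cls <- rep("background", n)
  cls[sample.int(n, n_tol + n_low)] <- c(rep("tolerant", n_tol),
                                         rep("low", n_low))
  bg <- which(cls == "background")
  n_trap <- max(1L, round(0.02 * n))
  traps <- split(sample(bg, min(length(bg), 5 * n_trap)),
                 rep(c("het_full", "partial_hom", "exon_hit",
                       "conserved_small", "conserved_big"),
                     length.out = min(length(bg), 5 * n_trap)))
  trap_of <- rep("", n)
  for (tn in names(traps)) trap_of[traps[[tn]]] <- tn

  ## ---- deletions ---------------------------------------------------------
  del <- list()
  add_del <- function(chrom, start, end, hom, het, explicit = FALSE) {
    del[[length(del) + 1L]] <<- tibble::tibble(
      id = sprintf("DEL%05d", length(del) + 1L), chrom = chrom,
      start = as.integer(start), end = as.integer(end),
      length = as.integer(end - start),
      af = (2 * length(hom) + length(het)) / (2 * spec$n_samples),
      n_hom = length(hom), n_het = length(het),
      hom_samples = list(hom), het_samples = list(het),
      filter = "PASS", explicit = explicit)
  }
  draw_carriers <- function(n_hom_min = 1) {
    n_hom <- n_hom_min + stats::rpois(1, spec$hom_rate)
    n_het <- stats::rpois(1, 3)
    picked <- sample(samples, min(spec$n_samples, n_hom + n_het))
    list(hom = picked[seq_len(min(n_hom, length(picked)))],
         het = setdiff(picked, picked[seq_len(min(n_hom, length(picked)))]))
  }
  for (i in which(cls == "tolerant")) {
    pad_l <- sample(50:500, 1); pad_r <- sample(50:500, 1)
    cr <- draw_carriers()
    add_del(slot_chrom[i], enh_start[i] - pad_l, enh_end[i] + pad_r,
            cr$hom, cr$het)
  }
  for (i in traps$het_full) {   # full coverage but never homozygous
    het <- sample(samples, 1 + stats::rpois(1, 3))
    add_del(slot_chrom[i], enh_start[i] - 100L, enh_end[i] + 100L,
            character(), het)
  }
  for (i in traps$partial_hom) { # homozygous but covers only ~60% of the span
    cr <- draw_carriers()
    mid <- enh_start[i] + round(0.4 * enh_len[i])
    add_del(slot_chrom[i], mid, enh_end[i] + 200L, cr$hom, cr$het)
  }
  trap_exons <- list()
  for (i in traps$exon_hit) {    # homozygous full coverage, but clips an exon
    cr <- draw_carriers()
    ex_start <- enh_end[i] + 120L
    trap_exons[[length(trap_exons) + 1L]] <-
      tibble::tibble(chrom = slot_chrom[i], start = ex_start,
                     end = ex_start + 150L,
                     name = sprintf("trapexon_%d", i))
    add_del(slot_chrom[i], enh_start[i] - 100L, ex_start + 50L,
            cr$hom, cr$het)
  }
  n_bgdel <- round(spec$deletion_rate * n)
  bg_slots <- sample.int(n, n_bgdel, replace = TRUE)
  for (i in bg_slots) {          # intergenic, never touching an enhancer
    st <- slot_start[i] + sample(100:600, 1)
    len <- sample(30:900, 1)
    cr <- if (stats::runif(1) < 0.5) draw_carriers(0) else draw_carriers()
    add_del(slot_chrom[i], st, st + len, cr$hom, cr$het, explicit = len < 60)
  }
  deletions <- dplyr::bind_rows(del)
  ord <- order(deletions$chrom, deletions$start, deletions$end)
  deletions <- deletions[ord, , drop = FALSE]
  attr(deletions, "samples") <- samples

  ## ---- exons -------------------------------------------------------------
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  gene_chrom <- chroms[((seq_len(spec$n_genes) - 1) %/%
                          ceiling(spec$n_genes / spec$n_chroms)) + 1]
  gene_slot <- (seq_len(spec$n_genes) - 1) %%
    ceiling(spec$n_genes / spec$n_chroms)
  exon_region <- floor(0.8 * spec$chrom_length)
  exon_start <- exon_region + gene_slot * 2000L + 200L
  exons <- tibble::tibble(chrom = gene_chrom, start = exon_start,
                          end = exon_start + 150L +
                            sample(0:100, spec$n_genes, replace = TRUE),
                          name = genes)
  exons <- dplyr::bind_rows(exons, trap_exons)
  exons <- exons[order(exons$chrom, exons$start), , drop = FALSE]

  ## ---- conserved elements -----------------------------------------------
  cons_el <- list()
  for (i in which(cls == "low")) {
    repeat {
      shift <- round(stats::runif(1, -0.15, 0.15) * enh_len[i])
      clen <- round(stats::runif(1, 0.85, 1.15) * enh_len[i])
      cs <- enh_start[i] + shift
      ce <- cs + clen
      ov <- overlap_width(enh_start[i], enh_end[i], cs, ce)
      if (ov / enh_len[i] > 0.5 && ov / clen > 0.5) break
    }
    cons_el[[length(cons_el) + 1L]] <- tibble::tibble(
      chrom = slot_chrom[i], start = as.integer(cs), end = as.integer(ce),
      name = sprintf("uce_%d", i))
  }
  for (i in traps$conserved_small) { # covers only 30% of the enhancer
    clen <- round(0.3 * enh_len[i])
    cons_el[[length(cons_el) + 1L]] <- tibble::tibble(
      chrom = slot_chrom[i], start = enh_start[i],
      end = enh_start[i] + clen, name = sprintf("uce_small_%d", i))
  }
  for (i in traps$conserved_big) { # covers the enhancer, but is 4x longer
    cons_el[[length(cons_el) + 1L]] <- tibble::tibble(
      chrom = slot_chrom[i], start = pmax(0L, enh_start[i] - enh_len[i]),
      end = enh_end[i] + 2L * enh_len[i], name = sprintf("uce_big_%d", i))
  }
  conserved <- dplyr::bind_rows(cons_el)
  conserved <- conserved[order(conserved$chrom, conserved$start), ,
                         drop = FALSE]

  ## ---- gene pools and indispensability ----------------------------------
  n_hub <- max(3L, round(0.1 * spec$n_genes))       # redundantly regulated,
  n_ess <- max(3L, round(0.1 * spec$n_genes))       # dispensable targets
  hub_genes <- genes[seq_len(n_hub)]
  ess_genes <- genes[(n_hub + 1):(n_hub + n_ess)]   # indispensable targets
  gis <- stats::setNames(stats::rbeta(spec$n_genes, 4, 4), genes)
  gis[hub_genes] <- stats::rbeta(n_hub, 2, 8)
  gis[ess_genes] <- stats::rbeta(n_ess, 8, 2)

  ## ---- tissue activity and regulatory edges ------------------------------
  imm <- tissues[seq_len(min(2, length(tissues)))]
  neuro <- if (length(tissues) >= 4) tissues[3:4] else tissues
  etu_lambda <- c(tolerant = max(0.2, 3 - s), background = 3,
                  low = 3 + 2.5 * s)
  eod_lambda <- c(tolerant = max(0.05, 1.5 - 0.45 * s), background = 1.5,
                  low = 1.5 + 0.8 * s)
  p_pool <- function() min(1, n_hub / spec$n_genes + 0.3 * s)
  net_rows <- list()
  enh_tissue_sets <- vector("list", n)
  for (i in seq_len(n)) {
    k <- cls[i]
    etu <- min(spec$n_tissues, 1 + stats::rpois(1, etu_lambda[[k]]))
    w <- rep(1, spec$n_tissues)
    names(w) <- tissues
    if (k == "tolerant") w[imm] <- 1 + s
    if (k == "low") w[neuro] <- 1 + s
    tset <- sample(tissues, etu, prob = w)
    enh_tissue_sets[[i]] <- sort(tset)
    eod <- min(spec$n_genes, 1 + stats::rpois(1, eod_lambda[[k]]))
    pool <- if (k == "tolerant" && stats::runif(1) < p_pool()) hub_genes
    else if (k == "low" && stats::runif(1) < p_pool()) ess_genes
    else genes
    targets <- sample(pool, min(eod, length(pool)))
    # distribute the enhancer's tissues over its edges; every edge gets at
    # least one tissue and the union reproduces the full set
    edge_sets <- lapply(targets, function(t_)
      sample(tset, 1 + stats::rbinom(1, etu - 1, 0.4)))
    missing <- setdiff(tset, unique(unlist(edge_sets)))
    for (mt in missing) {
      j <- sample.int(length(edge_sets), 1)
      edge_sets[[j]] <- c(edge_sets[[j]], mt)
    }
    for (j in seq_along(targets)) {
      net_rows[[length(net_rows) + 1L]] <- tibble::tibble(
        enhancer = enh_ids[i], gene = targets[j],
        tissue = sort(unique(edge_sets[[j]])))
    }
  }
  network <- dplyr::bind_rows(net_rows)
  network <- network[order(network$enhancer, network$gene, network$tissue), ,
                     drop = FALSE]

  ## ---- gene-gene interactions -------------------------------------------
  n_int <- round(spec$n_genes / 2)
  inter <- list()
  for (ty in DIRECT_INTERACTION_TYPES) {
    for (j in seq_len(n_int)) {
      a <- if (stats::runif(1) < 0.5) sample(ess_genes, 1) else
        sample(genes, 1)
      b <- sample(setdiff(genes, a), 1)
      inter[[length(inter) + 1L]] <- tibble::tibble(
        gene_a = min(a, b), gene_b = max(a, b), type = ty)
    }
  }
  interactions <- dplyr::bind_rows(inter) |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)

  ## ---- conservation scores ----------------------------------------------
  cons_mean <- c(tolerant = max(0.03, 0.2 - 0.04 * s), background = 0.2,
                 low = min(0.95, 0.2 + 0.25 * s))
  kconc <- 8
  conservation <- stats::setNames(vapply(seq_len(n), function(i) {
    m <- cons_mean[[cls[i]]]
    stats::rbeta(1, m * kconc, (1 - m) * kconc)
  }, numeric(1)), enh_ids)

  ## ---- sequences and motifs ----------------------------------------------
  pwms <- synthetic_pwms()
  consensus <- lapply(pwms, function(p)
    paste(rownames(p)[apply(p, 2, which.max)], collapse = ""))
  sequences <- stats::setNames(vapply(seq_len(n), function(i) {
    sq <- paste(sample(c("A", "C", "G", "T"), enh_len[i], replace = TRUE),
                collapse = "")
    if (cls[i] == "low" && stats::runif(1) < min(1, 0.2 * s)) {
      mo <- consensus[[sample(seq_along(consensus), 1)]]
      at <- sample.int(nchar(sq) - nchar(mo), 1)
      substr(sq, at, at + nchar(mo) - 1L) <- mo
    }
    sq
  }, character(1)), enh_ids)

  ## ---- disease table ------------------------------------------------------
  n_dis <- min(12L, n)
  dis_idx <- sample(c(which(cls == "low"), bg), n_dis)
  dis_types <- sample(c("neurological disorder", "developmental disease",
                        "immune disorder", "skin disease", "cancer"),
                      n_dis, replace = TRUE)
  first_target <- vapply(dis_idx, function(i)
    network$gene[network$enhancer == enh_ids[i]][1], character(1))
  disease <- tibble::tibble(
    id = sprintf("DIS%03d", seq_len(n_dis)),
    chrom = slot_chrom[dis_idx],
    start = pmax(0L, enh_start[dis_idx] - sample(0:300, n_dis,
                                                 replace = TRUE)),
    end = enh_end[dis_idx] + sample(0:300, n_dis, replace = TRUE),
    target_gene = first_target,
    disease = dis_types)

  ## ---- assemble -----------------------------------------------------------
  gis_tbl <- gis[stats::runif(spec$n_genes) > 0.05]      # ~5% missing
  cons_tbl <- conservation[stats::runif(n) > 0.02]       # ~2% missing
  enhancers <- tibble::tibble(id = enh_ids, chrom = slot_chrom,
                              start = enh_start, end = enh_end,
                              tissues = enh_tissue_sets)
  manifest <- tibble::tibble(id = enh_ids, class = cls, trap = trap_of,
                             length = enh_len)
  tissue_map <- stats::setNames(tissues, tissues)
  universe <- structure(
    list(spec = spec, enhancers = enhancers, network = network,
         interactions = interactions, deletions = deletions, exons = exons,
         conserved = conserved, gis = gis_tbl, conservation = cons_tbl,
         gis_full = gis, conservation_full = conservation,
         sequences = sequences, pwms = pwms, disease = disease,
         manifest = manifest, samples = samples, tissue_map = tissue_map),
    class = "synthetic_universe")
  if (!is.null(out_dir)) write_universe(universe, out_dir)
  universe
}

#' @export
print.synthetic_universe <- function(x, ...) {
  tab <- table(x$manifest$class)
  cat("<synthetic_universe> ", nrow(x$enhancers), " enhancers (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "), ",
      nrow(x$deletions), " deletions, ", length(x$samples), " samples, ",
      x$spec$n_tissues, " tissues; seed ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

# four synthetic motifs with strong consensus columns (counts 17 vs 1)
synthetic_pwms <- function() {
  consensi <- c(SYNM01 = "TGACGTCA", SYNM02 = "CACGTGAC",
                SYNM03 = "GGGCGGGGC", SYNM04 = "ATTTGCATAA")
  lapply(consensi, function(cons) {
    ch <- strsplit(cons, "")[[1]]
    m <- matrix(1, nrow = 4, ncol = length(ch),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(ch)) m[ch[j], j] <- 17
    m
  })
}

#' Write a synthetic universe to disk
#'
#' Emits the full bundle as plain-text files (BED, VCF, TSV, FASTA, JASPAR
#' motif text) with fixed formatting, so regeneration from the same spec is
#' byte-identical.
#'
#' @param universe a `synthetic_universe`.
#' @param dir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_universe <- function(universe, dir) {
  stopifnot(inherits(universe, "synthetic_universe"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_bed(universe$enhancers[c("chrom", "start", "end", "id")] |>
              stats::setNames(c("chrom", "start", "end", "name")),
            p("enhancers.bed"))
  readr::write_tsv(universe$network, p("network.tsv"), progress = FALSE)
  readr::write_tsv(universe$interactions, p("interactions.tsv"),
                   progress = FALSE)
  write_deletions_vcf(universe$deletions, universe$samples,
                      p("deletions.vcf"))
  write_bed(universe$exons, p("exons.bed"))
  write_bed(universe$conserved, p("conserved.bed"))
  write_scalar_table(universe$gis, p("gis.tsv"))
  write_scalar_table(universe$conservation, p("conservation.tsv"))
  writeLines(unlist(lapply(names(universe$sequences), function(id)
    c(paste0(">", id), universe$sequences[[id]]))), p("sequences.fa"))
  writeLines(unlist(lapply(names(universe$pwms), function(nm) {
    m <- universe$pwms[[nm]]
    c(paste0(">", nm),
      vapply(c("A", "C", "G", "T"), function(b)
        paste0(b, "  [ ", paste(m[b, ], collapse = " "), " ]"),
        character(1)))
  })), p("pwms.txt"))
  readr::write_tsv(universe$disease, p("disease.tsv"), progress = FALSE)
  readr::write_tsv(universe$manifest, p("manifest.tsv"), progress = FALSE)
  tm <- universe$tissue_map
  writeLines(jsonlite::toJSON(as.list(tm), auto_unbox = TRUE, pretty = TRUE),
             p("tissue_map.json"))
  files <- c("enhancers.bed", "network.tsv", "interactions.tsv",
             "deletions.vcf", "exons.bed", "conserved.bed", "gis.tsv",
             "conservation.tsv", "sequences.fa", "pwms.txt", "disease.tsv",
             "manifest.tsv", "tissue_map.json")
  invisible(stats::setNames(file.path(dir, files), files))
}

# VCF 4.2 writer for the synthetic deletion calls: symbolic <DEL> records
# with SVTYPE/END/AF, explicit REF/ALT records for the short calls flagged
# `explicit`, and per-sample GT columns.
write_deletions_vcf <- function(deletions, samples, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of SV\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  explicit <- if ("explicit" %in% names(deletions)) deletions$explicit else
    rep(FALSE, nrow(deletions))
  base4 <- c("A", "C", "G", "T")
  rows <- vapply(seq_len(nrow(deletions)), function(i) {
    d <- deletions[i, ]
    gt <- rep("0|0", length(samples))
    gt[samples %in% d$hom_samples[[1]]] <- "1|1"
    gt[samples %in% d$het_samples[[1]]] <- "0|1"
    if (explicit[i]) {
      # anchor base + deleted bases; bases are deterministic in coordinates
      pos <- d$start                       # 1-based anchor == 0-based start
      ref <- paste(base4[(seq_len(d$length + 1) + d$start) %% 4 + 1],
                   collapse = "")
      alt <- substr(ref, 1, 1)
      info <- sprintf("AF=%s", format_num(d$af, 4))
    } else {
      pos <- d$start + 1L                  # POS..END 1-based inclusive span
      ref <- base4[d$start %% 4 + 1]
      alt <- "<DEL>"
      info <- sprintf("SVTYPE=DEL;END=%d;AF=%s", d$end,
                      format_num(d$af, 4))
    }
    paste(c(d$chrom, pos, d$id, ref, alt, ".", d$filter, info, "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Generate long-read-like novel deletions
#'
#' Emulates a deletion callset from a handful of deeply sequenced genomes:
#' every emitted call overlaps every base-universe deletion by strictly less
#' than `max_overlap` of its own length, and a subset newly deletes (fully,
#' homozygously) background enhancers that the base callset never touched.
#'
#' @param universe a `synthetic_universe`.
#' @param n_novel_enhancers background enhancers to delete completely.
#' @param n_noise additional novel calls not deleting any enhancer.
#' @param max_overlap maximum tolerated overlap fraction with any base call.
#' @param prefer_tissue_specific if TRUE (default) the newly deleted
#'   enhancers are drawn from the most tissue-specific background enhancers,
#'   emulating genuinely tolerant elements that short-read callsets simply
#'   missed; FALSE draws uniformly.
#' @param seed RNG seed.
#' @return list: `deletions` (tibble in [read_deletions()] shape, with its
#'   own 3-sample panel), `newly_deleted` (enhancer ids now fully deleted).
#' @export
generate_pacbio_like_deletions <- function(universe, n_novel_enhancers = 20,
                                           n_noise = 40, max_overlap = 0.8,
                                           prefer_tissue_specific = TRUE,
                                           seed = 1) {
  stopifnot(inherits(universe, "synthetic_universe"))
  set.seed(seed)
  man <- universe$manifest
  enh <- universe$enhancers
  base <- universe$deletions
  lr_samples <- sprintf("LR%02d", 1:3)
  # background enhancers with no trap geometry and no base deletion overlap
  clean_bg <- man$id[man$class == "background" & man$trap == ""]
  cand <- enh[enh$id %in% clean_bg, , drop = FALSE]
  untouched <- !overlaps_any(cand, base)
  picked <- cand[untouched, , drop = FALSE]
  if (isTRUE(prefer_tissue_specific)) {
    picked <- picked[order(lengths(picked$tissues), picked$id), , drop = FALSE]
  }
  picked <- picked[seq_len(min(n_novel_enhancers, nrow(picked))), ,
                   drop = FALSE]
  rows <- list()
  add <- function(chrom, start, end) {
    hom <- sample(lr_samples, 1 + stats::rbinom(1, 2, 0.3))
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      id = sprintf("PB%05d", length(rows) + 1L), chrom = chrom,
      start = as.integer(start), end = as.integer(end),
      length = as.integer(end - start),
      af = length(hom) / length(lr_samples),
      n_hom = length(hom), n_het = 0L,
      hom_samples = list(hom), het_samples = list(character()),
      filter = "PASS", explicit = FALSE)
  }
  for (i in seq_len(nrow(picked))) {
    add(picked$chrom[i], picked$start[i] - sample(50:300, 1),
        picked$end[i] + sample(50:300, 1))
  }
  # noise calls placed in free slot prefixes, allowed to graze base calls
  free_start <- sample(seq(500, 1200, by = 50), n_noise, replace = TRUE)
  slot_pick <- sample(seq_len(nrow(enh)), n_noise, replace = TRUE)
  for (j in seq_len(n_noise)) {
    st <- enh$start[slot_pick[j]] - 1900L + free_start[j]
    add(enh$chrom[slot_pick[j]], st, st + sample(80:400, 1))
  }
  novel <- dplyr::bind_rows(rows)
  # enforce the overlap ceiling against every base call
  keep <- vapply(seq_len(nrow(novel)), function(i) {
    same <- base[base$chrom == novel$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) return(TRUE)
    ov <- overlap_width(novel$start[i], novel$end[i], same$start, same$end)
    all(ov / novel$length[i] < max_overlap)
  }, logical(1))
  novel <- novel[keep, , drop = FALSE]
  attr(novel, "samples") <- lr_samples
  newly <- call_lof_tolerant(enh, novel)
  list(deletions = novel, newly_deleted = newly)
}
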