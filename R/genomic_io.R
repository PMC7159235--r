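#' Read a tissue-annotated enhancer-target network
#'
#' Reads a TSV with columns `enhancer` (region id, optionally the compound
#' `chr:start-end$GENE` form), `gene` and `tissue` (one raw tissue label per
#' row). Raw labels are mapped to tissue groups through `tissue_map`; rows
#' whose label has no mapping are dropped and counted, mirroring the practice
#' of discarding ungrouped cell types when collapsing epigenome panels into
#' tissue groups.
#'
#' Multiple rows for the same (enhancer, gene) pair are merged into a single
#' regulatory edge carrying the union of its tissue groups; the edge weight is
#' the number of distinct groups.
#'
#' @param path TSV file. Lines starting with `#` are ignored.
#' @param tissue_map named character vector mapping raw tissue labels to group
#'   labels. `NULL` keeps raw labels as their own groups.
#' @return list with
#'   \describe{
#'     \item{edges}{tibble `enhancer`, `gene`, `tissues` (list of character),
#'       `weight` (tissue count)}
#'     \item{enhancers}{tibble `id`, `chrom`, `start`, `end`, `tissues`
#'       (list), deduplicated by coordinates}
#'     \item{n_discarded}{rows dropped for unmapped tissue labels}
#'   }
#' @export
read_enhancer_network <- function(path, tissue_map = NULL) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(raw) == 0) stop("empty network file: ", path, call. = FALSE)
  if (!all(c("enhancer", "gene", "tissue") %in% names(raw))) {
    # positional fallback: enhancer, gene, tissue
    if (ncol(raw) < 3) stop("network file needs columns enhancer/gene/tissue",
                            call. = FALSE)
    names(raw)[1:3] <- c("enhancer", "gene", "tissue")
  }
  parsed <- parse_region_id(raw$enhancer)
  # compound keys carry their own gene; explicit gene column wins when present
  gene <- ifelse(is.na(raw$gene) & !is.na(parsed$gene), parsed$gene, raw$gene)
  df <- tibble::tibble(
    enhancer = parsed$id, chrom = parsed$chrom,
    start = parsed$start, end = parsed$end,
    gene = as.character(gene), tissue = as.character(raw$tissue)
  )
  if (is.null(tissue_map)) {
    labs <- unique(df$tissue)
    tissue_map <- stats::setNames(labs, labs)
  }
  mapped <- unname(tissue_map[df$tissue])
  n_discarded <- sum(is.na(mapped))
  df$group <- mapped
  df <- df[!is.na(df$group), , drop = FALSE]
  if (nrow(df) == 0) {
    return(list(edges = tibble::tibble(enhancer = character(), gene = character(),
                                       tissues = list(), weight = integer()),
                enhancers = tibble::tibble(id = character(), chrom = character(),
                                           start = integer(), end = integer(),
                                           tissues = list()),
                n_discarded = n_discarded))
  }
  edges <- df |>
    dplyr::group_by(.data$enhancer, .data$gene) |>
    dplyr::summarise(tissues = list(sort(unique(.data$group))),
                     .groups = "drop") |>
    dplyr::mutate(weight = lengths(.data$tissues)) |>
    dplyr::arrange(.data$enhancer, .data$gene)
  enhancers <- df |>
    dplyr::group_by(id = .data$enhancer, .data$chrom, .data$start, .data$end) |>
    dplyr::summarise(tissues = list(sort(unique(.data$group))),
                     .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
  validate_intervals(enhancers, context = path)
  list(edges = edges, enhancers = enhancers, n_discarded = n_discarded)
}

#' Read deletion calls from a VCF
#'
#' Accepts symbolic `<DEL>` records (deleted span taken as `[POS, END]`
#' 1-based inclusive, i.e. `[POS-1, END)` internally) and explicit REF/ALT
#' deletions (deleted span = the REF suffix beyond the shared ALT prefix).
#' Multi-allelic explicit records are split into per-allele calls; genotypes
#' referencing other alternate alleles are treated as non-carrier. Phased and
#' unphased genotypes are normalized (`1|1` -> `1/1`).
#'
#' @param path VCF 4.x file (uncompressed or bgzipped).
#' @param pass_only if TRUE keep only FILTER `PASS`/`.` records. Default FALSE:
#'   no FILTER policy is imposed.
#' @param min_length,max_length optional deletion-length bounds in bp
#'   (permissive by default).
#' @return tibble with one row per deletion call: `id`, `chrom`, `start`,
#'   `end` (0-based half-open), `length`, `af` (allele frequency: INFO AF when
#'   present, else computed from genotypes), `n_hom`, `n_het`, `hom_samples`,
#'   `het_samples` (list columns of sample names), `filter`. Attribute
#'   `samples` carries the full sample panel; attribute `n_skipped` counts
#'   records dropped for missing END / non-DEL type.
#' @export
read_deletions <- function(path, pass_only = FALSE,
                           min_length = 1L, max_length = Inf) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no records in VCF: ", path, call. = FALSE)
  gt_raw <- if (!is.null(v@gt) && ncol(v@gt) > 1) {
    vcfR::extract.gt(v, element = "GT")
  } else NULL
  samples <- if (is.null(gt_raw)) character() else colnames(gt_raw)

  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(^|;)", key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_,
           character(1))
  }

  out <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    pos <- as.integer(fix$POS[i])
    ref <- fix$REF[i]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    filt <- fix$FILTER[i]
    if (isTRUE(pass_only) && !filt %in% c("PASS", ".", NA)) next
    info <- fix$INFO[i]
    svtype <- info_field(info, "SVTYPE")
    af_info <- suppressWarnings(as.numeric(
      strsplit(info_field(info, "AF"), ",", fixed = TRUE)[[1]]))
    gts <- if (is.null(gt_raw)) NULL else gt_raw[i, ]

    for (a in seq_along(alts)) {
      alt <- alts[a]
      if (alt == "<DEL>" || (!is.na(svtype) && svtype == "DEL" &&
                             startsWith(alt, "<"))) {
        endpos <- suppressWarnings(as.integer(info_field(info, "END")))
        if (is.na(endpos)) {
          svlen <- suppressWarnings(as.numeric(
            strsplit(info_field(info, "SVLEN"), ",")[[1]][a]))
          if (is.na(svlen)) { n_skipped <- n_skipped + 1L; next }
          endpos <- pos + abs(svlen) - 1L
        }
        start0 <- pos - 1L
        end0 <- endpos
      } else if (!is.na(svtype) && svtype != "DEL" && startsWith(alt, "<")) {
        next  # non-DEL symbolic SV
      } else if (nchar(ref) > nchar(alt) && startsWith(ref, alt)) {
        # explicit deletion: deleted bases are the REF suffix after the anchor
        start0 <- pos - 1L + nchar(alt)
        end0 <- pos - 1L + nchar(ref)
      } else {
        next  # SNV / insertion / complex — not a deletion
      }
      len <- end0 - start0
      if (len < min_length || len > max_length || len <= 0) next

      if (!is.null(gts)) {
        code <- normalize_genotypes(gts, allele = a)
        hom <- samples[!is.na(code) & code == "1/1"]
        het <- samples[!is.na(code) & code == "0/1"]
        n_called <- sum(!is.na(code))
        af_gt <- if (n_called > 0) {
          (2 * length(hom) + length(het)) / (2 * n_called)
        } else NA_real_
      } else {
        hom <- het <- character()
        af_gt <- NA_real_
      }
      af <- if (length(af_info) >= a && !is.na(af_info[a])) af_info[a] else af_gt
      out[[length(out) + 1L]] <- tibble::tibble(
        id = if (is.na(fix$ID[i]) || fix$ID[i] == ".") {
          sprintf("%s:%d-%d_DEL", fix$CHROM[i], start0, end0)
        } else if (length(alts) > 1) {
          paste0(fix$ID[i], "_", a)
        } else fix$ID[i],
        chrom = fix$CHROM[i], start = start0, end = end0, length = len,
        af = af, n_hom = length(hom), n_het = length(het),
        hom_samples = list(hom), het_samples = list(het),
        filter = filt
      )
    }
  }
  if (length(out) == 0) {
    res <- tibble::tibble(id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          length = integer(), af = numeric(),
                          n_hom = integer(), n_het = integer(),
                          hom_samples = list(), het_samples = list(),
                          filter = character())
  } else {
    res <- dplyr::bind_rows(out)
    validate_intervals(res, context = path)
  }
  if (n_skipped > 0) {
    warning(n_skipped, " deletion record(s) skipped (END not resolvable)",
            call. = FALSE)
  }
  attr(res, "samples") <- samples
  attr(res, "n_skipped") <- n_skipped
  res
}

# Internal: normalize raw GT strings against alternate allele index `allele`.
# Returns "0/0", "0/1", "1/1" or NA. Genotypes carrying other alt alleles are
# counted as non-carrier for this allele (conservative carrier counting).
normalize_genotypes <- function(gt, allele = 1L) {
  gt <- as.character(gt)
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) == 0 || any(p == ".") || any(is.na(p))) return(NA_character_)
    n_alt <- sum(p == as.character(allele))
    if (n_alt >= 2) "1/1" else if (n_alt == 1) "0/1" else "0/0"
  }, character(1))
}

#' Read a BED file
#'
#' BED3/BED4+, 0-based half-open; `#`, `track` and `browser` lines skipped.
#' Coordinate violations are reported with their line number.
#'
#' @param path BED file.
#' @return interval tibble (`chrom`, `start`, `end`, and `name` when a fourth
#'   column is present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3)) {
    stop(path, ": line ", lineno[which(nf < 3)[1]], " has fewer than 3 fields",
         call. = FALSE)
  }
  df <- tibble::tibble(
    chrom = vapply(fields, `[`, character(1), 1),
    start = suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2))),
    end = suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  )
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 |
                 df$start >= df$end)
  if (length(bad) > 0) {
    stop(path, ": invalid interval at line ", lineno[bad[1]], call. = FALSE)
  }
  if (any(nf >= 4)) {
    df$name <- vapply(fields, function(x) if (length(x) >= 4) x[4]
                      else NA_character_, character(1))
  }
  df
}

#' Write a BED file
#'
#' @param df interval tibble (optionally with `name`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  df <- validate_intervals(df)
  cols <- c("chrom", "start", "end", if ("name" %in% names(df)) "name")
  lines <- do.call(paste, c(unname(as.list(df[cols])), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column id->value table
#'
#' Used for gene indispensability scores and per-enhancer conservation scores.
#' Keys must be unique; values must parse as numbers.
#'
#' @param path TSV with two columns (id, value); `#` lines and an optional
#'   header row are skipped.
#' @return named numeric vector (possibly empty).
#' @export
read_scalar_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(stats::setNames(numeric(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) < 2)) {
    stop(path, ": expected two tab-separated columns", call. = FALSE)
  }
  key <- vapply(fields, `[`, character(1), 1)
  valchr <- vapply(fields, `[`, character(1), 2)
  # tolerate a single header row of non-numeric text
  if (length(key) > 0 && is.na(suppressWarnings(as.numeric(valchr[1]))) &&
      length(valchr) > 1) {
    key <- key[-1]; valchr <- valchr[-1]
  }
  if (length(key) == 0) return(stats::setNames(numeric(), character()))
  val <- suppressWarnings(as.numeric(valchr))
  if (anyNA(val)) {
    stop(path, ": non-numeric value for key '", key[which(is.na(val))[1]],
         "'", call. = FALSE)
  }
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    stop(path, ": duplicated key '", dup[1], "'", call. = FALSE)
  }
  stats::setNames(val, key)
}

#' Write a two-column id->value table
#'
#' @param x named numeric vector.
#' @param path output path.
#' @param header optional vector of `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_scalar_table <- function(x, path, header = NULL) {
  lines <- c(header, paste(names(x), format_num(unname(x)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-gene interaction edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `type`. Only the four direct
#' interaction kinds (protein-protein, metabolic, phosphorylation, signaling)
#' belong in the integrated network; filtering against a whitelist happens in
#' [build_meganet()].
#'
#' @param path TSV file.
#' @return tibble `gene_a`, `gene_b`, `type`.
#' @export
read_interactions <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("gene_a", "gene_b", "type") %in% names(raw))) {
    if (ncol(raw) < 3) stop("interaction file needs gene_a/gene_b/type",
                            call. = FALSE)
    names(raw)[1:3] <- c("gene_a", "gene_b", "type")
  }
  tibble::tibble(gene_a = as.character(raw$gene_a),
                 gene_b = as.character(raw$gene_b),
                 type = as.character(raw$type))
}

#' Read JASPAR-style position weight matrices
#'
#' Parses the plain-text JASPAR format:
#' ```
#' >MA0001.1 NAME
#' A  [ 1 2 3 ]
#' C  [ 0 1 0 ]
#' G  [ 2 0 1 ]
#' T  [ 1 1 0 ]
#' ```
#' Brackets are optional; rows may appear in any order.
#'
#' @param path motif text file.
#' @return named list of 4 x L numeric count matrices with rownames
#'   `A, C, G, T`.
#' @export
read_jaspar_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop(path, ": no motif headers ('>') found",
                                call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  pwms <- list()
  for (k in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[k]])
    nm <- strsplit(hdr, "\\s+")[[1]][1]
    block <- lines[(starts[k] + 1L):(bounds[k + 1L] - 1L)]
    rows <- list()
    for (bl in block) {
      base <- toupper(sub("^\\s*([ACGTacgt]).*", "\\1", bl))
      nums <- as.numeric(strsplit(trimws(gsub("[][]", " ",
                                              sub("^\\s*[ACGTacgt]", "", bl))),
                                  "\\s+")[[1]])
      rows[[base]] <- nums
    }
    if (!all(c("A", "C", "G", "T") %in% names(rows))) {
      stop(path, ": motif ", nm, " is missing one of the A/C/G/T rows",
           call. = FALSE)
    }
    mat <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
    if (any(colSums(mat) <= 0)) {
      stop(path, ": motif ", nm, " has a zero column sum", call. = FALSE)
    }
    pwms[[nm]] <- mat
  }
  pwms
}

#' Read enhancer sequences from FASTA
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] named by record id.
#' @export
read_enhancer_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

# Internal: fixed-format numeric rendering so regenerated files are
# byte-identical across runs.
format_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA",
         sub("\\.?0+$", "", formatC(x, digits = digits, format = "f")))
}
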