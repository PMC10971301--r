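REGION_CLASSES <- c("intergenic", "intron", "exon_nonsynonymous",
                    "exon_synonymous", "core_promoter")

# Per-gene helper: CDS segments in genomic order, concatenated coding
# sequence (reverse-complemented for '-' strand genes) and the cumulative
# offsets used to map genomic positions into CDS coordinates.
build_gene_index <- function(models, genome) {
  models %>%
    dplyr::group_by(.data$gene_id, .data$contig, .data$strand) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    tidyr::nest(segments = c("start", "end", "phase")) %>%
    dplyr::ungroup()
}

# Coding sequence of one gene (5'->3' on the coding strand).
gene_cds_seq <- function(genome, contig, strand, segments) {
  seqs <- substring(as.character(genome[[contig]]), segments$start, segments$end)
  cds <- paste(seqs, collapse = "")
  if (strand == "-") cds <- revcomp(cds)
  cds
}

# 1-based position within the coding sequence of a genomic position known
# to fall in one of the segments; honours the first segment's phase.
cds_coordinate <- function(pos, strand, segments) {
  seg_len <- segments$end - segments$start + 1L
  if (strand == "+") {
    i <- which(pos >= segments$start & pos <= segments$end)
    before <- if (i > 1) sum(seg_len[seq_len(i - 1)]) else 0L
    coord <- before + (pos - segments$start[i] + 1L)
    first_phase <- segments$phase[1]
  } else {
    # transcription order is rightmost segment first
    ord <- order(segments$start, decreasing = TRUE)
    segs <- segments[ord, , drop = FALSE]
    lens <- segs$end - segs$start + 1L
    i <- which(pos >= segs$start & pos <= segs$end)
    before <- if (i > 1) sum(lens[seq_len(i - 1)]) else 0L
    coord <- before + (segs$end[i] - pos + 1L)
    first_phase <- segs$phase[1]
  }
  coord - first_phase
}

#' Annotate mutation sites with genic regions
#'
#' Assigns each record one of five regions: exonic CDS (split into
#' synonymous / non-synonymous by translating the affected codon with the
#' standard genetic code on the coding strand), intron (inside a gene span
#' but outside CDS), core promoter (the 200 bases immediately 5' of the
#' start codon on the coding strand, truncated at contig ends), or
#' intergenic. Precedence when features overlap: CDS > intron >
#' core promoter > intergenic; ties between genes are broken by the
#' lexicographically smallest gene id.
#'
#' Sites falling in a partial codon at a model edge stay exonic with `NA`
#' codon change and are reported as `exon_undetermined`.
#'
#' @param records Records tibble.
#' @param models Gene models tibble from [read_gene_models()].
#' @param genome `DNAStringSet` reference.
#' @param promoter_width Core promoter width in bp (default 200).
#' @return The records tibble with added columns `region`, `gene_id`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`.
#' @export
annotate_sites <- function(records, models, genome, promoter_width = 200L) {
  records <- validate_records(records, genome)
  n <- nrow(records)
  out <- records %>%
    dplyr::mutate(region = "intergenic", gene_id = NA_character_,
                  ref_codon = NA_character_, alt_codon = NA_character_,
                  ref_aa = NA_character_, alt_aa = NA_character_)
  if (n == 0 || nrow(models) == 0) return(out)

  idx <- build_gene_index(models, genome)
  gene_span <- models %>%
    dplyr::group_by(.data$gene_id, .data$contig, .data$strand) %>%
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  clen <- genome_lengths(genome)
  promoters <- gene_span %>%
    dplyr::left_join(clen, by = "contig") %>%
    dplyr::mutate(
      p_start = ifelse(.data$strand == "+",
                       pmax(1L, .data$start - promoter_width), .data$end + 1L),
      p_end = ifelse(.data$strand == "+",
                     .data$start - 1L,
                     pmin(.data$length, .data$end + promoter_width))
    ) %>%
    dplyr::filter(.data$p_start <= .data$p_end)

  site_gr <- GenomicRanges::GRanges(records$contig,
                                    IRanges::IRanges(records$pos, records$pos))
  overlap_gene <- function(feat) {
    gr <- GenomicRanges::GRanges(feat$contig,
                                 IRanges::IRanges(feat$start, feat$end))
    hits <- GenomicRanges::findOverlaps(site_gr, gr)
    if (length(hits) == 0) return(rep(NA_character_, n))
    tibble::tibble(site = S4Vectors::queryHits(hits),
                   gene_id = feat$gene_id[S4Vectors::subjectHits(hits)]) %>%
      dplyr::group_by(.data$site) %>%
      dplyr::summarise(gene_id = min(.data$gene_id), .groups = "drop") %>%
      {replace(rep(NA_character_, n), .$site, .$gene_id)}
  }
  cds_gene <- overlap_gene(models)
  span_gene <- overlap_gene(gene_span)
  prom_gene <- overlap_gene(
    promoters %>% dplyr::select("gene_id", "contig",
                                start = "p_start", end = "p_end"))

  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(n)) {
    if (!is.na(cds_gene[i])) {
      g <- idx[idx$gene_id == cds_gene[i], ]
      segs <- g$segments[[1]]
      cds <- gene_cds_seq(genome, g$contig, g$strand, segs)
      # coord: position in the in-frame coding sequence (phase-trimmed);
      # <= 0 means the site sits in the leading partial codon
      coord <- cds_coordinate(records$pos[i], g$strand, segs)
      first_phase <- if (g$strand == "+") segs$phase[1] else
        segs$phase[order(segs$start, decreasing = TRUE)][1]
      out$gene_id[i] <- g$gene_id
      if (coord < 1L) {
        out$region[i] <- "exon_undetermined"
        next
      }
      codon_i <- (coord - 1L) %/% 3L
      c_start <- first_phase + codon_i * 3L + 1L
      c_end <- c_start + 2L
      if (c_end > nchar(cds)) { # trailing partial codon
        out$region[i] <- "exon_undetermined"
        next
      }
      ref_codon <- substr(cds, c_start, c_end)
      within <- coord - codon_i * 3L # 1..3
      alt_coding <- if (g$strand == "+") records$alt[i] else complement_bases(records$alt[i])
      alt_codon <- ref_codon
      substr(alt_codon, within, within) <- alt_coding
      ref_aa <- unname(code[ref_codon])
      alt_aa <- unname(code[alt_codon])
      out$region[i] <- if (is.na(ref_aa) || is.na(alt_aa)) {
        "exon_undetermined"
      } else if (ref_aa == alt_aa) "exon_synonymous" else "exon_nonsynonymous"
      out$ref_codon[i] <- ref_codon; out$alt_codon[i] <- alt_codon
      out$ref_aa[i] <- ref_aa; out$alt_aa[i] <- alt_aa
    } else if (!is.na(span_gene[i])) {
      out$region[i] <- "intron"; out$gene_id[i] <- span_gene[i]
    } else if (!is.na(prom_gene[i])) {
      out$region[i] <- "core_promoter"; out$gene_id[i] <- prom_gene[i]
    }
  }
  out
}

#' Summarise region calls
#'
#' @param calls Output of [annotate_sites()].
#' @return A tibble with one row per region (`region`, `count`,
#'   `proportion`, `percent`). Rare `exon_undetermined` calls (partial
#'   codons at model edges) are reported in their own row and excluded
#'   from the five-way proportions, with a warning.
#' @export
region_summary <- function(calls) {
  stopifnot("region" %in% names(calls))
  undet <- sum(calls$region == "exon_undetermined")
  main <- calls %>% dplyr::filter(.data$region != "exon_undetermined")
  counts <- table(factor(main$region, levels = REGION_CLASSES))
  total <- sum(counts)
  out <- tibble::tibble(
    region = REGION_CLASSES,
    count = as.integer(counts),
    proportion = if (total > 0) as.integer(counts) / total else NA_real_
  ) %>%
    dplyr::mutate(percent = round(.data$proportion * 100, 2))
  if (undet > 0) {
    warning(undet, " exon_undetermined call(s) excluded from the five-way proportions",
            call. = FALSE)
    out <- dplyr::bind_rows(out, tibble::tibble(
      region = "exon_undetermined", count = undet,
      proportion = NA_real_, percent = NA_real_))
  }
  out
}

#' Genes carrying non-synonymous mutations
#'
#' @param calls Output of [annotate_sites()].
#' @return A tibble of unique, sorted `gene_id`s with their
#'   non-synonymous call counts.
#' @export
nonsynonymous_gene_list <- function(calls) {
  calls %>%
    dplyr::filter(.data$region == "exon_nonsynonymous") %>%
    dplyr::count(.data$gene_id, name = "n_nonsynonymous") %>%
    dplyr::arrange(.data$gene_id)
}
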