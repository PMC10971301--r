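# Default class weights: the six strand-collapsed substitution classes at
# the relative frequencies characteristic of UVC mutagenesis
# (G:C→A:T, A:T→G:C, A:T→T:A, G:C→T:A, A:T→C:G, G:C→C:G).
UV_CLASS_WEIGHTS <- c("G:C→A:T" = 2239, "A:T→G:C" = 651, "A:T→T:A" = 394,
                      "G:C→T:A" = 221, "A:T→C:G" = 135, "G:C→C:G" = 67)

# For a collapsed paired class, the (centre, alt_centre) on the collapsed
# strand.
class_centre_alt <- function(cls_paired) {
  map <- list("G:C→A:T" = c("C", "T"), "A:T→G:C" = c("A", "G"),
              "A:T→T:A" = c("A", "T"), "G:C→T:A" = c("C", "A"),
              "A:T→C:G" = c("A", "C"), "G:C→C:G" = c("C", "G"))
  map[[cls_paired]]
}

#' Simulate a random genome
#'
#' Contigs of i.i.d. bases at a target GC fraction. The default GC of 0.48
#' matches a typical agaric fungal assembly.
#'
#' @param contig_lengths Integer vector of contig lengths (bp), named or
#'   not; default names `tig1`, `tig2`, ...
#' @param gc GC fraction in \[0, 1\].
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A named `DNAStringSet`.
#' @export
sim_genome <- function(contig_lengths, gc = 0.48, seed) {
  stopifnot(all(contig_lengths > 0), gc >= 0, gc <= 1, !missing(seed))
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(contig_lengths, function(L) {
    paste(sample(BASES, L, replace = TRUE, prob = p[BASES]), collapse = "")
  }, character(1))
  nm <- names(contig_lengths)
  if (is.null(nm)) nm <- paste0("tig", seq_along(contig_lengths))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Simulate a panel of mutant SNV sets
#'
#' Draws SNV positions without replacement within each mutant, assigns each
#' site a strand-collapsed substitution class from `class_weights`, and
#' realises it on the reference strand: a site whose reference base is the
#' collapsed centre (A or C) mutates directly; a G or T site realises the
#' complementary change. Optional 5'-flank context bias is applied by
#' rejection sampling. Tandem events and deletions are planted on top.
#'
#' @param genome `DNAStringSet` reference.
#' @param n_mutants Number of mutants in the panel.
#' @param snvs_per_mutant SNVs per mutant; a single value or a vector
#'   recycled to `n_mutants` (allowing exact panel totals).
#' @param class_weights Named non-negative weights over the six paired
#'   classes (default: UV spectrum).
#' @param context_weights Optional named numeric multipliers over 5'-flank
#'   bases (e.g. `c(T = 4, A = 3, C = 2, G = 1)`); `NULL` disables bias.
#' @param tandem_classes Named integer counts of tandem events to plant
#'   across the panel (names among `double_transition`,
#'   `double_transversion`, `transition_3prime`, `transition_5prime`).
#' @param deletions Optional tibble/data.frame with columns `contig`,
#'   `start`, `length`: intervals excised from one mutant's genome copy
#'   each (cycled over mutants in order).
#' @param seed Integer seed.
#' @return A list: `records` (tibble of all SNVs, tandem members included),
#'   `truth` (list of tibbles: `spectrum` planted class per site, `tandems`
#'   planted tandem events, `deletions` planted intervals with the carrier
#'   mutant), and `mutant_genomes` (named list of `DNAStringSet`, only for
#'   mutants carrying deletions).
#' @export
sim_mutants <- function(genome, n_mutants = 100, snvs_per_mutant = 37,
                        class_weights = UV_CLASS_WEIGHTS,
                        context_weights = NULL,
                        tandem_classes = NULL,
                        deletions = NULL, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  stopifnot(all(class_weights >= 0), sum(class_weights) > 0)
  class_weights <- class_weights[SPECTRUM_CLASSES]
  glen <- genome_lengths(genome)
  total_len <- sum(glen$length)
  snvs_per_mutant <- rep_len(snvs_per_mutant, n_mutants)
  if (sum(snvs_per_mutant) > total_len / 10) {
    stop("requested SNV load too dense for the genome", call. = FALSE)
  }
  genome_chr <- as.character(genome)

  draw_mutant <- function(mid, n) {
    if (n == 0) {
      return(tibble::tibble(mutant_id = character(), contig = character(),
                            pos = integer(), ref = character(),
                            alt = character(), cls_true = character()))
    }
    cls <- sample(SPECTRUM_CLASSES, n, replace = TRUE,
                  prob = class_weights / sum(class_weights))
    # draw genome-wide offsets without replacement, oversampling to allow
    # rejection on base identity / context
    pos_tbl <- tibble::tibble(contig = character(n), pos = integer(n),
                              ref = character(n), alt = character(n))
    used <- character(0)
    for (i in seq_len(n)) {
      ca <- class_centre_alt(cls[i])
      centre <- ca[1]; alt_c <- ca[2]
      wanted <- c(centre, complement_bases(centre))
      repeat {
        off <- sample.int(total_len, 1L)
        ci <- findInterval(off - 1L, cumsum(c(0, glen$length)),
                           rightmost.closed = FALSE)
        ct <- glen$contig[ci]
        p <- off - c(0, cumsum(glen$length))[ci]
        key <- paste0(ct, ":", p)
        if (key %in% used) next
        base <- substr(genome_chr[[ct]], p, p)
        if (!base %in% wanted) next
        if (!is.null(context_weights)) {
          # rejection sampling on the collapsed 5' flank
          if (p <= 1L || p >= glen$length[ci]) next
          flank5 <- if (base == centre) {
            substr(genome_chr[[ct]], p - 1L, p - 1L)
          } else {
            complement_bases(substr(genome_chr[[ct]], p + 1L, p + 1L))
          }
          w <- context_weights[flank5]
          if (is.na(w)) w <- 0
          if (stats::runif(1) > w / max(context_weights)) next
        }
        used <- c(used, key)
        ref <- base
        alt <- if (base == centre) alt_c else complement_bases(alt_c)
        pos_tbl[i, ] <- list(ct, as.integer(p), ref, alt)
        break
      }
    }
    dplyr::mutate(pos_tbl, mutant_id = mid, cls_true = cls, .before = 1)
  }

  mutant_ids <- sprintf("mut%03d", seq_len(n_mutants))
  records <- purrr::map2_dfr(mutant_ids, snvs_per_mutant, draw_mutant)
  # drop accidental adjacencies so planted tandem counts are exact
  if (nrow(records) > 0) {
    records <- records %>%
      dplyr::group_by(.data$mutant_id, .data$contig) %>%
      dplyr::arrange(.data$pos, .by_group = TRUE) %>%
      dplyr::filter(is.na(dplyr::lag(.data$pos)) |
                      .data$pos - dplyr::lag(.data$pos) > 1L) %>%
      dplyr::ungroup()
  }

  truth_tandems <- tibble::tibble(mutant_id = character(), contig = character(),
                                  pos5 = integer(), ref_dinuc = character(),
                                  alt_dinuc = character(), class = character())
  if (!is.null(tandem_classes)) {
    truth_tandems <- plant_tandems(genome_chr, glen, records, mutant_ids,
                                   tandem_classes)
    tandem_records <- truth_tandems %>%
      dplyr::reframe(
        mutant_id = rep(.data$mutant_id, each = 2),
        contig = rep(.data$contig, each = 2),
        pos = as.integer(rbind(.data$pos5, .data$pos5 + 1L)),
        ref = as.character(rbind(substr(.data$ref_dinuc, 1, 1),
                                 substr(.data$ref_dinuc, 2, 2))),
        alt = as.character(rbind(substr(.data$alt_dinuc, 1, 1),
                                 substr(.data$alt_dinuc, 2, 2)))
      ) %>%
      dplyr::mutate(cls_true = NA_character_)
    records <- dplyr::bind_rows(records, tandem_records)
  }

  truth_dels <- tibble::tibble(mutant_id = character(), contig = character(),
                               start = integer(), end = integer(),
                               length = integer())
  mutant_genomes <- list()
  if (!is.null(deletions) && nrow(deletions) > 0) {
    deletions <- tibble::as_tibble(deletions)
    carrier <- mutant_ids[((seq_len(nrow(deletions)) - 1L) %% n_mutants) + 1L]
    truth_dels <- deletions %>%
      dplyr::mutate(mutant_id = carrier,
                    start = as.integer(.data$start),
                    end = as.integer(.data$start + .data$length - 1L),
                    length = as.integer(.data$length)) %>%
      dplyr::select("mutant_id", "contig", "start", "end", "length")
    stopifnot(all(truth_dels$contig %in% glen$contig),
              all(truth_dels$start >= 1),
              all(truth_dels$end <=
                    glen$length[match(truth_dels$contig, glen$contig)]))
    for (mid in unique(carrier)) {
      g <- genome_chr
      # apply the carrier's SNVs, then excise its deletions (right to left
      # so reference coordinates stay valid during excision)
      snvs <- dplyr::filter(records, .data$mutant_id == mid)
      for (j in seq_len(nrow(snvs))) {
        substr(g[[snvs$contig[j]]], snvs$pos[j], snvs$pos[j]) <- snvs$alt[j]
      }
      dels <- truth_dels %>%
        dplyr::filter(.data$mutant_id == mid) %>%
        dplyr::arrange(dplyr::desc(.data$start))
      for (j in seq_len(nrow(dels))) {
        seq_str <- g[[dels$contig[j]]]
        g[[dels$contig[j]]] <- paste0(
          substr(seq_str, 1, dels$start[j] - 1L),
          substr(seq_str, dels$end[j] + 1L, nchar(seq_str)))
      }
      gset <- Biostrings::DNAStringSet(unlist(g))
      names(gset) <- names(g)
      mutant_genomes[[mid]] <- gset
    }
  }

  records <- records %>%
    dplyr::arrange(.data$mutant_id, .data$contig, .data$pos)
  list(
    records = dplyr::select(records, "mutant_id", "contig", "pos",
                            "ref", "alt"),
    truth = list(
      spectrum = dplyr::select(records, "mutant_id", "contig", "pos",
                               "cls_true"),
      tandems = truth_tandems,
      deletions = truth_dels
    ),
    mutant_genomes = mutant_genomes
  )
}

# Plant tandem events of the four classes at positions away from existing
# SNVs and from each other.
plant_tandems <- function(genome_chr, glen, records, mutant_ids,
                          tandem_classes) {
  stopifnot(all(names(tandem_classes) %in% TANDEM_CLASSES))
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                           C = c("A", "G"), T = c("A", "G"))
  taken <- paste0(records$mutant_id, ":", records$contig, ":", records$pos)
  out <- list()
  n_total <- sum(tandem_classes)
  cls_seq <- rep(names(tandem_classes), times = tandem_classes)
  mid_seq <- sample(rep_len(mutant_ids, n_total))
  for (j in seq_len(n_total)) {
    cls <- cls_seq[j]; mid <- mid_seq[j]
    repeat {
      ci <- sample.int(nrow(glen), 1L, prob = glen$length)
      ct <- glen$contig[ci]
      p <- sample.int(glen$length[ci] - 1L, 1L)
      keys <- paste0(mid, ":", ct, ":", c(p - 1L, p, p + 1L, p + 2L))
      if (any(keys %in% taken)) next
      ref5 <- substr(genome_chr[[ct]], p, p)
      ref3 <- substr(genome_chr[[ct]], p + 1L, p + 1L)
      alt5 <- switch(cls,
        double_transition = transition_of[ref5],
        transition_5prime = transition_of[ref5],
        sample(transversions_of[[ref5]], 1L))
      alt3 <- switch(cls,
        double_transition = transition_of[ref3],
        transition_3prime = transition_of[ref3],
        sample(transversions_of[[ref3]], 1L))
      taken <- c(taken, keys[2:3])
      out[[length(out) + 1L]] <- tibble::tibble(
        mutant_id = mid, contig = ct, pos5 = as.integer(p),
        ref_dinuc = paste0(ref5, ref3),
        alt_dinuc = paste0(unname(alt5), unname(alt3)), class = cls)
      break
    }
  }
  dplyr::bind_rows(out)
}

#' Plant CDS-only gene models into a genome
#'
#' Writes non-overlapping single-exon genes (random strand, length a
#' multiple of 3) into a copy of the genome: ATG start, internal stop
#' codons scrubbed, stop codon at the end — the shape ab-initio fungal
#' gene predictors emit.
#'
#' @param genome `DNAStringSet`.
#' @param n_genes Number of genes to plant.
#' @param cds_length CDS length in bp (multiple of 3, incl. start & stop).
#' @param seed Integer seed.
#' @return A list: `genome` (modified `DNAStringSet`), `models` (tibble as
#'   from [read_gene_models()]).
#' @export
plant_gene_models <- function(genome, n_genes, cds_length = 300L, seed) {
  stopifnot(!missing(seed), cds_length %% 3 == 0, cds_length >= 9)
  set.seed(seed)
  if (n_genes == 0) {
    return(list(genome = genome,
                models = tibble::tibble(gene_id = character(),
                                        contig = character(),
                                        strand = character(),
                                        start = integer(), end = integer(),
                                        phase = integer())))
  }
  glen <- genome_lengths(genome)
  gap <- 250L # room for a promoter and intergenic space between genes
  slot <- cds_length + gap
  capacity <- sum(pmax(0, (glen$length - gap) %/% slot))
  if (n_genes > capacity) stop("genes do not fit without overlap", call. = FALSE)
  slots <- purrr::pmap_dfr(glen, function(contig, length) {
    n_here <- max(0, (length - gap) %/% slot)
    if (n_here == 0) return(tibble::tibble(contig = character(),
                                           start = integer()))
    tibble::tibble(contig = contig,
                   start = gap + (seq_len(n_here) - 1L) * slot + 1L)
  })
  pick <- slots[sample.int(nrow(slots), n_genes), ]
  genome_chr <- as.character(genome)
  no_stop_codons <- setdiff(
    apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  models <- list()
  for (i in seq_len(n_genes)) {
    ct <- pick$contig[i]
    s <- pick$start[i]
    e <- s + cds_length - 1L
    strand <- sample(c("+", "-"), 1L)
    n_codons <- cds_length / 3L - 2L
    body <- paste(sample(no_stop_codons, n_codons, replace = TRUE),
                  collapse = "")
    cds <- paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L))
    insert <- if (strand == "+") cds else revcomp(cds)
    seq_str <- genome_chr[[ct]]
    genome_chr[[ct]] <- paste0(substr(seq_str, 1, s - 1L), insert,
                               substr(seq_str, e + 1L, nchar(seq_str)))
    models[[i]] <- tibble::tibble(
      gene_id = sprintf("gene%04d", i), contig = ct, strand = strand,
      start = as.integer(s), end = as.integer(e), phase = 0L)
  }
  new_genome <- Biostrings::DNAStringSet(unlist(genome_chr))
  names(new_genome) <- names(genome_chr)
  list(genome = new_genome,
       models = dplyr::arrange(dplyr::bind_rows(models),
                               .data$contig, .data$start))
}

#' Simulate shotgun reads
#'
#' Single-end reads with uniform start positions on both strands and
#' i.i.d. per-base substitution errors.
#'
#' @param genome `DNAStringSet` (or a mutant genome copy).
#' @param coverage Target mean coverage (> 0).
#' @param read_len Read length in bp (at most the shortest contig).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return A character vector of read sequences (named `read000001`, ...).
#' @export
sim_reads <- function(genome, coverage = 30, read_len = 100L,
                      error_rate = 0, seed) {
  stopifnot(!missing(seed), coverage > 0)
  glen <- genome_lengths(genome)
  if (read_len > min(glen$length)) {
    stop("read_len exceeds the shortest contig", call. = FALSE)
  }
  set.seed(seed)
  total_len <- sum(glen$length)
  n_reads <- ceiling(coverage * total_len / read_len)
  ci <- sample.int(nrow(glen), n_reads, replace = TRUE,
                   prob = glen$length - read_len + 1L)
  starts <- vapply(ci, function(j) {
    sample.int(glen$length[j] - read_len + 1L, 1L)
  }, integer(1))
  genome_chr <- as.character(genome)
  reads <- substring(genome_chr[ci], starts, starts + read_len - 1L)
  flip <- stats::runif(n_reads) < 0.5
  reads[flip] <- revcomp(reads[flip])
  if (error_rate > 0) {
    reads <- vapply(reads, function(r) {
      hit <- which(stats::runif(read_len) < error_rate)
      for (h in hit) {
        substr(r, h, h) <- sample(setdiff(BASES, substr(r, h, h)), 1L)
      }
      r
    }, character(1), USE.NAMES = FALSE)
  }
  stats::setNames(reads, sprintf("read%06d", seq_len(n_reads)))
}

#' Write reads as FASTQ
#'
#' @param reads Named character vector from [sim_reads()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(L) strrep("I", L), character(1))
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write mutation records as a minimal VCF
#'
#' One VCF 4.2 file per call; records must belong to a single mutant.
#'
#' @param records Records tibble (single `mutant_id`).
#' @param path Output path.
#' @param genome Optional `DNAStringSet` to emit contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, genome = NULL) {
  assert_records(records)
  if (length(unique(records$mutant_id)) > 1) {
    stop("write_vcf expects records from a single mutant", call. = FALSE)
  }
  hdr <- c("##fileformat=VCFv4.2")
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome),
                          Biostrings::width(genome)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  records$contig, records$pos, records$ref, records$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/CDS rows compatible with [read_gene_models()].
#'
#' @param models Gene models tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (gid in unique(models$gene_id)) {
    segs <- models[models$gene_id == gid, ]
    s <- min(segs$start); e <- max(segs$end)
    ct <- segs$contig[1]; st <- segs$strand[1]
    lines <- c(lines,
      sprintf("%s\tuvmutspec\tgene\t%d\t%d\t.\t%s\t.\tID=%s", ct, s, e, st, gid),
      sprintf("%s\tuvmutspec\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              ct, s, e, st, gid, gid),
      sprintf("%s\tuvmutspec\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds.%s;Parent=%s.t1",
              segs$contig, segs$start, segs$end, segs$strand, segs$phase,
              gid, gid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate a full synthetic fixture bundle on disk
#'
#' Genome FASTA, GFF3 gene models, per-mutant VCFs, optional FASTQ reads,
#' and truth tables (TSV) for every planted feature — a self-contained
#' input set for the whole pipeline.
#'
#' @param dir Output directory (created if needed).
#' @param contig_lengths,gc Genome shape, see [sim_genome()].
#' @param n_genes Genes planted, see [plant_gene_models()].
#' @param n_mutants,snvs_per_mutant,class_weights,context_weights,tandem_classes,deletions
#'   Passed to [sim_mutants()].
#' @param reads_for Character vector of mutant ids for which FASTQ reads
#'   are written (requires those mutants to carry deletions or none).
#' @param coverage,read_len,error_rate Read simulation parameters.
#' @param seed Integer master seed; all randomness derives from it.
#' @return Invisibly, a list with the in-memory `genome`, `models`,
#'   `records`, `truth`, and the output `dir`.
#' @export
sim_bundle <- function(dir, contig_lengths = c(tig1 = 50000L), gc = 0.48,
                       n_genes = 20L, n_mutants = 10L, snvs_per_mutant = 37L,
                       class_weights = UV_CLASS_WEIGHTS,
                       context_weights = NULL, tandem_classes = NULL,
                       deletions = NULL, reads_for = character(),
                       coverage = 30, read_len = 100L, error_rate = 0,
                       seed) {
  stopifnot(!missing(seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- sim_genome(contig_lengths, gc, seed = seed)
  planted <- plant_gene_models(base, n_genes, seed = seed + 1L)
  genome <- planted$genome
  sim <- sim_mutants(genome, n_mutants = n_mutants,
                     snvs_per_mutant = snvs_per_mutant,
                     class_weights = class_weights,
                     context_weights = context_weights,
                     tandem_classes = tandem_classes,
                     deletions = deletions, seed = seed + 2L)
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
  write_gene_models_gff3(planted$models, file.path(dir, "models.gff3"))
  vcf_dir <- file.path(dir, "mutants")
  dir.create(vcf_dir, showWarnings = FALSE)
  for (mid in unique(sim$records$mutant_id)) {
    write_vcf(dplyr::filter(sim$records, .data$mutant_id == mid),
              file.path(vcf_dir, paste0(mid, ".vcf")), genome)
  }
  truth_dir <- file.path(dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  for (nm in names(sim$truth)) {
    utils::write.table(sim$truth[[nm]],
                       file.path(truth_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(reads_for) > 0) {
    read_dir <- file.path(dir, "reads")
    dir.create(read_dir, showWarnings = FALSE)
    for (i in seq_along(reads_for)) {
      mid <- reads_for[i]
      g <- if (!is.null(sim$mutant_genomes[[mid]])) {
        sim$mutant_genomes[[mid]]
      } else genome
      reads <- sim_reads(g, coverage, read_len, error_rate,
                         seed = seed + 10L + i)
      write_fastq(reads, file.path(read_dir, paste0(mid, ".fastq")))
    }
  }
  invisible(list(genome = genome, models = planted$models,
                 records = sim$records, truth = sim$truth,
                 mutant_genomes = sim$mutant_genomes, dir = dir))
}
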