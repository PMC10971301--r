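#' Read a reference genome from FASTA
#'
#' Loads a (multi-contig) genome into a [Biostrings::DNAStringSet], uppercased.
#' Sequences may contain only A/C/G/T/N.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`; contig lengths are available through
#'   [genome_lengths()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path, call. = FALSE)
  genome <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed FASTA '", path, "': ",
                               conditionMessage(w), call. = FALSE)
  )
  if (length(genome) == 0) stop("no sequences in FASTA: ", path, call. = FALSE)
  # drop description after first whitespace, keep the contig id
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    stop("duplicate contig ids in ", path, call. = FALSE)
  }
  genome <- Biostrings::DNAStringSet(toupper(as.character(genome)))
  af <- Biostrings::alphabetFrequency(genome, baseOnly = TRUE)
  n_count <- Biostrings::letterFrequency(genome, "N")
  if (any(af[, "other"] != as.vector(n_count))) {
    stop("genome contains letters outside A/C/G/T/N", call. = FALSE)
  }
  genome
}

#' Contig lengths of a genome
#'
#' @param genome A `DNAStringSet` as returned by [read_genome()].
#' @return A tibble with columns `contig` and `length` (bp).
#' @export
genome_lengths <- function(genome) {
  tibble::tibble(contig = names(genome),
                 length = Biostrings::width(genome))
}

#' Read single-nucleotide variants from a VCF file
#'
#' Parses a (single-sample) VCF and keeps only biallelic single-nucleotide
#' records; indels and multi-nucleotide alleles are skipped and their count
#' attached as attribute `n_skipped` (and reported via a message).
#' Positions stay 1-based as in the VCF.
#'
#' @param path Path to a VCF file (plain text).
#' @param mutant_id Identifier assigned to every record from this file.
#' @return A tibble with columns `mutant_id`, `contig`, `pos`, `ref`, `alt`,
#'   with attribute `n_skipped`.
#' @export
read_snvs <- function(path, mutant_id) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- tibble::tibble(mutant_id = character(), contig = character(),
                          pos = integer(), ref = character(), alt = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% BASES & alt %in% BASES
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message("read_snvs: skipped ", n_skipped,
            " non-biallelic-SNV record(s) in ", basename(path))
  }
  out <- tibble::tibble(
    mutant_id = mutant_id,
    contig = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = ref[keep],
    alt = alt[keep]
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read SNVs for a panel of mutants from a directory of VCFs
#'
#' @param dir Directory containing one `.vcf` per mutant; the file stem is
#'   used as the mutant id.
#' @return A tibble of combined [read_snvs()] output.
#' @export
read_snv_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.vcf$", full.names = TRUE)
  if (length(files) == 0) stop("no .vcf files under ", dir, call. = FALSE)
  purrr::map2_dfr(files, sub("\\.vcf$", "", basename(files)), read_snvs)
}

#' Validate mutation records against a genome
#'
#' Checks contigs exist, positions are in range, and the VCF reference base
#' matches the genome. A reference mismatch is an error by default,
#' downgradeable to warn-and-drop.
#'
#' @param records Tibble of mutation records.
#' @param genome `DNAStringSet` reference.
#' @param on_ref_mismatch `"error"` (default) or `"warn"` (drop offending rows).
#' @return The validated (possibly filtered) records tibble.
#' @export
validate_records <- function(records, genome,
                             on_ref_mismatch = c("error", "warn")) {
  on_ref_mismatch <- match.arg(on_ref_mismatch)
  assert_records(records)
  if (nrow(records) == 0) return(records)
  unknown <- setdiff(unique(records$contig), names(genome))
  if (length(unknown) > 0) {
    stop("record(s) on contig(s) absent from genome: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  len <- Biostrings::width(genome)[match(records$contig, names(genome))]
  if (any(records$pos < 1L | records$pos > len)) {
    stop("record position(s) outside contig bounds", call. = FALSE)
  }
  assert_bases(records$ref, "ref"); assert_bases(records$alt, "alt")
  if (any(records$ref == records$alt)) {
    stop("ref equals alt in some record(s)", call. = FALSE)
  }
  genome_base <- genome_base_at(genome, records$contig, records$pos)
  bad <- genome_base != records$ref
  if (any(bad)) {
    msg <- sprintf("%d record(s) whose ref base disagrees with the genome",
                   sum(bad))
    if (on_ref_mismatch == "error") stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    records <- records[!bad, , drop = FALSE]
  }
  records
}

# Base(s) of the genome at 1-based positions (vectorised over parallel
# contig/pos vectors).
genome_base_at <- function(genome, contig, pos) {
  out <- character(length(pos))
  for (ct in unique(contig)) {
    idx <- contig == ct
    seq_str <- as.character(genome[[ct]])
    out[idx] <- substring(seq_str, pos[idx], pos[idx])
  }
  out
}

#' Hard-filter thresholds for variant annotations
#'
#' Constructs the cutoff set used by [apply_hard_filters()]. A site fails
#' when any configured condition is met: `QD < qd_min`, `MQ < mq_min`,
#' `FS > fs_max`, `SOR > sor_max`, `MQRankSum <= mqranksum_bound`,
#' `ReadPosRankSum <= readposranksum_bound`.
#'
#' The default rank-sum bounds are the positive values +12.5/+8.0; GATK's
#' conventional bounds are negative, available via
#' [gatk_hard_filter_thresholds()].
#'
#' @param qd_min,mq_min,fs_max,sor_max,mqranksum_bound,readposranksum_bound
#'   Finite numeric cutoffs.
#' @return A named list of class `uv_filter_thresholds`.
#' @export
hard_filter_thresholds <- function(qd_min = 2.0, mq_min = 40.0, fs_max = 60.0,
                                   sor_max = 3.0, mqranksum_bound = 12.5,
                                   readposranksum_bound = 8.0) {
  t <- list(qd_min = qd_min, mq_min = mq_min, fs_max = fs_max,
            sor_max = sor_max, mqranksum_bound = mqranksum_bound,
            readposranksum_bound = readposranksum_bound)
  if (!all(vapply(t, function(x) is.numeric(x) && is.finite(x), logical(1)))) {
    stop("all thresholds must be finite numerics", call. = FALSE)
  }
  structure(t, class = "uv_filter_thresholds")
}

#' @rdname hard_filter_thresholds
#' @export
gatk_hard_filter_thresholds <- function() {
  hard_filter_thresholds(mqranksum_bound = -12.5, readposranksum_bound = -8.0)
}

#' Apply hard filters to variant annotations
#'
#' Evaluates GATK-style site annotations against a threshold set. A missing
#' annotation leaves its condition unevaluated; a site fails iff at least one
#' evaluated condition is met, and every triggered condition is reported.
#'
#' @param annotations A data frame (one row per site) or a single named list /
#'   vector with any of the metrics `QD`, `MQ`, `FS`, `SOR`, `MQRankSum`,
#'   `ReadPosRankSum`.
#' @param thresholds A [hard_filter_thresholds()] object.
#' @return A tibble with columns `pass` (logical) and `reasons`
#'   (comma-separated triggered conditions, `""` when passing).
#' @export
apply_hard_filters <- function(annotations,
                               thresholds = hard_filter_thresholds()) {
  stopifnot(inherits(thresholds, "uv_filter_thresholds"))
  if (!is.data.frame(annotations)) {
    annotations <- tibble::as_tibble(as.list(annotations))
  }
  metrics <- c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")
  for (m in intersect(metrics, names(annotations))) {
    if (!is.numeric(annotations[[m]])) {
      stop("non-numeric annotation value for metric ", m, call. = FALSE)
    }
  }
  n <- nrow(annotations)
  get <- function(m) if (m %in% names(annotations)) annotations[[m]] else rep(NA_real_, n)
  cond <- list(
    `QD<2.0` = get("QD") < thresholds$qd_min,
    `MQ<40.0` = get("MQ") < thresholds$mq_min,
    `FS>60.0` = get("FS") > thresholds$fs_max,
    `SOR>3.0` = get("SOR") > thresholds$sor_max,
    `MQRankSum<=bound` = get("MQRankSum") <= thresholds$mqranksum_bound,
    `ReadPosRankSum<=bound` = get("ReadPosRankSum") <= thresholds$readposranksum_bound
  )
  names(cond) <- c(
    sprintf("QD<%g", thresholds$qd_min), sprintf("MQ<%g", thresholds$mq_min),
    sprintf("FS>%g", thresholds$fs_max), sprintf("SOR>%g", thresholds$sor_max),
    sprintf("MQRankSum<=%g", thresholds$mqranksum_bound),
    sprintf("ReadPosRankSum<=%g", thresholds$readposranksum_bound)
  )
  trig <- vapply(cond, function(x) ifelse(is.na(x), FALSE, x), logical(n))
  if (n == 1L) trig <- matrix(trig, nrow = 1, dimnames = list(NULL, names(cond)))
  reasons <- apply(trig, 1, function(r) paste(names(cond)[r], collapse = ","))
  tibble::tibble(pass = rowSums(trig) == 0, reasons = reasons)
}

#' Read gene models from GFF3
#'
#' Imports CDS features (GeneMark-ES-style CDS-only models are expected) and
#' returns one row per CDS segment with its parent gene, strand and phase.
#' The start codon sits at the first CDS base in transcription order.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `contig`, `strand`, `start`,
#'   `end`, `phase` (1-based closed intervals), sorted by contig then start.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 not found: ", path, call. = FALSE)
  gff <- rtracklayer::import(path, format = "gff3")
  cds <- gff[gff$type == "CDS"]
  if (length(cds) == 0) {
    return(tibble::tibble(gene_id = character(), contig = character(),
                          strand = character(), start = integer(),
                          end = integer(), phase = integer()))
  }
  parent <- as.character(S4Vectors::mcols(cds)$Parent)
  if (length(parent) == 0 || all(is.na(parent) | parent == "")) {
    parent <- as.character(S4Vectors::mcols(cds)$ID)
  }
  if (any(is.na(parent) | parent == "")) {
    stop("CDS feature(s) without parent gene in ", path, call. = FALSE)
  }
  # strip mRNA-level suffixes like ".t1" so segments group per gene
  gene_id <- sub("\\.t\\d+$", "", parent)
  strand <- as.character(BiocGenerics::strand(cds))
  if (any(!strand %in% c("+", "-"))) {
    stop("unknown strand symbol in gene models", call. = FALSE)
  }
  phase <- S4Vectors::mcols(cds)$phase
  phase <- if (is.null(phase)) rep(0L, length(cds)) else as.integer(phase)
  phase[is.na(phase)] <- 0L
  tibble::tibble(
    gene_id = gene_id,
    contig = as.character(GenomicRanges::seqnames(cds)),
    strand = strand,
    start = BiocGenerics::start(cds),
    end = BiocGenerics::end(cds),
    phase = phase
  ) %>%
    dplyr::arrange(.data$contig, .data$start)
}

#' Start-codon positions of gene models
#'
#' First CDS base in transcription order: the smallest CDS start on `+`
#' strand genes, the largest CDS end on `-` strand genes.
#'
#' @param models Tibble from [read_gene_models()].
#' @return One row per gene: `gene_id`, `contig`, `strand`, `start_codon`,
#'   `cds_length`.
#' @export
gene_start_codons <- function(models) {
  models %>%
    dplyr::group_by(.data$gene_id, .data$contig, .data$strand) %>%
    dplyr::summarise(
      start_codon = if (.data$strand[1] == "+") min(.data$start) else max(.data$end),
      cds_length = sum(.data$end - .data$start + 1L),
      .groups = "drop"
    )
}

#' Write mutation records to TSV
#'
#' Tab-delimited, header line, `#` comment header stating the coordinate
#' convention (1-based, fully closed).
#'
#' @param records Records tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records_tsv <- function(records, path) {
  assert_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based, fully closed", con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read mutation records from TSV
#'
#' @param path Path written by [write_records_tsv()].
#' @return A records tibble.
#' @export
read_records_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = c("character", "character", "integer",
                                         "character", "character"))
  tibble::as_tibble(df)
}
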