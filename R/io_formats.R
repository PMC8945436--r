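#' Read a FASTA file
#'
#' Records are returned in file order with sequences uppercased; `U`/`T` are
#' preserved as read (RNA/DNA conversion is left to callers). Duplicate ids
#' and empty sequences are errors.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for FASTA id: ", ids[nchar(seqs) == 0L][1])
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' @param records data.frame with columns `id`, `sequence`, or a named
#'   character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a MAF (Multiple Alignment Format) file
#'
#' Parses `a`/`s` blocks into alignment blocks. Every row of a block must
#' have the same gapped width, the declared ungapped size must match the row
#' text, and the reference species must be present in every block.
#'
#' @param path path to a MAF file.
#' @param ref_species reference species name (the part of the `s` source
#'   field before the first `.`).
#' @return list of alignment blocks; each block is a list with fields
#'   `species`, `chrom`, `start` (0-based), `size`, `strand`, `src_size`,
#'   `text` (gapped rows), `width`, `ref_species`.
#' @export
read_maf <- function(path, ref_species = "hg") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  starts <- grep("^a", lines)
  if (length(starts) == 0L) stop("no alignment blocks in MAF file: ", path)
  bounds <- c(starts, length(lines) + 1L)
  blocks <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    chunk <- lines[seq(bounds[b], bounds[b + 1L] - 1L)]
    srows <- chunk[grepl("^s\\s", chunk)]
    if (length(srows) == 0L) stop("MAF block ", b, " has no sequence rows")
    fields <- strsplit(trimws(srows), "\\s+")
    ok <- vapply(fields, length, 0L) == 7L
    if (!all(ok)) stop("malformed s-line in MAF block ", b)
    src <- vapply(fields, `[[`, "", 2L)
    species <- sub("\\..*$", "", src)
    chrom <- ifelse(grepl("\\.", src), sub("^[^.]*\\.", "", src), NA_character_)
    start <- as.integer(vapply(fields, `[[`, "", 3L))
    size <- as.integer(vapply(fields, `[[`, "", 4L))
    strand <- vapply(fields, `[[`, "", 5L)
    src_size <- as.integer(vapply(fields, `[[`, "", 6L))
    text <- toupper(vapply(fields, `[[`, "", 7L))
    widths <- nchar(text)
    if (length(unique(widths)) != 1L) {
      stop("ragged MAF block ", b, ": row widths ", paste(widths, collapse = ","))
    }
    ungapped <- nchar(gsub("-", "", text, fixed = TRUE))
    if (any(ungapped != size)) {
      stop("MAF block ", b, ": declared size disagrees with row text for ",
           species[ungapped != size][1])
    }
    if (!ref_species %in% species) {
      stop("MAF block ", b, " is missing reference species '", ref_species, "'")
    }
    if (!all(strand %in% c("+", "-"))) stop("MAF block ", b, ": bad strand symbol")
    blocks[[b]] <- list(species = species, chrom = chrom, start = start,
                        size = size, strand = strand, src_size = src_size,
                        text = text, width = widths[1], ref_species = ref_species)
  }
  blocks
}

#' Write alignment blocks as MAF
#'
#' @param blocks list of alignment blocks as produced by [read_maf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (bl in blocks) {
    writeLines("a score=0.0", con)
    src <- ifelse(is.na(bl$chrom), bl$species, paste0(bl$species, ".", bl$chrom))
    writeLines(sprintf("s %s %d %d %s %d %s",
                       src, bl$start, bl$size, bl$strand, bl$src_size, bl$text), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read biallelic SNVs from a VCF
#'
#' Keeps biallelic single-nucleotide records only; indels and multiallelic
#' records are skipped (their count is attached as attribute `n_skipped`).
#' The allele frequency from `maf_field` is folded onto the minor allele
#' (f > 0.5 becomes 1 - f). Positions are converted to 0-based immediately.
#'
#' @param path path to an uncompressed VCF.
#' @param maf_field name of the INFO field holding the alternate allele
#'   frequency (default `"AF"`).
#' @return data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `maf`; attribute `n_skipped` counts excluded records.
#' @export
read_vcf_snvs <- function(path, maf_field = "AF") {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), maf = numeric())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, maf_field)))
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snv)
  if (n_skipped > 0L) {
    message("read_vcf_snvs: skipped ", n_skipped, " non-SNV/multiallelic records")
  }
  maf <- fold_maf(af[snv])
  out <- data.frame(chrom = fix$CHROM[snv],
                    pos = as.integer(fix$POS[snv]) - 1L,
                    ref = fix$REF[snv], alt = fix$ALT[snv],
                    maf = maf, stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Fold allele frequencies onto the minor allele
#'
#' Idempotent: folding twice equals folding once.
#'
#' @param f numeric vector of allele frequencies in `[0, 1]`.
#' @return minor allele frequencies in `[0, 0.5]`.
#' @export
fold_maf <- function(f) ifelse(!is.na(f) & f > 0.5, 1 - f, f)

#' Write a minimal SNV VCF
#'
#' @param variants data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `maf`.
#' @param path output path.
#' @param maf_field INFO field name to write the allele frequency under.
#' @return `path`, invisibly.
#' @export
write_vcf_snvs <- function(variants, path, maf_field = "AF") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"Allele frequency\">",
                       maf_field),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0L) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s=%.10g",
                       variants$chrom, variants$pos + 1L, variants$ref,
                       variants$alt, maf_field, variants$maf), con)
  }
  invisible(path)
}

#' Read UTR / miRNA-locus regions from BED6
#'
#' Intervals are 0-based half-open. The name field may be
#' `"gene_id|transcript_id"`; when several isoforms share one gene id, only
#' the isoform with the longest interval is kept. Zero-length intervals and
#' unknown strand symbols are errors.
#'
#' @param path path to a BED6 file.
#' @param collapse_isoforms keep only the longest isoform per gene
#'   (default TRUE).
#' @return data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start` (0-based), `end`, `strand`.
#' @export
read_regions <- function(path, collapse_isoforms = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  start0 <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(end <= start0)) {
    stop("empty or inverted interval in BED record ", which(end <= start0)[1])
  }
  if (any(!strand %in% c("+", "-"))) {
    stop("unknown strand symbol in BED record ", which(!strand %in% c("+", "-"))[1])
  }
  name <- if (!is.null(gr$name)) gr$name else paste0("region", seq_along(gr))
  gene_id <- sub("\\|.*$", "", name)
  transcript_id <- ifelse(grepl("|", name, fixed = TRUE),
                          sub("^[^|]*\\|", "", name), name)
  out <- data.frame(gene_id = gene_id, transcript_id = transcript_id,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = start0, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  if (collapse_isoforms && anyDuplicated(out$gene_id)) {
    len <- out$end - out$start
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$gene_id),
                          function(i) i[which.max(len[i])]))
    out <- out[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write regions as BED6
#'
#' @param regions data.frame with columns `gene_id`, `transcript_id`
#'   (optional), `chrom`, `start` (0-based), `end`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  name <- if (!is.null(regions$transcript_id) &&
              !all(regions$transcript_id == regions$gene_id)) {
    paste0(regions$gene_id, "|", regions$transcript_id)
  } else {
    regions$gene_id
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", regions$chrom, regions$start,
                   regions$end, name, regions$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Assemble UTR records from a FASTA and a BED6 file
#'
#' Joins sequences to coordinates by gene id and validates that sequence
#' length equals the interval span and that the alphabet is A/C/G/T/N.
#'
#' @param fasta_path UTR sequences (FASTA, ids = gene ids).
#' @param bed_path UTR coordinates (BED6).
#' @return data.frame with columns `gene_id`, `transcript_id`, `sequence`,
#'   `chrom`, `start`, `end`, `strand`.
#' @export
read_utrs <- function(fasta_path, bed_path) {
  seqs <- read_fasta(fasta_path)
  regions <- read_regions(bed_path)
  idx <- match(regions$gene_id, seqs$id)
  if (anyNA(idx)) {
    stop("no sequence for gene ", regions$gene_id[is.na(idx)][1])
  }
  out <- cbind(regions[, c("gene_id", "transcript_id")],
               sequence = seqs$sequence[idx],
               regions[, c("chrom", "start", "end", "strand")])
  if (any(grepl("[^ACGTN]", out$sequence))) {
    stop("UTR sequence with non-ACGTN characters: ",
         out$gene_id[grepl("[^ACGTN]", out$sequence)][1])
  }
  if (any(nchar(out$sequence) != out$end - out$start)) {
    stop("sequence length disagrees with coordinates for gene ",
         out$gene_id[nchar(out$sequence) != out$end - out$start][1])
  }
  rownames(out) <- NULL
  out
}

#' Write a data frame as a TSV result table
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV result table
#'
#' @param path path to a TSV written by [write_tsv_table()].
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
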