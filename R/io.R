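#' Read genotypes from VCF or a dosage TSV
#'
#' VCF v4.2 GT fields are mapped to alternate-allele dosages 0/1/2; missing
#' calls (`./.`) become `NA` and lower the variant's call rate. Multi-allelic
#' records are rejected. The dosage TSV format is variants x samples with
#' columns `variant_id`, `chromosome`, `position`, `ref`, `alt` followed by
#' one column per sample.
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage-tsv"`.
#' @return A [GenotypeData-class] object.
#' @export
readGenotypes <- function(path, format = c("vcf", "dosage-tsv")) {
  format <- match.arg(format)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    if (any(grepl(",", fix$ALT, fixed = TRUE)))
      stop("multi-allelic VCF records are not supported; found ALT with ",
           "a comma at ", sum(grepl(",", fix$ALT, fixed = TRUE)), " site(s)")
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (anyDuplicated(colnames(gt)))
      stop("duplicate sample ids in VCF header")
    gt_clean <- gsub("\\|", "/", gt)
    dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    dos[gt_clean == "0/0"] <- 0
    dos[gt_clean %in% c("0/1", "1/0")] <- 1
    dos[gt_clean == "1/1"] <- 2
    ids <- fix$ID
    ids[is.na(ids) | ids == "."] <-
      paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
    variants <- data.frame(variant_id = ids, chromosome = fix$CHROM,
                           position = as.integer(fix$POS),
                           ref = fix$REF, alt = fix$ALT,
                           stringsAsFactors = FALSE)
    dosage <- t(dos)
    colnames(dosage) <- variants$variant_id
    return(GenotypeData(dosage, variants))
  }
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  meta <- c("variant_id", "chromosome", "position", "ref", "alt")
  if (!all(meta %in% names(tab)))
    stop("dosage TSV must start with columns: ", paste(meta, collapse = ", "))
  samples <- setdiff(names(tab), meta)
  if (anyDuplicated(samples)) stop("duplicate sample ids in dosage TSV")
  dosage <- t(as.matrix(tab[, samples, drop = FALSE]))
  colnames(dosage) <- tab$variant_id
  GenotypeData(dosage, tab[, meta])
}

#' Write genotypes
#'
#' `writeGenotypesVcf` emits a minimal VCF v4.2 with GT-only genotype
#' fields; `writeDosageTsv` emits the tabular dosage format read back by
#' [readGenotypes()].
#'
#' @param geno A [GenotypeData-class] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(geno, path) {
  v <- variantInfo(geno)
  dos <- dosageMatrix(geno)
  gt <- matrix("./.", ncol(dos), nrow(dos))
  gt[t(dos) == 0] <- "0/0"
  gt[t(dos) == 1] <- "0/1"
  gt[t(dos) == 2] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", rownames(dos)),
                    collapse = "\t"))
  body <- paste(v$chromosome, v$position, v$variant_id, v$ref, v$alt,
                ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname writeGenotypesVcf
#' @export
writeDosageTsv <- function(geno, path) {
  v <- variantInfo(geno)
  tab <- cbind(v[, c("variant_id", "chromosome", "position", "ref", "alt")],
               as.data.frame(t(dosageMatrix(geno))))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write BED3 region sets
#'
#' BED's 0-based half-open intervals are converted to the package-internal
#' 1-based inclusive convention on read (start+1, end) and back on write.
#' Intervals are kept as-is (no merging).
#'
#' @param path BED file.
#' @return `readRegionsBed`: a [GenomicRanges::GRanges].
#' @export
readRegionsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::width(gr) < 1))
    stop("BED interval with end <= start at line(s) ",
         paste(which(GenomicRanges::width(gr) < 1), collapse = ", "))
  GenomicRanges::granges(gr)
}

#' @rdname readRegionsBed
#' @param regions a `GRanges`.
#' @export
writeRegionsBed <- function(regions, path) {
  lines <- paste(as.character(GenomicRanges::seqnames(regions)),
                 GenomicRanges::start(regions) - 1L,
                 GenomicRanges::end(regions), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write gene tables (GFF3)
#'
#' Gene features only; coordinates are 1-based inclusive on both sides of
#' the conversion (GFF3 is already 1-based).
#'
#' @param path GFF3 file.
#' @return `readGenesGff3`: data.frame with gene_id, chromosome, start, end,
#'   strand.
#' @export
readGenesGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(gene_id = gr$ID,
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname readGenesGff3
#' @param genes gene table (gene_id, chromosome, start, end, strand).
#' @export
writeGenesGff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chromosome, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Accepts the JASPAR text layout: an optional `>` header line followed by
#' four rows, one per base in A, C, G, T order, each either
#' `A [ 10 0 5 ]` or a bare whitespace-separated count vector. Counts are
#' preserved as read; column sums may differ across positions
#' (normalisation happens in [pfmToPssm()]).
#'
#' @param path PFM text file.
#' @return 4 x L counts matrix with rownames A, C, G, T.
#' @export
readPfmJaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^>", lines) & nzchar(trimws(lines))]
  if (length(lines) < 4) stop("PFM parse error: expected 4 base rows")
  lines <- lines[1:4]
  parseRow <- function(x) {
    x <- gsub("^[ACGTacgt]\\s*", "", trimws(x))
    x <- gsub("[][]", " ", x)
    as.numeric(strsplit(trimws(x), "\\s+")[[1]])
  }
  rows <- lapply(lines, parseRow)
  lens <- vapply(rows, length, 1L)
  if (length(unique(lens)) != 1)
    stop("PFM parse error: ragged rows (lengths ",
         paste(lens, collapse = ", "), ")")
  counts <- do.call(rbind, rows)
  if (any(is.na(counts))) stop("PFM parse error: non-numeric count")
  if (any(counts < 0)) stop("PFM counts must be non-negative")
  rownames(counts) <- c("A", "C", "G", "T")
  counts
}

#' Write a counts matrix in JASPAR text format
#' @param counts 4 x L counts matrix.
#' @param path output file.
#' @param name motif name for the header line.
#' @export
writePfmJaspar <- function(counts, path, name = "motif") {
  rows <- vapply(1:4, function(i)
    paste0(c("A", "C", "G", "T")[i], " [ ",
           paste(counts[i, ], collapse = " "), " ]"), "")
  writeLines(c(paste0(">", name), rows), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT (set name, description, member genes per line). Duplicate
#' set names are rejected.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  nm <- vapply(strsplit(readLines(path), "\t"), `[`, "", 1)
  if (anyDuplicated(nm))
    stop("duplicate gene-set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  fgsea::gmtPathways(path)
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, "synthetic", sets[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an expression matrix TSV (genes x samples)
#'
#' Requires a header row whose first field is `gene_id`; duplicate gene ids
#' are rejected.
#'
#' @param path TSV file.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionTsv <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (!identical(first[1], "gene_id"))
    stop("expression TSV must have a header row starting with 'gene_id'")
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene ids in expression TSV")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  m
}

#' @rdname readExpressionTsv
#' @param expression genes x samples matrix.
#' @export
writeExpressionTsv <- function(expression, path) {
  tab <- data.frame(gene_id = rownames(expression), expression,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a generic sample table TSV (covariates, phenotypes)
#'
#' Header required; first column must be `sample_id`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readSampleTsv <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (!identical(first[1], "sample_id"))
    stop("sample table must have a header row starting with 'sample_id'")
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' @rdname readSampleTsv
#' @param tab data.frame with a `sample_id` column.
#' @export
writeSampleTsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
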