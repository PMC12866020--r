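#' Read a feature-by-sample matrix from TSV
#'
#' Expects a header row of sample ids and a first column of unique feature
#' ids; missing values are encoded as `NA`. Round-trips with
#' [write_matrix_tsv()].
#'
#' @param path File path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature ids in ", path, ": ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample matrix to TSV
#'
#' @param m Matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @param feature_col Name of the id column (default `"id"`).
#' @export
write_matrix_tsv <- function(m, path, feature_col = "id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write genotype dosages as a minimal VCF 4.2
#'
#' Emits a GT-only VCF: dosage 0 becomes `0/0`, 1 becomes `0/1`, 2 becomes
#' `1/1`, missing becomes `./.`. REF/ALT are placeholder alleles (A/B is not
#' representable in VCF, so A and G are used).
#'
#' @param genotypes SNP x sample dosage matrix.
#' @param annotation data.frame with `id`, `chrom`, `pos` (1-based), rows
#'   matching `genotypes`.
#' @param path Output path.
#' @export
write_vcf <- function(genotypes, annotation, path) {
  stopifnot(nrow(genotypes) == nrow(annotation))
  gt <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1], nrow(genotypes))
  gt[is.na(genotypes)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(genotypes)),
                     collapse = "\t")), con)
  body <- cbind(annotation$chrom, annotation$pos, annotation$id, "A", "G",
                ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read additive dosages from a GT-only VCF
#'
#' Parses the GT field of a VCF into a SNP x sample dosage matrix (count of
#' ALT alleles; `./.` becomes NA). Uses the vcfR reader when available and a
#' plain-text fallback otherwise.
#'
#' @param path VCF path.
#' @return List: `genotypes` (dosage matrix), `annotation` (id/chrom/pos).
#' @export
read_vcf_dosages <- function(path) {
  gt_to_dosage <- function(gtchar) {
    d <- rep(NA_integer_, length(gtchar))
    d[gtchar %in% c("0/0", "0|0")] <- 0L
    d[gtchar %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    d[gtchar %in% c("1/1", "1|1")] <- 2L
    d
  }
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- matrix(gt_to_dosage(gt), nrow(gt), dimnames = dimnames(gt))
    ann <- data.frame(id = vcfR::getID(v), chrom = vcfR::getCHROM(v),
                      pos = vcfR::getPOS(v), stringsAsFactors = FALSE)
    return(list(genotypes = dos, annotation = ann))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  fields <- strsplit(lines[-1], "\t")
  samples <- header[-(1:9)]
  dos <- t(vapply(fields, function(f) gt_to_dosage(f[-(1:9)]),
                  integer(length(samples))))
  dimnames(dos) <- list(vapply(fields, `[[`, character(1), 3), samples)
  ann <- data.frame(id = rownames(dos),
                    chrom = vapply(fields, `[[`, character(1), 1),
                    pos = as.integer(vapply(fields, `[[`, character(1), 2)),
                    stringsAsFactors = FALSE)
  list(genotypes = dos, annotation = ann)
}

#' Write feature coordinates as BED
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open intervals at the boundary.
#'
#' @param annotation data.frame with `id`, `chrom` and either `pos` (point
#'   features) or `start`/`end` (1-based inclusive).
#' @param path Output path.
#' @export
write_bed <- function(annotation, path) {
  if ("pos" %in% names(annotation)) {
    start0 <- annotation$pos - 1L
    end0 <- annotation$pos
  } else {
    start0 <- annotation$start - 1L
    end0 <- annotation$end
  }
  df <- data.frame(annotation$chrom, start0, end0, annotation$id)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 1-based coordinates
#'
#' @param path BED path (chrom, start, end, id; 0-based half-open).
#' @return data.frame with `id`, `chrom`, `start`, `end` (1-based inclusive)
#'   and `pos` (= start) for point features.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start0", "end0", "id")
  out <- data.frame(id = df$id, chrom = df$chrom, start = df$start0 + 1L,
                    end = df$end0, stringsAsFactors = FALSE)
  out$pos <- out$start
  out
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort as plain-text interchange files: methylation and
#' expression matrices as TSV, genotypes as both additive-dosage TSV and
#' GT-only VCF 4.2, covariates and phenotypes as one TSV, coordinates as BED,
#' and the ground-truth block as JSON.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cohort$methylation, file.path(dir, "methylation.tsv"),
                   feature_col = "cpg_id")
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"),
                   feature_col = "gene_id")
  write_matrix_tsv(cohort$genotypes, file.path(dir, "dosages.tsv"),
                   feature_col = "snp_id")
  write_vcf(cohort$genotypes, cohort$annotation$snp,
            file.path(dir, "genotypes.vcf"))
  samples <- merge(cohort$covariates, cohort$phenotypes, by = "sample_id")
  write.table(samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  write_bed(cohort$annotation$cpg, file.path(dir, "cpgs.bed"))
  write_bed(cohort$annotation$snp, file.path(dir, "snps.bed"))
  write_bed(cohort$annotation$gene, file.path(dir, "genes.bed"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
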