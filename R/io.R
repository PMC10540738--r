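#' Read genotypes from VCF, matrix CSV, or HapMap-like TSV
#'
#' Codes are the count of alternate alleles per call. Only biallelic SNPs are
#' supported: in a VCF, multi-allelic records and half-calls are dropped (or
#' rejected when `strict = TRUE`). The matrix CSV dialect is an
#' accession x marker table (first column `accession`) with a PLINK-style
#' sidecar map `<path>.map` (columns marker_id, chrom, pos, ref, alt). The
#' HapMap dialect follows the classic 11-column header with per-accession
#' genotype columns holding allele pairs such as `AA`, `AG`, `NN`.
#'
#' @param path input file path
#' @param format one of "vcf", "matrix_csv", "hapmap_tsv"
#' @param strict reject (error) rather than drop non-biallelic/half-call VCF
#'   records
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix_csv", "hapmap_tsv"),
                           strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    vcf = read_genotypes_vcf(path, strict),
    matrix_csv = read_genotypes_csv(path),
    hapmap_tsv = read_genotypes_hapmap(path))
}

read_genotypes_vcf <- function(path, strict = FALSE) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("malformed VCF: no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)
  biallelic <- nalt == 1L
  gt_flat <- unique(as.vector(gt))
  known <- c("0/0", "0/1", "1/0", "1/1", "./.", ".", "0|0", "0|1", "1|0", "1|1", ".|.")
  halfish <- setdiff(gt_flat, known)
  ok_rows <- biallelic
  if (length(halfish)) {
    bad_rows <- apply(gt, 1L, function(z) any(z %in% halfish))
    ok_rows <- ok_rows & !bad_rows
  }
  if (strict && !all(ok_rows))
    stop("non-biallelic or half-call records present (strict = TRUE): e.g. row ",
         which(!ok_rows)[1L])
  gt <- gt[ok_rows, , drop = FALSE]
  rr <- rr[ok_rows]
  code_lut <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
                "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  codes <- matrix(unname(code_lut[gt]), nrow = nrow(gt))
  codes <- t(codes)  # accessions x markers
  rownames(codes) <- colnames(gt)
  colnames(codes) <- rownames(gt)
  if (anyDuplicated(colnames(codes))) stop("duplicate marker id in VCF")
  map <- data.frame(
    marker_id = rownames(gt),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)[ok_rows]),
    alt = vapply(as(alt[ok_rows], "CharacterList"), `[`, character(1), 1L),
    stringsAsFactors = FALSE)
  genotype_matrix(codes, map)
}

read_genotypes_csv <- function(path) {
  dt <- data.table::fread(path, na.strings = c("NA", ".", "-9"))
  if (names(dt)[1L] != "accession")
    stop("matrix CSV must have first column 'accession' (", path, " line 1)")
  acc <- as.character(dt[[1L]])
  codes <- as.matrix(dt[, -1L])
  rownames(codes) <- acc
  map_path <- paste0(path, ".map")
  if (!file.exists(map_path)) stop("missing sidecar map file: ", map_path)
  map <- data.table::fread(map_path)
  genotype_matrix(codes, as.data.frame(map))
}

read_genotypes_hapmap <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  meta_cols <- 11L
  if (ncol(dt) <= meta_cols) stop("malformed HapMap TSV: no genotype columns")
  alleles <- strsplit(dt[["alleles"]], "/", fixed = TRUE)
  if (any(lengths(alleles) != 2L)) stop("non-biallelic HapMap record")
  ref <- vapply(alleles, `[`, character(1), 1L)
  alt <- vapply(alleles, `[`, character(1), 2L)
  gcols <- as.matrix(dt[, -seq_len(meta_cols), with = FALSE])
  n_acc <- ncol(gcols)
  codes <- matrix(NA_integer_, nrow = n_acc, ncol = nrow(dt))
  for (m in seq_len(nrow(dt))) {
    g <- gcols[m, ]
    a1 <- substr(g, 1L, 1L); a2 <- substr(g, 2L, 2L)
    cnt <- (a1 == alt[m]) + (a2 == alt[m])
    cnt[a1 == "N" | a2 == "N" | !(a1 %in% c(ref[m], alt[m])) |
          !(a2 %in% c(ref[m], alt[m]))] <- NA_integer_
    codes[, m] <- as.integer(cnt)
  }
  rownames(codes) <- colnames(gcols)
  colnames(codes) <- dt[["rs#"]]
  map <- data.frame(marker_id = dt[["rs#"]], chrom = as.character(dt[["chrom"]]),
                    pos = dt[["pos"]], ref = ref, alt = alt)
  genotype_matrix(codes, map)
}

#' Write genotypes to VCF, matrix CSV, or HapMap-like TSV
#'
#' Round-trips with [read_genotypes()] losslessly for codes, map and ids.
#' Missing calls are written as `./.` (VCF), `NA` (CSV), `NN` (HapMap).
#'
#' @param g a [genotype_matrix()]
#' @param path output path
#' @param format one of "vcf", "matrix_csv", "hapmap_tsv"
#' @return `path`, invisibly
#' @export
write_genotypes <- function(g, path, format = c("vcf", "matrix_csv", "hapmap_tsv")) {
  format <- match.arg(format)
  switch(format,
    vcf = write_genotypes_vcf(g, path),
    matrix_csv = write_genotypes_csv(g, path),
    hapmap_tsv = write_genotypes_hapmap(g, path))
  invisible(path)
}

write_genotypes_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=metqtl",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g$codes)), collapse = "\t"), con)
  gt_lut <- c("0/0", "0/1", "1/1")
  for (m in seq_len(ncol(g$codes))) {
    calls <- g$codes[, m]
    gt <- ifelse(is.na(calls), "./.", gt_lut[calls + 1L])
    writeLines(paste(c(g$map$chrom[m], g$map$pos[m], g$map$marker_id[m],
                       g$map$ref[m], g$map$alt[m], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
}

write_genotypes_csv <- function(g, path) {
  dt <- data.table::data.table(accession = rownames(g$codes), g$codes)
  data.table::fwrite(dt, path, na = "NA", quote = FALSE)
  data.table::fwrite(g$map, paste0(path, ".map"), quote = FALSE)
}

write_genotypes_hapmap <- function(g, path) {
  n_m <- ncol(g$codes)
  gstr <- matrix("NN", nrow = n_m, ncol = nrow(g$codes))
  for (m in seq_len(n_m)) {
    r <- g$map$ref[m]; a <- g$map$alt[m]
    lut <- c(paste0(r, r), paste0(r, a), paste0(a, a))
    calls <- g$codes[, m]
    gstr[m, ] <- ifelse(is.na(calls), "NN", lut[calls + 1L])
  }
  dt <- data.table::data.table(
    "rs#" = g$map$marker_id, alleles = paste0(g$map$ref, "/", g$map$alt),
    chrom = g$map$chrom, pos = g$map$pos, strand = "+", "assembly#" = "NA",
    center = "NA", protLSID = "NA", assayLSID = "NA", panelLSID = "NA",
    QCcode = "NA")
  dt <- cbind(dt, data.table::as.data.table(gstr))
  data.table::setnames(dt, 12:ncol(dt), rownames(g$codes))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
}
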