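#' Genotype matrix container
#'
#' An accession x marker grid of biallelic SNP dosage codes together with a
#' marker map. Codes count copies of the alternate allele: 0 = homozygous
#' reference (AA), 1 = heterozygous (AB), 2 = homozygous alternate (BB);
#' `NA` marks a missing call. Positions are 1-based inclusive bp (VCF
#' convention) and must be strictly increasing within a chromosome.
#'
#' @param codes integer matrix, rows = accessions, columns = markers, values
#'   in `c(0, 1, 2, NA)`. Dimnames supply accession and marker ids unless
#'   given explicitly.
#' @param map data.frame with one row per marker and columns `marker_id`,
#'   `chrom`, `pos`, `ref`, `alt` (ref/alt default to "A"/"B").
#' @param accession_ids,marker_ids optional id vectors overriding dimnames.
#' @return An object of class `genotype_matrix`: list with elements `codes`
#'   (named integer matrix) and `map` (data.frame).
#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a

genotype_matrix <- function(codes, map, accession_ids = NULL, marker_ids = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (!is.null(accession_ids)) rownames(codes) <- accession_ids
  if (!is.null(marker_ids)) colnames(codes) <- marker_ids
  if (is.null(rownames(codes)))
    rownames(codes) <- sprintf("ACC%03d", seq_len(nrow(codes)))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (is.null(colnames(codes)))
    colnames(codes) <- if (!is.null(map$marker_id)) map$marker_id
      else sprintf("M%05d", seq_len(ncol(codes)))
  if (is.null(map$marker_id)) map$marker_id <- colnames(codes)
  if (is.null(map$ref)) map$ref <- "A"
  if (is.null(map$alt)) map$alt <- "B"
  req <- c("marker_id", "chrom", "pos", "ref", "alt")
  map <- map[, c(req, setdiff(names(map), req))]
  map$pos <- as.integer(map$pos)
  obj <- structure(list(codes = codes, map = map), class = "genotype_matrix")
  validate_genotype_matrix(obj)
}

validate_genotype_matrix <- function(g) {
  codes <- g$codes; map <- g$map
  bad <- codes[!is.na(codes)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(colnames(codes)))
    stop("duplicate marker ids")
  if (anyDuplicated(rownames(codes)))
    stop("duplicate accession ids")
  if (!identical(as.character(map$marker_id),
                 as.character(colnames(codes) %||% character(0))))
    stop("map marker_id must match code columns in order")
  if (any(is.na(map$pos)) || any(map$pos < 1L))
    stop("positions must be integer bp >= 1")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  g
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d markers on %d chromosome(s); %.2f%% missing\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom)),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix by accessions and/or markers
#'
#' @param g a `genotype_matrix`
#' @param accessions,markers logical/integer/character index vectors
#' @return the subsetted `genotype_matrix`
#' @export
subset_genotypes <- function(g, accessions = NULL, markers = NULL) {
  codes <- g$codes
  map <- g$map
  if (!is.null(accessions)) codes <- codes[accessions, , drop = FALSE]
  if (!is.null(markers)) {
    codes <- codes[, markers, drop = FALSE]
    map <- map[match(colnames(codes), map$marker_id), , drop = FALSE]
    rownames(map) <- NULL
  }
  genotype_matrix(codes, map)
}

#' Per-marker minor allele frequency
#'
#' MAF is computed from observed allele counts, independent of the code
#' orientation (a marker whose alternate allele is the major one still
#' reports the minor frequency).
#'
#' @param g a `genotype_matrix`
#' @return named numeric vector of MAF in `[0, 0.5]`
#' @export
marker_maf <- function(g) {
  p <- colMeans(g$codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- NA_real_
  maf
}

#' Per-marker heterozygous-call fraction
#' @param g a `genotype_matrix`
#' @return named numeric vector: fraction of non-missing calls equal to 1
#' @export
marker_het <- function(g) {
  colMeans(g$codes == 1L, na.rm = TRUE)
}
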