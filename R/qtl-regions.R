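#' Squared dosage correlation between two markers
#' @param x,y dosage vectors (pairwise-complete)
#' @return r-squared, or `NA` when either marker is monomorphic
#' @keywords internal
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Interchromosomal LD baseline
#'
#' The given percentile of r-squared over marker pairs on different
#' chromosomes; significant-SNP candidate regions are extended to markers
#' whose LD with the lead exceeds this baseline. The percentile is taken as
#' the order statistic `sorted[ceiling(q * n)]` so it matches a sort-based
#' computation exactly. At most `max_pairs` random pairs are sampled (set a
#' seed beforehand for reproducibility).
#'
#' @param g a [genotype_matrix()] with >= 2 chromosomes
#' @param percentile quantile in (0, 1), default 0.95
#' @param max_pairs pair subsample cap
#' @return the r-squared baseline (single number)
#' @export
interchrom_r2_baseline <- function(g, percentile = 0.95, max_pairs = 50000L) {
  chrom <- g$map$chrom
  if (length(unique(chrom)) < 2L) stop("need >= 2 chromosomes")
  m <- ncol(g$codes)
  n_all <- (as.numeric(m)^2 - sum(table(chrom)^2)) / 2  # inter-chromosomal pairs
  want <- min(max_pairs, n_all)
  seen <- new.env()
  r2 <- numeric(0)
  while (length(r2) < want) {
    i <- sample.int(m, 1L); j <- sample.int(m, 1L)
    if (i == j || chrom[i] == chrom[j]) next
    key <- paste(min(i, j), max(i, j))
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    v <- dosage_r2(g$codes[, i], g$codes[, j])
    if (!is.na(v)) r2 <- c(r2, v)
    if (length(seen) >= n_all) break
  }
  sorted <- sort(r2)
  sorted[ceiling(percentile * length(sorted))]
}

#' Pairwise within-window LD table
#'
#' r-squared (squared Pearson correlation of dosages over pairwise-complete
#' accessions) for all marker pairs on the same chromosome within
#' `window_bp`.
#'
#' @param g a [genotype_matrix()]
#' @param window_bp maximum bp separation (strict `<`)
#' @return data.frame: marker_a, marker_b, chrom, dist_bp, r2 (monomorphic
#'   pairs excluded)
#' @export
pairwise_r2 <- function(g, window_bp = 1e6) {
  out <- list()
  for (ch in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == ch)
    pos <- g$map$pos[idx]
    for (a in seq_along(idx)) {
      b <- a + 1L
      while (b <= length(idx) && pos[b] - pos[a] < window_bp) {
        v <- dosage_r2(g$codes[, idx[a]], g$codes[, idx[b]])
        if (!is.na(v))
          out[[length(out) + 1L]] <- data.frame(
            marker_a = g$map$marker_id[idx[a]],
            marker_b = g$map$marker_id[idx[b]], chrom = ch,
            dist_bp = pos[b] - pos[a], r2 = v, stringsAsFactors = FALSE)
        b <- b + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(marker_a = character(), marker_b = character(),
                      chrom = character(), dist_bp = numeric(), r2 = numeric()))
  do.call(rbind, out)
}

#' Candidate region around a lead SNP
#'
#' The interval spanning the lead and every same-chromosome marker with
#' r-squared to the lead above `baseline` and strictly within `window_bp`
#' of the lead position.
#'
#' @param g a [genotype_matrix()]
#' @param lead_marker lead SNP id
#' @param baseline r-squared baseline (strict `>`)
#' @param window_bp distance rule (strict `<`), default 2 Mb
#' @return list(chrom, start, end, lead = lead_marker, members = linked
#'   marker ids including the lead)
#' @export
candidate_region <- function(g, lead_marker, baseline, window_bp = 2e6) {
  li <- match(lead_marker, g$map$marker_id)
  if (is.na(li)) stop("unknown lead marker ", lead_marker)
  ch <- g$map$chrom[li]; lp <- g$map$pos[li]
  idx <- which(g$map$chrom == ch & abs(g$map$pos - lp) < window_bp)
  linked <- vapply(idx, function(j) {
    if (j == li) return(TRUE)
    v <- dosage_r2(g$codes[, li], g$codes[, j])
    !is.na(v) && v > baseline
  }, logical(1))
  members <- idx[linked]
  list(chrom = ch, start = min(g$map$pos[members]),
       end = max(g$map$pos[members]), lead = lead_marker,
       members = g$map$marker_id[members])
}

#' Regional LD block intervals for a lead SNP
#'
#' Maximal position-sorted runs of markers within the candidate region whose
#' r-squared with the lead exceeds the baseline; each run contributes one
#' interval.
#'
#' @param g a [genotype_matrix()]
#' @param region a [candidate_region()] result
#' @param baseline r-squared baseline
#' @return data.frame(chrom, start, end) of block intervals
#' @export
regional_blocks <- function(g, region, baseline) {
  idx <- which(g$map$chrom == region$chrom &
                 g$map$pos >= region$start & g$map$pos <= region$end)
  li <- match(region$lead, g$map$marker_id)
  linked <- vapply(idx, function(j) {
    if (j == li) return(TRUE)
    v <- dosage_r2(g$codes[, li], g$codes[, j])
    !is.na(v) && v > baseline
  }, logical(1))
  runs <- rle(linked)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  data.frame(chrom = region$chrom,
             start = g$map$pos[idx[starts[keep]]],
             end = g$map$pos[idx[ends[keep]]])
}

merge_intervals <- function(iv, gap_bp) {
  if (!nrow(iv)) return(iv)
  out <- list()
  for (ch in unique(iv$chrom)) {
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    cur_s <- sub$start[1]; cur_e <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= cur_e + gap_bp) {
        cur_e <- max(cur_e, sub$end[i])
      } else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s, end = cur_e)
        cur_s <- sub$start[i]; cur_e <- sub$end[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s, end = cur_e)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Build loci from candidate regions
#'
#' Each lead's regional LD block intervals (and its candidate region span)
#' are merged transitively when they overlap or lie within `gap_bp` of each
#' other; merged intervals become loci with stable ids ordered by chromosome
#' and position, and every lead SNP maps into exactly one locus.
#'
#' @param g a [genotype_matrix()]
#' @param regions list of [candidate_region()] results
#' @param baseline r-squared baseline for the regional blocks
#' @param gap_bp merge distance (inclusive `<=`), default 100 kb
#' @return data.frame: locus_id, chrom, start, end, members
#'   (comma-separated member marker ids of the merged leads)
#' @export
build_loci <- function(g, regions, baseline, gap_bp = 1e5) {
  if (!length(regions))
    return(data.frame(locus_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), members = character()))
  iv <- do.call(rbind, lapply(regions, function(r) {
    blocks <- regional_blocks(g, r, baseline)
    rbind(blocks, data.frame(chrom = r$chrom, start = r$start, end = r$end))
  }))
  merged <- merge_intervals(iv, gap_bp)
  merged$locus_id <- sprintf("L%02d", seq_len(nrow(merged)))
  all_members <- unique(unlist(lapply(regions, `[[`, "members")))
  mpos <- g$map$pos[match(all_members, g$map$marker_id)]
  mchr <- g$map$chrom[match(all_members, g$map$marker_id)]
  merged$members <- vapply(seq_len(nrow(merged)), function(i) {
    inside <- all_members[mchr == merged$chrom[i] & mpos >= merged$start[i] &
                            mpos <= merged$end[i]]
    paste(inside, collapse = ",")
  }, character(1))
  rownames(merged) <- NULL
  merged[, c("locus_id", "chrom", "start", "end", "members")]
}

#' Map marker-trait associations to loci
#' @param mtas data.frame with columns marker, chrom, pos (plus any others)
#' @param loci a [build_loci()] table
#' @return `mtas` with a `locus_id` column (error if any MTA maps nowhere,
#'   which cannot happen when every MTA seeded a region)
#' @export
assign_mta_loci <- function(mtas, loci) {
  locus_of <- function(ch, p) {
    hit <- which(loci$chrom == ch & loci$start <= p & loci$end >= p)
    if (!length(hit)) stop("MTA at ", ch, ":", p, " outside all loci")
    loci$locus_id[hit[1L]]
  }
  mtas$locus_id <- mapply(locus_of, mtas$chrom, mtas$pos)
  mtas
}

#' Group MTAs into QTLs and label co-localization
#'
#' One QTL per (trait, analysis class, locus): all significant SNPs for the
#' same trait and class within a locus collectively constitute a single QTL.
#' Classes are `meanQTL` (analysis "mean"), `stbQTL` ("stability") and `QTI`
#' (any "gei:*" analysis). Per trait x locus, the set of classes present
#' yields the co-localization label: a single class gives
#' mean_specific/stb_specific/qti_specific; mean with either stability class
#' gives "mean+stability"; QTI with stbQTL gives "qti+stb"; all three give
#' "all_classes".
#'
#' @param mtas MTA data.frame with columns marker, chrom, pos, trait,
#'   analysis, p and `locus_id` (see [assign_mta_loci()])
#' @return list(qtls = data.frame(trait, class, locus_id, n_mta, markers,
#'   colocalization), summary = counts per label)
#' @export
group_qtls <- function(mtas) {
  cls <- ifelse(mtas$analysis == "mean", "meanQTL",
                ifelse(mtas$analysis == "stability", "stbQTL", "QTI"))
  mtas$class <- cls
  key <- paste(mtas$trait, mtas$class, mtas$locus_id, sep = "\r")
  qtls <- do.call(rbind, lapply(split(mtas, key), function(s) {
    data.frame(trait = s$trait[1], class = s$class[1],
               locus_id = s$locus_id[1], n_mta = nrow(s),
               markers = paste(sort(unique(s$marker)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(qtls) <- NULL
  tl_key <- paste(qtls$trait, qtls$locus_id, sep = "\r")
  label_of <- function(classes) {
    classes <- sort(unique(classes))
    if (identical(classes, "meanQTL")) "mean_specific"
    else if (identical(classes, "stbQTL")) "stb_specific"
    else if (identical(classes, "QTI")) "qti_specific"
    else if (setequal(classes, c("meanQTL", "stbQTL", "QTI"))) "all_classes"
    else if ("meanQTL" %in% classes) "mean+stability"
    else "qti+stb"
  }
  labels <- tapply(qtls$class, tl_key, label_of)
  qtls$colocalization <- unname(labels[tl_key])
  qtls <- qtls[order(qtls$locus_id, qtls$trait, qtls$class), ]
  rownames(qtls) <- NULL
  summary <- as.data.frame(table(label = qtls$colocalization),
                           stringsAsFactors = FALSE)
  list(qtls = qtls, summary = summary)
}

#' Arithmetic summary of QTL classes and inheritance-mode tallies
#'
#' Given per-class QTL counts and mode-of-inheritance counts, returns totals
#' and percentages on the printed scale (a convenience for reporting
#' consistency of published tallies).
#'
#' @param class_counts named integer vector of QTL counts per class
#' @param mode_counts optional named integer vector of inheritance-mode
#'   counts among analysable QTLs
#' @param not_analysable,non_conclusive counts excluded from mode assessment
#' @return list(total, analysable, mode_percent)
#' @export
qtl_class_summary <- function(class_counts, mode_counts = NULL,
                              not_analysable = 0L, non_conclusive = 0L) {
  total <- sum(class_counts)
  analysable <- total - not_analysable - non_conclusive
  mode_percent <- if (is.null(mode_counts)) NULL else
    100 * mode_counts / total
  list(total = total, analysable = analysable, mode_percent = mode_percent)
}
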