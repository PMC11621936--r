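## Copy number at each query interval start, diploid (2) where uncovered.
copy_at_points <- function(segments, points) {
  if (is.null(segments) || nrow(segments) == 0L) {
    return(rep(2L, length(points)))
  }
  segments <- segments[order(segments$start), , drop = FALSE]
  idx <- findInterval(points, segments$start)
  cn <- rep(2L, length(points))
  hit <- idx > 0L
  covered <- hit & points <= segments$end[pmax(idx, 1L)]
  cn[covered] <- segments$copy_number[idx[covered]]
  cn
}

#' Position-wise copy-number difference between matched lines
#'
#' Computes resistant minus parental copy number as a piecewise-constant
#' profile over the union of both profiles' segment breakpoints.
#' Chromosomes present in only one profile are imputed diploid (copy 2)
#' in the other, with a warning. The positions of the maximum and
#' minimum difference are attached as attributes `argmax` and `argmin`.
#'
#' @param resistant,parental segment data frames (`chrom`, `start`,
#'   `end`, `copy_number`; 1-based inclusive coordinates).
#' @return data frame (`chrom`, `start`, `end`, `delta`).
#' @export
delta_cnv <- function(resistant, parental) {
  need <- c("chrom", "start", "end", "copy_number")
  stopifnot(all(need %in% names(resistant)), all(need %in% names(parental)))
  chroms <- union(unique(resistant$chrom), unique(parental$chrom))
  only <- c(setdiff(unique(resistant$chrom), unique(parental$chrom)),
            setdiff(unique(parental$chrom), unique(resistant$chrom)))
  if (length(only) > 0L) {
    warning("chromosomes present in one profile only treated as diploid: ",
            paste(only, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(chroms, function(ch) {
    r <- resistant[resistant$chrom == ch, , drop = FALSE]
    p <- parental[parental$chrom == ch, , drop = FALSE]
    brk <- sort(unique(c(r$start, r$end + 1L, p$start, p$end + 1L)))
    starts <- brk[-length(brk)]
    ends <- brk[-1L] - 1L
    data.frame(chrom = ch, start = starts, end = ends,
               delta = copy_at_points(r, starts) -
                 copy_at_points(p, starts),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "argmax") <- out[which.max(out$delta), c("chrom", "start", "end")]
  attr(out, "argmin") <- out[which.min(out$delta), c("chrom", "start", "end")]
  out
}

#' Count copy-number loss and gain loci
#'
#' Counts loss events (copy number <= `loss_cutoff`) and gain events
#' (copy number >= `gain_cutoff`) in a segment profile. Adjacent
#' qualifying segments (contiguous coordinates on the same chromosome,
#' same direction) merge into a single locus, so the counts measure
#' events rather than segmentation artefacts.
#'
#' @param profile segment data frame (`chrom`, `start`, `end`,
#'   `copy_number`).
#' @param loss_cutoff,gain_cutoff integer copy-number cuts on a diploid
#'   baseline.
#' @return list with `n_loss` and `n_gain`.
#' @export
count_cnv_loci <- function(profile, loss_cutoff = 1L, gain_cutoff = 3L) {
  stopifnot(all(c("chrom", "start", "end", "copy_number") %in%
                  names(profile)))
  count_dir <- function(qual) {
    total <- 0L
    for (ch in unique(profile$chrom)) {
      seg <- profile[profile$chrom == ch, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      q <- qual(seg$copy_number)
      if (!any(q)) next
      ## a new locus starts where a qualifying segment is not contiguous
      ## with a preceding qualifying segment
      new_locus <- q & !c(FALSE, q[-length(q)] &
                            seg$start[-1L] == seg$end[-nrow(seg)] + 1L)
      total <- total + sum(new_locus)
    }
    total
  }
  list(n_loss = count_dir(function(cn) cn <= loss_cutoff),
       n_gain = count_dir(function(cn) cn >= gain_cutoff))
}

#' Binary gene-by-line copy-number loss matrix
#'
#' A gene is called lost in a cell line when any profile segment
#' overlapping the gene has copy number at or below `loss_cutoff`.
#'
#' @param profiles named list of segment data frames, one per cell line.
#' @param genes data frame (`gene`, `chrom`, `start`, `end`).
#' @param loss_cutoff loss call cut (default 1).
#' @return 0/1 matrix, genes x cell lines.
#' @export
shared_loss_matrix <- function(profiles, genes, loss_cutoff = 1L) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)))
  m <- vapply(profiles, function(pr) {
    vapply(seq_len(nrow(genes)), function(i) {
      seg <- pr[pr$chrom == genes$chrom[i] &
                  pr$start <= genes$end[i] &
                  pr$end >= genes$start[i], , drop = FALSE]
      as.integer(nrow(seg) > 0L && any(seg$copy_number <= loss_cutoff))
    }, integer(1))
  }, integer(nrow(genes)))
  m <- matrix(m, nrow = nrow(genes),
              dimnames = list(genes$gene, names(profiles)))
  m
}

#' Test per-gene loss against a group label
#'
#' For each gene, forms the 2x2 table of loss status by group and
#' applies the two-sided Fisher exact test, identifying genes whose loss
#' is confined to (or enriched in) one sensitivity group.
#'
#' @param loss_mat 0/1 matrix from [shared_loss_matrix()] (genes x
#'   lines).
#' @param groups logical or two-level vector over the columns: `TRUE`
#'   (or the first level) marks the index group.
#' @return data frame (gene, n_loss_in, n_loss_out, p), sorted by p.
#' @export
shared_loss_test <- function(loss_mat, groups) {
  stopifnot(ncol(loss_mat) == length(groups))
  g <- if (is.logical(groups)) groups else groups == unique(groups)[1]
  res <- do.call(rbind, lapply(rownames(loss_mat), function(gene) {
    loss <- loss_mat[gene, ] == 1L
    tab <- rbind(c(sum(loss & g), sum(!loss & g)),
                 c(sum(loss & !g), sum(!loss & !g)))
    data.frame(gene = gene, n_loss_in = sum(loss & g),
               n_loss_out = sum(loss & !g),
               p = fisher_exact_2x2(tab), stringsAsFactors = FALSE)
  }))
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  res
}

#' Compare per-line CNV locus counts between two groups
#'
#' Two-sided Mann-Whitney U test of e.g. loss counts in sensitive versus
#' resistant lines (exact for small samples, tie-corrected normal
#' approximation otherwise).
#'
#' @param counts_a,counts_b integer count samples.
#' @return list with `u`, `p`, `method` (see [mann_whitney_u()]).
#' @export
compare_group_counts <- function(counts_a, counts_b) {
  mann_whitney_u(counts_a, counts_b)
}

#' Correlate a gene's copy number with dose-response AUC
#'
#' @param copy_number per-line copy number of one gene.
#' @param auc paired per-line AUC values.
#' @return list with `r`, `p`, `n` (see [pearson_cor()]).
#' @export
gene_cn_vs_auc <- function(copy_number, auc) pearson_cor(copy_number, auc)
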