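#' Per-gene ribosome polarity score
#'
#' Summarizes whether footprint density on a CDS skews 5' (negative) or 3'
#' (positive). With per-nucleotide densities \eqn{d_i = c_i / \sum c} and
#' linear weights \eqn{w_i = (2i - (L+1)) / (L-1)} over positions
#' \eqn{i = 1..L}, the polarity is \eqn{\sum_i d_i w_i}, bounded in
#' \eqn{[-1, 1]}: all reads on the first nucleotide give -1, all on the last
#' give +1, a uniform profile gives 0.
#'
#' @param profile a [gene_profile()].
#' @return list with `gene_id`, `library_id`, `polarity` (NA when the profile
#'   has no reads) and `n_reads`.
#' @export
polarity_score <- function(profile) {
  L <- length(profile$counts)
  if (L < 2) stop("polarity needs a CDS of length >= 2")
  n <- sum(profile$counts)
  pol <- if (n > 0) {
    w <- (2 * seq_len(L) - (L + 1)) / (L - 1)
    sum(profile$counts * w) / n
  } else NA_real_
  list(gene_id = profile$gene_id, library_id = profile$library_id,
       polarity = pol, n_reads = n)
}

#' Polarity score distribution over genes
#'
#' Computes per-gene polarity scores for all profiles with more than
#' `min_reads` reads (strict inequality, matching the ">25 reads per library"
#' filter) and returns them with a smoothed density for plotting.
#'
#' @param profiles list of [gene_profile()] objects (one library).
#' @param min_reads read-count filter; genes with `n_reads > min_reads` are
#'   kept.
#' @return object of class `polarity_dist`: data.frame `scores`
#'   (gene_id, n_reads, polarity), `density` (stats::density, Silverman
#'   bandwidth Gaussian kernel; NULL when fewer than 2 genes pass), and the
#'   applied filter.
#' @export
polarity_distribution <- function(profiles, min_reads = 25) {
  rows <- lapply(profiles, polarity_score)
  df <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    n_reads = vapply(rows, `[[`, numeric(1), "n_reads"),
    polarity = vapply(rows, `[[`, numeric(1), "polarity"),
    stringsAsFactors = FALSE
  )
  df <- df[!is.na(df$polarity) & df$n_reads > min_reads, , drop = FALSE]
  if (nrow(df) == 0)
    stop("no gene passes the filter n_reads > ", min_reads)
  dens <- if (nrow(df) >= 2 && sd(df$polarity) > 0)
    density(df$polarity, bw = "nrd0", kernel = "gaussian") else NULL
  structure(list(scores = df, density = dens, min_reads = min_reads),
            class = "polarity_dist")
}

#' @export
print.polarity_dist <- function(x, ...) {
  cat(sprintf("<polarity_dist> %d genes (> %g reads), mean %.3f, median %.3f\n",
              nrow(x$scores), x$min_reads, mean(x$scores$polarity),
              median(x$scores$polarity)))
  invisible(x)
}

#' Shift between two polarity distributions
#'
#' @param dist_a,dist_b [polarity_distribution()] results; deltas are
#'   `b - a` (a is the reference, e.g. log phase).
#' @return list with `delta_mean`, `delta_median`, and `per_gene` deltas for
#'   genes passing the filter in both libraries (empty data.frame when none
#'   are shared).
#' @export
polarity_shift <- function(dist_a, dist_b) {
  a <- dist_a$scores; b <- dist_b$scores
  shared <- intersect(a$gene_id, b$gene_id)
  per_gene <- data.frame(
    gene_id = shared,
    delta = b$polarity[match(shared, b$gene_id)] -
      a$polarity[match(shared, a$gene_id)],
    stringsAsFactors = FALSE
  )
  list(delta_mean = mean(b$polarity) - mean(a$polarity),
       delta_median = median(b$polarity) - median(a$polarity),
       per_gene = per_gene)
}

#' Polarity as a function of gene length
#'
#' Bins genes by CDS length and summarizes polarity per bin.
#'
#' @param scores data.frame with `gene_id` and `polarity` columns (e.g. the
#'   `scores` element of a [polarity_distribution()]).
#' @param genes gene model table supplying `cds_length_nt`.
#' @param bins length bin edges in nt (must cover the observed lengths).
#' @return data.frame with one row per bin: `bin_lo`, `bin_hi`, `n`,
#'   `mean_polarity`, `median_polarity` (NA statistics for empty bins).
#' @export
polarity_vs_length <- function(scores, genes,
                               bins = c(0, 1000, 2000, 3000, 5000, Inf)) {
  len <- genes$cds_length_nt[match(scores$gene_id, genes$gene_id)]
  if (anyNA(len)) stop("scores contain genes absent from the model table")
  if (min(len) < min(bins) || max(len) > max(bins))
    stop("bins do not cover observed gene lengths")
  idx <- cut(len, bins, labels = FALSE, right = TRUE)
  out <- lapply(seq_len(length(bins) - 1), function(b) {
    p <- scores$polarity[which(idx == b)]
    data.frame(bin_lo = bins[b], bin_hi = bins[b + 1], n = length(p),
               mean_polarity = if (length(p)) mean(p) else NA_real_,
               median_polarity = if (length(p)) median(p) else NA_real_)
  })
  do.call(rbind, out)
}
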