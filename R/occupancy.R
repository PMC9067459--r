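#' Transcripts per million
#'
#' \eqn{TPM_g = 10^6 \, (c_g/L_g) / \sum_h (c_h/L_h)}: counts are first
#' length-normalized to rates, then scaled to sum to one million.
#'
#' @param counts per-gene read counts.
#' @param lengths per-gene lengths (nt), positive.
#' @return per-gene TPM values (same order; sums to 1e6).
#' @export
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (all(counts == 0)) stop("all counts are zero")
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Per-gene log2 ribosome occupancy
#'
#' \eqn{\log_2(\mathrm{RPF}/\mathrm{mRNA})} per gene. Undefined (NA) when
#' either side is zero; such genes are excluded from occupancy plots.
#'
#' @param rpf,mrna non-negative abundances (raw counts or TPM; the package
#'   default is TPM, see [expression_table()]).
#' @return numeric vector of log2 occupancies.
#' @export
log2_ro <- function(rpf, mrna) {
  out <- rep(NA_real_, length(rpf))
  ok <- rpf > 0 & mrna > 0
  out[ok] <- log2(rpf[ok] / mrna[ok])
  out
}

#' Build an expression table from RPF and mRNA counts
#'
#' @param gene_id gene identifiers.
#' @param rpf_count,mrna_count non-negative per-gene counts.
#' @param lengths per-gene CDS lengths (nt).
#' @param ro_on `"tpm"` (default) or `"counts"`: scale on which occupancy is
#'   computed. Length bias cancels in fold changes either way.
#' @return data.frame with counts, `rpf_tpm`, `mrna_tpm` (each summing to
#'   1e6), and `log2_ro`.
#' @export
expression_table <- function(gene_id, rpf_count, mrna_count, lengths,
                             ro_on = c("tpm", "counts")) {
  ro_on <- match.arg(ro_on)
  df <- data.frame(gene_id = as.character(gene_id),
                   length_nt = lengths,
                   rpf_count = rpf_count, mrna_count = mrna_count,
                   rpf_tpm = tpm(rpf_count, lengths),
                   mrna_tpm = tpm(mrna_count, lengths),
                   stringsAsFactors = FALSE)
  df$log2_ro <- if (ro_on == "tpm") log2_ro(df$rpf_tpm, df$mrna_tpm)
  else log2_ro(df$rpf_count, df$mrna_count)
  df
}

#' Join two conditions and compute fold changes
#'
#' Adds `log2_mrna_fc` and `log2_ro_fc` (stress minus reference). Zero counts
#' receive a +0.5 pseudocount before fold-change computation only (occupancy
#' definedness is unaffected), keeping log2 finite for induced genes absent
#' in the reference.
#'
#' @param table_ref,table_stress [expression_table()] data.frames sharing
#'   gene ids.
#' @param pseudocount added to zero counts before fold changes.
#' @return merged data.frame (suffixes `_ref`, `_stress`) with fold-change
#'   columns.
#' @export
join_conditions <- function(table_ref, table_stress, pseudocount = 0.5) {
  m <- merge(table_ref, table_stress, by = c("gene_id"),
             suffixes = c("_ref", "_stress"))
  pc <- function(x) ifelse(x == 0, pseudocount, x)
  # fold changes on TPM scale (depth-normalized), pseudocounted
  mrna_ref <- tpm(pc(m$mrna_count_ref), m$length_nt_ref)
  mrna_str <- tpm(pc(m$mrna_count_stress), m$length_nt_ref)
  rpf_ref <- tpm(pc(m$rpf_count_ref), m$length_nt_ref)
  rpf_str <- tpm(pc(m$rpf_count_stress), m$length_nt_ref)
  m$log2_mrna_fc <- log2(mrna_str / mrna_ref)
  m$log2_ro_fc <- log2(rpf_str / mrna_str) - log2(rpf_ref / mrna_ref)
  m
}

#' Classify genes by induction and abundance
#'
#' Applies the printed thresholds: a gene is `upregulated` when
#' `log2_mrna_fc > 2.5` and `log2_ro_fc > 0.09` (both strict);
#' `induced_4fold` when its mRNA fold change exceeds 4; and
#' `abundant_log_top150` when it ranks in the top `top_n` genes by mean
#' reference-condition RPF TPM across replicates (ties at the boundary broken
#' by gene_id order, deterministically). Labels are not exclusive.
#'
#' @param table_ref,table_stress [expression_table()] data.frames; `table_ref`
#'   may be a list of replicate tables (mean TPM is used; with a single table
#'   a warning notes the fallback).
#' @param top_n size of the abundant class.
#' @param pseudocount passed to [join_conditions()].
#' @return data.frame: `gene_id`, logical class columns, fold changes.
#' @export
classify_genes <- function(table_ref, table_stress, top_n = 150,
                           pseudocount = 0.5) {
  reps <- if (is.data.frame(table_ref)) list(table_ref) else table_ref
  if (length(reps) == 1)
    warning("single reference library: mean TPM falls back to one replicate")
  base <- reps[[1]]
  tpm_mat <- vapply(reps, function(r)
    r$rpf_tpm[match(base$gene_id, r$gene_id)], numeric(nrow(base)))
  mean_tpm <- rowMeans(as.matrix(tpm_mat))
  j <- join_conditions(base, table_stress, pseudocount)
  j$mean_ref_tpm <- mean_tpm[match(j$gene_id, base$gene_id)]
  classify_from_fc(j[c("gene_id", "log2_mrna_fc", "log2_ro_fc",
                       "mean_ref_tpm")], top_n = top_n)
}

#' Apply the classification thresholds to precomputed fold changes
#'
#' The threshold layer of [classify_genes()], separated so the strict
#' inequalities can be exercised directly: `upregulated` requires
#' `log2_mrna_fc > 2.5` and `log2_ro_fc > 0.09` (a gene sitting exactly at a
#' threshold is not labelled); `induced_4fold` requires a linear mRNA fold
#' change > 4 (`log2_mrna_fc > 2`).
#'
#' @param fc data.frame with `gene_id`, `log2_mrna_fc`, `log2_ro_fc`,
#'   `mean_ref_tpm`.
#' @param top_n abundant-class size.
#' @return classification data.frame (see [classify_genes()]).
#' @export
classify_from_fc <- function(fc, top_n = 150) {
  ord <- order(-fc$mean_ref_tpm, fc$gene_id)
  top <- fc$gene_id[ord][seq_len(min(top_n, nrow(fc)))]
  data.frame(
    gene_id = fc$gene_id,
    upregulated = fc$log2_mrna_fc > 2.5 & fc$log2_ro_fc > 0.09,
    induced_4fold = fc$log2_mrna_fc > 2,
    abundant_log_top150 = fc$gene_id %in% top,
    log2_mrna_fc = fc$log2_mrna_fc,
    log2_ro_fc = fc$log2_ro_fc,
    stringsAsFactors = FALSE
  )
}

#' Fraction of reads per gene category
#'
#' Partitions genes into disjoint reporting buckets — `induced`
#' (induced_4fold), `abundant` (abundant_log_top150, minus overlap with
#' induced, which wins), `other` — and reports the fraction of RPF and mRNA
#' reads in each. Fractions sum to 1 per library type.
#'
#' @param table an [expression_table()] data.frame.
#' @param classes output of [classify_genes()].
#' @return data.frame with `category`, `rpf_fraction`, `mrna_fraction`.
#' @export
read_category_proportions <- function(table, classes) {
  if (nrow(table) == 0) stop("empty expression table")
  cl <- classes[match(table$gene_id, classes$gene_id), ]
  bucket <- ifelse(!is.na(cl$induced_4fold) & cl$induced_4fold, "induced",
                   ifelse(!is.na(cl$abundant_log_top150) & cl$abundant_log_top150,
                          "abundant", "other"))
  agg <- function(x) tapply(x, factor(bucket, c("induced", "abundant", "other")),
                            sum, default = 0)
  rpf <- agg(table$rpf_count); mrna <- agg(table$mrna_count)
  data.frame(category = names(rpf),
             rpf_fraction = as.numeric(rpf) / sum(table$rpf_count),
             mrna_fraction = as.numeric(mrna) / sum(table$mrna_count),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Occupancy change versus gene length
#'
#' Per-gene linear ratio of ribosome occupancy between stress and reference
#' (\eqn{2^{\Delta \log_2 RO}}), with a per-length-bin summary. Genes lacking
#' a defined occupancy on either side are omitted.
#'
#' @param table_ref,table_stress [expression_table()] data.frames.
#' @param genes gene model table (lengths).
#' @param bins length bin edges, nt.
#' @return list: `per_gene` (gene_id, length_nt, ro_ratio) and `by_bin`
#'   (median/mean ratio and count per bin).
#' @export
ro_change_vs_length <- function(table_ref, table_stress, genes,
                                bins = c(0, 1000, 2000, 4000, Inf)) {
  shared <- intersect(table_ref$gene_id, table_stress$gene_id)
  dropped <- setdiff(union(table_ref$gene_id, table_stress$gene_id), shared)
  if (length(dropped))
    message(length(dropped), " gene(s) absent from one table omitted")
  ro_r <- table_ref$log2_ro[match(shared, table_ref$gene_id)]
  ro_s <- table_stress$log2_ro[match(shared, table_stress$gene_id)]
  ok <- !is.na(ro_r) & !is.na(ro_s)
  per <- data.frame(
    gene_id = shared[ok],
    length_nt = genes$cds_length_nt[match(shared[ok], genes$gene_id)],
    ro_ratio = 2^(ro_s[ok] - ro_r[ok]),
    stringsAsFactors = FALSE
  )
  idx <- cut(per$length_nt, bins, labels = FALSE, right = TRUE)
  by_bin <- do.call(rbind, lapply(seq_len(length(bins) - 1), function(b) {
    r <- per$ro_ratio[which(idx == b)]
    data.frame(bin_lo = bins[b], bin_hi = bins[b + 1], n = length(r),
               median_ratio = if (length(r)) median(r) else NA_real_,
               mean_ratio = if (length(r)) mean(r) else NA_real_)
  }))
  list(per_gene = per, by_bin = by_bin)
}
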