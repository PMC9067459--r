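#' Start-codon-aligned metagene density
#'
#' Aggregates footprint counts across genes after aligning all CDSs at the
#' start codon. Genes with CDS length strictly above `min_len_nt` and total
#' reads strictly above `min_reads` (matching the ">1,000 nt with >25 reads"
#' filters) contribute; the summed per-offset counts are divided by the
#' library's total mapped reads and scaled per million so that libraries of
#' different depth are comparable.
#'
#' @param profiles list of [gene_profile()] objects from one library.
#' @param genes gene model table.
#' @param min_len_nt length filter (strict >), nt.
#' @param min_reads per-gene read filter (strict >).
#' @param max_offset largest offset (nt downstream of the start codon)
#'   reported.
#' @param total_mapped_reads library depth used for normalization; defaults
#'   to the summed reads of `profiles`.
#' @return object of class `metagene_profile`: `offsets` (1..max_offset),
#'   `density`, `n_genes_included`, and the applied filters.
#' @export
metagene_density <- function(profiles, genes, min_len_nt = 1000,
                             min_reads = 25, max_offset = 1000,
                             total_mapped_reads = NULL) {
  if (min_len_nt <= 0 || max_offset <= 0) stop("thresholds must be positive")
  if (is.null(total_mapped_reads)) total_mapped_reads <- total_reads(profiles)
  lens <- genes$cds_length_nt[match(names(profiles), genes$gene_id)]
  dens <- numeric(max_offset)
  n_inc <- 0L
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    if (is.na(lens[i]) || lens[i] <= min_len_nt) next
    if (sum(p$counts) <= min_reads) next
    m <- min(length(p$counts), max_offset)
    dens[seq_len(m)] <- dens[seq_len(m)] + p$counts[seq_len(m)]
    n_inc <- n_inc + 1L
  }
  if (n_inc == 0)
    stop("no gene passes length > ", min_len_nt, " and reads > ", min_reads)
  structure(
    list(offsets = seq_len(max_offset),
         density = dens * 1e6 / total_mapped_reads,
         n_genes_included = n_inc,
         filter_min_len_nt = min_len_nt, filter_min_reads = min_reads),
    class = "metagene_profile"
  )
}

#' Start-codon density-drop magnitude between two metagenes
#'
#' Quantifies how much near-start read density differs between two libraries.
#' Each metagene is first normalized to its own mean density over the
#' reference offsets (default 151-1,000 nt) so the statistic is robust to
#' depth and gene-set composition; the returned value is the mean normalized
#' density over `window_nt` of `meta_b` minus that of `meta_a`. A value of -1
#' means the window emptied completely relative to the gene body.
#'
#' @param meta_a,meta_b [metagene_density()] results (a = reference).
#' @param window_nt two-element interval of offsets near the start codon.
#' @param reference_nt two-element interval used for self-normalization.
#' @return single number.
#' @export
start_drop_magnitude <- function(meta_a, meta_b, window_nt = c(1, 150),
                                 reference_nt = c(151, 1000)) {
  norm_window <- function(m) {
    if (max(window_nt) > max(m$offsets) || max(reference_nt) > max(m$offsets))
      stop("window outside covered offsets")
    ref <- mean(m$density[m$offsets >= reference_nt[1] &
                            m$offsets <= reference_nt[2]])
    if (ref <= 0) stop("reference region has zero density")
    mean(m$density[m$offsets >= window_nt[1] &
                     m$offsets <= window_nt[2]]) / ref
  }
  norm_window(meta_b) - norm_window(meta_a)
}

#' Ribosome transit-rate proxy from two snapshots of one gene
#'
#' The displacement of the read-weighted centroid position between two
#' timepoints, per minute. Positive values indicate net downstream (3')
#' movement. This is a proxy for the average transit rate of the bound
#' ribosome population, not a single-ribosome velocity.
#'
#' @param profile_t1,profile_t2 [gene_profile()] objects for the same gene.
#' @param dt_min elapsed time between the snapshots, minutes.
#' @return displacement rate in nt/min (NA with a `reason` attribute when a
#'   profile has no reads).
#' @export
transit_rate_proxy <- function(profile_t1, profile_t2, dt_min) {
  if (profile_t1$gene_id != profile_t2$gene_id)
    stop("profiles are from different genes")
  if (dt_min <= 0) stop("dt_min must be > 0")
  centroid <- function(p) {
    n <- sum(p$counts)
    if (n == 0) return(NA_real_)
    sum(seq_along(p$counts) * p$counts) / n
  }
  c1 <- centroid(profile_t1); c2 <- centroid(profile_t2)
  if (is.na(c1) || is.na(c2))
    return(structure(NA_real_, reason = "zero reads in a snapshot"))
  (c2 - c1) / dt_min
}
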