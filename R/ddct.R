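#' Spike-in-normalized delta-delta-Ct fold change
#'
#' Livak-style relative quantification across polysome fraction pools with an
#' exogenous spike-in as the reference: per replicate,
#' \eqn{\Delta Ct_c = Ct(gene, pool, c) - Ct(spike, pool, c)}; replicate
#' means are differenced between conditions and exponentiated,
#' \eqn{fold = E^{-(\overline{\Delta Ct}_{test} - \overline{\Delta Ct}_{ref})}}.
#' Per-replicate folds (paired by replicate id) and their SEM are also
#' returned.
#'
#' @param table Ct data.frame with columns `gene_id`, `pool`, `condition`,
#'   `replicate`, `ct`; spike rows use `gene_id == spike`.
#' @param gene gene to quantify.
#' @param pool fraction pool (`total`, `free`, `monosome`, `di_tri`,
#'   `dense_poly`).
#' @param cond_test,cond_ref condition labels (fold = test / ref).
#' @param efficiency amplification efficiency (2 = perfect doubling).
#' @param spike spike-in row label.
#' @return list: `fold`, `per_replicate` folds, `sem`.
#' @export
delta_delta_ct <- function(table, gene, pool, cond_test, cond_ref,
                           efficiency = 2.0, spike = "spike") {
  dct <- function(cond) {
    rows <- table[table$pool == pool & table$condition == cond, , drop = FALSE]
    g <- rows[rows$gene_id == gene, , drop = FALSE]
    s <- rows[rows$gene_id == spike, , drop = FALSE]
    if (nrow(g) == 0)
      stop("missing gene rows for (", gene, ", ", pool, ", ", cond, ")")
    if (nrow(s) == 0)
      stop("missing spike row for (", pool, ", ", cond, ")")
    reps <- sort(unique(g$replicate))
    vapply(reps, function(r) {
      gi <- g$ct[g$replicate == r]
      si <- s$ct[s$replicate == r]
      if (!length(gi) || !length(si))
        stop("missing spike row for (", pool, ", ", cond, ", replicate ", r, ")")
      mean(gi) - mean(si)
    }, numeric(1))
  }
  d_test <- dct(cond_test)
  d_ref <- dct(cond_ref)
  fold <- efficiency^-(mean(d_test) - mean(d_ref))
  per <- if (length(d_test) == length(d_ref))
    efficiency^-(d_test - d_ref) else NULL
  list(fold = fold, per_replicate = per,
       sem = if (!is.null(per) && length(per) > 1)
         sd(per) / sqrt(length(per)) else NA_real_)
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates the polysome-fraction RT-qPCR: each well's Ct is
#' \eqn{c_0 - \log_2(abundance)} plus Gaussian noise, and every
#' (pool, condition, replicate) group carries one spike row derived from the
#' constant spike amount (the 2 ng in-vitro transcript added per fraction).
#'
#' @param abundances data.frame with columns `gene_id`, `pool`, `condition`,
#'   `abundance` (> 0, arbitrary units).
#' @param spike_amount constant spike-in abundance.
#' @param ct_noise_sd Gaussian Ct noise (cycles).
#' @param n_replicates replicates per group.
#' @param c0 Ct of one abundance unit.
#' @param seed RNG seed.
#' @return Ct data.frame suitable for [delta_delta_ct()].
#' @export
generate_ct_table <- function(abundances, spike_amount = 2,
                              ct_noise_sd = 0.2, n_replicates = 3,
                              c0 = 30, seed = 1) {
  if (any(abundances$abundance <= 0)) stop("abundances must be positive")
  set.seed(seed)
  groups <- unique(abundances[c("pool", "condition")])
  rows <- list()
  for (gi in seq_len(nrow(groups))) {
    p <- groups$pool[gi]; cond <- groups$condition[gi]
    sub <- abundances[abundances$pool == p & abundances$condition == cond, ]
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = c(sub$gene_id, "spike"), pool = p, condition = cond,
        replicate = r,
        ct = c0 - log2(c(sub$abundance, spike_amount)) +
          rnorm(nrow(sub) + 1, 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
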