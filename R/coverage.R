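#' Construct a per-gene footprint profile
#'
#' A gene profile holds per-nucleotide footprint counts along one CDS in one
#' library. Position 1 is the first nucleotide of the start codon; the vector
#' length equals the CDS length.
#'
#' @param gene_id gene identifier.
#' @param counts non-negative numeric vector, one entry per CDS nucleotide.
#' @param library_id library identifier.
#' @return object of class `gene_profile`.
#' @export
gene_profile <- function(gene_id, counts, library_id = "lib1") {
  if (any(counts < 0)) stop("negative counts in profile for ", gene_id)
  structure(list(gene_id = gene_id, library_id = library_id,
                 counts = as.numeric(counts)),
            class = "gene_profile")
}

#' @export
print.gene_profile <- function(x, ...) {
  cat(sprintf("<gene_profile> %s [%s]: %d nt, %.6g reads\n",
              x$gene_id, x$library_id, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Read per-nucleotide CDS coverage
#'
#' Accepts two plain-text dialects in transcript (CDS) space:
#' \describe{
#'   \item{tsv}{long format with header `gene_id  position  count`,
#'     1-based positions.}
#'   \item{bedgraph}{four columns `gene_id  start  end  count` with 0-based
#'     half-open intervals, the bedGraph convention applied along the CDS.}
#' }
#' Positions absent from the file are zero-filled; positions outside the
#' annotated CDS are dropped with a warning; negative counts are an error.
#'
#' @param path file path.
#' @param genes gene model table ([gene_models()]).
#' @param library_id library identifier attached to each profile.
#' @param format `"tsv"`, `"bedgraph"`, or `"auto"` (sniffed from the header).
#' @param p_site_offset nucleotides added to each recorded position to reach
#'   the inferred P-site (real libraries record 5' read ends; the offset
#'   depends on footprint size and protocol and must be supplied by the
#'   user). Default 0: the synthetic generator emits P-site positions
#'   directly.
#' @return named list of [gene_profile()] objects, one per gene in `genes`.
#' @export
read_coverage <- function(path, genes, library_id = "lib1", format = "auto",
                          p_site_offset = 0L) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- match.arg(format, c("auto", "tsv", "bedgraph"))
  lines <- readLines(path, warn = FALSE, n = 1)
  if (format == "auto") {
    format <- if (length(lines) && grepl("position", lines[1])) "tsv" else "bedgraph"
  }
  empty <- file.size(path) == 0 ||
    length(readLines(path, warn = FALSE)) == 0
  if (empty) {
    tab <- data.frame(gene_id = character(), position = integer(),
                      count = numeric())
  } else if (format == "tsv") {
    tab <- data.table::fread(path, header = TRUE, sep = "\t",
                             col.names = c("gene_id", "position", "count"),
                             data.table = FALSE)
  } else {
    has_header <- length(lines) && grepl("start|track", lines[1])
    bg <- data.table::fread(path, header = has_header, sep = "\t",
                            data.table = FALSE)
    names(bg) <- c("gene_id", "start", "end", "count")
    n <- bg$end - bg$start
    tab <- data.frame(
      gene_id = rep(bg$gene_id, n),
      position = unlist(lapply(seq_len(nrow(bg)),
                               function(i) seq(bg$start[i] + 1L, bg$end[i]))),
      count = rep(bg$count, n)
    )
  }
  if (nrow(tab) && any(tab$count < 0)) stop("negative count in ", path)
  if (p_site_offset != 0) tab$position <- tab$position + as.integer(p_site_offset)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes$gene_id[i]
    L <- genes$cds_length_nt[i]
    rows <- tab[tab$gene_id == g, , drop = FALSE]
    oob <- rows$position < 1 | rows$position > L
    if (any(oob)) {
      warning(sum(oob), " record(s) outside CDS dropped for ", g)
      rows <- rows[!oob, , drop = FALSE]
    }
    counts <- numeric(L)
    if (nrow(rows))
      counts[rows$position] <- counts[rows$position] + rows$count
    gene_profile(g, counts, library_id)
  })
  names(out) <- genes$gene_id
  out
}

#' Write gene profiles as long-format TSV
#'
#' Emits `gene_id  position  count` rows (nonzero positions only) with a
#' header line; [read_coverage()] round-trips the counts exactly.
#'
#' @param profiles list of [gene_profile()] objects.
#' @param path output path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  tabs <- lapply(profiles, function(p) {
    nz <- which(p$counts > 0)
    if (!length(nz)) return(NULL)
    data.frame(gene_id = p$gene_id, position = nz, count = p$counts[nz])
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab))
    tab <- data.frame(gene_id = character(), position = integer(),
                      count = numeric())
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Depth-normalize a profile to reads per million
#'
#' Each count is multiplied by `1e6 / total_mapped_reads` (the library's
#' total), the usual rpm scaling for per-nucleotide footprint traces.
#'
#' @param profile a [gene_profile()].
#' @param meta a [library_meta()] (or a positive total read count).
#' @return a rpm-scaled [gene_profile()].
#' @export
rpm_normalize <- function(profile, meta) {
  total <- if (inherits(meta, "library_meta")) meta$total_mapped_reads else meta
  if (is.null(total) || total <= 0) stop("total_mapped_reads must be > 0")
  gene_profile(profile$gene_id, profile$counts * 1e6 / total,
               profile$library_id)
}

total_reads <- function(profiles) {
  sum(vapply(profiles, function(p) sum(p$counts), numeric(1)))
}
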