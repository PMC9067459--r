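#' Gene model table
#'
#' Builds the per-gene annotation table used throughout the package. Internal
#' coordinates are 1-based along the CDS: position 1 is the A of the AUG, and
#' minus-strand genes are stored 5'->3' of the mRNA. Genomic coordinates only
#' appear at the I/O boundary ([read_gff_cds()]).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param cds_length_nt positive integer CDS lengths in nucleotides.
#' @param tags optional character vector of labels (e.g. "stress_induced",
#'   "glycolytic", "ribi"); `""` for untagged genes.
#' @param copies optional baseline mRNA copy numbers (used by the simulator).
#' @return data.frame with columns `gene_id`, `cds_length_nt`, `tags`,
#'   `copies`.
#' @export
gene_models <- function(gene_id, cds_length_nt, tags = "", copies = 1) {
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (any(cds_length_nt < 3)) stop("cds_length_nt must be >= 3")
  if (any(cds_length_nt %% 3 != 0))
    warning("some CDS lengths are not divisible by 3")
  data.frame(
    gene_id = as.character(gene_id),
    cds_length_nt = as.integer(cds_length_nt),
    tags = rep_len(as.character(tags), length(gene_id)),
    copies = rep_len(as.numeric(copies), length(gene_id)),
    stringsAsFactors = FALSE
  )
}

#' Library metadata record
#'
#' @param library_id library identifier.
#' @param condition one of `log_phase`, `starvation`, `readdition`, `heat`,
#'   `oxidative`, `aa_starvation`, `postdiauxic`, `stationary`.
#' @param timepoint_min minutes since stress onset (0 for log phase).
#' @param chx_pretreated logical; cycloheximide pretreatment before harvest.
#' @param total_mapped_reads positive total mapped read count of the library.
#' @return a `library_meta` list.
#' @export
library_meta <- function(library_id, condition = "log_phase",
                         timepoint_min = 0, chx_pretreated = FALSE,
                         total_mapped_reads = 1e6) {
  conditions <- c("log_phase", "starvation", "readdition", "heat",
                  "oxidative", "aa_starvation", "postdiauxic", "stationary")
  condition <- match.arg(condition, conditions)
  if (total_mapped_reads <= 0) stop("total_mapped_reads must be > 0")
  structure(
    list(library_id = library_id, condition = condition,
         timepoint_min = timepoint_min, chx_pretreated = chx_pretreated,
         total_mapped_reads = total_mapped_reads),
    class = "library_meta"
  )
}

#' Read CDS gene models from a GFF3 file
#'
#' Parses CDS features and sums segment lengths per parent gene. GFF3
#' coordinates (1-based inclusive, genomic) are converted to internal CDS
#' lengths; multi-exon minus-strand genes are handled by summing widths, and
#' coverage mapping for such genes orders positions 5'->3' along the mRNA.
#'
#' @param path GFF3 file path.
#' @return a gene model data.frame (see [gene_models()]) with extra columns
#'   `chrom` and `strand`.
#' @export
read_gff_cds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == "CDS"]
    if (length(gr) == 0) stop("no CDS features in ", path)
    parent <- .gff_parent_ids(gr)
    wd <- GenomicRanges::width(gr)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    strand <- as.character(GenomicRanges::strand(gr))
    seg_start <- GenomicRanges::start(gr)
    seg_end <- GenomicRanges::end(gr)
  } else {
    tab <- .read_gff_table(path)
    tab <- tab[tab$type == "CDS", , drop = FALSE]
    if (nrow(tab) == 0) stop("no CDS features in ", path)
    parent <- .gff_attr_parent(tab$attributes)
    wd <- tab$end - tab$start + 1L
    chrom <- tab$seqid
    strand <- tab$strand
    seg_start <- tab$start
    seg_end <- tab$end
  }
  len <- tapply(wd, parent, sum)
  first <- !duplicated(parent)
  out <- data.frame(
    gene_id = names(len),
    cds_length_nt = as.integer(len),
    tags = "",
    copies = 1,
    chrom = chrom[first][match(names(len), parent[first])],
    strand = strand[first][match(names(len), parent[first])],
    stringsAsFactors = FALSE
  )
  bad <- out$cds_length_nt %% 3 != 0
  if (any(bad))
    warning("CDS length not divisible by 3 for: ",
            paste(out$gene_id[bad], collapse = ", "))
  rownames(out) <- NULL
  seg <- data.frame(gene_id = parent, start = seg_start, end = seg_end,
                    strand = strand, stringsAsFactors = FALSE)
  attr(out, "segments") <- split(seg, seg$gene_id)
  out
}

#' Map a genomic position to a 1-based CDS position
#'
#' Uses the CDS segments recorded by [read_gff_cds()]. For minus-strand genes
#' segments are walked 5'->3' of the mRNA (descending genomic coordinate), so
#' the returned position 1 is always the first nucleotide of the start codon.
#'
#' @param models gene model table from [read_gff_cds()].
#' @param gene_id single gene identifier.
#' @param genomic_pos vector of 1-based genomic positions.
#' @return integer CDS positions (NA for positions outside the CDS).
#' @export
genomic_to_cds <- function(models, gene_id, genomic_pos) {
  segs <- attr(models, "segments")[[gene_id]]
  if (is.null(segs)) stop("no segments recorded for gene ", gene_id)
  minus <- segs$strand[1] == "-"
  segs <- segs[order(segs$start, decreasing = minus), , drop = FALSE]
  offs <- cumsum(c(0L, segs$end - segs$start + 1L))
  vapply(genomic_pos, function(p) {
    for (i in seq_len(nrow(segs))) {
      if (p >= segs$start[i] && p <= segs$end[i]) {
        within <- if (minus) segs$end[i] - p else p - segs$start[i]
        return(as.integer(offs[i] + within + 1L))
      }
    }
    NA_integer_
  }, integer(1))
}

.gff_parent_ids <- function(gr) {
  md <- S4Vectors::mcols(gr)
  p <- if ("Parent" %in% names(md)) md$Parent else md$ID
  p <- vapply(as.list(p), function(x) {
    if (length(x) == 0 || is.na(x[1])) NA_character_ else as.character(x[1])
  }, character(1))
  sub("_mRNA$|_CDS$|\\.1$", "", p)
}

# Fallback GFF3 reader (tab-separated, '#' comments), with line numbers in
# parse errors.
.read_gff_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9))
    stop("malformed GFF line ", keep[which(nf != 9)[1]], " in ", path)
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end))
    stop("malformed GFF line ", keep[which(is.na(start) | is.na(end))[1]],
         " in ", path)
  data.frame(seqid = m[, 1], type = m[, 3], start = start, end = end,
             strand = m[, 7], attributes = m[, 9], stringsAsFactors = FALSE)
}

.gff_attr_parent <- function(attrs) {
  p <- sub(".*(?:Parent|ID)=([^;]+).*", "\\1", attrs)
  sub("_mRNA$|_CDS$|\\.1$", "", p)
}
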