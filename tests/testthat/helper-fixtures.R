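# Fixtures are built in code at test time; nothing binary is stored.

# one single-exon plus-strand gene, GFF3
write_toy_gff_single <- function(path, start = 101, end = 130) {
  writeLines(c(
    "##gff-version 3",
    "chrI\ttoy\tgene\t1\t500\t.\t+\t.\tID=gA",
    sprintf("chrI\ttoy\tCDS\t%d\t%d\t.\t+\t0\tID=gA_CDS;Parent=gA", start, end)
  ), path)
  path
}

# two CDS segments (60 + 90 nt) on the plus strand
write_toy_gff_twoexon <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chrI\ttoy\tgene\t100\t400\t.\t+\t.\tID=gB",
    "chrI\ttoy\tCDS\t100\t159\t.\t+\t0\tID=gB_CDS;Parent=gB",
    "chrI\ttoy\tCDS\t250\t339\t.\t+\t0\tID=gB_CDS;Parent=gB"
  ), path)
  path
}

# 10-codon (30 nt) minus-strand gene split into two exons: 18 nt at
# genomic 200..217 (3'-ward in mRNA: positions 13..30) and 12 nt at
# 300..311 (mRNA positions 1..12, position 1 at genomic 311).
write_toy_gff_minus <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chrII\ttoy\tgene\t200\t311\t.\t-\t.\tID=gM",
    "chrII\ttoy\tCDS\t200\t217\t.\t-\t0\tID=gM_CDS;Parent=gM",
    "chrII\ttoy\tCDS\t300\t311\t.\t-\t0\tID=gM_CDS;Parent=gM"
  ), path)
  path
}

toy_genes <- function() {
  gene_models(c("gA", "gB"), c(6, 9))
}

uniform_profile <- function(L, reads_per_nt = 1, gene_id = "g",
                            library_id = "lib1") {
  gene_profile(gene_id, rep(reads_per_nt, L), library_id)
}

point_profile <- function(L, at, n = 1, gene_id = "g", library_id = "lib1") {
  counts <- numeric(L)
  counts[at] <- n
  gene_profile(gene_id, counts, library_id)
}

# small scenario for fast simulator tests: trimmed panel, 2 copies
small_overrides <- function(...) {
  g <- sim_gene_panel()
  keep <- g$gene_id %in% c("g0600", "gPGK1", "g2400", "g6000", "hs0900")
  c(list(genes = g[keep, ], copies_sim = 2L, burn_in_s = 400,
         sequencing_depth = 2e5), list(...))
}
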