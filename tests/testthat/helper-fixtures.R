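# Shared in-code fixtures: tiny hand-built genomes and random variant tables.

# Single-contig genome with one plus-strand gene: 5'UTR(4) ATG AAA TGG GGA TAA
# 3'UTR(4), all in one exon.
toy_plus_gene <- function() {
  seq <- paste0("TTTT", "ATGAAATGGGGATAA", "CCCC")
  genome <- c(chr1 = seq)
  gene <- gene_model("gA", "chr1", "+", cds = c(5L, 19L),
                     utr5 = c(1L, 4L), utr3 = c(20L, 23L))
  list(genome = genome, gene = gene)
}

# The same coding content on the minus strand: genomic sequence is the
# reverse complement, so coordinates mirror.
toy_minus_gene <- function() {
  plus <- toy_plus_gene()
  seq <- revcomp_str(plus$genome[["chr1"]])
  n <- nchar(seq)
  genome <- c(chr1 = seq)
  gene <- gene_model("gA", "chr1", "-", cds = c(n - 19L + 1L, n - 5L + 1L),
                     utr5 = c(n - 4L + 1L, n), utr3 = c(1L, n - 20L + 1L))
  list(genome = genome, gene = gene)
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# A two-exon minus-strand gene with an intron, for UTR-side and splice-order
# checks.  Coding sequence: ATG AAG TAA (MK*), split 4|5 across two exons.
toy_minus_two_exon <- function() {
  cds_seq <- "ATGAAGTAA"
  genomic_cds <- revcomp_str(cds_seq)                  # TTACTTCAT
  # layout: [3'utr 1-3][cds2 4-8][intron 9-14][cds1 15-18][5'utr 19-22]
  seq <- paste0("GGG", substr(genomic_cds, 1, 5), "TTTTTT",
                substr(genomic_cds, 6, 9), "CCCC")
  genome <- c(chr1 = seq)
  gene <- gene_model("gM", "chr1", "-",
                     cds = matrix(c(4L, 8L, 15L, 18L), ncol = 2, byrow = TRUE),
                     utr5 = c(19L, 22L), utr3 = c(1L, 3L))
  list(genome = genome, gene = gene)
}

TRANSITION_PAIR <- function(b) c(A = "G", G = "A", C = "T", T = "C")[b]

# One-row variant data frame with sane defaults.
make_variant <- function(contig = "chr1", pos = 1L, ref = "A", alt = "G",
                         qual = 200, mq = 60, depth = 30L,
                         alt_forward = 15L, alt_reverse = 14L) {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt, qual = qual,
             mq = mq, depth = depth, alt_forward = alt_forward,
             alt_reverse = alt_reverse, stringsAsFactors = FALSE)
}

# Random variant table with a spread of qualities so filters actually act.
random_variant_table <- function(n, contig = "chr1", max_pos = 1e6L) {
  pos <- sample.int(max_pos, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  depth <- pmax(4L, rnbinom(n, mu = 33, size = 50))
  altn <- pmin(depth, rbinom(n, depth, runif(n, 0.5, 1)))
  fwd <- rbinom(n, altn, 0.5)
  data.frame(contig = contig, pos = pos, ref = ref, alt = unname(alt),
             qual = runif(n, 0, 400), mq = runif(n, 0, 60), depth = depth,
             alt_forward = fwd, alt_reverse = altn - fwd,
             stringsAsFactors = FALSE)
}

random_strain_set <- function(n, id = "s1") {
  v <- random_variant_table(n)
  v <- v[!duplicated(paste(v$contig, v$pos)), , drop = FALSE]
  strain_variant_set(id, v)
}

# Small default-shaped config scaled down for fast unit tests.
small_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, genome_length = 2e5, n_genes = 30,
             n_background_mutations_per_strain = 10,
             n_shared_false_positives = 50, n_panel_private_per_line = 5, ...)
}
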