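#' Read a genome from FASTA
#'
#' Sequences are uppercased on read; contig ids are taken up to the first
#' whitespace of each header.
#'
#' @param path FASTA file.
#' @return named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) stop("duplicate contig ids in ", path)
  if (any(nchar(seqs) == 0L)) stop("empty sequence in ", path)
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# CDS phase column: bases of the previous CDS segment(s), in coding order,
# that overhang the last complete codon.
cds_phases <- function(gene) {
  segs <- gene$cds
  ord <- if (gene$strand == "+") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
  lens <- segs[ord, 2L] - segs[ord, 1L] + 1L
  before <- cumsum(c(0L, lens))[seq_along(lens)]
  phase <- (3L - before %% 3L) %% 3L
  phase[order(ord)]   # back to genomic order
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR features,
#' 1-based inclusive, with the CDS phase column populated.
#'
#' @param genes list of [gene_model()].
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    span <- gene_span(g)
    mrna_id <- paste0(g$gene_id, ".t1")
    add <- function(type, start, end, id = NA, parent = NA, phase = NA) {
      data.frame(contig = g$contig, type = type, start = start, end = end,
                 strand = g$strand, id = id, parent = parent, phase = phase,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add("gene", span[1L], span[2L], id = g$gene_id)
    rows[[length(rows) + 1L]] <- add("mRNA", span[1L], span[2L], id = mrna_id,
                                     parent = g$gene_id)
    for (i in seq_len(nrow(g$exons)))
      rows[[length(rows) + 1L]] <- add("exon", g$exons[i, 1L], g$exons[i, 2L],
                                       parent = mrna_id)
    ph <- cds_phases(g)
    for (i in seq_len(nrow(g$cds)))
      rows[[length(rows) + 1L]] <- add("CDS", g$cds[i, 1L], g$cds[i, 2L],
                                       parent = mrna_id, phase = ph[i])
    for (i in seq_len(nrow(g$utr5)))
      rows[[length(rows) + 1L]] <- add("five_prime_UTR", g$utr5[i, 1L],
                                       g$utr5[i, 2L], parent = mrna_id)
    for (i in seq_len(nrow(g$utr3)))
      rows[[length(rows) + 1L]] <- add("three_prime_UTR", g$utr3[i, 1L],
                                       g$utr3[i, 2L], parent = mrna_id)
  }
  if (length(rows) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$id
  S4Vectors::mcols(gr)$Parent <- df$parent
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Assembles [gene_model()] objects from CDS/UTR/exon features grouped by
#' parent mRNA (one transcript per gene expected).  Genes whose total CDS
#' length is not divisible by 3, or that violate segment invariants, are
#' excluded with a warning naming the gene.
#'
#' @param path GFF3 file.
#' @return list of `gene_model`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (nrow(df) == 0L) return(list())
  parent <- vapply(as.list(df$Parent %||% list()), function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))
  id <- as.character(df$ID)
  # map mRNA -> gene
  mrna <- df$type == "mRNA"
  mrna_gene <- setNames(parent[mrna], id[mrna])
  feat <- df[df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ]
  feat_parent <- parent[df$type %in% c("exon", "CDS", "five_prime_UTR",
                                       "three_prime_UTR")]
  genes <- list()
  for (m in names(mrna_gene)) {
    sub <- feat[feat_parent == m, , drop = FALSE]
    cds <- sub[sub$type == "CDS", c("start", "end"), drop = FALSE]
    if (nrow(cds) == 0L) next
    gid <- unname(mrna_gene[[m]])
    g <- tryCatch(
      gene_model(gid, as.character(sub$seqnames[1L]),
                 as.character(sub$strand[1L]),
                 as.matrix(cds),
                 utr5 = as.matrix(sub[sub$type == "five_prime_UTR",
                                      c("start", "end"), drop = FALSE]),
                 utr3 = as.matrix(sub[sub$type == "three_prime_UTR",
                                      c("start", "end"), drop = FALSE]),
                 exons = as.matrix(sub[sub$type == "exon",
                                       c("start", "end"), drop = FALSE])),
      error = function(e) {
        warning("gene ", gid, " unannotatable, excluded: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(g)) genes[[length(genes) + 1L]] <- g
  }
  genes
}

#' Export variants to BED (0-based half-open)
#'
#' @param variants data frame with contig/pos/ref/alt.
#' @param path output file.
#' @export
write_bed <- function(variants, path) {
  v <- variants[order(variants$contig, variants$pos, variants$alt), ,
                drop = FALSE]
  df <- data.frame(chrom = v$contig, start = v$pos - 1L, end = v$pos,
                   name = paste0(v$ref, ">", v$alt))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
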