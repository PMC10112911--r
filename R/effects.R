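classify_consequence <- function(ref_aa, alt_aa, codon_index) {
  if (ref_aa == alt_aa) "silent"
  else if (codon_index == 1L && ref_aa == "M") "start_loss"
  else if (alt_aa == "*" && ref_aa != "*") "nonsense"
  else if (ref_aa == "*" && alt_aa != "*") "stop_loss"
  else "missense"
}

#' Locate a variant relative to gene models
#'
#' Region classes partition the genome for a fixed gene set: a position is
#' `CDS` when strictly inside a CDS segment, `utr5`/`utr3` when inside an
#' exon but outside the CDS (side determined on the coding strand), `intron`
#' inside the gene span but in no exon, `intergenic` outside all genes.
#' When several genes overlap the position, the gene with the
#' lexicographically smallest id is reported and `ambiguous` is flagged
#' (use [annotate_variants()] for one record per overlapping gene).
#'
#' @param v one-row variant data frame (needs `contig`, `pos`).
#' @param genes list of [gene_model()].
#' @return list with `gene_id` (or `NA`), `region`, `ambiguous` flag.
#' @export
locate_variant <- function(v, genes) {
  hits <- list()
  for (g in genes) {
    if (g$contig != v$contig) next
    span <- gene_span(g)
    if (v$pos < span[1L] || v$pos > span[2L]) next
    hits[[length(hits) + 1L]] <- list(gene_id = g$gene_id,
                                      region = region_in_gene(v$pos, g))
  }
  if (length(hits) == 0L)
    return(list(gene_id = NA_character_, region = "intergenic",
                ambiguous = FALSE))
  ord <- order(vapply(hits, `[[`, character(1), "gene_id"))
  first <- hits[[ord[1L]]]
  if (length(hits) > 1L)
    message("position ", v$contig, ":", v$pos, " overlaps ", length(hits),
            " genes; reporting ", first$gene_id)
  list(gene_id = first$gene_id, region = first$region,
       ambiguous = length(hits) > 1L)
}

region_in_gene <- function(pos, g) {
  if (in_segments(pos, g$cds)) return("CDS")
  in_exon <- in_segments(pos, g$exons)
  if (in_exon) {
    cds_lo <- min(g$cds[, 1L]); cds_hi <- max(g$cds[, 2L])
    if (g$strand == "+") {
      if (pos < cds_lo) "utr5" else "utr3"
    } else {
      if (pos > cds_hi) "utr5" else "utr3"
    }
  } else "intron"
}

#' Codon-level effect of a CDS variant
#'
#' Builds the spliced coding sequence (reverse-complemented for minus-strand
#' genes), substitutes the strand-corrected alt base at the variant's CDS
#' offset and translates the affected codon under the standard nuclear code.
#'
#' @param v one-row variant data frame.
#' @param gene a [gene_model()] whose CDS contains `v$pos`.
#' @param genome named character vector of contig sequences.
#' @return one-row effect data frame: variant key columns, `gene_id`,
#'   `region = "CDS"`, `consequence` (silent/missense/nonsense/stop_loss/
#'   start_loss), `codon_index`, `ref_aa`, `alt_aa` and `notation` such as
#'   `"K302E"` or `"W190*"`.
#' @export
annotate_cds_effect <- function(v, gene, genome) {
  if (cds_length(gene) %% 3L != 0L)
    stop("gene ", gene$gene_id, " is unannotatable (CDS length not multiple of 3)")
  offset <- genomic_to_cds(gene, v$pos)
  if (is.na(offset))
    stop("variant ", v$contig, ":", v$pos, " is not in the CDS of ",
         gene$gene_id)
  genome_base <- substr(genome[[v$contig]], v$pos, v$pos)
  if (genome_base != v$ref)
    stop("REF mismatch at ", v$contig, ":", v$pos, " (genome ", genome_base,
         ", variant ", v$ref, ")")
  cds <- spliced_cds(gene, genome)
  coding_alt <- if (gene$strand == "+") v$alt else comp_base(v$alt)
  codon_index <- (offset - 1L) %/% 3L + 1L
  within <- (offset - 1L) %% 3L + 1L
  start <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds, start, start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- coding_alt
  ref_aa <- unname(CODON_TABLE[[ref_codon]])
  alt_aa <- unname(CODON_TABLE[[alt_codon]])
  consequence <- classify_consequence(ref_aa, alt_aa, codon_index)
  data.frame(contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
             gene_id = gene$gene_id, region = "CDS",
             consequence = consequence, codon_index = codon_index,
             ref_aa = ref_aa, alt_aa = alt_aa,
             notation = paste0(ref_aa, codon_index, alt_aa),
             stringsAsFactors = FALSE)
}

#' Annotate a variant table against all overlapping genes
#'
#' Emits one effect record per (variant, overlapping gene) pair; variants
#' overlapping no gene get a single intergenic record.  CDS records carry
#' codon-level consequences from [annotate_cds_effect()].
#'
#' @param variants variant data frame.
#' @param genes list of [gene_model()].
#' @param genome named character vector of contig sequences.
#' @return effect data frame (columns as in [annotate_cds_effect()], with
#'   `NA` consequence fields outside CDS).
#' @export
annotate_variants <- function(variants, genes, genome) {
  template <- data.frame(contig = character(), pos = integer(),
                         ref = character(), alt = character(),
                         gene_id = character(), region = character(),
                         consequence = character(), codon_index = integer(),
                         ref_aa = character(), alt_aa = character(),
                         notation = character(), stringsAsFactors = FALSE)
  if (nrow(variants) == 0L) return(template)
  spans <- if (length(genes))
    GenomicRanges::GRanges(
      vapply(genes, `[[`, character(1), "contig"),
      IRanges::IRanges(vapply(genes, function(g) gene_span(g)[1L], integer(1)),
                       vapply(genes, function(g) gene_span(g)[2L], integer(1))))
  else GenomicRanges::GRanges()
  vr <- GenomicRanges::GRanges(variants$contig,
                               IRanges::IRanges(variants$pos, variants$pos))
  ov <- GenomicRanges::findOverlaps(vr, spans)
  rows <- list()
  hit_v <- S4Vectors::queryHits(ov); hit_g <- S4Vectors::subjectHits(ov)
  for (j in seq_along(hit_v)) {
    v <- variants[hit_v[j], , drop = FALSE]
    g <- genes[[hit_g[j]]]
    region <- region_in_gene(v$pos, g)
    if (region == "CDS" && cds_length(g) %% 3L == 0L) {
      rows[[length(rows) + 1L]] <- annotate_cds_effect(v, g, genome)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
        gene_id = g$gene_id, region = region, consequence = NA_character_,
        codon_index = NA_integer_, ref_aa = NA_character_,
        alt_aa = NA_character_, notation = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  no_gene <- setdiff(seq_len(nrow(variants)), unique(hit_v))
  for (i in no_gene) {
    v <- variants[i, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
      gene_id = NA_character_, region = "intergenic",
      consequence = NA_character_, codon_index = NA_integer_,
      ref_aa = NA_character_, alt_aa = NA_character_,
      notation = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$pos, out$alt, out$gene_id,
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
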