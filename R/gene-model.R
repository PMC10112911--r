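#' Construct a gene model
#'
#' A gene model is a strand-aware set of genomic segments: CDS, optional
#' 5'/3' UTRs and exons, all 1-based inclusive and stored in genomic order.
#' UTR sides are named relative to the coding strand (a minus-strand gene's
#' 5' UTR lies genomically downstream of its CDS).
#'
#' @param gene_id identifier.
#' @param contig contig identifier.
#' @param strand `"+"` or `"-"`.
#' @param cds two-column integer matrix of (start, end) segments.
#' @param utr5,utr3,exons same encoding; `exons` defaults to the union of
#'   CDS and UTR segments merged where adjacent.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, cds,
                       utr5 = NULL, utr3 = NULL, exons = NULL) {
  stopifnot(strand %in% c("+", "-"))
  cds <- as_segments(cds)
  utr5 <- as_segments(utr5)
  utr3 <- as_segments(utr3)
  if (nrow(cds) == 0L) stop("gene ", gene_id, ": CDS is empty")
  if (is.null(exons)) exons <- merge_segments(rbind(cds, utr5, utr3))
  else exons <- as_segments(exons)
  g <- structure(list(gene_id = gene_id, contig = contig, strand = strand,
                      cds = cds, utr5 = utr5, utr3 = utr3, exons = exons),
                 class = "gene_model")
  validate_gene_model(g)
  g
}

as_segments <- function(x) {
  if (is.null(x) || length(x) == 0L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  m <- matrix(as.integer(x), ncol = 2L)
  colnames(m) <- c("start", "end")
  m[order(m[, 1L]), , drop = FALSE]
}

merge_segments <- function(m) {
  m <- as_segments(m)
  if (nrow(m) <= 1L) return(m)
  out <- m[1L, , drop = FALSE]
  for (i in 2L:nrow(m)) {
    if (m[i, 1L] <= out[nrow(out), 2L] + 1L)
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], m[i, 2L])
    else out <- rbind(out, m[i, , drop = FALSE])
  }
  out
}

validate_gene_model <- function(g) {
  for (nm in c("cds", "utr5", "utr3", "exons")) {
    m <- g[[nm]]
    if (nrow(m) == 0L) next
    if (any(m[, 2L] < m[, 1L]))
      stop("gene ", g$gene_id, ": ", nm, " segment with end < start")
    if (nrow(m) > 1L && any(m[-1L, 1L] <= m[-nrow(m), 2L]))
      stop("gene ", g$gene_id, ": overlapping ", nm, " segments")
  }
  if (cds_length(g) %% 3L != 0L)
    stop("gene ", g$gene_id, ": CDS length ", cds_length(g),
         " not divisible by 3")
  # CDS must be covered by exons
  for (i in seq_len(nrow(g$cds))) {
    covered <- any(g$exons[, 1L] <= g$cds[i, 1L] & g$exons[, 2L] >= g$cds[i, 2L])
    if (!covered) stop("gene ", g$gene_id, ": CDS segment outside exons")
  }
  invisible(g)
}

cds_length <- function(gene) {
  if (nrow(gene$cds) == 0L) return(0L)
  sum(gene$cds[, 2L] - gene$cds[, 1L] + 1L)
}

gene_span <- function(gene) {
  segs <- rbind(gene$exons, gene$cds)
  c(min(segs[, 1L]), max(segs[, 2L]))
}

in_segments <- function(pos, m) {
  nrow(m) > 0L && any(pos >= m[, 1L] & pos <= m[, 2L])
}

#' Spliced coding sequence of a gene
#'
#' Concatenates the CDS segments and reverse-complements for minus-strand
#' genes, yielding the mRNA-order coding sequence.
#'
#' @param gene a `gene_model`.
#' @param genome named character vector of contig sequences.
#' @return character scalar.
#' @export
spliced_cds <- function(gene, genome) {
  seq <- genome[[gene$contig]]
  parts <- substring(seq, gene$cds[, 1L], gene$cds[, 2L])
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

# 1-based offset within the coding sequence -> genomic position.
cds_to_genomic <- function(gene, offset) {
  stopifnot(offset >= 1L, offset <= cds_length(gene))
  segs <- gene$cds
  ord <- if (gene$strand == "+") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
  for (i in ord) {
    len <- segs[i, 2L] - segs[i, 1L] + 1L
    if (offset <= len) {
      return(unname(if (gene$strand == "+") segs[i, 1L] + offset - 1L
                    else segs[i, 2L] - offset + 1L))
    }
    offset <- offset - len
  }
  stop("unreachable")
}

# Genomic position -> 1-based coding-sequence offset (NA if outside CDS).
genomic_to_cds <- function(gene, pos) {
  segs <- gene$cds
  ord <- if (gene$strand == "+") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
  before <- 0L
  for (i in ord) {
    len <- segs[i, 2L] - segs[i, 1L] + 1L
    if (pos >= segs[i, 1L] && pos <= segs[i, 2L]) {
      within <- if (gene$strand == "+") pos - segs[i, 1L] + 1L
                else segs[i, 2L] - pos + 1L
      return(unname(before + within))
    }
    before <- before + len
  }
  NA_integer_
}

#' @exportS3Method base::print
print.gene_model <- function(x, ...) {
  span <- gene_span(x)
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), CDS %d bp in %d segment(s)\n",
              x$gene_id, x$contig, span[1L], span[2L], x$strand,
              cds_length(x), nrow(x$cds)))
  invisible(x)
}
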