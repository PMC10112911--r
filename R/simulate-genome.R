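NON_STOP_CODONS <- names(CODON_TABLE)[CODON_TABLE != "*"]
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Random coding sequence: ATG, internal non-stop codons, terminal stop.
random_cds_seq <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  n_internal <- len %/% 3L - 2L
  paste0("ATG",
         paste(sample(NON_STOP_CODONS, n_internal, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

# sample() treats a scalar x as 1:x; guard ranges whose bounds coincide.
sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(lo, n) else sample(lo:hi, n, replace = TRUE)
}

# Random composition of `total` into `k` parts each >= min_part.
random_partition <- function(total, k, min_part) {
  stopifnot(total >= k * min_part)
  if (k == 1L) return(total)
  extra <- total - k * min_part
  cuts <- sort(sample.int(extra + k - 1L, k - 1L))
  parts <- diff(c(0L, cuts, extra + k)) - 1L + min_part
  parts
}

#' Generate a random genome with gene models
#'
#' Random uppercase ACGT contigs with `n_genes` non-overlapping protein-coding
#' gene models placed on both strands.  Each gene's spliced CDS starts with
#' ATG, ends with a stop codon and contains no internal stop; CDS segments are
#' split at arbitrary (non-codon) boundaries so downstream phase handling is
#' exercised.  Genes carry 5' and 3' UTR segments flanking the CDS.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector of contig sequences),
#'   `genes` (list of [gene_model()] sorted by position) and `config`.
#' @export
make_genome <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    contig_len <- rep(config$genome_length %/% config$n_contigs, config$n_contigs)
    contig_len[config$n_contigs] <- contig_len[config$n_contigs] +
      config$genome_length %% config$n_contigs
    contig_ids <- sprintf("chr%02d", seq_len(config$n_contigs))
    # contigs held as integer character codes during construction; writing a
    # CDS is then O(segment) instead of an O(contig) string copy per segment
    codes <- setNames(lapply(contig_len, function(L) {
      sample(c(65L, 67L, 71L, 84L), L, replace = TRUE)
    }), contig_ids)

    occupied <- setNames(vector("list", config$n_contigs), contig_ids)
    genes <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      placed <- FALSE
      for (attempt in seq_len(500L)) {
        k <- sample_range(config$exon_count_range[1L],
                          config$exon_count_range[2L])
        L <- 3L * sample_range(config$cds_length_range[1L] %/% 3L,
                               config$cds_length_range[2L] %/% 3L)
        cds_parts <- random_partition(L, k, min_part = 10L)
        introns <- if (k > 1L)
          sample_range(config$intron_length_range[1L],
                       config$intron_length_range[2L], k - 1L) else integer()
        utr_len <- sample_range(config$utr_length_range[1L],
                                config$utr_length_range[2L], 2L)
        footprint <- sum(cds_parts) + sum(introns) + sum(utr_len)
        contig <- sample(contig_ids, 1L,
                         prob = contig_len / sum(contig_len))
        if (contig_len[match(contig, contig_ids)] < footprint + 2L) next
        start <- sample.int(contig_len[match(contig, contig_ids)] - footprint, 1L)
        end <- start + footprint - 1L
        occ <- occupied[[contig]]
        clash <- any(vapply(occ, function(iv) start <= iv[2L] && end >= iv[1L],
                            logical(1)))
        if (clash) next
        strand <- sample(c("+", "-"), 1L)
        # Lay out genomically left-to-right: leftUTR, exon1..exonk, rightUTR.
        cds <- matrix(0L, nrow = k, ncol = 2L)
        pos <- start + utr_len[1L]
        for (j in seq_len(k)) {
          cds[j, ] <- c(pos, pos + cds_parts[j] - 1L)
          pos <- pos + cds_parts[j] + if (j < k) introns[j] else 0L
        }
        left_utr <- c(start, start + utr_len[1L] - 1L)
        right_utr <- c(end - utr_len[2L] + 1L, end)
        utr5 <- if (strand == "+") left_utr else right_utr
        utr3 <- if (strand == "+") right_utr else left_utr
        # exons: terminal UTRs fused to terminal CDS segments
        exons <- cds
        exons[1L, 1L] <- start
        exons[k, 2L] <- end
        genes[[i]] <- gene_model(sprintf("gene_%04d", i), contig, strand,
                                 cds, utr5 = matrix(utr5, ncol = 2L),
                                 utr3 = matrix(utr3, ncol = 2L), exons = exons)
        occupied[[contig]] <- c(occ, list(c(start, end)))
        # Write the coding sequence into the contig.
        cds_seq <- random_cds_seq(L)
        genomic_cds <- if (strand == "+") cds_seq else revcomp(cds_seq)
        cds_codes <- utf8ToInt(genomic_cds)
        offset <- 0L
        for (j in seq_len(k)) {
          seg_len <- cds[j, 2L] - cds[j, 1L] + 1L
          codes[[contig]][cds[j, 1L]:cds[j, 2L]] <-
            cds_codes[(offset + 1L):(offset + seg_len)]
          offset <- offset + seg_len
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place gene ", i, " without overlap after 500 attempts; ",
             "increase genome_length or reduce n_genes")
    }
    genome <- setNames(vapply(codes, intToUtf8, character(1)), contig_ids)
    ord <- order(vapply(genes, function(g) g$contig, character(1)),
                 vapply(genes, function(g) gene_span(g)[1L], integer(1)))
    genes <- genes[ord]
    # Re-walking in genomic order keeps downstream gene ids stable: rename.
    for (i in seq_along(genes)) genes[[i]]$gene_id <- sprintf("gene_%04d", i)
    list(genome = genome, genes = genes, config = config)
  })
}

#' Total CDS fraction of a simulated genome
#'
#' @param sim result of [make_genome()].
#' @return fraction of genome bp lying in CDS segments.
#' @export
cds_fraction <- function(sim) {
  cds_bp <- sum(vapply(sim$genes, cds_length, integer(1)))
  cds_bp / sum(nchar(sim$genome))
}
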