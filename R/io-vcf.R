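#' Write a strain variant set to VCF v4.2
#'
#' Single-sample VCF with INFO `DP` (site depth) and `MQ` (mapping quality)
#' and FORMAT `GT:AD:ADF:ADR`.  Records are emitted in deterministic
#' (contig, pos, alt) order.  Reference-allele strand support is not tracked
#' internally, so AD/ADF/ADR reference counts split the non-alt depth evenly.
#'
#' @param strain a `strain_variant_set`.
#' @param path output file.
#' @param genome optional named character vector; contig header lines carry
#'   lengths when supplied.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(strain, path, genome = NULL) {
  v <- strain$variants
  v <- v[order(v$contig, v$pos, v$alt), , drop = FALSE]
  contigs <- if (!is.null(genome))
    sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome))
  else sprintf("##contig=<ID=%s>", unique(v$contig))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mutfunnel",
    contigs,
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Allelic depths, forward strand\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Allelic depths, reverse strand\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", strain$strain_id, sep = "\t"))
  alt_tot <- v$alt_forward + v$alt_reverse
  ref_tot <- v$depth - alt_tot
  ref_f <- ref_tot %/% 2L
  ref_r <- ref_tot - ref_f
  records <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%.6g\tPASS\tDP=%d;MQ=%.6g\tGT:AD:ADF:ADR\t1:%d,%d:%d,%d:%d,%d",
    v$contig, v$pos, v$ref, v$alt, v$qual, v$depth, v$mq,
    ref_tot, alt_tot, ref_f, v$alt_forward, ref_r, v$alt_reverse)
  writeLines(c(header, records), path)
  invisible(path)
}

split_num <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(p) suppressWarnings(as.numeric(p)))
}

#' Read a VCF into a strain variant set
#'
#' Multi-allelic records are split into one variant per alt allele; non-SNV
#' alleles (indels, MNVs, symbolic/spanning alleles) are skipped with a
#' message reporting the count.  Site depth comes from INFO `DP`, mapping
#' quality from INFO `MQ`; per-strand alt support from FORMAT `ADF`/`ADR`
#' (`dialect = "adf_adr"`) or from INFO `DP4` as emitted by common pileup
#' callers (`dialect = "dp4"`: ref-fwd, ref-rev, alt-fwd, alt-rev).
#'
#' @param path VCF v4.x file.
#' @param dialect strand-support encoding; see Details.
#' @param strain_id defaults to the VCF sample name (or the file name).
#' @param genome optional genome; when supplied, reference alleles are
#'   checked and mismatching records dropped with a warning.
#' @return a `strain_variant_set`.
#' @export
read_vcf <- function(path, dialect = c("adf_adr", "dp4"), strain_id = NULL,
                     genome = NULL) {
  dialect <- match.arg(dialect)
  vc <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                 error = function(e) stop("malformed VCF ", path, ": ",
                                          conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(vc, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  sample_name <- if (ncol(vc@gt) >= 2L) colnames(vc@gt)[2L] else NULL
  if (is.null(strain_id))
    strain_id <- sample_name %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  if (nrow(fix) == 0L)
    return(strain_variant_set(strain_id))

  info_field <- function(key) {
    out <- rep(NA_character_, nrow(fix))
    hit <- grepl(paste0("(?:^|;)", key, "="), fix$INFO, perl = TRUE)
    out[hit] <- sub(paste0(".*(?:^|;)", key, "=([^;]+).*"), "\\1",
                    fix$INFO[hit], perl = TRUE)
    out
  }
  dp <- suppressWarnings(as.integer(info_field("DP")))
  mq <- suppressWarnings(as.numeric(info_field("MQ")))
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  gt_field <- function(key) {
    if (ncol(vc@gt) < 2L) return(rep(NA_character_, nrow(fix)))
    fmt <- strsplit(vc@gt[, 1L], ":", fixed = TRUE)
    val <- strsplit(vc@gt[, 2L], ":", fixed = TRUE)
    vapply(seq_len(nrow(fix)), function(i) {
      j <- match(key, fmt[[i]])
      if (is.na(j) || j > length(val[[i]])) NA_character_ else val[[i]][j]
    }, character(1))
  }
  adf <- if (dialect == "adf_adr") split_num(gt_field("ADF")) else NULL
  adr <- if (dialect == "adf_adr") split_num(gt_field("ADR")) else NULL
  dp4 <- if (dialect == "dp4") split_num(info_field("DP4")) else NULL

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  rows <- list()
  n_skipped <- 0L
  n_dropped <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- fix$REF[i]
    for (k in seq_along(alts[[i]])) {
      alt <- alts[[i]][k]
      if (nchar(ref) != 1L || nchar(alt) != 1L ||
          !ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (dialect == "adf_adr") {
        af <- adf[[i]][k + 1L]; ar <- adr[[i]][k + 1L]
      } else {
        af <- dp4[[i]][3L]; ar <- dp4[[i]][4L]
        if (is.null(dp) || is.na(dp[i]))
          dp[i] <- as.integer(sum(dp4[[i]]))
      }
      if (is.na(dp[i]) || is.na(af) || is.na(ar)) {
        warning("record ", fix$CHROM[i], ":", fix$POS[i],
                " lacks depth/strand support; excluded", call. = FALSE)
        n_dropped <- n_dropped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = ref,
        alt = alt, qual = if (is.na(qual[i])) 0 else qual[i],
        mq = if (is.na(mq[i])) 0 else mq[i], depth = dp[i],
        alt_forward = as.integer(af), alt_reverse = as.integer(ar),
        stringsAsFactors = FALSE)
    }
  }
  if (n_skipped > 0L)
    message(n_skipped, " non-SNV allele(s) skipped in ", basename(path))
  v <- if (length(rows)) do.call(rbind, rows) else empty_variants()
  if (!is.null(genome) && nrow(v) > 0L) {
    ok <- substring(genome[v$contig], v$pos, v$pos) == v$ref
    if (any(!ok)) {
      warning(sum(!ok), " record(s) with REF not matching the genome dropped",
              call. = FALSE)
      v <- v[ok, , drop = FALSE]
    }
  }
  strain_variant_set(strain_id, v)
}

#' Write simulation truth, family and count tables as TSV
#'
#' Convenience writers for the simulator's tabular outputs.
#'
#' @param x data frame (or matrix for counts, written with row names).
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x)) {
    df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
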