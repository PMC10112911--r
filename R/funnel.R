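#' Quality-filter configuration
#'
#' The five-filter rule used on strain-unique variants: site depth within
#' ±`depth_band_fraction` of the genome mean (closed interval), mapping
#' quality strictly above `min_mq`, call quality strictly above `min_qual`,
#' alt read fraction strictly above `min_alt_fraction`, and at least
#' `min_per_strand` alt-supporting reads on each sequencing strand.
#'
#' @param depth_band_fraction half-width of the depth band as a fraction of
#'   the mean (default 0.5).
#' @param min_mq mapping-quality threshold, strict (default 20).
#' @param min_qual call-quality threshold, strict (default 50).
#' @param min_alt_fraction alt-fraction threshold, strict (default 0.9).
#' @param require_both_strands require alt support on both strands.
#' @param min_per_strand minimum alt reads per strand when required.
#' @param genome_mean_depth explicit mean depth; when `NULL` it is computed
#'   from the strain's own variant records by [compute_mean_depth()].
#' @return object of class `filter_config`.
#' @export
filter_config <- function(depth_band_fraction = 0.5, min_mq = 20,
                          min_qual = 50, min_alt_fraction = 0.9,
                          require_both_strands = TRUE, min_per_strand = 1L,
                          genome_mean_depth = NULL) {
  stopifnot(depth_band_fraction > 0, depth_band_fraction < 1,
            min_mq >= 0, min_qual >= 0, min_alt_fraction >= 0,
            min_per_strand >= 1L)
  structure(list(depth_band_fraction = depth_band_fraction, min_mq = min_mq,
                 min_qual = min_qual, min_alt_fraction = min_alt_fraction,
                 require_both_strands = isTRUE(require_both_strands),
                 min_per_strand = as.integer(min_per_strand),
                 genome_mean_depth = genome_mean_depth),
            class = "filter_config")
}

#' Remove variants shared with the sibling-line panel
#'
#' @param strain a `strain_variant_set`.
#' @param panel a [panel_index()].
#' @param match_mode `"allele_exact"` matches on (contig, pos, ref, alt);
#'   `"position_only"` on (contig, pos).
#' @return the strain set minus panel-matching variants, order preserved.
#' @export
subtract_panel <- function(strain, panel,
                           match_mode = c("allele_exact", "position_only")) {
  match_mode <- match.arg(match_mode)
  v <- strain$variants
  if (nrow(v) == 0L || nrow(panel$keys) == 0L) return(strain)
  hit <- if (match_mode == "allele_exact")
    variant_key(v) %in% variant_key(panel$keys)
  else position_key(v) %in% position_key(panel$keys)
  strain_variant_set(strain$strain_id, v[!hit, , drop = FALSE])
}

#' Mean site depth of a strain's variant records
#'
#' Arithmetic mean of per-variant DP; the per-strain stand-in for the
#' genome-wide mean coverage when no alignment-level estimate is supplied.
#'
#' @param strain a `strain_variant_set`.
#' @return mean depth (reads).
#' @export
compute_mean_depth <- function(strain) {
  if (nrow(strain$variants) == 0L)
    stop("cannot compute mean depth of an empty variant set")
  mean(strain$variants$depth)
}

#' Apply the five quality filters
#'
#' A variant survives iff all of: depth within the closed band
#' `[mean(1-f), mean(1+f)]`; mq > min_mq; qual > min_qual; alt fraction >
#' min_alt_fraction; and, when required, at least `min_per_strand` alt reads
#' on each strand.  The scalar thresholds are strict inequalities; the depth
#' band is inclusive at both ends.
#'
#' @param strain a `strain_variant_set`.
#' @param config a [filter_config()]; `genome_mean_depth` is taken from the
#'   config or computed from the strain itself.
#' @return the filtered `strain_variant_set`.
#' @export
filter_variants <- function(strain, config = filter_config()) {
  v <- strain$variants
  if (nrow(v) == 0L) return(strain)
  mean_depth <- config$genome_mean_depth %||% compute_mean_depth(strain)
  f <- config$depth_band_fraction
  af <- alt_fraction(strain$variants)
  keep <- v$depth >= mean_depth * (1 - f) & v$depth <= mean_depth * (1 + f) &
    v$mq > config$min_mq & v$qual > config$min_qual &
    af > config$min_alt_fraction
  if (config$require_both_strands)
    keep <- keep & v$alt_forward >= config$min_per_strand &
      v$alt_reverse >= config$min_per_strand
  strain_variant_set(strain$strain_id, v[keep, , drop = FALSE])
}

#' Genes with CDS hits in every strain
#'
#' The cross-strain intersection step that nominates candidate causal genes:
#' a gene qualifies when it has at least one CDS-region effect record (any
#' consequence) in every strain.
#'
#' @param effects_by_strain named list of effect data frames (from
#'   [annotate_variants()] on each strain's surviving variants).
#' @return sorted character vector of gene ids.
#' @export
intersect_strain_genes <- function(effects_by_strain) {
  if (length(effects_by_strain) < 1L)
    stop("need at least one strain's effect records")
  per_strain <- lapply(effects_by_strain, function(e) {
    unique(e$gene_id[e$region == "CDS" & !is.na(e$gene_id)])
  })
  sort(Reduce(intersect, per_strain))
}

#' Assemble the candidate funnel report
#'
#' @param funnels named list (per strain) of funnel counts: `raw`,
#'   `after_subtraction`, `after_filters`, `in_cds`.
#' @param effects_by_strain named list of effect data frames on the
#'   filtered variants.
#' @param genome_size optional genome size in bp; adds per-strain mutation
#'   density (Mb of genome per surviving mutation).
#' @return object of class `candidate_report`: per-strain funnel table,
#'   pooled CDS fraction (unrounded and nearest-integer percent), shared
#'   genes with their per-strain supporting records, and optional density.
#' @export
build_report <- function(funnels, effects_by_strain = NULL,
                         genome_size = NULL) {
  tab <- do.call(rbind, lapply(names(funnels), function(s) {
    f <- funnels[[s]]
    data.frame(strain = s, raw = f$raw,
               after_subtraction = f$after_subtraction,
               after_filters = f$after_filters, in_cds = f$in_cds,
               stringsAsFactors = FALSE)
  }))
  for (i in seq_len(nrow(tab))) {
    counts <- unlist(tab[i, c("raw", "after_subtraction", "after_filters",
                              "in_cds")])
    if (any(diff(counts) > 0))
      stop("funnel counts must be non-increasing for strain ", tab$strain[i])
  }
  tot_filtered <- sum(tab$after_filters)
  tot_cds <- sum(tab$in_cds)
  cds_fraction_pooled <- if (tot_filtered > 0) 100 * tot_cds / tot_filtered
    else NA_real_
  shared <- if (!is.null(effects_by_strain) && length(effects_by_strain))
    intersect_strain_genes(effects_by_strain) else character(0)
  supporting <- if (length(shared) && !is.null(effects_by_strain)) {
    lapply(setNames(shared, shared), function(gid) {
      lapply(effects_by_strain, function(e) {
        e[e$region == "CDS" & !is.na(e$gene_id) & e$gene_id == gid, ,
          drop = FALSE]
      })
    })
  } else list()
  density <- if (!is.null(genome_size) && any(tab$after_filters > 0)) {
    setNames(ifelse(tab$after_filters > 0,
                    genome_size / 1e6 / tab$after_filters, NA_real_),
             tab$strain)
  } else NULL
  structure(list(funnel = tab,
                 cds_fraction_pooled = cds_fraction_pooled,
                 cds_percent_pooled = if (is.na(cds_fraction_pooled))
                   NA_real_ else round(cds_fraction_pooled),
                 shared_genes = shared, supporting = supporting,
                 mb_per_mutation = density),
            class = "candidate_report")
}

#' @exportS3Method base::print
print.candidate_report <- function(x, ...) {
  cat("<candidate_report>\n")
  print(x$funnel, row.names = FALSE)
  if (is.na(x$cds_fraction_pooled)) {
    cat("pooled CDS fraction: undefined (no variants after filters)\n")
  } else {
    cat(sprintf("pooled CDS fraction: %d%% (%.2f%% unrounded)\n",
                x$cds_percent_pooled, x$cds_fraction_pooled))
  }
  cat("shared candidate gene(s):",
      if (length(x$shared_genes)) paste(x$shared_genes, collapse = ", ")
      else "(none)", "\n")
  if (!is.null(x$mb_per_mutation))
    cat("Mb of genome per mutation:",
        paste(sprintf("%s=%.1f", names(x$mb_per_mutation),
                      x$mb_per_mutation), collapse = ", "), "\n")
  invisible(x)
}

#' Run the full candidate-mutation funnel
#'
#' Panel subtraction, quality filtering, effect annotation and cross-strain
#' CDS gene intersection in the order the screen applies them.
#'
#' @param strains named list of `strain_variant_set`s (one per mutant).
#' @param panel a [panel_index()].
#' @param genes list of [gene_model()].
#' @param genome named character vector of contig sequences.
#' @param config a [filter_config()].
#' @param match_mode panel matching mode, see [subtract_panel()].
#' @return list: `report` ([build_report()] output with genome density),
#'   `effects_by_strain`, `surviving` (named list of filtered variant sets).
#' @export
nominate_candidates <- function(strains, panel, genes, genome,
                                config = filter_config(),
                                match_mode = "allele_exact") {
  funnels <- list(); effects <- list(); surviving <- list()
  for (s in names(strains)) {
    raw <- strains[[s]]
    sub <- subtract_panel(raw, panel, match_mode)
    filt <- filter_variants(sub, config)
    eff <- annotate_variants(filt$variants, genes, genome)
    cds_vars <- unique(variant_key(eff[eff$region == "CDS", , drop = FALSE]))
    funnels[[s]] <- list(raw = nrow(raw$variants),
                         after_subtraction = nrow(sub$variants),
                         after_filters = nrow(filt$variants),
                         in_cds = length(cds_vars))
    effects[[s]] <- eff
    surviving[[s]] <- filt
  }
  report <- build_report(funnels, effects, genome_size = sum(nchar(genome)))
  list(report = report, effects_by_strain = effects, surviving = surviving)
}
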