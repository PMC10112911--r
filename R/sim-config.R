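#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators.  Defaults describe a
#' desk-scale haploid UV-mutagenesis screen: a 2-Mb single-contig genome
#' carrying 300 protein-coding genes, two mutant strains each with one causal
#' CDS lesion (a missense and a nonsense transition) planted in a shared gene
#' plus 30 background mutations, sequencing depth around 33x with alt-allele
#' fractions near 1, and a 14-line sibling panel sharing 500 recurrent
#' false-positive variants that mimic reference errors.
#'
#' @param seed integer seed; every generator derived from this config is
#'   deterministic in it.
#' @param genome_length total genome size in bp.
#' @param n_contigs number of contigs (genome_length split evenly).
#' @param n_genes number of non-overlapping gene models to place.
#' @param exon_count_range integer range of exons per gene.
#' @param cds_length_range CDS length range in bp; both bounds multiples of 3.
#' @param utr_length_range length range for each UTR in bp.
#' @param intron_length_range length range for each intron in bp.
#' @param n_background_mutations_per_strain background SNVs per strain.
#' @param transition_fraction fraction of planted SNVs that are transitions
#'   (A<->G, C<->T); UV spectra are strongly transition-biased.
#' @param causal_gene_policy list with `shared_gene` flag and
#'   `consequence_per_strain`, one of `"missense"`/`"nonsense"` per strain.
#' @param mean_depth mean sequencing depth at variant sites.
#' @param depth_dispersion negative-binomial size parameter for site depth as
#'   a multiple of `mean_depth` (larger = closer to Poisson).
#' @param alt_fraction_true range the true-mutation alt read fraction is
#'   drawn from (haploid strains: near 1).
#' @param n_panel_lines number of sibling mutant lines in the panel.
#' @param n_shared_false_positives recurrent variants injected identically
#'   into every strain and panel line.
#' @param n_panel_private_per_line private variants per panel line (panel
#'   index padding; never touch the focal strains).
#' @param false_positive_alt_fraction_range alt-fraction range for the
#'   recurrent false positives.
#' @param ensure_disjoint_background if `TRUE`, no non-causal gene receives a
#'   CDS background variant in more than one strain (and none in the causal
#'   gene), so the causal gene is the unique cross-strain CDS intersection.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       n_contigs = 1L,
                       n_genes = 300L,
                       exon_count_range = c(1L, 6L),
                       cds_length_range = c(300L, 1800L),
                       utr_length_range = c(50L, 200L),
                       intron_length_range = c(60L, 300L),
                       n_background_mutations_per_strain = 30L,
                       transition_fraction = 0.9,
                       causal_gene_policy = list(
                         shared_gene = TRUE,
                         consequence_per_strain = c("missense", "nonsense")),
                       mean_depth = 33,
                       depth_dispersion = 10,
                       alt_fraction_true = c(0.92, 1.0),
                       n_panel_lines = 14L,
                       n_shared_false_positives = 500L,
                       n_panel_private_per_line = 40L,
                       false_positive_alt_fraction_range = c(0.3, 1.0),
                       ensure_disjoint_background = TRUE) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_contigs = as.integer(n_contigs), n_genes = as.integer(n_genes),
              exon_count_range = as.integer(exon_count_range),
              cds_length_range = as.integer(cds_length_range),
              utr_length_range = as.integer(utr_length_range),
              intron_length_range = as.integer(intron_length_range),
              n_background_mutations_per_strain =
                as.integer(n_background_mutations_per_strain),
              transition_fraction = transition_fraction,
              causal_gene_policy = causal_gene_policy,
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              alt_fraction_true = alt_fraction_true,
              n_panel_lines = as.integer(n_panel_lines),
              n_shared_false_positives = as.integer(n_shared_false_positives),
              n_panel_private_per_line = as.integer(n_panel_private_per_line),
              false_positive_alt_fraction_range =
                false_positive_alt_fraction_range,
              ensure_disjoint_background = isTRUE(ensure_disjoint_background))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$genome_length >= 1L, cfg$n_contigs >= 1L, cfg$n_genes >= 0L,
    cfg$transition_fraction >= 0, cfg$transition_fraction <= 1,
    cfg$n_background_mutations_per_strain >= 0L,
    cfg$n_panel_lines >= 0L, cfg$n_shared_false_positives >= 0L,
    cfg$mean_depth > 0, cfg$depth_dispersion > 0,
    length(cfg$cds_length_range) == 2L,
    length(cfg$exon_count_range) == 2L,
    cfg$exon_count_range[1L] >= 1L,
    all(cfg$alt_fraction_true >= 0), all(cfg$alt_fraction_true <= 1)
  )
  if (any(cfg$cds_length_range %% 3L != 0L))
    stop("cds_length_range bounds must be divisible by 3")
  pol <- cfg$causal_gene_policy
  if (!all(pol$consequence_per_strain %in% c("missense", "nonsense")))
    stop("consequence_per_strain entries must be 'missense' or 'nonsense'")
  invisible(cfg)
}
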