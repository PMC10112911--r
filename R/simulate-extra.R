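#' Simulate a segregating family
#'
#' Haploid partheno-progeny of a cross segregating a single recessive locus:
#' genotypes drawn fairly (p = 0.5) and phenotype equal to genotype (full
#' penetrance), so the expected segregation ratio is 1:1.
#'
#' @param n_individuals family size.
#' @param seed integer seed.
#' @return data frame with `individual_id`, `genotype`, `phenotype`
#'   (levels `"mut"`/`"wt"`).
#' @export
simulate_family <- function(n_individuals, seed = 1L) {
  stopifnot(n_individuals >= 0L)
  with_seed(seed, {
    geno <- if (n_individuals > 0L)
      sample(c("wt", "mut"), n_individuals, replace = TRUE) else character(0)
    data.frame(individual_id = sprintf("ind_%03d", seq_len(n_individuals)),
               genotype = geno, phenotype = geno, stringsAsFactors = FALSE)
  })
}

#' Simulate a two-condition count matrix with programmed differential expression
#'
#' Negative-binomial counts for `n_genes` genes in two conditions (wt,
#' mutant) with `n_reps` replicates each.  A `de_fraction` of genes receives
#' a condition fold change of `2^lfc_magnitude` (half up, half down in
#' expectation); `n_exclusive` DE-up genes are zeroed in wild type and
#' `n_silenced` DE-down genes zeroed in the mutant so the exclusive/silenced
#' set rules can be exercised against known truth.
#'
#' @param n_genes,n_reps matrix dimensions (two conditions of `n_reps` each).
#' @param de_fraction fraction of genes that are DE.
#' @param lfc_magnitude absolute log2 fold change of DE genes.
#' @param dispersion negative-binomial dispersion (1/size); must be > 0.
#' @param seed integer seed.
#' @param n_exclusive,n_silenced genes with zero counts in exactly one
#'   condition (subsets of the up/down DE genes; capped at availability).
#' @return list with `counts` (genes x samples integer matrix), `lengths`
#'   (per-gene transcript lengths, bp), `condition` (per-sample labels) and
#'   `truth` (per-gene data frame: `is_de`, `direction`, `true_lfc`,
#'   `zero_condition`).
#' @export
simulate_counts <- function(n_genes, n_reps, de_fraction = 0.1,
                            lfc_magnitude = 2, dispersion = 0.05, seed = 1L,
                            n_exclusive = 0L, n_silenced = 0L) {
  stopifnot(n_genes >= 1L, n_reps >= 1L, de_fraction >= 0, de_fraction <= 1)
  if (dispersion <= 0) stop("dispersion must be > 0")
  with_seed(seed, {
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    lengths <- round(runif(n_genes, 500, 3000))
    base_mu <- rlnorm(n_genes, meanlog = log(200), sdlog = 1)
    n_de <- round(de_fraction * n_genes)
    de_idx <- if (n_de > 0L) sample.int(n_genes, n_de) else integer(0)
    direction <- rep("none", n_genes)
    if (n_de > 0L)
      direction[de_idx] <- sample(c("up", "down"), n_de, replace = TRUE)
    true_lfc <- ifelse(direction == "up", lfc_magnitude,
                       ifelse(direction == "down", -lfc_magnitude, 0))
    mu_wt <- base_mu
    mu_mut <- base_mu * 2^true_lfc
    zero_condition <- rep("none", n_genes)
    up_idx <- which(direction == "up")
    dn_idx <- which(direction == "down")
    if (n_exclusive > 0L && length(up_idx) > 0L) {
      sel <- up_idx[seq_len(min(n_exclusive, length(up_idx)))]
      mu_wt[sel] <- 0
      zero_condition[sel] <- "wt"
    }
    if (n_silenced > 0L && length(dn_idx) > 0L) {
      sel <- dn_idx[seq_len(min(n_silenced, length(dn_idx)))]
      mu_mut[sel] <- 0
      zero_condition[sel] <- "mut"
    }
    size <- 1 / dispersion
    draw <- function(mu) {
      m <- matrix(0L, n_genes, n_reps)
      nz <- mu > 0
      m[nz, ] <- rnbinom(sum(nz) * n_reps, mu = rep(mu[nz], n_reps), size = size)
      m
    }
    counts <- cbind(draw(mu_wt), draw(mu_mut))
    rownames(counts) <- gene_ids
    condition <- rep(c("wt", "mut"), each = n_reps)
    colnames(counts) <- paste0(condition, "_", rep(seq_len(n_reps), 2L))
    truth <- data.frame(gene_id = gene_ids, is_de = direction != "none",
                        direction = direction, true_lfc = true_lfc,
                        zero_condition = zero_condition,
                        stringsAsFactors = FALSE)
    list(counts = counts, lengths = setNames(lengths, gene_ids),
         condition = condition, truth = truth)
  })
}

#' Simulate a 1-D intensity profile with planted peaks
#'
#' Sum of equal-amplitude Gaussian bumps at regular spacing plus white
#' noise; a synthetic stand-in for a fluorescence transect across parallel
#' filament bundles.
#'
#' @param n_peaks number of bumps.
#' @param peak_width Gaussian sd in pixels.
#' @param spacing centre-to-centre distance in pixels (> 2 * peak_width
#'   recommended so bumps stay resolvable).
#' @param noise_sd white-noise sd in intensity units (amplitude is 1).
#' @param length profile length in pixels.
#' @param seed integer seed.
#' @return list with `intensity` (numeric vector), `positions` (1..length)
#'   and `truth` (`n_peaks`, planted `centers`).
#' @export
simulate_profile <- function(n_peaks, peak_width = 2, spacing = 12,
                             noise_sd = 0, length = 200L, seed = 1L) {
  stopifnot(n_peaks >= 0L, length >= 1L)
  span <- (n_peaks - 1L) * spacing
  margin <- 4 * peak_width
  if (n_peaks > 0L && span + 2 * margin > length)
    stop("cannot place ", n_peaks, " peaks at spacing ", spacing,
         " within length ", length)
  with_seed(seed, {
    x <- seq_len(length)
    y <- numeric(length)
    centers <- numeric(0)
    if (n_peaks > 0L) {
      start <- (length - span) / 2
      centers <- start + (seq_len(n_peaks) - 1L) * spacing
      for (c0 in centers) y <- y + exp(-((x - c0)^2) / (2 * peak_width^2))
    }
    if (noise_sd > 0) y <- y + rnorm(length, 0, noise_sd)
    list(intensity = y, positions = x,
         truth = list(n_peaks = as.integer(n_peaks), centers = centers))
  })
}
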