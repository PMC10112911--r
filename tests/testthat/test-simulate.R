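test_that("make_genome places valid, translatable, non-overlapping genes", {
  cfg <- small_sim_config(seed = 1)
  sim <- make_genome(cfg)
  expect_length(sim$genes, cfg$n_genes)
  expect_equal(sum(nchar(sim$genome)), cfg$genome_length)
  expect_false(any(grepl("[^ACGT]", sim$genome)))
  # every CDS translates to M...* with no internal stop
  peps <- vapply(sim$genes, function(g) translate(spliced_cds(g, sim$genome)),
                 character(1))
  expect_true(all(substr(peps, 1, 1) == "M"))
  expect_true(all(substring(peps, nchar(peps)) == "*"))
  expect_false(any(grepl("*", substr(peps, 1, nchar(peps) - 1), fixed = TRUE)))
  # non-overlapping spans per contig
  for (ct in names(sim$genome)) {
    spans <- t(vapply(Filter(function(g) g$contig == ct, sim$genes),
                      gene_span, integer(2)))
    if (nrow(spans) > 1) {
      spans <- spans[order(spans[, 1]), ]
      expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))
    }
  }
})

test_that("make_genome honours degenerate and deterministic contracts", {
  cfg <- small_sim_config(seed = 1)
  cfg$n_genes <- 0L
  expect_length(make_genome(cfg)$genes, 0)
  a <- make_genome(small_sim_config(seed = 7))
  b <- make_genome(small_sim_config(seed = 7))
  expect_identical(a$genome, b$genome)
  expect_identical(a$genes, b$genes)
  # written files byte-identical across reruns of the same seed
  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  gff1 <- tempfile(fileext = ".gff3"); gff2 <- tempfile(fileext = ".gff3")
  write_fasta(a$genome, fa1); write_fasta(b$genome, fa2)
  write_gff3(a$genes, gff1); write_gff3(b$genes, gff2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(gff1), readLines(gff2))
  # impossible placement errors out
  tiny <- sim_config(seed = 1, genome_length = 5000, n_genes = 50,
                     n_background_mutations_per_strain = 0)
  expect_error(make_genome(tiny), "overlap")
})

test_that("plant_mutations plants configured causal variants with truth", {
  cfg <- small_sim_config(seed = 3)
  sim <- make_genome(cfg)
  pm <- plant_mutations(sim$genome, sim$genes, cfg)
  expect_length(pm$strains, 2)
  # causal variants are transitions in the shared gene's CDS
  causal <- pm$truth$causal
  expect_equal(unique(causal$gene_id), pm$truth$causal_gene_id)
  expect_true(all(TRANSITION_PAIR(causal$ref) == causal$alt))
  gene <- Filter(function(g) g$gene_id == pm$truth$causal_gene_id,
                 sim$genes)[[1]]
  for (i in seq_len(nrow(causal))) {
    eff <- annotate_cds_effect(causal[i, ], gene, sim$genome)
    expect_equal(eff$consequence, causal$consequence[i])
  }
  # every truth variant is present in its strain set with identical key
  for (s in names(pm$strains)) {
    keys <- paste(pm$strains[[s]]$variants$contig,
                  pm$strains[[s]]$variants$pos,
                  pm$strains[[s]]$variants$ref,
                  pm$strains[[s]]$variants$alt)
    truth_keys <- c(
      paste(causal$contig[causal$strain == s], causal$pos[causal$strain == s],
            causal$ref[causal$strain == s], causal$alt[causal$strain == s]),
      paste(pm$truth$background[[s]]$contig, pm$truth$background[[s]]$pos,
            pm$truth$background[[s]]$ref, pm$truth$background[[s]]$alt))
    expect_setequal(keys, truth_keys)
    # read evidence invariants
    v <- pm$strains[[s]]$variants
    expect_true(all(v$alt_forward >= 1 & v$alt_reverse >= 1))
    expect_true(all((v$alt_forward + v$alt_reverse) / v$depth > 0.9))
  }
})

test_that("plant_mutations degenerate cases and transition forcing", {
  cfg <- small_sim_config(seed = 5)
  cfg$n_background_mutations_per_strain <- 0L
  sim <- make_genome(cfg)
  pm <- plant_mutations(sim$genome, sim$genes, cfg)
  for (s in pm$strains) expect_equal(nrow(s$variants), 1)
  expect_equal(length(unique(pm$truth$causal$gene_id)), 1)

  cfg2 <- small_sim_config(seed = 6)
  cfg2$transition_fraction <- 1.0
  pm2 <- plant_mutations(sim$genome, sim$genes, cfg2)
  for (s in names(pm2$strains)) {
    v <- pm2$strains[[s]]$variants
    expect_true(all(unname(TRANSITION_PAIR(v$ref)) == v$alt))
  }
})

test_that("disjoint background yields exactly one shared CDS-hit gene", {
  cfg <- small_sim_config(seed = 11)
  sim <- make_genome(cfg)
  pm <- plant_mutations(sim$genome, sim$genes, cfg)
  # brute-force: per strain, gene ids whose CDS contains a truth variant
  hit_sets <- lapply(names(pm$strains), function(s) {
    all_truth <- rbind(
      pm$truth$background[[s]][, c("contig", "pos")],
      pm$truth$causal[pm$truth$causal$strain == s, c("contig", "pos")])
    hits <- character(0)
    for (i in seq_len(nrow(all_truth))) {
      for (g in sim$genes) {
        if (g$contig == all_truth$contig[i] &&
            any(all_truth$pos[i] >= g$cds[, 1] & all_truth$pos[i] <= g$cds[, 2]))
          hits <- c(hits, g$gene_id)
      }
    }
    unique(hits)
  })
  shared <- Reduce(intersect, hit_sets)
  expect_identical(shared, pm$truth$causal_gene_id)
})

test_that("make_panel injects recurrent false positives and spares truth", {
  cfg <- small_sim_config(seed = 2)
  sim <- make_genome(cfg)
  pm <- plant_mutations(sim$genome, sim$genes, cfg)
  mp <- make_panel(cfg, pm$strains, sim$genome, pm$truth)
  fp_n <- cfg$n_shared_false_positives
  expect_gte(nrow(mp$panel$keys), fp_n)
  # every strain gains exactly the shared false-positive keys, all of which
  # are in the panel index; the injected keys are identical across strains
  panel_keys <- paste(mp$panel$keys$contig, mp$panel$keys$pos,
                      mp$panel$keys$ref, mp$panel$keys$alt)
  gained <- lapply(names(mp$strains), function(s) {
    before <- paste(pm$strains[[s]]$variants$contig,
                    pm$strains[[s]]$variants$pos,
                    pm$strains[[s]]$variants$ref,
                    pm$strains[[s]]$variants$alt)
    v <- mp$strains[[s]]$variants
    setdiff(paste(v$contig, v$pos, v$ref, v$alt), before)
  })
  for (g in gained) {
    expect_length(g, fp_n)
    expect_true(all(g %in% panel_keys))
  }
  expect_setequal(gained[[1]], gained[[2]])
  # no planted true mutation appears in the panel
  truth_keys <- paste(pm$truth$causal$contig, pm$truth$causal$pos)
  panel_pos <- paste(mp$panel$keys$contig, mp$panel$keys$pos)
  expect_false(any(truth_keys %in% panel_pos))
  for (s in names(pm$truth$background)) {
    bg <- pm$truth$background[[s]]
    expect_false(any(paste(bg$contig, bg$pos) %in% panel_pos))
  }
  # zero false positives: empty panel, untouched strains
  cfg0 <- small_sim_config(seed = 2)
  cfg0$n_shared_false_positives <- 0L
  mp0 <- make_panel(cfg0, pm$strains, sim$genome)
  expect_equal(nrow(mp0$panel$keys), 0)
  expect_identical(mp0$strains, pm$strains)
})

test_that("simulate_family is fully penetrant, fair and deterministic", {
  fam <- simulate_family(38, seed = 4)
  expect_equal(nrow(fam), 38)
  expect_identical(fam$genotype, fam$phenotype)
  expect_identical(simulate_family(38, seed = 4), fam)
  expect_equal(nrow(simulate_family(0, seed = 1)), 0)
  big <- simulate_family(10000, seed = 1)
  frac <- mean(big$genotype == "mut")
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("simulate_counts encodes the programmed fold changes", {
  sim <- simulate_counts(n_genes = 200, n_reps = 50, de_fraction = 0.2,
                         lfc_magnitude = 2, dispersion = 0.01, seed = 9)
  expect_identical(dim(sim$counts), c(200L, 100L))
  expect_identical(sim$counts,
                   simulate_counts(200, 50, 0.2, 2, 0.01, seed = 9)$counts)
  up <- which(sim$truth$direction == "up")[1]
  ratio <- mean(sim$counts[up, sim$condition == "mut"]) /
    mean(sim$counts[up, sim$condition == "wt"])
  expect_lt(abs(ratio - 4) / 4, 0.2)
  none <- simulate_counts(50, 3, de_fraction = 0, seed = 1)
  expect_equal(sum(none$truth$is_de), 0)
  expect_error(simulate_counts(50, 3, dispersion = 0), "dispersion")
  # engineered zero-condition genes
  z <- simulate_counts(300, 3, de_fraction = 0.3, seed = 2,
                       n_exclusive = 4, n_silenced = 3)
  excl <- z$truth$gene_id[z$truth$zero_condition == "wt"]
  expect_length(excl, 4)
  expect_true(all(z$counts[excl, z$condition == "wt"] == 0))
  sil <- z$truth$gene_id[z$truth$zero_condition == "mut"]
  expect_length(sil, 3)
  expect_true(all(z$counts[sil, z$condition == "mut"] == 0))
})

test_that("simulate_profile plants the requested peaks", {
  flat <- simulate_profile(0, noise_sd = 0, length = 100, seed = 1)
  expect_identical(flat$intensity, rep(0, 100))
  p3 <- simulate_profile(3, peak_width = 2, spacing = 20, noise_sd = 0,
                         length = 120, seed = 1)
  y <- p3$intensity
  maxima <- which(diff(sign(diff(y))) == -2) + 1
  expect_equal(sum(y[maxima] > 0.5), 3)
  expect_identical(p3$intensity,
                   simulate_profile(3, 2, 20, 0, 120, seed = 1)$intensity)
  expect_error(simulate_profile(10, peak_width = 2, spacing = 30,
                                length = 100), "cannot place")
})
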