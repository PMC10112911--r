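test_that("subtract_panel removes exactly the panel-matching keys", {
  v <- do.call(rbind, lapply(1:5, function(i)
    make_variant(pos = i * 10L, ref = "A", alt = "G")))
  s <- strain_variant_set("s1", v)
  empty <- panel_index(v[0, ])
  expect_identical(subtract_panel(s, empty)$variants, s$variants)
  panel <- panel_index(v[c(2, 4), c("contig", "pos", "ref", "alt")])
  out <- subtract_panel(s, panel)
  expect_equal(nrow(out$variants), 3)
  expect_setequal(out$variants$pos, c(10L, 30L, 50L))
  # allele-exact does not remove a different alt at the same position
  v2 <- v; v2$alt <- "T"
  panel2 <- panel_index(v2[, c("contig", "pos", "ref", "alt")])
  expect_equal(nrow(subtract_panel(s, panel2)$variants), 5)
  expect_equal(nrow(subtract_panel(s, panel2, "position_only")$variants), 0)
})

test_that("simulated panel false positives are all removed, truth retained", {
  cfg <- small_sim_config(seed = 41)
  sim <- make_genome(cfg)
  pm <- plant_mutations(sim$genome, sim$genes, cfg)
  mp <- make_panel(cfg, pm$strains, sim$genome, pm$truth)
  for (s in names(mp$strains)) {
    out <- subtract_panel(mp$strains[[s]], mp$panel)
    # all injected false positives removed
    pk <- paste(mp$panel$keys$contig, mp$panel$keys$pos)
    expect_false(any(paste(out$variants$contig, out$variants$pos) %in% pk))
    # truth retained
    expect_equal(nrow(out$variants), nrow(pm$strains[[s]]$variants))
  }
})

test_that("compute_mean_depth averages site depths unless overridden", {
  v <- do.call(rbind, lapply(seq_along(c(30L, 34L, 32L)), function(i)
    make_variant(pos = i * 10L, depth = c(30L, 34L, 32L)[i])))
  s <- strain_variant_set("s1", v)
  expect_equal(compute_mean_depth(s), 32)
  cfg <- filter_config(genome_mean_depth = 33)
  out <- filter_variants(s, cfg)   # uses override, not 32
  expect_true(all(out$variants$depth >= 33 * 0.5 &
                    out$variants$depth <= 33 * 1.5))
  expect_error(compute_mean_depth(strain_variant_set("e")), "empty")
  cfg2 <- small_sim_config(seed = 42)
  sim <- make_genome(cfg2)
  pm <- plant_mutations(sim$genome, sim$genes, cfg2)
  mp <- make_panel(cfg2, pm$strains, sim$genome)
  for (s in mp$strains)
    expect_lt(abs(compute_mean_depth(s) - 33) / 33, 0.05)
})

test_that("the five filters apply with documented strictness and band edges", {
  base <- list(qual = 200, mq = 60, depth = 30L, af = 29L)
  mk <- function(pos, qual = 200, mq = 60, depth = 30L, altn = 29L) {
    make_variant(pos = pos, qual = qual, mq = mq, depth = depth,
                 alt_forward = altn %/% 2L + altn %% 2L,
                 alt_reverse = altn %/% 2L)
  }
  cfg <- filter_config(genome_mean_depth = 30)
  # boundary: mq exactly 20 rejected (strict >)
  s <- strain_variant_set("s", mk(1L, mq = 20))
  expect_equal(nrow(filter_variants(s, cfg)$variants), 0)
  s <- strain_variant_set("s", mk(1L, mq = 20.01))
  expect_equal(nrow(filter_variants(s, cfg)$variants), 1)
  # qual exactly 50 rejected
  expect_equal(nrow(filter_variants(
    strain_variant_set("s", mk(1L, qual = 50)), cfg)$variants), 0)
  # depth exactly at band edges retained (inclusive)
  expect_equal(nrow(filter_variants(
    strain_variant_set("s", mk(1L, depth = 45L, altn = 44L)), cfg)$variants), 1)
  expect_equal(nrow(filter_variants(
    strain_variant_set("s", mk(1L, depth = 15L, altn = 15L)), cfg)$variants), 1)
  expect_equal(nrow(filter_variants(
    strain_variant_set("s", mk(1L, depth = 46L, altn = 46L)), cfg)$variants), 0)
  # alt fraction exactly 0.9 rejected (strict >)
  expect_equal(nrow(filter_variants(
    strain_variant_set("s", mk(1L, depth = 30L, altn = 27L)), cfg)$variants), 0)
  # both-strand support required
  v <- make_variant(pos = 1L, depth = 30L, alt_forward = 29L, alt_reverse = 0L)
  expect_equal(nrow(filter_variants(
    strain_variant_set("s", v), cfg)$variants), 0)
  nostrand <- filter_config(genome_mean_depth = 30, require_both_strands = FALSE)
  expect_equal(nrow(filter_variants(
    strain_variant_set("s", v), nostrand)$variants), 1)
})

test_that("a hand-built 10-variant fixture filters to exactly the passing 4", {
  cfg <- filter_config(genome_mean_depth = 30)
  rows <- list(
    pass1 = make_variant(pos = 10L),                                  # all good
    pass2 = make_variant(pos = 20L, depth = 45L, alt_forward = 30L,
                         alt_reverse = 14L),                          # band edge
    fail_mq = make_variant(pos = 30L, mq = 15),
    fail_qual = make_variant(pos = 40L, qual = 12),
    fail_depth_low = make_variant(pos = 50L, depth = 10L,
                                  alt_forward = 5L, alt_reverse = 5L),
    fail_depth_high = make_variant(pos = 60L, depth = 80L,
                                   alt_forward = 40L, alt_reverse = 39L),
    fail_af = make_variant(pos = 70L, depth = 30L, alt_forward = 13L,
                           alt_reverse = 13L),
    pass3 = make_variant(pos = 80L, depth = 33L, alt_forward = 16L,
                         alt_reverse = 16L),
    fail_strand = make_variant(pos = 90L, depth = 30L, alt_forward = 28L,
                               alt_reverse = 0L),
    pass4 = make_variant(pos = 100L, depth = 22L, alt_forward = 11L,
                         alt_reverse = 10L))
  s <- strain_variant_set("s", do.call(rbind, rows))
  out <- filter_variants(s, cfg)
  expect_setequal(out$variants$pos, c(10L, 20L, 80L, 100L))
})

test_that("filtering and subtraction are monotone, idempotent and commute", {
  set.seed(99)
  cfg <- filter_config(genome_mean_depth = 33)
  for (rep in 1:25) {
    s <- random_strain_set(40)
    panel <- panel_index(random_variant_table(30)[, c("contig", "pos", "ref",
                                                      "alt")])
    f1 <- filter_variants(s, cfg)
    # monotone: survivors are a subset
    expect_true(all(paste(f1$variants$contig, f1$variants$pos) %in%
                      paste(s$variants$contig, s$variants$pos)))
    # idempotent
    expect_identical(filter_variants(f1, cfg)$variants, f1$variants)
    sub1 <- subtract_panel(s, panel)
    expect_identical(subtract_panel(sub1, panel)$variants, sub1$variants)
    # commute
    a <- filter_variants(subtract_panel(s, panel), cfg)
    b <- subtract_panel(filter_variants(s, cfg), panel)
    expect_identical(a$variants, b$variants)
  }
})

test_that("intersect_strain_genes returns genes CDS-hit in every strain", {
  eff <- function(genes, regions) {
    data.frame(contig = "c", pos = seq_along(genes), ref = "A", alt = "G",
               gene_id = genes, region = regions, stringsAsFactors = FALSE)
  }
  one <- list(s1 = eff(c("g1", "g2", "g3"), c("CDS", "CDS", "intron")))
  expect_equal(intersect_strain_genes(one), c("g1", "g2"))
  two <- c(one, list(s2 = eff(c("g2", "g4"), c("CDS", "CDS"))))
  expect_equal(intersect_strain_genes(two), "g2")
  disjoint <- c(one, list(s2 = eff("g9", "CDS")))
  expect_equal(intersect_strain_genes(disjoint), character(0))
  expect_error(intersect_strain_genes(list()), "at least one")
})

test_that("build_report computes funnel arithmetic and guards division by zero", {
  funnels <- list(
    s1 = list(raw = 41000, after_subtraction = 827, after_filters = 118,
              in_cds = 26),
    s2 = list(raw = 41000, after_subtraction = 769, after_filters = 67,
              in_cds = 15))
  rep <- build_report(funnels)
  expect_equal(rep$cds_percent_pooled, 22)
  expect_equal(rep$cds_fraction_pooled, 100 * 41 / 185, tolerance = 1e-9)
  # division-by-zero rule: undefined, not 0
  zero <- build_report(list(s1 = list(raw = 0, after_subtraction = 0,
                                      after_filters = 0, in_cds = 0)))
  expect_true(is.na(zero$cds_fraction_pooled))
  # non-increasing funnel enforced
  expect_error(build_report(list(s1 = list(raw = 5, after_subtraction = 9,
                                           after_filters = 1, in_cds = 0))),
               "non-increasing")
  # genome density: Mb per surviving mutation
  dens <- build_report(funnels, genome_size = 214e6)$mb_per_mutation
  expect_equal(unname(dens["s1"]), 214 / 118, tolerance = 1e-9)
  expect_equal(unname(dens["s2"]), 214 / 67, tolerance = 1e-9)
})

test_that("report counts match brute-force recounts on a simulated run", {
  cfg <- small_sim_config(seed = 43)
  sim <- make_genome(cfg)
  pm <- plant_mutations(sim$genome, sim$genes, cfg)
  mp <- make_panel(cfg, pm$strains, sim$genome, pm$truth)
  res <- nominate_candidates(mp$strains, mp$panel, sim$genes, sim$genome)
  for (s in names(mp$strains)) {
    row <- res$report$funnel[res$report$funnel$strain == s, ]
    expect_equal(row$raw, nrow(mp$strains[[s]]$variants))
    # brute force: set differences and per-variant predicate evaluation
    v <- mp$strains[[s]]$variants
    pk <- paste(mp$panel$keys$contig, mp$panel$keys$pos, mp$panel$keys$ref,
                mp$panel$keys$alt)
    kept <- v[!(paste(v$contig, v$pos, v$ref, v$alt) %in% pk), ]
    expect_equal(row$after_subtraction, nrow(kept))
    m <- mean(kept$depth)
    af <- (kept$alt_forward + kept$alt_reverse) / kept$depth
    surv <- kept[kept$depth >= 0.5 * m & kept$depth <= 1.5 * m &
                   kept$mq > 20 & kept$qual > 50 & af > 0.9 &
                   kept$alt_forward >= 1 & kept$alt_reverse >= 1, ]
    expect_equal(row$after_filters, nrow(surv))
    in_cds <- sum(vapply(seq_len(nrow(surv)), function(i) {
      any(vapply(sim$genes, function(g) {
        g$contig == surv$contig[i] &&
          any(surv$pos[i] >= g$cds[, 1] & surv$pos[i] <= g$cds[, 2])
      }, logical(1)))
    }, logical(1)))
    expect_equal(row$in_cds, in_cds)
  }
  expect_identical(res$report$shared_genes, pm$truth$causal_gene_id)
})
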