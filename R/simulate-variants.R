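# Depth of a true mutation site: negative binomial around mean_depth with
# size mean_depth * depth_dispersion, truncated to [0.65, 1.35] x mean.
# Truncation emulates callable, well-covered sites -- the real pipeline only
# ever reports variants observed at usable depth -- and guarantees planted
# mutations sit inside the ±50% depth band the quality filter uses.
draw_true_depth <- function(n, mean_depth, dispersion) {
  lo <- ceiling(0.65 * mean_depth); hi <- floor(1.35 * mean_depth)
  out <- integer(0)
  while (length(out) < n) {
    d <- rnbinom(2L * (n - length(out)) + 10L, mu = mean_depth,
                 size = mean_depth * dispersion)
    out <- c(out, d[d >= lo & d <= hi])
  }
  out[seq_len(n)]
}

# Simulated read evidence for true haploid mutations: alt fraction drawn in
# alt_fraction_true, alt count ceiling'd so the realised fraction never drops
# below the draw, at least one alt read per strand.
true_read_evidence <- function(n, cfg) {
  depth <- draw_true_depth(n, cfg$mean_depth, cfg$depth_dispersion)
  f <- runif(n, cfg$alt_fraction_true[1L], cfg$alt_fraction_true[2L])
  alt <- pmin(depth, as.integer(ceiling(depth * f)))
  fwd <- rbinom(n, pmax(alt - 2L, 0L), 0.5) + pmin(alt, 1L)
  rev <- alt - fwd
  data.frame(depth = depth, alt_forward = fwd, alt_reverse = rev,
             qual = qual_from_counts(alt, depth),
             mq = pmin(60, pmax(0, rnorm(n, 58, 2))))
}

random_alt <- function(ref, transition_fraction) {
  n <- length(ref)
  is_ts <- runif(n) < transition_fraction
  alt <- unname(TRANSITION[ref])
  if (any(!is_ts)) {
    tv <- vapply(ref[!is_ts], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), c(b, TRANSITION[[b]])), 1L)
    }, character(1))
    alt[!is_ts] <- tv
  }
  alt
}

# Enumerate CDS offsets where a coding-strand transition yields the requested
# consequence. Returns data frame of candidate edits (offset, ref/alt coding
# base) or zero rows.
transition_edits <- function(cds_seq, consequence) {
  n_cod <- nchar(cds_seq) %/% 3L
  offs <- seq_len(nchar(cds_seq))
  refb <- substring(cds_seq, offs, offs)
  altb <- unname(TRANSITION[refb])
  codon_idx <- (offs - 1L) %/% 3L + 1L
  within <- (offs - 1L) %% 3L + 1L
  starts <- (codon_idx - 1L) * 3L + 1L
  ref_codon <- substring(cds_seq, starts, starts + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- altb
  ref_aa <- unname(CODON_TABLE[ref_codon])
  alt_aa <- unname(CODON_TABLE[alt_codon])
  keep <- switch(consequence,
    missense = ref_aa != alt_aa & ref_aa != "*" & alt_aa != "*" &
      codon_idx > 1L & codon_idx < n_cod,
    nonsense = ref_aa != "*" & alt_aa == "*" & codon_idx < n_cod,
    silent = ref_aa == alt_aa,
    stop("unknown consequence ", consequence))
  data.frame(offset = offs, ref = refb, alt = altb, codon_index = codon_idx,
             ref_aa = ref_aa, alt_aa = alt_aa)[keep, , drop = FALSE]
}

#' Plant causal and background mutations into simulated strains
#'
#' Each strain receives one causal CDS transition (missense or nonsense as
#' configured, in a single shared gene when `shared_gene` is set) plus
#' uniformly placed background SNVs with the configured transition bias.
#' Every variant carries simulated depth, alt-allele fraction near 1 and at
#' least one alt-supporting read on each strand, as expected for real
#' mutations in a haploid genome sequenced at ~33x.
#'
#' With `ensure_disjoint_background`, background mutations are re-drawn so no
#' non-causal gene has CDS hits in more than one strain and the causal gene
#' receives no background CDS hit: the causal gene is then the unique gene
#' with CDS variants in every strain.
#'
#' @param genome named character vector of contig sequences.
#' @param genes list of [gene_model()].
#' @param config a [sim_config()].
#' @return list with `strains` (named list of strain variant sets, each a
#'   list of `strain_id` and a `variants` data frame) and `truth` (a
#'   `sim_truth` list: `causal_gene_id`, `causal` per-strain variant table,
#'   `background` per-strain variant tables).
#' @export
plant_mutations <- function(genome, genes, config) {
  pol <- config$causal_gene_policy
  n_strains <- length(pol$consequence_per_strain)
  strain_ids <- sprintf("strain_%d", seq_len(n_strains))
  with_seed(config$seed + 1L, {
    # -- choose causal gene(s) able to host every requested consequence
    eligible <- function(gene, consequences) {
      s <- spliced_cds(gene, genome)
      all(vapply(unique(consequences),
                 function(cq) nrow(transition_edits(s, cq)) > 0L, logical(1)))
    }
    causal_gene <- vector("list", n_strains)
    if (isTRUE(pol$shared_gene)) {
      if (length(genes) == 0L) stop("no genes to host the causal mutation")
      idx <- sample(seq_along(genes))
      hit <- NULL
      for (i in idx) {
        if (eligible(genes[[i]], pol$consequence_per_strain)) { hit <- i; break }
      }
      if (is.null(hit))
        stop("no gene admits all requested causal consequences by transition")
      causal_gene[] <- list(genes[[hit]])
    } else {
      for (s in seq_len(n_strains)) {
        idx <- sample(seq_along(genes))
        hit <- NULL
        for (i in idx) {
          if (eligible(genes[[i]], pol$consequence_per_strain[s])) { hit <- i; break }
        }
        if (is.null(hit)) stop("no eligible gene for strain ", s)
        causal_gene[[s]] <- genes[[hit]]
      }
    }

    gene_by_id <- setNames(genes, vapply(genes, `[[`, character(1), "gene_id"))
    contig_len <- nchar(genome)

    causal_rows <- list(); background_rows <- list()
    cds_hit_genes <- setNames(vector("list", n_strains), strain_ids)
    taken_keys <- character(0)   # contig:pos occupied by any planted variant

    for (s in seq_len(n_strains)) {
      g <- causal_gene[[s]]
      edits <- transition_edits(spliced_cds(g, genome),
                                pol$consequence_per_strain[s])
      if (nrow(edits) == 0L)
        stop("cannot construct a ", pol$consequence_per_strain[s],
             " transition in gene ", g$gene_id)
      pick <- edits[sample.int(nrow(edits), 1L), ]
      gpos <- cds_to_genomic(g, pick$offset)
      ref <- if (g$strand == "+") pick$ref else comp_base(pick$ref)
      alt <- if (g$strand == "+") pick$alt else comp_base(pick$alt)
      stopifnot(substr(genome[[g$contig]], gpos, gpos) == ref)
      ev <- true_read_evidence(1L, config)
      causal_rows[[s]] <- data.frame(
        strain = strain_ids[s], contig = g$contig, pos = gpos,
        ref = ref, alt = alt, qual = ev$qual, mq = ev$mq, depth = ev$depth,
        alt_forward = ev$alt_forward, alt_reverse = ev$alt_reverse,
        gene_id = g$gene_id, consequence = pol$consequence_per_strain[s],
        stringsAsFactors = FALSE)
      taken_keys <- c(taken_keys, paste0(g$contig, ":", gpos))
    }

    gene_of_cds_pos <- function(contig, pos) {
      for (g in genes) {
        if (g$contig == contig && in_segments(pos, g$cds)) return(g$gene_id)
      }
      NA_character_
    }
    # genes CDS-hit in earlier strains (and the causal gene) are off-limits
    # for later strains' background when ensure_disjoint_background is set
    blocked <- if (isTRUE(pol$shared_gene))
      vapply(causal_gene, `[[`, character(1), "gene_id") else character(0)
    blocked <- unique(blocked)

    for (s in seq_len(n_strains)) {
      nb <- config$n_background_mutations_per_strain
      rows <- empty_variants(); rows$strain <- character(0)
      hit_genes <- character(0)
      attempts <- 0L
      while (nrow(rows) < nb) {
        attempts <- attempts + 1L
        if (attempts > 200L * max(nb, 1L))
          stop("could not place background mutations under disjointness")
        contig <- sample(names(genome), 1L, prob = contig_len / sum(contig_len))
        pos <- sample.int(contig_len[[contig]], 1L)
        key <- paste0(contig, ":", pos)
        if (key %in% taken_keys) next
        gid <- gene_of_cds_pos(contig, pos)
        if (config$ensure_disjoint_background && !is.na(gid) &&
            gid %in% blocked) next
        ref <- substr(genome[[contig]], pos, pos)
        alt <- random_alt(ref, config$transition_fraction)
        ev <- true_read_evidence(1L, config)
        rows <- rbind(rows, data.frame(
          contig = contig, pos = pos, ref = ref, alt = alt, qual = ev$qual,
          mq = ev$mq, depth = ev$depth, alt_forward = ev$alt_forward,
          alt_reverse = ev$alt_reverse, strain = strain_ids[s],
          stringsAsFactors = FALSE))
        taken_keys <- c(taken_keys, key)
        if (!is.na(gid)) hit_genes <- c(hit_genes, gid)
      }
      if (config$ensure_disjoint_background)
        blocked <- unique(c(blocked, hit_genes))
      cds_hit_genes[[s]] <- unique(hit_genes)
      background_rows[[s]] <- rows
    }

    strains <- setNames(vector("list", n_strains), strain_ids)
    for (s in seq_len(n_strains)) {
      cv <- causal_rows[[s]]
      v <- rbind(
        cv[, c("contig", "pos", "ref", "alt", "qual", "mq", "depth",
               "alt_forward", "alt_reverse")],
        background_rows[[s]][, c("contig", "pos", "ref", "alt", "qual", "mq",
                                 "depth", "alt_forward", "alt_reverse")])
      strains[[s]] <- strain_variant_set(strain_ids[s], v)
    }
    truth <- structure(list(
      causal_gene_id = if (isTRUE(pol$shared_gene))
        causal_gene[[1L]]$gene_id
      else vapply(causal_gene, `[[`, character(1), "gene_id"),
      causal = do.call(rbind, causal_rows),
      background = setNames(background_rows, strain_ids)),
      class = "sim_truth")
    list(strains = strains, truth = truth)
  })
}

#' Build a sibling-line variant panel and inject recurrent false positives
#'
#' Emulates the subtraction panel of independently sequenced mutant lines:
#' the same `n_shared_false_positives` variants (reference-error mimics with
#' broad alt-fraction range) appear in every panel line and are injected into
#' every focal strain's variant set; each panel line additionally carries
#' private variants that pad the panel index.  No planted true mutation ever
#' enters the panel.
#'
#' @param config a [sim_config()].
#' @param strains named list of strain variant sets from [plant_mutations()].
#' @param genome optional genome so false positives carry the true reference
#'   base; random refs otherwise.
#' @param truth optional `sim_truth`; any collision between a generated panel
#'   site and a planted true mutation raises an error.
#' @return list with `panel` (a `panel_index`: `keys` data frame and
#'   `n_source_lines`) and `strains` (the input sets with false positives
#'   appended).
#' @export
make_panel <- function(config, strains, genome = NULL, truth = NULL) {
  if (config$n_shared_false_positives == 0L) {
    # panel emulation is keyed to the recurrent false positives; with none
    # requested the index is empty and the strains pass through untouched
    return(list(panel = panel_index(empty_variants(),
                                    n_source_lines = max(config$n_panel_lines, 1L)),
                strains = strains))
  }
  with_seed(config$seed + 2L, {
    contig_ids <- if (!is.null(genome)) names(genome)
      else unique(unlist(lapply(strains, function(s) s$variants$contig))) %||% "chr01"
    if (length(contig_ids) == 0L) contig_ids <- "chr01"
    contig_len <- if (!is.null(genome)) nchar(genome)
      else setNames(rep(config$genome_length, length(contig_ids)), contig_ids)

    truth_pos <- unlist(lapply(strains, function(s) position_key(s$variants)))

    draw_sites <- function(n) {
      if (n == 0L) return(empty_variants()[, c("contig", "pos", "ref", "alt")])
      out <- NULL; guard <- 0L
      while (is.null(out) || nrow(out) < n) {
        guard <- guard + 1L
        if (guard > 200L) stop("could not draw panel sites avoiding true mutations")
        m <- 2L * n
        contig <- sample(contig_ids, m, replace = TRUE,
                         prob = contig_len / sum(contig_len))
        pos <- vapply(contig, function(cc) sample.int(contig_len[[cc]], 1L),
                      integer(1))
        ref <- if (!is.null(genome))
          substring(genome[contig], pos, pos)
        else sample(c("A", "C", "G", "T"), m, replace = TRUE)
        df <- data.frame(contig = contig, pos = pos, ref = unname(ref),
                         alt = random_alt(unname(ref), 0.5),
                         stringsAsFactors = FALSE, row.names = NULL)
        df <- df[!duplicated(position_key(df)) &
                   !(position_key(df) %in% truth_pos), , drop = FALSE]
        out <- rbind(out, df)
        out <- out[!duplicated(position_key(out)), , drop = FALSE]
      }
      out[seq_len(n), , drop = FALSE]
    }

    shared <- draw_sites(config$n_shared_false_positives)
    if (!is.null(truth)) {
      tkeys <- c(position_key(truth$causal),
                 unlist(lapply(truth$background, position_key)))
      if (any(position_key(shared) %in% tkeys))
        stop("panel false-positive site collides with a planted true mutation")
    }
    n_priv <- config$n_panel_lines * config$n_panel_private_per_line
    private <- draw_sites(n_priv)
    # private sites drawn after shared: drop any position collision
    private <- private[!(position_key(private) %in% position_key(shared)), ,
                       drop = FALSE]
    keys <- rbind(shared, private)
    keys <- keys[order(keys$contig, keys$pos, keys$alt), , drop = FALSE]
    rownames(keys) <- NULL
    panel <- panel_index(keys, n_source_lines = max(config$n_panel_lines, 1L))

    if (nrow(shared) > 0L) {
      n <- nrow(shared)
      f <- runif(n, config$false_positive_alt_fraction_range[1L],
                 config$false_positive_alt_fraction_range[2L])
      depth <- draw_true_depth(n, config$mean_depth, config$depth_dispersion)
      alt <- pmax(1L, pmin(depth, as.integer(round(depth * f))))
      fwd <- rbinom(n, alt, 0.5)
      fp_rows <- data.frame(
        contig = shared$contig, pos = shared$pos, ref = shared$ref,
        alt = shared$alt, qual = qual_from_counts(alt, depth),
        mq = pmin(60, pmax(0, rnorm(n, 50, 10))), depth = depth,
        alt_forward = fwd, alt_reverse = alt - fwd, stringsAsFactors = FALSE)
      strains <- lapply(strains, function(s) {
        strain_variant_set(s$strain_id, rbind(s$variants, fp_rows))
      })
    }
    list(panel = panel, strains = strains)
  })
}

#' Construct a strain variant set
#'
#' @param strain_id identifier.
#' @param variants data frame with columns contig, pos, ref, alt, qual, mq,
#'   depth, alt_forward, alt_reverse.  Rows are sorted by (contig, pos, alt)
#'   and duplicate (contig, pos, alt) keys rejected.
#' @return object of class `strain_variant_set`.
#' @export
strain_variant_set <- function(strain_id, variants = empty_variants()) {
  needed <- c("contig", "pos", "ref", "alt", "qual", "mq", "depth",
              "alt_forward", "alt_reverse")
  missing <- setdiff(needed, names(variants))
  if (length(missing))
    stop("variant table lacks columns: ", paste(missing, collapse = ", "))
  variants <- variants[, needed, drop = FALSE]
  variants <- variants[order(variants$contig, variants$pos, variants$alt), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  key <- paste(variants$contig, variants$pos, variants$alt)
  if (anyDuplicated(key))
    stop("duplicate (contig, pos, alt) keys in strain ", strain_id)
  if (any(variants$ref == variants$alt))
    stop("ref == alt in strain ", strain_id)
  if (any(variants$alt_forward + variants$alt_reverse > variants$depth))
    stop("alt support exceeds depth in strain ", strain_id)
  structure(list(strain_id = strain_id, variants = variants),
            class = "strain_variant_set")
}

#' @exportS3Method base::print
print.strain_variant_set <- function(x, ...) {
  cat(sprintf("<strain_variant_set> %s: %d variant(s)\n",
              x$strain_id, nrow(x$variants)))
  invisible(x)
}

#' Construct a panel index
#'
#' @param keys data frame with columns contig, pos, ref, alt (unique keys).
#' @param n_source_lines number of panel lines the keys came from.
#' @return object of class `panel_index`.
#' @export
panel_index <- function(keys, n_source_lines = 1L) {
  keys <- keys[, c("contig", "pos", "ref", "alt"), drop = FALSE]
  keys <- keys[!duplicated(variant_key(keys)), , drop = FALSE]
  rownames(keys) <- NULL
  stopifnot(n_source_lines >= 1L)
  structure(list(keys = keys, n_source_lines = as.integer(n_source_lines)),
            class = "panel_index")
}

#' @exportS3Method base::print
print.panel_index <- function(x, ...) {
  cat(sprintf("<panel_index> %d variant key(s) from %d line(s)\n",
              nrow(x$keys), x$n_source_lines))
  invisible(x)
}
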