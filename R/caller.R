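#' Construct a pileup site
#'
#' Per-base read counts at one position, split by sequencing strand.
#'
#' @param contig,pos site coordinates (1-based).
#' @param ref reference base.
#' @param fwd,rev named numeric vectors of counts for A, C, G, T on the
#'   forward and reverse strand.
#' @return object of class `pileup_site`.
#' @export
pileup_site <- function(contig, pos, ref, fwd, rev) {
  bases <- c("A", "C", "G", "T")
  norm <- function(x) {
    out <- setNames(integer(4L), bases)
    if (length(x)) out[intersect(names(x), bases)] <-
        as.integer(x[intersect(names(x), bases)])
    out
  }
  fwd <- norm(fwd); rev <- norm(rev)
  if (any(fwd < 0L) || any(rev < 0L)) stop("negative pileup counts")
  structure(list(contig = contig, pos = as.integer(pos), ref = ref,
                 fwd = fwd, rev = rev), class = "pileup_site")
}

#' Naive frequency-based variant calling at one site
#'
#' Calls the majority non-reference base when total depth reaches
#' `min_depth` and its read fraction reaches `min_alt_fraction`.  Call
#' quality is a monotone function of the alt count: -10 log10 of the upper
#' binomial tail of the alt count under a sequencing error rate of 0.01.
#' Ties between alt bases break deterministically by base order A < C < G < T.
#'
#' @param site a [pileup_site()].
#' @param min_depth minimum total depth for a call.
#' @param min_alt_fraction minimum alt read fraction for a call.
#' @return one-row variant data frame, or `NULL` when no call.
#' @export
call_site <- function(site, min_depth = 10L, min_alt_fraction = 0.5) {
  tot <- site$fwd + site$rev
  depth <- sum(tot)
  if (depth < min_depth) return(NULL)
  alt_bases <- setdiff(names(tot), site$ref)
  alt_counts <- tot[alt_bases]
  if (all(alt_counts == 0L)) return(NULL)
  best <- alt_bases[which.max(alt_counts)]   # which.max: first max, A<C<G<T
  if (alt_counts[[best]] / depth < min_alt_fraction) return(NULL)
  data.frame(contig = site$contig, pos = site$pos, ref = site$ref, alt = best,
             qual = qual_from_counts(alt_counts[[best]], depth),
             mq = NA_real_, depth = depth,
             alt_forward = site$fwd[[best]], alt_reverse = site$rev[[best]],
             stringsAsFactors = FALSE)
}
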