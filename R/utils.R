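#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate median p.adjust pbinom pchisq quantile rbinom
#'   rnbinom rnorm runif setNames rlnorm sd
#' @importFrom utils head read.table write.table
#' @importFrom methods is
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators are pure functions of their seed.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(expr)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

comp_base <- function(b) unname(COMPLEMENT[b])

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# Transition partner of each base (A<->G, C<->T).
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# Canonical variant key used for panel subtraction and truth comparison.
variant_key <- function(df) {
  paste(df$contig, df$pos, df$ref, df$alt, sep = ":")
}

position_key <- function(df) paste(df$contig, df$pos, sep = ":")

# Empty variant table with the canonical column set.
empty_variants <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), mq = numeric(),
             depth = integer(), alt_forward = integer(),
             alt_reverse = integer(), stringsAsFactors = FALSE)
}

# Phred-like call quality: upper binomial tail of observing >= alt reads out
# of depth under a per-base error rate, floored to keep the score finite.
qual_from_counts <- function(alt, depth, error_rate = 0.01) {
  p <- pbinom(alt - 1, depth, error_rate, lower.tail = FALSE)
  -10 * log10(pmax(p, 1e-100))
}

#' Alt-allele read fraction of a variant table
#'
#' Defined as (alt_forward + alt_reverse) / depth, the read-fraction reading
#' of "variant frequency" natural for haploid data.
#'
#' @param variants data frame with `alt_forward`, `alt_reverse`, `depth`.
#' @return numeric vector in \[0, 1\].
#' @export
alt_fraction <- function(variants) {
  (variants$alt_forward + variants$alt_reverse) / variants$depth
}

`%||%` <- function(a, b) if (is.null(a)) b else a
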