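#' Upper-tail chi-squared probability
#'
#' @param statistic chi-squared value (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return upper-tail probability.
#' @export
chisq_pvalue <- function(statistic, df = 1L) {
  stopifnot(statistic >= 0, df >= 1)
  pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Yates-corrected goodness-of-fit test against an expected ratio
#'
#' Tests observed category counts against expected proportions (e.g. a 1:1
#' Mendelian segregation ratio).  The continuity correction is clamped,
#' `max(0, |O - E| - 0.5)`, so a perfect fit gives a statistic of exactly 0;
#' by default it is applied only for two categories (df = 1), the standard
#' practice.
#'
#' @param observed integer counts per category.
#' @param expected_ratio positive weights, e.g. `c(1, 1)`.
#' @param yates apply the continuity correction ("auto" = only when df is 1).
#' @return object of class `segregation_result`: observed, expected,
#'   statistic, df, p_value, yates flag.
#' @export
yates_chisq_gof <- function(observed, expected_ratio = rep(1, length(observed)),
                            yates = c("auto", "always", "never")) {
  yates <- match.arg(yates)
  stopifnot(length(observed) >= 2L, length(observed) == length(expected_ratio),
            all(observed >= 0), all(expected_ratio > 0))
  total <- sum(observed)
  if (total <= 0) stop("total count must be positive")
  expected <- total * expected_ratio / sum(expected_ratio)
  if (any(expected == 0)) stop("expected count of zero")
  df <- length(observed) - 1L
  use_yates <- switch(yates, auto = df == 1L, always = TRUE, never = FALSE)
  dev <- abs(observed - expected)
  if (use_yates) dev <- pmax(0, dev - 0.5)
  statistic <- sum(dev^2 / expected)
  structure(list(observed = observed, expected_ratio = expected_ratio,
                 expected = expected, statistic = statistic, df = df,
                 p_value = chisq_pvalue(statistic, df), yates = use_yates),
            class = "segregation_result")
}

#' @exportS3Method base::print
print.segregation_result <- function(x, ...) {
  cat(sprintf(
    "<segregation_result> observed %s vs ratio %s: chi2%s = %.4f, df = %d, P = %.4f\n",
    paste(x$observed, collapse = ":"),
    paste(x$expected_ratio, collapse = ":"),
    if (x$yates) " (Yates)" else "", x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Mutation-phenotype co-segregation check
#'
#' Counts individuals whose genotype class matches their phenotype class;
#' perfect co-segregation of a candidate mutation means zero discordant
#' individuals.
#'
#' @param genotypes data frame with `individual_id` and `genotype`.
#' @param phenotypes data frame with `individual_id` and `phenotype`.
#' @return list: `n_concordant`, `n_discordant`, `discordant_ids`.
#' @export
cosegregation <- function(genotypes, phenotypes) {
  g_ids <- genotypes$individual_id; p_ids <- phenotypes$individual_id
  missing <- c(setdiff(g_ids, p_ids), setdiff(p_ids, g_ids))
  if (length(missing))
    stop("individual ids not shared by both tables: ",
         paste(sort(unique(missing)), collapse = ", "))
  if (nrow(genotypes) == 0L)
    return(list(n_concordant = 0L, n_discordant = 0L,
                discordant_ids = character(0)))
  m <- merge(genotypes[, c("individual_id", "genotype")],
             phenotypes[, c("individual_id", "phenotype")],
             by = "individual_id")
  disc <- m$genotype != m$phenotype
  list(n_concordant = sum(!disc), n_discordant = sum(disc),
       discordant_ids = m$individual_id[disc])
}
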