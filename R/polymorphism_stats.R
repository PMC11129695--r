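#' Morph percentages from a count row
#'
#' @param counts named or unnamed non-negative integer vector of morph counts
#'   with positive total.
#' @param digits decimal places to report (default 1, the field's convention).
#' @return numeric vector of percentages (`100 * count / total`), rounded.
#' @examples
#' phenotype_percentages(c(darter = 48, leech = 9)) # 84.2 / 15.8
#' @export
phenotype_percentages <- function(counts, digits = 1) {
  if (any(counts < 0) || any(counts != trunc(counts))) {
    stop("counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total <= 0) stop("count total must be > 0")
  round(100 * counts / total, digits)
}

#' Temporal stability test of morph frequencies
#'
#' Tests whether the morph ratio differs between two samples (e.g. a
#' historical and a contemporary collection) from a 2x2 table of counts.
#' Reports both the Pearson chi-square statistic WITHOUT continuity
#' correction (with its df = 1 p-value) and the two-sided Fisher exact
#' p-value (hypergeometric: summing all tables at least as improbable as the
#' observed one), since both are in common use for such tables.
#'
#' @param table a 2x2 matrix (rows: time periods/samples; columns: morphs) of
#'   non-negative integer counts with no all-zero row or column margin.
#' @return list with `chi2`, `chi2_p`, `fisher_p`, `percentages` (per-row
#'   morph percentages), and the input `table`.
#' @export
ratio_stability_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != trunc(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("table has an all-zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  ft <- stats::fisher.test(table)
  pct <- t(apply(table, 1L, phenotype_percentages))
  list(chi2 = unname(ct$statistic), chi2_p = ct$p.value,
       fisher_p = ft$p.value, percentages = pct, table = table)
}

#' Brood phenotype counts
#'
#' @param n_darter,n_leech offspring counts per morph (non-negative; positive
#'   total required for testing).
#' @param dam_morph the dam's own lure morph.
#' @return object of class `brood_counts`.
#' @export
brood_counts <- function(n_darter, n_leech, dam_morph = c("leech", "darter")) {
  dam_morph <- match.arg(dam_morph)
  if (n_darter < 0 || n_leech < 0) stop("counts must be >= 0")
  structure(list(n_darter = n_darter, n_leech = n_leech,
                 dam_morph = dam_morph),
            class = "brood_counts")
}

#' Single-locus genetic model for the lure polymorphism
#'
#' One autosomal biallelic locus with complete dominance of one morph's
#' allele. The dam's genotype is specified directly; the (unknown, possibly
#' multiple) sires are modelled collectively by the frequency of the dominant
#' allele among the paternal gametes — multiple paternity changes only that
#' frequency, not the random-union-of-gametes calculation.
#'
#' @param dominant_morph which morph the dominant allele produces.
#' @param dam_genotype `"AA"` (homozygous dominant), `"Aa"` (heterozygous) or
#'   `"aa"` (homozygous recessive), written in terms of the dominant allele A.
#' @param sire_dominant_freq frequency of the dominant allele among paternal
#'   gametes, in [0, 1].
#' @return object of class `genetic_model`.
#' @export
genetic_model <- function(dominant_morph = c("leech", "darter"),
                          dam_genotype = c("Aa", "AA", "aa"),
                          sire_dominant_freq = 0) {
  dominant_morph <- match.arg(dominant_morph)
  dam_genotype <- match.arg(dam_genotype)
  if (sire_dominant_freq < 0 || sire_dominant_freq > 1) {
    stop("sire_dominant_freq must be in [0, 1]")
  }
  structure(list(dominant_morph = dominant_morph,
                 dam_genotype = dam_genotype,
                 sire_dominant_freq = sire_dominant_freq),
            class = "genetic_model")
}

# Dam's phenotype implied by the model.
model_dam_morph <- function(model) {
  morphs <- c("darter", "leech")
  recessive <- setdiff(morphs, model$dominant_morph)
  if (model$dam_genotype == "aa") recessive else model$dominant_morph
}

# Probability the dam transmits the dominant allele.
dam_dominant_transmission <- function(model) {
  switch(model$dam_genotype, AA = 1, Aa = 0.5, aa = 0)
}

#' Expected offspring morph proportions under a single-locus model
#'
#' Random union of gametes: an offspring shows the dominant morph unless both
#' the maternal and the paternal allele are recessive.
#'
#' @param model a [genetic_model()].
#' @return named numeric vector with the expected fraction of `darter` and
#'   `leech` offspring.
#' @export
expected_offspring_proportions <- function(model) {
  stopifnot(inherits(model, "genetic_model"))
  d <- dam_dominant_transmission(model)
  s <- model$sire_dominant_freq
  p_dominant <- 1 - (1 - d) * (1 - s)
  out <- c(p_dominant, 1 - p_dominant)
  names(out) <- c(model$dominant_morph,
                  setdiff(c("darter", "leech"), model$dominant_morph))
  out[c("darter", "leech")]
}

#' Exact segregation test of brood phenotype counts
#'
#' Exact binomial test of the observed count of maternal-morph offspring
#' against the proportion expected under a single-locus model. The dam's
#' morph implied by the model must match the brood's recorded dam morph.
#' Two-sided p sums the probabilities of all outcomes no more probable than
#' the observed one (the `stats::binom.test` convention); the one-sided p is
#' taken in the direction of the observed deviation. A model whose expected
#' proportion is 0 or 1 but is contradicted by the observations is reported
#' as impossible (p = 0).
#'
#' @param brood a [brood_counts()] with positive total.
#' @param model a [genetic_model()].
#' @param alpha rejection level for the verdict (default 0.05, applied to the
#'   two-sided p).
#' @return list with `expected_proportion` (of the maternal morph),
#'   `observed` (maternal-morph count), `n`, `p_one_sided`, `p_two_sided`,
#'   `alpha`, and `verdict` (`"rejected"`, `"not rejected"`, or
#'   `"impossible under model"`).
#' @export
segregation_test <- function(brood, model, alpha = 0.05) {
  stopifnot(inherits(brood, "brood_counts"), inherits(model, "genetic_model"))
  n <- brood$n_darter + brood$n_leech
  if (n <= 0) stop("brood total must be > 0")
  if (model_dam_morph(model) != brood$dam_morph) {
    stop("model implies a ", model_dam_morph(model),
         " dam but the brood's dam is ", brood$dam_morph)
  }
  exp_prop <- expected_offspring_proportions(model)[[brood$dam_morph]]
  x <- if (brood$dam_morph == "darter") brood$n_darter else brood$n_leech
  if (exp_prop %in% c(0, 1) && ((exp_prop == 0 && x > 0) ||
                                (exp_prop == 1 && x < n))) {
    return(list(expected_proportion = exp_prop, observed = x, n = n,
                p_one_sided = 0, p_two_sided = 0, alpha = alpha,
                verdict = "impossible under model"))
  }
  p_two <- stats::binom.test(x, n, exp_prop)$p.value
  p_one <- if (x / n <= exp_prop) {
    stats::pbinom(x, n, exp_prop)
  } else {
    stats::pbinom(x - 1L, n, exp_prop, lower.tail = FALSE)
  }
  list(expected_proportion = exp_prop, observed = x, n = n,
       p_one_sided = p_one, p_two_sided = p_two, alpha = alpha,
       verdict = if (p_two <= alpha) "rejected" else "not rejected")
}
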