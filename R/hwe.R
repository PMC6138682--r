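#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test for a biallelic variant: enumerates all possible
#' heterozygote counts compatible with the observed allele counts, and sums
#' the conditional probabilities of genotype configurations no more likely
#' than the observed one (the standard exact HWE test used in genotype QC).
#'
#' @param n_het Observed heterozygote count.
#' @param n_hom_ref,n_hom_alt Observed homozygote counts.
#' @return Two-sided exact P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_het, n_hom_ref, n_hom_alt) {
  if (any(c(n_het, n_hom_ref, n_hom_alt) < 0)) stopf("genotype counts must be nonnegative")
  n <- n_het + n_hom_ref + n_hom_alt
  if (n == 0L) return(1)
  n_rare <- n_het + 2L * min(n_hom_ref, n_hom_alt)
  ## heterozygote count must have the parity of the rare-allele count
  hets <- seq(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  ## log conditional probability of each het count given allele counts
  logp <- lchoose(n, hets) + hets * log(2) +
    lchoose(n - hets, (n_rare - hets) / 2) -
    lchoose(2L * n, n_rare)
  ## normalise within the enumerated support (lchoose form is exact up to
  ## the common normalising constant)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}
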