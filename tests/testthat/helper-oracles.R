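# Independent oracles used to freeze expected values.

# Root-finder oracle for the level-curve conversion: the midpoint-to-E10
# ratio K/E10 such that the Hill curve with midpoint K, scaled by 2.5 from
# -3, passes through -1.5 (10% of maximal) at glucose = E10.
oracle_beta <- function(n, E10 = 0.1) {
  f <- function(K) (K^n / (E10^n + K^n)) * 2.5 - 3 + 1.5
  uniroot(f, c(E10 * 1e-4, E10 * 1e4), tol = 1e-13)$root / E10
}

# Root-finder oracle for the fraction-curve conversion: the ratio a such
# that a Hill curve with midpoint a*F90 passes through 0.9 at F90.
oracle_alpha <- function(n) {
  f <- function(a) a^n / (1 + a^n) - 0.9
  uniroot(f, c(1e-6, 1e6), tol = 1e-13)$root
}

# Brute-force enumeration of the descending geometric titration series.
oracle_titration <- function(top, bottom, factor) {
  out <- c()
  g <- top
  while (g >= bottom * (1 - 1e-8)) {
    out <- c(out, g)
    g <- g / factor
  }
  out
}

# Two-component normal mixture with exact component counts. The means are
# placed `sep` base SDs apart around `center`, weighted so the overall mean
# stays at `center`; minor weight `w` sits on the high-expression side.
make_mixture <- function(n, sep, w, base_sd = 0.3, center = -1.75, seed = 1) {
  n_min <- round(w * n)
  withr::with_seed(seed, c(
    rnorm(n - n_min, center - sep * base_sd * w, base_sd),
    rnorm(n_min, center + sep * base_sd * (1 - w), base_sd)
  ))
}
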