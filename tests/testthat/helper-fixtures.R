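# Shared fixtures, built in code.

# genotype table with hand-set dosages: 4 sites, 2 diploids per population
hand_genotypes <- function() {
  tibble::tibble(
    chrom = "chr1",
    pos = c(10, 20, 30, 40),
    a1 = c(0, 1, 2, 0),
    a2 = c(0, 2, 2, 1),
    b1 = c(2, 0, 2, 0),
    b2 = c(2, 1, 2, 0)
  )
}

# independent per-site Hudson components, written directly from the
# estimator definition (oracle for windowed_stats)
hudson_oracle <- function(ca, cb, na, nb) {
  pa <- ca / na
  pb <- cb / nb
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  list(num = num, den = den,
       pi_a = 2 * pa * (1 - pa) * na / (na - 1),
       pi_b = 2 * pb * (1 - pb) * nb / (nb - 1),
       dxy = den)
}

# dense two-step ancestry signal: first half population 1, second half pop 2
two_step_p1 <- function(n) c(rep(1, n / 2), rep(0, n / 2))

# random discrete dosage signal on the {0, 1/2, 1} alphabet
random_dosage <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(c(0, 0.5, 1), n, replace = TRUE)
}

# eigen-based matrix exponential, independent of the package internals
expm_eigen <- function(M) {
  eg <- eigen(M)
  Re(eg$vectors %*% diag(exp(eg$values)) %*% solve(eg$vectors))
}

# per-taxon frequency table for site-pattern tests
freq_sites <- function(p1, p2, o1, o2 = NULL, pos = NULL, chrom = "chr1") {
  n <- length(p1)
  tb <- tibble::tibble(chrom = chrom,
                       pos = if (is.null(pos)) seq_len(n) * 100 else pos,
                       p1 = p1, p2 = p2, o1 = o1)
  if (!is.null(o2)) tb$o2 <- o2
  tb
}
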