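#' Two-deme coalescent pair simulation with lineage-specific mutation rates
#'
#' Continuous-time (Gillespie) simulation of the two-lineage structured
#' coalescent of [im_rate_matrix()]: each lineage migrates between the two
#' demes at rate `m` and a pair in the same deme coalesces at rate `1/N`.
#' Sojourn times per lineage per deme are accumulated and, under the
#' infinite-site model, the number of derived alleles exclusive to each
#' lineage is Poisson with mean `mu_i x` (sojourn in deme `i`), so pooled
#' `mean(n2) / mean(n1)` estimates the observed rate ratio of
#' [r_from_fst()].
#'
#' @param n_loci Number of independent loci (exchangeable pair draws).
#' @param N Haploid deme size.
#' @param m Per-generation migration rate per lineage.
#' @param mu1,mu2 Substitution rates (per locus per generation) in demes 1
#'   and 2; `r0 = mu2 / mu1`.
#' @param sampling `"between"` (default: lineage 1 from deme 1, lineage 2
#'   from deme 2) or `"within"` (both from deme 1), the latter used for
#'   empirical FST.
#' @param seed Integer seed (mandatory).
#' @return Tibble with one row per locus: `t_coal`, per-lineage sojourn
#'   times `s1_d1`, `s1_d2`, `s2_d1`, `s2_d2` (lineage x deme), exclusive
#'   derived-allele counts `n1`, `n2`, and the sampled-deme labels
#'   `deme1`, `deme2`.
#' @export
#' @examples
#' sim <- simulate_im_pair(2000, N = 100, m = 0.01, mu1 = 1, mu2 = 2,
#'                         seed = 1)
#' mean(sim$n2) / mean(sim$n1)  # near r_from_fst(0.2, 2)
simulate_im_pair <- function(n_loci, N, m, mu1, mu2,
                             sampling = c("between", "within"), seed) {
  sampling <- match.arg(sampling)
  check_positive(N, "N", scalar = TRUE)
  check_positive(m, "m", scalar = TRUE)
  check_positive(mu1, "mu1", scalar = TRUE)
  check_positive(mu2, "mu2", scalar = TRUE)
  with_seed(seed, {
    start2 <- if (sampling == "between") 2L else 1L
    p1 <- rep(1L, n_loci)           # deme of lineage 1
    p2 <- rep(start2, n_loci)       # deme of lineage 2
    s <- matrix(0, n_loci, 4)       # s1_d1, s1_d2, s2_d1, s2_d2
    t_coal <- rep(NA_real_, n_loci)
    t_now <- rep(0, n_loci)
    active <- seq_len(n_loci)
    while (length(active)) {
      a1 <- p1[active]; a2 <- p2[active]
      same <- a1 == a2
      rate <- 2 * m + same / N
      dt <- rexp(length(active), rate)
      t_now[active] <- t_now[active] + dt
      s[cbind(active, a1)] <- s[cbind(active, a1)] + dt
      s[cbind(active, 2L + a2)] <- s[cbind(active, 2L + a2)] + dt
      u <- runif(length(active)) * rate
      coal <- same & u < 1 / N
      mig1 <- !coal & (u - same / N) < m    # else migrate lineage 2
      idx <- active[coal]
      t_coal[idx] <- t_now[idx]
      flip <- active[!coal & mig1]
      p1[flip] <- 3L - p1[flip]
      flip2 <- active[!coal & !mig1]
      p2[flip2] <- 3L - p2[flip2]
      active <- active[!coal]
    }
    n1 <- rpois(n_loci, mu1 * s[, 1] + mu2 * s[, 2])
    n2 <- rpois(n_loci, mu1 * s[, 3] + mu2 * s[, 4])
    tibble::tibble(t_coal = t_coal,
                   s1_d1 = s[, 1], s1_d2 = s[, 2],
                   s2_d1 = s[, 3], s2_d2 = s[, 4],
                   n1 = n1, n2 = n2,
                   deme1 = 1L, deme2 = start2)
  })
}

#' Summaries of a pair simulation: rate ratio and empirical FST
#'
#' `im_pair_ratio()` returns the pooled ratio `mean(n2) / mean(n1)` with a
#' delta-method Monte-Carlo SE. `im_pair_fst()` combines between- and
#' within-deme pair simulations into Hudson-style
#' `FST = 1 - mean(T_within) / mean(T_between)` with a delta-method SE.
#'
#' @param sim,between,within Tibbles from [simulate_im_pair()].
#' @return One-row tibble (`estimate`, `se`, `n`).
#' @export
im_pair_ratio <- function(sim) {
  m1 <- mean(sim$n1); m2 <- mean(sim$n2)
  n <- nrow(sim)
  est <- m2 / m1
  se <- est * sqrt(var(sim$n2) / (n * m2^2) + var(sim$n1) / (n * m1^2))
  tibble::tibble(estimate = est, se = se, n = n)
}

#' @rdname im_pair_ratio
#' @export
im_pair_fst <- function(between, within) {
  tb <- mean(between$t_coal); tw <- mean(within$t_coal)
  ratio <- tw / tb
  se <- ratio * sqrt(var(within$t_coal) / (nrow(within) * tw^2) +
                       var(between$t_coal) / (nrow(between) * tb^2))
  tibble::tibble(estimate = 1 - ratio, se = se,
                 n = nrow(between) + nrow(within))
}

# ---- multi-sample structured coalescent (one locus) ------------------------

# Simulates n1 + n2 haploid lineages in two demes (sizes N, migration m_rate)
# until the MRCA; drops infinite-site mutations on each lineage interval with
# deme-specific rates. Returns a 0/1 haplotype matrix (tips x sites).
coalesce_window <- function(n_tips_1, n_tips_2, N, m_rate, mu1, mu2) {
  n_tips <- n_tips_1 + n_tips_2
  deme <- c(rep(1L, n_tips_1), rep(2L, n_tips_2))
  members <- as.list(seq_len(n_tips))   # descendant tips of each lineage
  derived <- list()                     # tip sets carrying each mutation
  k <- length(members)
  while (k > 1) {
    in1 <- sum(deme == 1); in2 <- k - in1
    c_rate <- (in1 * (in1 - 1) + in2 * (in2 - 1)) / (2 * N)
    tot <- c_rate + k * m_rate
    dt <- rexp(1, tot)
    # mutations along every active lineage during dt
    lam <- ifelse(deme == 1, mu1, mu2) * dt
    hits <- rpois(k, lam)
    for (j in which(hits > 0)) {
      derived <- c(derived, rep(members[j], hits[j]))
    }
    if (runif(1) * tot < c_rate) {
      # coalescence within a deme chosen by pair weight
      w1 <- in1 * (in1 - 1)
      d <- if (runif(1) * (w1 + in2 * (in2 - 1)) < w1) 1L else 2L
      pair <- sample(which(deme == d), 2)
      members[[pair[1]]] <- c(members[[pair[1]]], members[[pair[2]]])
      members[[pair[2]]] <- NULL
      deme <- deme[-pair[2]]
      k <- k - 1
    } else {
      j <- sample.int(k, 1)
      deme[j] <- 3L - deme[j]
    }
  }
  n_mut <- length(derived)
  H <- matrix(0L, n_tips, n_mut)
  for (s in seq_len(n_mut)) H[derived[[s]], s] <- 1L
  # segregating among the sampled tips only
  seg <- colSums(H) > 0 & colSums(H) < n_tips
  H[, seg, drop = FALSE]
}

#' Simulate a multi-window genomic landscape under heterogeneous gene flow
#'
#' Emulates a two-population genome scan: windows belong to gene-flow
#' classes with distinct `Nm` (hence distinct equilibrium FST by
#' [fst_equilibrium()]), each window is an independent equilibrium two-deme
#' coalescent locus with deme-specific substitution rates `mu1`, `mu2`, and
#' haploid genomes are paired into unphased diploid genotypes. Two outgroup
#' taxa fixed for the ancestral allele are appended; optional recurrent
#' outgroup mutations (probability `p_recur[i]` per site in outgroup `i`,
#' converting to the focal derived allele with probability `conversion`,
#' otherwise dropping the site as triallelic) switch D3/D4 biases on.
#'
#' @param classes Data frame with one row per gene-flow class: columns `nm`
#'   (the product `Nm`) and `n_windows`.
#' @param N Haploid deme size (sets the time scale).
#' @param mu1,mu2 Per-window per-generation substitution rates in demes 1
#'   and 2.
#' @param n_dip Diploid samples per population (default 4).
#' @param window_span Window width in bp (default 5e4); windows are laid
#'   end-to-end on one synthetic chromosome per class, separated so 1 Mb
#'   jackknife blocks hold several windows.
#' @param loci_per_window Number of freely recombining coalescent loci per
#'   window (default 10): genomic windows span many quasi-independent
#'   genealogies, so averaging several loci per window mimics intra-window
#'   recombination and keeps realized window FST close to its equilibrium
#'   expectation.
#' @param p_recur Length-2 recurrent-mutation probabilities for the two
#'   outgroups (default `c(0, 0)`: outgroups stay ancestral).
#' @param conversion Conversion probability `c` for recurrent mutations.
#' @param seed Integer seed (mandatory).
#' @return List with `genotypes` (tibble: `chrom`, `pos`, focal diploid
#'   dosage columns `p1_1..`, `p2_1..`, homozygous outgroup dosage columns
#'   `o1`, `o2`), `windows` (tibble: window coordinates, class, true `nm`,
#'   expected FST) and `samples` (population map tibble).
#' @export
simulate_im_landscape <- function(classes, N = 50, mu1 = 0.2, mu2 = 0.2,
                                  n_dip = 4, window_span = 5e4,
                                  loci_per_window = 10,
                                  p_recur = c(0, 0), conversion = 1, seed) {
  classes <- tibble::as_tibble(classes)
  stopifnot(all(c("nm", "n_windows") %in% names(classes)))
  if (nrow(classes) < 1) abort("need at least one gene-flow class.")
  with_seed(seed, {
    pop_a <- paste0("p1_", seq_len(n_dip))
    pop_b <- paste0("p2_", seq_len(n_dip))
    geno <- list()
    windows <- list()
    wi <- 0L
    for (ci in seq_len(nrow(classes))) {
      m_rate <- classes$nm[ci] / N
      chrom <- sprintf("sim%02d", ci)
      for (w in seq_len(classes$n_windows[ci])) {
        wi <- wi + 1L
        start <- (w - 1L) * window_span
        H <- do.call(cbind, lapply(seq_len(loci_per_window), function(l) {
          coalesce_window(2 * n_dip, 2 * n_dip, N, m_rate,
                          mu1 / loci_per_window, mu2 / loci_per_window)
        }))
        n_sites <- ncol(H)
        windows[[wi]] <- tibble::tibble(
          chrom = chrom, start = start, end = start + window_span,
          class = ci, nm = classes$nm[ci],
          fst_expected = fst_equilibrium(N, m_rate))
        if (n_sites == 0) next
        pos <- start + sort(sample.int(window_span, n_sites))
        dip_a <- H[seq_len(n_dip) * 2 - 1, , drop = FALSE] +
          H[seq_len(n_dip) * 2, , drop = FALSE]
        dip_b <- H[2 * n_dip + seq_len(n_dip) * 2 - 1, , drop = FALSE] +
          H[2 * n_dip + seq_len(n_dip) * 2, , drop = FALSE]
        g <- tibble::tibble(chrom = chrom, pos = pos)
        for (j in seq_len(n_dip)) g[[pop_a[j]]] <- dip_a[j, ]
        for (j in seq_len(n_dip)) g[[pop_b[j]]] <- dip_b[j, ]
        # outgroups: ancestral unless a recurrent mutation converts them
        o1 <- o2 <- rep(0, n_sites)
        keep <- rep(TRUE, n_sites)
        for (oi in 1:2) {
          p <- p_recur[oi]
          if (p <= 0) next
          hit <- runif(n_sites) < p
          conv <- hit & runif(n_sites) < conversion
          keep <- keep & (!hit | conv)     # unconverted hits -> triallelic
          if (oi == 1) o1[conv] <- 1 else o2[conv] <- 1
        }
        g$o1 <- 2 * o1   # homozygous outgroup dosage
        g$o2 <- 2 * o2
        geno[[wi]] <- g[keep, , drop = FALSE]
      }
    }
    list(genotypes = dplyr::bind_rows(geno),
         windows = dplyr::bind_rows(windows),
         samples = tibble::tibble(
           sample = c(pop_a, pop_b, "o1", "o2"),
           population = c(rep(c("pop1", "pop2"), each = n_dip),
                          "outgroup1", "outgroup2")))
  })
}

#' Stepping-stone pair simulation
#'
#' Structured-coalescent simulation of a lineage pair on a 1-D chain of
#' demes split into two species, probing how within-species population
#' structure inflates FST without an equivalent rise in rate divergence.
#' Lineages walk to adjacent demes at rate `m_within` (same species) or
#' `m_between` (the boundary edge) and coalesce at rate `1/N` when
#' co-located; mutation rates are species-specific (`mu1` for demes in
#' species 1, `mu2` in species 2). With 2 demes the model reduces exactly
#' to [simulate_im_pair()].
#'
#' @param n_loci Number of independent pair draws.
#' @param n_demes Number of demes in the chain (>= 2).
#' @param split Last deme index belonging to species 1 (demes `1..split`
#'   are species 1; default `n_demes / 2`).
#' @param N Haploid deme size.
#' @param m_within Migration rate along within-species edges.
#' @param m_between Migration rate across the species boundary edge
#'   (default `m_within`).
#' @param mu1,mu2 Species-specific substitution rates.
#' @param sample_demes Length-2 deme indices the two lineages are sampled
#'   from (default: the two demes flanking the species boundary).
#' @param seed Integer seed.
#' @return Tibble per locus: `t_coal`, species-wise sojourns `s1_sp1`,
#'   `s1_sp2`, `s2_sp1`, `s2_sp2`, exclusive mutation counts `n1`, `n2`.
#' @export
simulate_stepping_stone <- function(n_loci, n_demes, split = n_demes %/% 2,
                                    N, m_within, m_between = m_within,
                                    mu1, mu2,
                                    sample_demes = c(split, split + 1),
                                    seed) {
  if (n_demes < 2) abort("need at least 2 demes.")
  if (split < 1 || split >= n_demes) abort("`split` must leave both species non-empty.")
  if (m_within <= 0 || m_between <= 0) abort("migration graph must be connected.")
  check_positive(N, "N", scalar = TRUE)
  with_seed(seed, {
    edge_rate <- function(from, to) {
      # rate of moving from deme `from` to adjacent deme `to`
      ifelse(to < 1 | to > n_demes, 0,
             ifelse((from <= split) == (to <= split), m_within, m_between))
    }
    d1 <- rep(sample_demes[1], n_loci)
    d2 <- rep(sample_demes[2], n_loci)
    s <- matrix(0, n_loci, 4)  # lineage x species sojourn
    t_coal <- rep(NA_real_, n_loci)
    t_now <- rep(0, n_loci)
    active <- seq_len(n_loci)
    while (length(active)) {
      a1 <- d1[active]; a2 <- d2[active]
      r1l <- edge_rate(a1, a1 - 1); r1r <- edge_rate(a1, a1 + 1)
      r2l <- edge_rate(a2, a2 - 1); r2r <- edge_rate(a2, a2 + 1)
      same <- a1 == a2
      tot <- r1l + r1r + r2l + r2r + same / N
      dt <- rexp(length(active), tot)
      t_now[active] <- t_now[active] + dt
      sp1 <- 1L + (a1 > split); sp2 <- 1L + (a2 > split)
      s[cbind(active, sp1)] <- s[cbind(active, sp1)] + dt
      s[cbind(active, 2L + sp2)] <- s[cbind(active, 2L + sp2)] + dt
      u <- runif(length(active)) * tot
      coal <- same & u < 1 / N
      u <- u - same / N
      e1 <- !coal & u < r1l
      e2 <- !coal & !e1 & u < r1l + r1r
      e3 <- !coal & !e1 & !e2 & u < r1l + r1r + r2l
      e4 <- !coal & !e1 & !e2 & !e3
      d1[active[e1]] <- d1[active[e1]] - 1L
      d1[active[e2]] <- d1[active[e2]] + 1L
      d2[active[e3]] <- d2[active[e3]] - 1L
      d2[active[e4]] <- d2[active[e4]] + 1L
      idx <- active[coal]
      t_coal[idx] <- t_now[idx]
      active <- active[!coal]
    }
    n1 <- rpois(n_loci, mu1 * s[, 1] + mu2 * s[, 2])
    n2 <- rpois(n_loci, mu1 * s[, 3] + mu2 * s[, 4])
    tibble::tibble(t_coal = t_coal, s1_sp1 = s[, 1], s1_sp2 = s[, 2],
                   s2_sp1 = s[, 3], s2_sp2 = s[, 4], n1 = n1, n2 = n2)
  })
}

#' Simulate site-pattern counts under recurrent outgroup mutation
#'
#' Starts from `n1` sites where the derived allele is exclusive to the
#' first focal lineage and `n2` where it is exclusive to the second, then
#' applies the single-hit recurrent-mutation model: each site experiences a
#' recurrent mutation in outgroup `i` with probability `p_i` (at most one
#' outgroup per site); a mutation converts to the focal derived allele with
#' probability `conversion` (flipping the pattern class) and otherwise
#' leaves the mutated outgroup triallelic, excluding the site from
#' analyses that use that outgroup. The ABB/BAB counts have expectation
#' matching [d3_observed()] exactly (O2 events are invisible to the
#' three-taxon classes); the converted sites form the ABBA/BABA classes
#' with expectation matching [d4_observed()].
#'
#' @param n1,n2 True pattern counts (derived exclusive to lineage 1 / 2).
#' @param p1 Recurrent-mutation probability in outgroup 1.
#' @param p2 Recurrent-mutation probability in outgroup 2 (default 0:
#'   three-taxon setting; `p1 + p2` must be <= 1).
#' @param conversion Conversion probability `c`.
#' @param n_blocks Number of equal blocks the sites are spread over
#'   (for jackknifing; default 20).
#' @param seed Integer seed.
#' @return Block tibble compatible with [d3()] / [d4()]: columns `block`,
#'   `n_sites`, `abb`, `bab`, `abba`, `baba`, `rr_num`, `rr_den` (the
#'   rate-ratio sums count surviving, unconverted sites).
#' @export
simulate_site_patterns <- function(n1, n2, p1, conversion, p2 = 0,
                                   n_blocks = 20, seed) {
  check_prob(p1, "p1"); check_prob(p2, "p2"); check_prob(conversion, "conversion")
  if (p1 + p2 > 1) abort("`p1 + p2` must not exceed 1 (single-hit model).")
  with_seed(seed, {
    sim_class <- function(n_true) {
      # multinomial over {no hit, hit O1, hit O2} then conversion thinning
      fate <- rmultinom(1, n_true, c(1 - p1 - p2, p1, p2))[, 1]
      conv1 <- rbinom(1, fate[2], conversion)
      conv2 <- rbinom(1, fate[3], conversion)
      c(keep = fate[1], hit_o1 = fate[2], hit_o2 = fate[3],
        conv_o1 = conv1, conv_o2 = conv2)
    }
    a <- sim_class(n1)   # sites with derived exclusive to lineage 1 ("ABB")
    b <- sim_class(n2)
    # Three-taxon classes see only O1: an O1 conversion flips the class, an
    # unconverted O1 hit makes O1 triallelic (site excluded), and any O2
    # event is invisible. O2 conversions create the four-taxon ABBA/BABA
    # classes (via relabelling; see d4_observed()); the rate-ratio sums
    # require every outgroup untouched.
    tot <- tibble::tibble(
      abb = a[["keep"]] + a[["hit_o2"]] + b[["conv_o1"]],
      bab = b[["keep"]] + b[["hit_o2"]] + a[["conv_o1"]],
      abba = a[["conv_o2"]] + b[["conv_o1"]],
      baba = b[["conv_o2"]] + a[["conv_o1"]],
      rr_num = a[["keep"]], rr_den = b[["keep"]])
    # spread counts over blocks multinomially (sites are exchangeable)
    split_count <- function(x) rmultinom(1, x, rep(1, n_blocks))[, 1]
    blocks <- tibble::tibble(block = sprintf("block%03d", seq_len(n_blocks)))
    for (col in names(tot)) blocks[[col]] <- split_count(tot[[col]])
    blocks$n_sites <- blocks$abb + blocks$bab
    blocks[c("block", "n_sites", "abb", "bab", "abba", "baba",
             "rr_num", "rr_den")]
  })
}

#' Simulate unphased block-ancestry signals
#'
#' Toy model of diploid local ancestry on a uniform chromosome: each
#' haploid chromosome carries `n_snps` equally spaced markers; between
#' adjacent markers ancestry dissociates (a new block starts) with
#' probability `break_prob`; each block's ancestry is drawn Bernoulli(`q`)
#' from parental population 1. Two haploids combine into an unphased
#' diploid dosage in \{0, 1/2, 1\}. Replicated cohorts support averaging
#' entropy over many simulations.
#'
#' @param n_snps Markers per chromosome (>= 2; default 1000).
#' @param break_prob Ancestry-disassociation probability per adjacent
#'   marker pair, in \[0, 1\].
#' @param q Average contribution of parental population 1, in \[0, 1\].
#' @param n_ind Diploid individuals per replicate (default 6).
#' @param n_replicates Number of replicate cohorts (default 1).
#' @param seed Integer seed.
#' @return Tibble with columns `replicate` and `dosage`, a list-column of
#'   `n_snps` x `n_ind` matrices of p1 fractions.
#' @export
simulate_block_ancestry <- function(n_snps = 1000, break_prob, q, n_ind = 6,
                                    n_replicates = 1, seed) {
  if (n_snps < 2) abort("`n_snps` must be >= 2.")
  check_prob(break_prob, "break_prob")
  check_prob(q, "q")
  with_seed(seed, {
    one_haploid <- function() {
      breaks <- c(TRUE, runif(n_snps - 1) < break_prob)
      block_id <- cumsum(breaks)
      anc <- rbinom(max(block_id), 1, q)
      anc[block_id]
    }
    purrr::map_dfr(seq_len(n_replicates), function(rep) {
      d <- vapply(seq_len(n_ind),
                  function(j) (one_haploid() + one_haploid()) / 2,
                  numeric(n_snps))
      tibble::tibble(replicate = rep, dosage = list(d))
    })
  })
}

#' Mean entropy of simulated block-ancestry cohorts
#'
#' Runs [simulate_block_ancestry()] over a parameter grid and summarizes
#' the replicate distribution of cohort-mean within-individual entropy and
#' between-individual entropy: the mean plus averaged upper and lower
#' deviations from the mean (the averages of positive and negative
#' deviations, respectively).
#'
#' @param grid Data frame with columns `break_prob` and `q`, one row per
#'   condition.
#' @param n_snps,n_ind,n_replicates Passed to [simulate_block_ancestry()].
#' @param seed Integer seed; condition `i` uses `seed + i`.
#' @return Tibble: the grid plus `sw_mean`, `sw_lo`, `sw_hi`, `sb_mean`,
#'   `sb_lo`, `sb_hi` (lo/hi are mean minus/plus the averaged deviations).
#' @export
sweep_block_ancestry <- function(grid, n_snps = 1000, n_ind = 6,
                                 n_replicates = 1000, seed) {
  grid <- tibble::as_tibble(grid)
  stopifnot(all(c("break_prob", "q") %in% names(grid)))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sims <- simulate_block_ancestry(n_snps, grid$break_prob[i], grid$q[i],
                                    n_ind, n_replicates, seed = seed + i)
    ent <- purrr::map_dfr(sims$dosage, function(d) {
      ce <- cohort_entropy(dosage_phasor_matrix(d))
      tibble::tibble(sw = mean(ce$sw), sb = ce$sb)
    })
    dev_stats <- function(x) {
      mu <- mean(x)
      up <- x[x > mu] - mu
      dn <- mu - x[x < mu]
      c(mu, mu - if (length(dn)) mean(dn) else 0,
        mu + if (length(up)) mean(up) else 0)
    }
    sw <- dev_stats(ent$sw); sb <- dev_stats(ent$sb)
    dplyr::bind_cols(grid[i, ],
                     tibble::tibble(sw_mean = sw[1], sw_lo = sw[2],
                                    sw_hi = sw[3], sb_mean = sb[1],
                                    sb_lo = sb[2], sb_hi = sb[3]))
  })
}
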