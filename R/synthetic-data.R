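#' Simulation configuration
#'
#' Bundles the parameters of the synthetic study system: `K` differentiated
#' source populations genotyped at `L` independent biallelic loci, with
#' `n_per_pop` diploid individuals per population. Population allele
#' frequencies drift away from a shared ancestral frequency under the
#' Balding-Nichols model, with `divergence` playing the role of the
#' per-population drift parameter F. The defaults emulate three
#' continental-scale source populations of 50 individuals each —
#' `divergence = 0.15` produces the strong differentiation seen between
#' African, East Asian and European reference groups, while values near
#' 0.01 emulate closely related populations (e.g. two East Asian groups)
#' among which small panels lose power.
#'
#' @param L number of loci (>= 1).
#' @param K number of source populations (>= 2).
#' @param n_per_pop individuals per population.
#' @param divergence per-population drift parameter in (0, 1); scalar or
#'   length-`K` vector.
#' @param maf_range interval within (0, 1) from which ancestral reference
#'   allele frequencies are drawn uniformly.
#' @param missing_rate fraction of genotype calls to knock out in `[0, 1)`.
#' @param seed integer seed making every generated object reproducible.
#' @param pop_names population labels (defaults `POP1..POPK`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(L = 5000, K = 3, n_per_pop = 50, divergence = 0.15,
                       maf_range = c(0.05, 0.95), missing_rate = 0,
                       seed = 1, pop_names = NULL) {
  stopifnot(L >= 1, K >= 2, n_per_pop >= 1,
            all(divergence > 0), all(divergence < 1),
            length(divergence) %in% c(1L, K),
            missing_rate >= 0, missing_rate < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] < 1,
            maf_range[1] <= maf_range[2])
  if (length(divergence) == 1) divergence <- rep(divergence, K)
  pop_names <- pop_names %||% paste0("POP", seq_len(K))
  stopifnot(length(pop_names) == K)
  structure(list(L = as.integer(L), K = as.integer(K),
                 n_per_pop = as.integer(n_per_pop), divergence = divergence,
                 maf_range = maf_range, missing_rate = missing_rate,
                 seed = as.integer(seed), pop_names = pop_names),
            class = "sim_config")
}

#' Simulate population allele frequencies (Balding-Nichols)
#'
#' Draws, for each locus, an ancestral reference-allele frequency `p_l`
#' uniformly from `maf_range`, then for each population `k` a drifted
#' frequency from `Beta(p_l (1 - F_k) / F_k, (1 - p_l)(1 - F_k) / F_k)`
#' where `F_k` is that population's divergence parameter. The Beta has mean
#' `p_l` and variance `F_k p_l (1 - p_l)`, so `F_k` is the expected
#' fixation index of population `k` against the ancestral pool.
#'
#' @param cfg a [sim_config()].
#' @return An [allele_freqs()] (K x L matrix) with the ancestral frequencies
#'   attached as attribute `ancestral`.
#' @export
simulate_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    p_anc <- runif(cfg$L, cfg$maf_range[1], cfg$maf_range[2])
    P <- matrix(0, cfg$K, cfg$L)
    for (k in seq_len(cfg$K)) {
      Fk <- cfg$divergence[k]
      P[k, ] <- rbeta(cfg$L, p_anc * (1 - Fk) / Fk,
                      (1 - p_anc) * (1 - Fk) / Fk)
    }
    out <- allele_freqs(P, pops = cfg$pop_names,
                        loci = paste0("locus", seq_len(cfg$L)))
    attr(out, "ancestral") <- p_anc
    out
  })
}

#' Simulate unadmixed genotypes from population frequencies
#'
#' Each individual in population `k` receives `g_il ~ Binomial(2, p_kl)`
#' independently across loci (Hardy-Weinberg within populations, linkage
#' equilibrium across loci — the admixture model's own assumptions).
#'
#' @param freqs an [allele_freqs()].
#' @param n_per_pop individuals per population.
#' @param seed integer seed.
#' @return A [genotype_matrix()] with population labels set.
#' @export
simulate_genotypes <- function(freqs, n_per_pop, seed = 1) {
  P <- unclass_freqs(freqs)
  K <- nrow(P); L <- ncol(P)
  pops <- rownames(P)
  with_seed(seed, {
    G <- matrix(NA_integer_, K * n_per_pop, L)
    for (k in seq_len(K)) {
      rows <- (k - 1L) * n_per_pop + seq_len(n_per_pop)
      G[rows, ] <- matrix(rbinom(n_per_pop * L, 2L,
                                 rep(P[k, ], each = n_per_pop)),
                          n_per_pop, L)
    }
    samples <- paste0(rep(pops, each = n_per_pop), "_",
                      rep(seq_len(n_per_pop), K))
    genotype_matrix(G, samples, colnames(P),
                    rep(pops, each = n_per_pop))
  })
}

#' Simulate a structured dataset in one call
#'
#' Convenience wrapper: frequencies, genotypes and (optionally) missingness
#' from a single [sim_config()].
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `freqs` (true population frequencies) and
#'   `genotypes` (a [genotype_matrix()]).
#' @export
simulate_dataset <- function(cfg) {
  freqs <- simulate_frequencies(cfg)
  gm <- simulate_genotypes(freqs, cfg$n_per_pop, seed = cfg$seed + 1L)
  if (cfg$missing_rate > 0) {
    gm <- inject_missing(gm, cfg$missing_rate, seed = cfg$seed + 2L)
  }
  list(freqs = freqs, genotypes = gm)
}

#' Build artificial admixed genomes ("AA-genomes")
#'
#' Emulates hybrid genomic profiles assembled by mixing loci at random from
#' several source populations in fixed proportions. For each hybrid the loci
#' are partitioned at random into `K` sets whose sizes follow
#' largest-remainder rounding of `proportions * L` (ties broken by
#' population index), and the genotype at every locus of set `k` is copied
#' from a single donor individual drawn uniformly from population `k` (one
#' donor per population per hybrid). The expected ancestry of every hybrid
#' is therefore exactly `proportions`; with equal thirds from three strongly
#' differentiated sources each hybrid carries ~1/3 ancestry from each group.
#'
#' @param sources a [genotype_matrix()] with population labels covering `K`
#'   source populations.
#' @param n_hybrids number of admixed genomes to build.
#' @param proportions length-`K` vector on the probability simplex giving
#'   the expected ancestry contribution of each source population (in the
#'   order of `sort(unique(pop_labels))` unless named).
#' @param seed integer seed.
#' @param label population label given to the hybrids (default
#'   `"ADMIXED"`).
#' @return A [genotype_matrix()] of `n_hybrids` rows with attribute
#'   `true_q`, the realized per-hybrid ancestry fractions (locus-set sizes /
#'   L, identical across hybrids).
#' @export
make_aa_genomes <- function(sources, n_hybrids, proportions = NULL,
                            seed = 1, label = "ADMIXED") {
  if (is.null(sources$pop_labels)) {
    stop("`sources` must carry population labels", call. = FALSE)
  }
  pops <- sort(unique(sources$pop_labels))
  K <- length(pops)
  proportions <- proportions %||% rep(1 / K, K)
  if (!is.null(names(proportions))) {
    stopifnot(setequal(names(proportions), pops))
    proportions <- proportions[pops]
  }
  if (length(proportions) != K) {
    stop("`proportions` must have one entry per source population",
         call. = FALSE)
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8) {
    stop("`proportions` must be nonnegative and sum to 1", call. = FALSE)
  }
  L <- n_loci(sources)
  sizes <- largest_remainder(proportions * L)

  pop_rows <- lapply(pops, function(p) which(sources$pop_labels == p))
  with_seed(seed, {
    G <- matrix(NA_integer_, n_hybrids, L)
    for (h in seq_len(n_hybrids)) {
      perm <- sample.int(L)
      donors <- vapply(pop_rows, function(r) r[sample.int(length(r), 1)],
                       integer(1))
      offset <- 0L
      for (k in seq_len(K)) {
        if (sizes[k] == 0) next
        cols <- perm[offset + seq_len(sizes[k])]
        G[h, cols] <- sources$G[donors[k], cols]
        offset <- offset + sizes[k]
      }
    }
    out <- genotype_matrix(G, paste0("AA_", seq_len(n_hybrids)),
                           sources$loci, rep(label, n_hybrids))
    true_q <- matrix(rep(sizes / L, each = n_hybrids), n_hybrids, K,
                     dimnames = list(out$samples, pops))
    attr(out, "true_q") <- true_q
    out
  })
}

# Largest-remainder (Hamilton) apportionment of fractional targets into
# integers summing to round(sum(x)); ties on the remainder go to the
# smallest index.
largest_remainder <- function(x) {
  total <- round(sum(x))
  base <- floor(x)
  rem <- x - base
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(-rem, seq_along(x))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Knock out genotype calls at random
#'
#' Sets each entry independently to missing with probability `rate`;
#' already-missing entries stay missing.
#'
#' @param gm a [genotype_matrix()].
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return A [genotype_matrix()].
#' @export
inject_missing <- function(gm, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(gm)
  with_seed(seed, {
    mask <- matrix(runif(length(gm$G)) < rate, nrow(gm$G), ncol(gm$G))
    G <- gm$G
    G[mask] <- NA_integer_
    genotype_matrix(G, gm$samples, gm$loci, gm$pop_labels)
  })
}
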