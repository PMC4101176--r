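# Grid-search oracle for the supervised likelihood: evaluates the
# per-individual log-likelihood on a simplex lattice with the given step.
# Kept deliberately independent of the EM implementation.
grid_loglik_max <- function(g, F, step = 0.01) {
  K <- nrow(F)
  eval_ll <- function(q) {
    p <- as.numeric(q %*% F)
    sum(g * log(p) + (2 - g) * log(1 - p), na.rm = TRUE)
  }
  best <- -Inf
  if (K == 2) {
    for (q1 in seq(0, 1, by = step)) {
      best <- max(best, eval_ll(c(q1, 1 - q1)))
    }
  } else if (K == 3) {
    for (q1 in seq(0, 1, by = step)) {
      for (q2 in seq(0, 1 - q1 + 1e-12, by = step)) {
        best <- max(best, eval_ll(c(q1, q2, 1 - q1 - q2)))
      }
    }
  } else {
    stop("oracle supports K in {2, 3}")
  }
  best
}

test_that("reference frequencies are allele counts over called chromosomes, clamped", {
  eps <- 1e-6
  G <- rbind(c(2L, 0L, 1L),
             c(2L, 1L, NA),
             c(2L, 2L, NA))
  gm <- genotype_matrix(G, paste0("s", 1:3), paste0("l", 1:3),
                        rep("P1", 3))
  fr <- estimate_frequencies(gm)
  expect_equal(unname(unclass(fr)[1, ]), c(1 - eps, 0.5, 0.5))

  # all-missing locus in one population -> 0.5 with a warning
  G2 <- rbind(c(NA, 1L), c(NA, 1L))
  gm2 <- genotype_matrix(G2, c("a", "b"), c("l1", "l2"), rep("P1", 2))
  expect_warning(fr2 <- estimate_frequencies(gm2), "no called")
  expect_equal(unname(unclass(fr2)[1, 1]), 0.5)
})

test_that("supervised estimates hit forced boundaries and degenerate cases", {
  eps <- 1e-6
  # K = 1: the simplex is a point
  F1 <- allele_freqs(matrix(0.4, 1, 6), "P1", paste0("l", 1:6))
  gm <- genotype_matrix(matrix(1L, 3, 6), paste0("s", 1:3), paste0("l", 1:6))
  fit1 <- supervised_ancestry(gm, F1)
  expect_true(all(fit1$Q == 1))

  # strongly opposed frequencies, all-reference genotypes -> q ~ (1, 0)
  F2 <- allele_freqs(rbind(rep(1 - eps, 20), rep(eps, 20)),
                     c("P1", "P2"), paste0("l", 1:20))
  gm2 <- genotype_matrix(matrix(2L, 2, 20), c("a", "b"), paste0("l", 1:20))
  fit2 <- supervised_ancestry(gm2, F2)
  expect_gt(min(fit2$Q[, "P1"]), 0.999)

  # single heterozygous locus with opposed frequencies: interior optimum at
  # (1/2, 1/2), confirmed by the grid oracle
  F3 <- allele_freqs(matrix(c(1 - eps, eps), 2, 1),
                     c("P1", "P2"), "l1")
  gm3 <- genotype_matrix(matrix(1L, 1, 1), "a", "l1")
  fit3 <- supervised_ancestry(gm3, F3, tol = 1e-10)
  expect_equal(unname(fit3$Q[1, ]), c(0.5, 0.5), tolerance = 1e-3)
  oracle <- grid_loglik_max(1, unclass(F3), step = 0.01)
  expect_gte(fit3$loglik, oracle - 1e-8)
})

test_that("supervised EM matches the simplex grid-search oracle on small instances", {
  set.seed(71)
  for (rep in 1:6) {
    K <- sample(2:3, 1)
    L <- sample(5:20, 1)
    F <- matrix(runif(K * L, 0.05, 0.95), K, L)
    g <- rbinom(L, 2, colMeans(F))
    fr <- allele_freqs(F, paste0("P", 1:K), paste0("l", 1:L))
    gm <- genotype_matrix(matrix(as.integer(g), 1), "s1", paste0("l", 1:L))
    fit <- supervised_ancestry(gm, fr, tol = 1e-12, max_iter = 5000)
    grid_best <- grid_loglik_max(g, F, step = 0.01)
    # EM solves the continuous problem: at least as good as any lattice
    # point, and the lattice can only under-shoot by its resolution
    expect_gte(fit$loglik, grid_best - 1e-6)
    # bound the lattice's resolution: worst case ll drop across one cell,
    # estimated from the gradient magnitude at the EM optimum
    p <- as.numeric(fit$Q[1, ] %*% F)
    grad <- vapply(seq_len(K), function(k) {
      sum(g * F[k, ] / p - (2 - g) * F[k, ] / (1 - p))
    }, numeric(1))
    res_bound <- 0.01 * K * max(abs(grad)) + 1e-6
    expect_lte(fit$loglik - grid_best, res_bound)
  }
})

test_that("unsupervised K = 1 reduces to pooled frequencies; clusters recover populations", {
  d <- small_structured(L = 300, n = 15)
  gm <- d$genotypes
  fit1 <- unsupervised_admixture(gm, 1)
  expect_true(all(fit1$Q == 1))
  pooled <- colMeans(gm$G) / 2
  clamped <- pmin(pmax(pooled, 1e-6), 1 - 1e-6)
  expect_equal(unname(unclass_freqs(fit1$freqs))[1, ], unname(clamped))

  # two well-separated populations, K = 2: own-cluster membership > 0.95
  d2 <- simulate_dataset(sim_config(L = 1000, K = 2, n_per_pop = 50,
                                    divergence = 0.15, seed = 21))
  fit2 <- unsupervised_admixture(d2$genotypes, 2, seed = 4)
  perm <- align_clusters(fit2, d2$genotypes$pop_labels)
  M <- attr(perm, "membership")
  expect_gt(mean(M[cbind(1:2, perm)]), 0.95)

  # determinism under a fixed seed
  fit2b <- unsupervised_admixture(d2$genotypes, 2, seed = 4)
  expect_identical(fit2$Q, fit2b$Q)
  expect_identical(fit2$loglik, fit2b$loglik)

  expect_error(unsupervised_admixture(gm, n_samples(gm) + 1), "exceed")
})

test_that("EM is monotone and simplex-conserving across random problems", {
  set.seed(202)
  for (rep in 1:5) {
    K <- sample(2:4, 1)
    d <- simulate_dataset(sim_config(L = 80, K = K, n_per_pop = 8,
                                     divergence = runif(1, 0.05, 0.3),
                                     missing_rate = runif(1, 0, 0.2),
                                     seed = 300 + rep))
    gm <- d$genotypes
    sup <- supervised_ancestry(gm, d$freqs)
    expect_true(all(diff(sup$loglik_trace) >= -1e-9))
    expect_lt(max(abs(rowSums(sup$Q) - 1)), 1e-8)
    uns <- unsupervised_admixture(gm, K, seed = rep)
    expect_true(all(diff(uns$loglik_trace) >= -1e-9))
    expect_lt(max(abs(rowSums(uns$Q) - 1)), 1e-8)
  }
})

test_that("supervised Q is invariant to locus order and equivariant to sample order", {
  d <- small_structured(L = 150, n = 8)
  gm <- d$genotypes
  fit <- supervised_ancestry(gm, d$freqs)

  perm_l <- sample(n_loci(gm))
  gm_l <- subset_by_panel(gm, gm$loci[perm_l])
  expect_equal(supervised_ancestry(gm_l, d$freqs)$Q, fit$Q)

  perm_s <- sample(n_samples(gm))
  gm_s <- genotype_matrix(gm$G[perm_s, ], gm$samples[perm_s], gm$loci,
                          gm$pop_labels[perm_s])
  expect_equal(supervised_ancestry(gm_s, d$freqs)$Q, fit$Q[perm_s, ])
})

test_that("cross-validation error identifies real structure and penalizes overfitting", {
  # three strongly diverged populations: K = 3 beats K = 1
  d <- simulate_dataset(sim_config(L = 400, K = 3, n_per_pop = 15,
                                   divergence = 0.15, seed = 31))
  e1 <- cross_validation_error(d$genotypes, 1, seed = 2)
  e3 <- cross_validation_error(d$genotypes, 3, seed = 2)
  expect_lt(e3, e1)

  # homogeneous data: no second cluster is supported
  hom_gm <- simulate_dataset(sim_config(L = 300, K = 2, n_per_pop = 20,
                                        divergence = 0.1, seed = 32))$genotypes
  one_pop <- subset_samples(hom_gm, which(hom_gm$pop_labels == "POP1"))
  one_pop <- genotype_matrix(one_pop$G, one_pop$samples, one_pop$loci)
  k_hom <- choose_k(one_pop, 1:2, seed = 5)
  expect_equal(as.integer(k_hom), 1L)

  # singleton candidate list is returned as-is
  expect_equal(as.integer(choose_k(d$genotypes, 2, n_folds = 2, seed = 1)),
               2L)

  # same seed -> same folds -> same error
  expect_identical(cross_validation_error(d$genotypes, 2, seed = 9),
                   cross_validation_error(d$genotypes, 2, seed = 9))
})

test_that("cluster alignment matches an exhaustive permutation search", {
  # already-aligned Q: identity permutation
  Q <- rbind(c(0.9, 0.05, 0.05), c(0.1, 0.8, 0.1), c(0.05, 0.1, 0.85))
  labs <- c("A", "B", "C")
  expect_equal(as.integer(align_clusters(Q, labs)), 1:3)
  # swap two columns: the transposition is recovered
  expect_equal(as.integer(align_clusters(Q[, c(2, 1, 3)], labs)),
               c(2L, 1L, 3L))

  # random problems against an independent exhaustive search
  set.seed(14)
  perms3 <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  for (rep in 1:10) {
    Qr <- matrix(rgamma(30 * 3, 1), 30, 3)
    Qr <- Qr / rowSums(Qr)
    labs_r <- sample(rep(c("A", "B", "C"), each = 10))
    got <- align_clusters(Qr, labs_r)
    M <- attr(got, "membership")
    scores <- apply(perms3, 1, function(p) sum(M[cbind(1:3, p)]))
    expect_equal(sum(M[cbind(1:3, as.integer(got))]), max(scores))
  }
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- small_structured(L = 100, n = 5)
  fit <- supervised_ancestry(d$genotypes, d$freqs)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("sample", "ancestry", "proportion"))
  expect_equal(nrow(td), n_samples(d$genotypes) * 3)
  gl <- glance(fit)
  expect_equal(gl$mode, "supervised")
  expect_true(gl$converged)
})
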