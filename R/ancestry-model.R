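#' Ancestral allele frequencies
#'
#' A `K x L` matrix of reference-allele frequencies, the `f_kl` parameters
#' of the admixture likelihood, with population and locus identifiers.
#'
#' @param F numeric matrix, populations in rows, loci in columns, entries
#'   in `[0, 1]`.
#' @param pops population labels (default rownames).
#' @param loci locus identifiers (default colnames).
#' @return An object of class `allele_freqs`.
#' @export
allele_freqs <- function(F, pops = rownames(F), loci = colnames(F)) {
  F <- as.matrix(F)
  if (is.null(pops)) pops <- paste0("POP", seq_len(nrow(F)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(F)))
  stopifnot(length(pops) == nrow(F), length(loci) == ncol(F))
  if (any(F < 0 | F > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  dimnames(F) <- list(pops, loci)
  structure(F, class = c("allele_freqs", "matrix"))
}

unclass_freqs <- function(freqs) {
  F <- unclass(freqs)
  attr(F, "ancestral") <- NULL
  F
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("<allele_freqs> ", nrow(x), " populations x ", ncol(x), " loci\n",
      sep = "")
  invisible(x)
}

FREQ_EPS <- 1e-6

#' Estimate reference-panel allele frequencies from labelled genotypes
#'
#' Per population and locus, the reference-allele frequency is the allele
#' count divided by twice the number of non-missing samples, clamped into
#' `[1e-6, 1 - 1e-6]` so the admixture log-likelihood stays finite at loci
#' fixed in the sample. A locus with no called genotype in some population
#' is set to 0.5 with a warning.
#'
#' @param gm a [genotype_matrix()] with population labels.
#' @return An [allele_freqs()] with one row per population (sorted label
#'   order).
#' @export
estimate_frequencies <- function(gm) {
  if (is.null(gm$pop_labels)) {
    stop("`gm` must carry population labels", call. = FALSE)
  }
  pops <- sort(unique(gm$pop_labels))
  L <- n_loci(gm)
  F <- matrix(NA_real_, length(pops), L)
  n_empty <- 0L
  for (k in seq_along(pops)) {
    Gk <- gm$G[gm$pop_labels == pops[k], , drop = FALSE]
    counts <- colSums(Gk, na.rm = TRUE)
    called <- colSums(!is.na(Gk))
    f <- counts / (2 * called)
    empty <- called == 0
    n_empty <- n_empty + sum(empty)
    f[empty] <- 0.5
    F[k, ] <- pmin(pmax(f, FREQ_EPS), 1 - FREQ_EPS)
  }
  if (n_empty > 0) {
    warning(n_empty, " population-locus combinations had no called ",
            "genotype; their frequencies were set to 0.5", call. = FALSE)
  }
  allele_freqs(F, pops, gm$loci)
}

# Shared EM machinery ------------------------------------------------------
#
# The likelihood treats each individual's genotype g_il as Binomial(2, p_il)
# with p_il = sum_k q_ik f_kl. All updates below are the exact EM steps for
# that model, vectorised across individuals. Missing entries are handled by
# zeroing both allele-count matrices (G0 = g with NA -> 0, Gc0 = 2 - g with
# NA -> 0) once up front: a missing locus then contributes nothing to any
# numerator or to the log-likelihood, and the per-individual called-locus
# count two_L normalises the simplex update. Because every Q row sums to 1,
# sum_k q_ik (1 - f_kl) = 1 - sum_k q_ik f_kl, so only one N x L mixture
# matrix is ever formed per iteration.

em_precompute <- function(G) {
  storage.mode(G) <- "double"
  G0 <- G
  G0[is.na(G0)] <- 0
  Gc0 <- 2 - G
  Gc0[is.na(Gc0)] <- 0
  list(G0 = G0, Gc0 = Gc0, two_L = 2 * rowSums(!is.na(G)))
}

loglik_admix <- function(G0, Gc0, Q, F) {
  D1 <- Q %*% F
  sum(G0 * log(D1)) + sum(Gc0 * log1p(-D1))
}

# Safeguarded squared-extrapolation acceleration of the EM map (SQUAREM
# scheme S3). `theta` is a list of parameter matrices; `em_step` advances it
# by one EM iteration, `ll_fun` scores it, `feasible` tests whether an
# extrapolated point is strictly inside the parameter space. An infeasible
# step length is backtracked halfway toward -1 (the plain EM step, always
# feasible). Each recorded cycle can never lose likelihood: an extrapolated
# proposal is kept only if it does not fall below the previous cycle, and
# the fallback is the plain double EM step, monotone by construction. Fixed
# points are exactly the EM fixed points.
squarem <- function(theta, em_step, ll_fun, feasible, tol, max_iter) {
  trace <- ll_fun(theta)
  ll_old <- trace[1]
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    t1 <- em_step(theta)
    t2 <- em_step(t1)
    iter <- iter + 2L
    r <- Map(`-`, t1, theta)
    v <- Map(`-`, Map(`-`, t2, t1), r)
    sr2 <- sum(vapply(r, function(m) sum(m * m), numeric(1)))
    sv2 <- sum(vapply(v, function(m) sum(m * m), numeric(1)))
    accepted <- FALSE
    ll <- NA_real_
    if (sv2 > 1e-300) {
      alpha <- min(-1, -sqrt(sr2 / sv2))
      prop <- NULL
      for (bt in 1:8) {
        cand <- Map(function(t0, rr, vv) {
          t0 - 2 * alpha * rr + alpha^2 * vv
        }, theta, r, v)
        if (feasible(cand)) {
          prop <- cand
          break
        }
        alpha <- (alpha - 1) / 2   # back off toward the plain EM step
      }
      if (!is.null(prop)) {
        prop <- em_step(prop)   # stabilising EM step after extrapolation
        iter <- iter + 1L
        ll_prop <- ll_fun(prop)
        if (is.finite(ll_prop) && ll_prop >= ll_old) {
          theta <- prop
          ll <- ll_prop
          accepted <- TRUE
        }
      }
    }
    if (!accepted) {
      theta <- t2
      ll <- ll_fun(theta)
    }
    trace <- c(trace, ll)
    if (abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(theta = theta, trace = trace, iter = iter, converged = converged)
}

new_fit <- function(Q, freqs, trace, iter, converged, mode, samples, pops) {
  dimnames(Q) <- list(samples, pops)
  structure(list(Q = Q, freqs = freqs, loglik = trace[length(trace)],
                 loglik_trace = trace, n_iter = iter, converged = converged,
                 mode = mode),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat("<ancestry_fit> ", x$mode, ", ", nrow(x$Q), " individuals x ",
      ncol(x$Q), " ancestries\n", sep = "")
  cat("  log-likelihood ", format(x$loglik), " after ", x$n_iter,
      " iterations (", if (x$converged) "converged" else "not converged",
      ")\n", sep = "")
  invisible(x)
}

#' Tidy an ancestry fit into a long tibble
#'
#' @param x an `ancestry_fit`.
#' @param ... unused.
#' @return A tibble with columns `sample`, `ancestry`, `proportion`.
#' @exportS3Method generics::tidy
tidy.ancestry_fit <- function(x, ...) {
  q <- tibble::as_tibble(x$Q, rownames = "sample")
  tidyr::pivot_longer(q, -"sample", names_to = "ancestry",
                      values_to = "proportion")
}

#' One-row summary of an ancestry fit
#'
#' @param x an `ancestry_fit`.
#' @param ... unused.
#' @return A tibble with the mode, dimensions, final log-likelihood,
#'   iteration count and convergence flag.
#' @exportS3Method generics::glance
glance.ancestry_fit <- function(x, ...) {
  tibble::tibble(mode = x$mode, n = nrow(x$Q), k = ncol(x$Q),
                 loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged)
}

#' Supervised ancestry estimation
#'
#' Maximises, independently for every individual, the admixture
#' log-likelihood
#' `l_i(q) = sum_l [ g_il log(sum_k q_k f_kl) + (2 - g_il) log(sum_k q_k (1 - f_kl)) ]`
#' over the probability simplex, holding the ancestral frequencies `f_kl`
#' fixed (the "supervised" mode: reference panels are known). The maximiser
#' is found by EM from a uniform start; each multiplicative update keeps the
#' row on the simplex exactly and never decreases the likelihood. Missing
#' genotypes drop out of the sums, so the effective locus count is
#' per-individual. Convergence is accelerated by safeguarded squared
#' extrapolation of the EM map (SQUAREM): the fixed points are unchanged
#' and the recorded log-likelihood trace remains non-decreasing, since any
#' extrapolated step that would lose likelihood is replaced by plain EM.
#'
#' @param gm a [genotype_matrix()]; its loci must all be present in `freqs`.
#' @param freqs an [allele_freqs()].
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return An `ancestry_fit` with the `N x K` matrix `Q`, the final
#'   log-likelihood and its per-iteration trace. Individuals with no called
#'   genotype get a uniform row and a warning.
#' @export
supervised_ancestry <- function(gm, freqs, tol = 1e-6, max_iter = 2000) {
  F <- unclass_freqs(freqs)
  idx <- match(gm$loci, colnames(F))
  if (anyNA(idx)) {
    stop(sum(is.na(idx)), " loci of `gm` are absent from `freqs`",
         call. = FALSE)
  }
  F <- F[, idx, drop = FALSE]
  F <- pmin(pmax(F, FREQ_EPS), 1 - FREQ_EPS)
  pc <- em_precompute(gm$G)
  G0 <- pc$G0; Gc0 <- pc$Gc0; two_L <- pc$two_L
  K <- nrow(F)
  N <- nrow(G0)
  none <- two_L == 0
  if (any(none)) {
    warning(sum(none), " individuals have no called genotype; ",
            "their ancestry is set uniform", call. = FALSE)
  }
  two_L_safe <- pmax(two_L, 1)
  Q <- matrix(1 / K, N, K)
  if (K == 1) {
    ll <- loglik_admix(G0, Gc0, Q, F)
    return(new_fit(Q, freqs, ll, 0L, TRUE, "supervised",
                   gm$samples, rownames(F)))
  }
  tF <- t(F); tFc <- t(1 - F)
  em_step <- function(th) {
    Q <- th[[1]]
    D1 <- Q %*% F
    Qn <- Q * ((G0 / D1) %*% tF + (Gc0 / (1 - D1)) %*% tFc) / two_L_safe
    if (any(none)) Qn[none, ] <- 1 / K
    list(Qn / rowSums(Qn))  # pin rows to the simplex: rounding must not drift
  }
  ll_fun <- function(th) loglik_admix(G0, Gc0, th[[1]], F)
  feasible <- function(th) all(is.finite(th[[1]])) && all(th[[1]] > 0)
  res <- squarem(list(Q), em_step, ll_fun, feasible, tol, max_iter)
  new_fit(res$theta[[1]], freqs, res$trace, res$iter, res$converged,
          "supervised", gm$samples, rownames(F))
}

#' Unsupervised admixture estimation
#'
#' Jointly estimates individual ancestry proportions `Q` and ancestral
#' allele frequencies `F` for `K` unlabelled clusters by EM on the same
#' binomial admixture likelihood as [supervised_ancestry()]. Initialisation
#' is seeded and random: `Q` rows from a symmetric Dirichlet(1), `F`
#' entries from Uniform(0.05, 0.95). A single start is used by default;
#' increase `n_starts` to take the best of several seeded starts.
#'
#' Cluster labels are arbitrary (`C1..CK`); use [align_clusters()] before
#' comparing to known population labels.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of ancestral clusters (>= 1, <= number of samples).
#' @param seed integer seed.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @param n_starts number of random starts; the fit with the best final
#'   log-likelihood is returned.
#' @return An `ancestry_fit` whose `freqs` element carries the estimated
#'   cluster frequencies.
#' @export
unsupervised_admixture <- function(gm, K, seed = 1, tol = 1e-6,
                                   max_iter = 2000, n_starts = 1) {
  stopifnot(K >= 1)
  if (K > n_samples(gm)) {
    stop("K must not exceed the number of samples", call. = FALSE)
  }
  pc <- em_precompute(gm$G)
  G0 <- pc$G0; Gc0 <- pc$Gc0; two_L <- pc$two_L
  N <- nrow(G0); L <- ncol(G0)
  none <- two_L == 0
  two_L_safe <- pmax(two_L, 1)
  clusters <- paste0("C", seq_len(K))

  if (K == 1) {
    # closed form: Q is all ones, F the pooled sample frequencies
    f <- colSums(gm$G, na.rm = TRUE) / pmax(colSums(!is.na(gm$G)) * 2, 1)
    F <- matrix(pmin(pmax(f, FREQ_EPS), 1 - FREQ_EPS), 1, L)
    Q <- matrix(1, N, 1)
    ll <- loglik_admix(G0, Gc0, Q, F)
    return(new_fit(Q, allele_freqs(F, clusters, gm$loci), ll, 0L, TRUE,
                   "unsupervised", gm$samples, clusters))
  }

  # One shared E-step: responsibilities from the current (Q, F) feed both
  # parameter blocks — the exact EM step for the complete-data model, so
  # the log-likelihood cannot decrease.
  em_step <- function(th) {
    Q <- th$Q; F <- th$F
    D1 <- Q %*% F
    A <- G0 / D1
    B <- Gc0 / (1 - D1)
    TA <- crossprod(Q, A)   # K x L: sum_i q_ik g_il / D1_il
    TB <- crossprod(Q, B)
    Qn <- Q * (A %*% t(F) + B %*% t(1 - F)) / two_L_safe
    if (any(none)) Qn[none, ] <- 1 / K
    Qn <- Qn / rowSums(Qn)  # pin rows to the simplex against rounding drift
    num <- F * TA
    den <- num + (1 - F) * TB
    Fn <- ifelse(den > 0, num / den, F)
    list(Q = Qn, F = pmin(pmax(Fn, FREQ_EPS), 1 - FREQ_EPS))
  }
  ll_fun <- function(th) loglik_admix(G0, Gc0, th$Q, th$F)
  feasible <- function(th) {
    all(is.finite(th$Q)) && all(th$Q > 0) &&
      all(is.finite(th$F)) && all(th$F > 0) && all(th$F < 1)
  }

  run_one <- function(start_seed) {
    with_seed(start_seed, {
      Q <- matrix(rgamma(N * K, 1), N, K)
      Q <- Q / rowSums(Q)
      F <- matrix(runif(K * L, 0.05, 0.95), K, L)
      res <- squarem(list(Q = Q, F = F), em_step, ll_fun, feasible,
                     tol, max_iter)
      new_fit(res$theta$Q, allele_freqs(res$theta$F, clusters, gm$loci),
              res$trace, res$iter, res$converged, "unsupervised",
              gm$samples, clusters)
    })
  }

  fits <- lapply(seed + seq_len(n_starts) - 1L, run_one)
  fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1)))]]
}

#' Cross-validation error for a given number of clusters
#'
#' Entry-wise cross-validation for choosing `K`: the non-missing genotype
#' entries are partitioned at random into `n_folds` masks; for each fold the
#' masked entries are set missing, the unsupervised model is refit, and the
#' held-out entries are predicted by their fitted expectation
#' `2 sum_k q_ik f_kl`. The fold error is the mean squared deviation over
#' masked entries and the returned value averages the folds.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of clusters.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed controlling the fold mask and the refit starts.
#' @param tol,max_iter EM controls for the refits; the defaults are looser
#'   than the user-facing fits because the held-out error is insensitive to
#'   the last increments of log-likelihood.
#' @param folds optional precomputed fold-assignment matrix (integer
#'   `N x L`, `NA` at missing entries) so several `K` values can share one
#'   partition.
#' @return The average held-out prediction error (a scalar).
#' @export
cross_validation_error <- function(gm, K, n_folds = 5, seed = 1,
                                   tol = 1e-5, max_iter = 500,
                                   folds = NULL) {
  stopifnot(n_folds >= 2)
  G <- gm$G
  folds <- folds %||% cv_folds(gm, n_folds, seed)
  errs <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    mask <- !is.na(folds) & folds == f
    Gtrain <- G
    Gtrain[mask] <- NA_integer_
    gtrain <- genotype_matrix(Gtrain, gm$samples, gm$loci, gm$pop_labels)
    fit <- unsupervised_admixture(gtrain, K, seed = seed + 1000L * f,
                                  tol = tol, max_iter = max_iter)
    pred <- 2 * fit$Q %*% unclass_freqs(fit$freqs)
    errs[f] <- mean((G[mask] - pred[mask])^2)
  }
  mean(errs)
}

cv_folds <- function(gm, n_folds, seed) {
  with_seed(seed, {
    folds <- matrix(NA_integer_, n_samples(gm), n_loci(gm))
    obs <- which(!is.na(gm$G))
    folds[obs] <- sample(rep_len(seq_len(n_folds), length(obs)))
    folds
  })
}

#' Choose the number of ancestral clusters by cross-validation
#'
#' Computes [cross_validation_error()] for each candidate `K` on a shared
#' fold partition and returns the `K` with the lowest error, breaking ties
#' toward the smaller `K`.
#'
#' @param gm a [genotype_matrix()].
#' @param k_values candidate cluster counts.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @param ... further EM controls passed to [cross_validation_error()].
#' @return The selected `K` (integer), with the full tibble of `(k,
#'   cv_error)` attached as attribute `cv_table`.
#' @export
choose_k <- function(gm, k_values = 1:5, n_folds = 5, seed = 1, ...) {
  stopifnot(length(k_values) >= 1)
  k_values <- as.integer(k_values)
  folds <- cv_folds(gm, n_folds, seed)
  errs <- vapply(k_values, function(k) {
    cross_validation_error(gm, k, n_folds = n_folds, seed = seed,
                           folds = folds, ...)
  }, numeric(1))
  tab <- tibble::tibble(k = k_values, cv_error = errs)
  ord <- order(errs, k_values)
  best <- k_values[ord[1]]
  attr(best, "cv_table") <- tab
  best
}

#' Resolve label switching against known population labels
#'
#' Unsupervised cluster labels are arbitrary. Given a fitted `Q` and a
#' per-sample population label with as many distinct values as clusters,
#' finds the cluster permutation maximising the summed mean membership of
#' each population in its assigned cluster (exact assignment by exhaustive
#' search over permutations; K <= 8).
#'
#' @param Q an `N x K` ancestry matrix or an `ancestry_fit`.
#' @param pop_labels per-sample labels with exactly `K` distinct values.
#' @return An integer permutation `perm` such that `Q[, perm]` puts the
#'   cluster best matching the `j`-th (sorted) population label in column
#'   `j`. The population-by-cluster mean-membership matrix is attached as
#'   attribute `membership`.
#' @export
align_clusters <- function(Q, pop_labels) {
  if (inherits(Q, "ancestry_fit")) Q <- Q$Q
  pops <- sort(unique(pop_labels))
  K <- ncol(Q)
  if (length(pops) != K) {
    stop("number of distinct labels (", length(pops),
         ") must equal the number of clusters (", K, ")", call. = FALSE)
  }
  if (K > 8) stop("exhaustive alignment supports K <= 8", call. = FALSE)
  M <- t(vapply(pops, function(p) {
    colMeans(Q[pop_labels == p, , drop = FALSE])
  }, numeric(K)))           # pops x clusters
  perms <- all_permutations(K)
  scores <- vapply(seq_len(nrow(perms)), function(i) {
    sum(M[cbind(seq_len(K), perms[i, ])])
  }, numeric(1))
  best <- perms[which.max(scores), ]
  attr(best, "membership") <- M
  best
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i) {
    sub <- all_permutations(n - 1L)
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}
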