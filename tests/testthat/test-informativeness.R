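# Independent scalar transcription of the Weir & Cockerham (1984) theta for
# two populations, from per-population sample sizes, allele frequencies and
# heterozygote frequencies. Written from the published formulas, separately
# from the package's vectorised implementation.
wc_theta_scalar <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

two_pop_gm <- function(gA, gB) {
  G <- matrix(c(gA, gB), ncol = 1)
  genotype_matrix(G, paste0("s", seq_along(c(gA, gB))), "l1",
                  rep(c("A", "B"), c(length(gA), length(gB))))
}

test_that("pairwise F_ST matches an independent Weir-Cockerham transcription", {
  # n = 50 each, p_A = 0.8 (32/16/2 genotype counts), p_B = 0.2 mirrored
  gA <- geno_block(2, 16, 32)
  gB <- geno_block(32, 16, 2)
  gm <- two_pop_gm(gA, gB)
  got <- pairwise_fst(gm, "A", "B")
  expected <- wc_theta_scalar(50, 0.8, 16 / 50, 50, 0.2, 16 / 50)
  expect_equal(got$theta, expected, tolerance = 1e-12)
  expect_equal(attr(got, "overall"), expected, tolerance = 1e-12)
})

test_that("F_ST is ~0 without differentiation and exactly 1 at a fixed difference", {
  # same large-sample genotype composition in both populations
  g <- geno_block(125, 250, 125)   # p = 0.5, HWE at n = 500
  same <- two_pop_gm(g, g)
  expect_lt(abs(pairwise_fst(same, "A", "B")$theta), 0.01)

  fixed <- two_pop_gm(rep(2L, 30), rep(0L, 30))
  expect_equal(pairwise_fst(fixed, "A", "B")$theta, 1)
})

test_that("F_ST handles missing data and flags uncallable loci", {
  G <- rbind(c(2L, NA), c(2L, NA), c(0L, 1L), c(1L, 1L))
  gm <- genotype_matrix(G, paste0("s", 1:4), c("l1", "l2"),
                        c("A", "A", "B", "B"))
  res <- pairwise_fst(gm, "A", "B")
  expect_true(is.na(res$theta[2]))       # population A uncallable at l2
  expect_false(is.na(res$theta[1]))
  expect_equal(attr(res, "overall"), res$theta[1])  # l2 excluded
})

test_that("branch lengths follow the cyclic half-sum formula with clamping", {
  sym <- lsbl(0.2, 0.2, 0.2)
  expect_equal(unlist(sym[1, 1:3], use.names = FALSE), c(0.1, 0.1, 0.1))

  hand <- lsbl(0.2, 0.3, 0.1)
  expect_equal(unlist(hand[1, 1:3], use.names = FALSE), c(0.2, 0.0, 0.1))
  expect_false(hand$clamped[1])

  clamp <- lsbl(0.1, 0.1, 0.4)
  expect_equal(clamp$branch_a[1], 0)
  expect_true(clamp$clamped[1])
  expect_equal(attr(clamp, "raw")[1, "branch_a"], -0.1,
               ignore_attr = TRUE)
})

test_that("pre-clamp branch sums reconstruct every pairwise distance exactly", {
  set.seed(8)
  n <- 500
  d_ab <- runif(n); d_ac <- runif(n); d_bc <- runif(n)
  raw <- attr(lsbl(d_ab, d_ac, d_bc), "raw")
  expect_equal(raw[, "branch_a"] + raw[, "branch_b"], d_ab)
  expect_equal(raw[, "branch_a"] + raw[, "branch_c"], d_ac)
  expect_equal(raw[, "branch_b"] + raw[, "branch_c"], d_bc)
})

test_that("a locus with identical composition in all populations has zero LSBL", {
  g <- geno_block(10, 20, 10)
  G <- matrix(rep(g, 3), ncol = 1)
  gm <- genotype_matrix(G, paste0("s", 1:120), "l1",
                        rep(c("A", "B", "C"), each = 40))
  tab <- lsbl_table(gm)
  expect_equal(unname(unlist(tab[1, c("A", "B", "C")])), c(0, 0, 0))
})

test_that("mean branch length tracks the branch population's divergence", {
  mean_branch1 <- function(div1) {
    d <- simulate_dataset(sim_config(L = 500, K = 3, n_per_pop = 30,
                                     divergence = c(div1, 0.1, 0.1),
                                     seed = 17))
    tab <- lsbl_table(d$genotypes)
    mean(tab$POP1, na.rm = TRUE)
  }
  expect_lt(mean_branch1(0.05), mean_branch1(0.3))
})

test_that("panel summaries accumulate and standardize per branch", {
  tab <- tibble::tibble(locus = paste0("l", 1:4),
                        A = c(0.1, 0.2, 0.1, 0.4),
                        B = c(0.05, 0.05, 0.1, 0.2),
                        C = c(0, 0.1, 0.3, 0.1),
                        clamped = FALSE)
  class(tab) <- c("lsbl_table", class(tab))
  attr(tab, "branches") <- c("A", "B", "C")

  one <- panel_lsbl_summary(tab, aim_panel("l2"))
  expect_equal(one$accumulated, c(0.2, 0.05, 0.1))
  expect_equal(one$average, one$accumulated)

  full <- panel_lsbl_summary(tab, aim_panel(paste0("l", 1:4), "all"))
  expect_equal(full$accumulated, full$average * full$panel_size)
  expect_equal(full$accumulated[1], 0.8)

  part <- panel_lsbl_summary(tab, aim_panel(c("l1", "l3", "ghost")))
  expect_equal(unique(part$panel_size), 2L)
  expect_equal(unique(part$n_missing), 1L)
})

test_that("balanced selection takes forced extremes and respects tie-breaking", {
  # one extreme locus per branch: n_aims = 3 must take exactly those
  tab <- tibble::tibble(locus = paste0("l", 1:6),
                        A = c(0.9, 0.01, 0.01, 0.02, 0.03, 0.01),
                        B = c(0.01, 0.8, 0.01, 0.03, 0.02, 0.01),
                        C = c(0.01, 0.01, 0.85, 0.01, 0.02, 0.03),
                        clamped = FALSE)
  class(tab) <- c("lsbl_table", class(tab))
  attr(tab, "branches") <- c("A", "B", "C")
  sel <- select_aims_lsbl(tab, 3)
  expect_setequal(sel$loci, c("l1", "l2", "l3"))

  # exact ties resolve to the smaller locus index
  tie <- tibble::tibble(locus = paste0("l", 1:3),
                        A = c(0.5, 0.5, 0.2),
                        B = c(0.1, 0.1, 0.1),
                        C = c(0.1, 0.1, 0.1),
                        clamped = FALSE)
  class(tie) <- c("lsbl_table", class(tie))
  attr(tie, "branches") <- c("A", "B", "C")
  expect_equal(select_aims_lsbl(tie, 1)$loci, "l1")

  expect_error(select_aims_lsbl(tie, 10), "exceeds")
})

test_that("selected panels are balanced within one locus's contribution", {
  set.seed(23)
  for (rep in 1:10) {
    L <- 40
    V <- matrix(rexp(L * 3, rate = 10), L, 3)
    tab <- tibble::tibble(locus = paste0("l", 1:L),
                          A = V[, 1], B = V[, 2], C = V[, 3],
                          clamped = FALSE)
    class(tab) <- c("lsbl_table", class(tab))
    attr(tab, "branches") <- c("A", "B", "C")
    sel <- select_aims_lsbl(tab, 12)
    s <- panel_lsbl_summary(tab, sel)
    acc <- s$accumulated
    max_single <- max(V[match(sel$loci, tab$locus), ])
    expect_lte(max(acc) - min(acc), max_single + 1e-12)
  }
})
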