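#' Per-locus Weir-Cockerham F_ST between two populations
#'
#' Computes the Weir & Cockerham (1984) theta estimator for every locus,
#' from genotype data of two labelled populations, together with the
#' overall multi-locus value formed as the ratio of the summed variance
#' components (the standard "ratio of averages"). Negative per-locus
#' estimates are reported as computed — they are clamped only downstream,
#' at the branch-length stage.
#'
#' @param gm a [genotype_matrix()] with population labels.
#' @param pop_a,pop_b the two population labels to compare.
#' @return A tibble with columns `locus`, `theta`, and the variance
#'   components `a` (among-population) and `abc` (total); `theta` is `NA`
#'   for loci uncallable in either population (fewer than 2 called
#'   samples), and such loci are excluded from the overall ratio, which is
#'   attached as attribute `overall`.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
pairwise_fst <- function(gm, pop_a, pop_b) {
  if (is.null(gm$pop_labels)) {
    stop("`gm` must carry population labels", call. = FALSE)
  }
  Ga <- gm$G[gm$pop_labels == pop_a, , drop = FALSE]
  Gb <- gm$G[gm$pop_labels == pop_b, , drop = FALSE]
  if (nrow(Ga) == 0 || nrow(Gb) == 0) {
    stop("both populations must be present in `gm`", call. = FALSE)
  }
  comp <- wc_components(Ga, Gb)
  ok <- comp$n_a >= 2 & comp$n_b >= 2
  theta <- ifelse(ok & comp$abc != 0, comp$a / comp$abc, NA_real_)
  theta[ok & comp$abc == 0] <- NA_real_   # monomorphic in both: undefined
  out <- tibble::tibble(locus = gm$loci, theta = unname(theta),
                        a = unname(ifelse(ok, comp$a, NA_real_)),
                        abc = unname(ifelse(ok, comp$abc, NA_real_)))
  usable <- ok & !is.na(theta)
  attr(out, "overall") <- sum(comp$a[usable]) / sum(comp$abc[usable])
  out
}

# Weir-Cockerham (1984) variance components for r = 2 populations, per
# locus, from genotype matrices (rows = individuals). Uses observed
# heterozygote frequencies, so departures from HWE feed component c.
wc_components <- function(Ga, Gb) {
  n_a <- colSums(!is.na(Ga))
  n_b <- colSums(!is.na(Gb))
  p_a <- colSums(Ga, na.rm = TRUE) / (2 * pmax(n_a, 1))
  p_b <- colSums(Gb, na.rm = TRUE) / (2 * pmax(n_b, 1))
  h_a <- colSums(Ga == 1, na.rm = TRUE) / pmax(n_a, 1)
  h_b <- colSums(Gb == 1, na.rm = TRUE) / pmax(n_b, 1)

  r <- 2
  nbar <- (n_a + n_b) / r
  nc <- (r * nbar - (n_a^2 + n_b^2) / (r * nbar)) / (r - 1)
  pbar <- (n_a * p_a + n_b * p_b) / (r * nbar)
  s2 <- (n_a * (p_a - pbar)^2 + n_b * (p_b - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n_a * h_a + n_b * h_b) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  list(a = a, abc = a + b + c, n_a = n_a, n_b = n_b)
}

#' Locus-specific branch lengths from three pairwise distances
#'
#' Decomposes the three pairwise distances among populations a, b, c into
#' population-specific branch lengths of the unrooted 3-taxon tree:
#' `branch_a = (d_ab + d_ac - d_bc) / 2`, and cyclically for b and c.
#' Negative branch lengths (possible when the triangle inequality fails,
#' e.g. from sampling noise in per-locus F_ST) are clamped to 0 and
#' flagged.
#'
#' @param d_ab,d_ac,d_bc pairwise distances (vectors of equal length).
#' @return A tibble with columns `branch_a`, `branch_b`, `branch_c` and
#'   `clamped` (TRUE where any branch was negative before clamping). The
#'   unclamped values are attached as attribute `raw`.
#' @export
lsbl <- function(d_ab, d_ac, d_bc) {
  stopifnot(length(d_ab) == length(d_ac), length(d_ab) == length(d_bc))
  raw <- cbind(branch_a = (d_ab + d_ac - d_bc) / 2,
               branch_b = (d_ab + d_bc - d_ac) / 2,
               branch_c = (d_ac + d_bc - d_ab) / 2)
  clamped <- rowSums(raw < 0) > 0
  out <- tibble::tibble(branch_a = as.numeric(pmax(raw[, 1], 0)),
                        branch_b = as.numeric(pmax(raw[, 2], 0)),
                        branch_c = as.numeric(pmax(raw[, 3], 0)),
                        clamped = as.logical(clamped))
  attr(out, "raw") <- raw
  out
}

#' Per-locus LSBL table for three populations
#'
#' Runs the three pairwise Weir-Cockerham F_ST scans and decomposes them
#' into per-locus, per-population branch lengths. Loci where any pairwise
#' value is undefined get `NA` branches.
#'
#' @param gm a [genotype_matrix()] whose labels include the three
#'   populations.
#' @param pops the three population labels; defaults to the sorted distinct
#'   labels of `gm` (which must then number exactly three).
#' @return A tibble of class `lsbl_table` with columns `locus`, one branch
#'   column per population (named by its label) and `clamped`.
#' @export
lsbl_table <- function(gm, pops = NULL) {
  pops <- pops %||% sort(unique(gm$pop_labels))
  if (length(pops) != 3) {
    stop("LSBL needs exactly three populations", call. = FALSE)
  }
  d_ab <- pairwise_fst(gm, pops[1], pops[2])$theta
  d_ac <- pairwise_fst(gm, pops[1], pops[3])$theta
  d_bc <- pairwise_fst(gm, pops[2], pops[3])$theta
  br <- lsbl(d_ab, d_ac, d_bc)
  out <- tibble::tibble(locus = gm$loci,
                        !!pops[1] := br$branch_a,
                        !!pops[2] := br$branch_b,
                        !!pops[3] := br$branch_c,
                        clamped = br$clamped)
  class(out) <- c("lsbl_table", class(out))
  attr(out, "branches") <- pops
  out
}

lsbl_values <- function(lsbl_table) {
  branches <- attr(lsbl_table, "branches") %||%
    setdiff(names(lsbl_table), c("locus", "clamped"))
  as.matrix(lsbl_table[branches])
}

#' Summarise a panel's accumulated and average LSBL
#'
#' For each population branch, the accumulated LSBL is the sum of per-locus
#' branch lengths over the panel's loci and the average LSBL is that sum
#' standardised by the number of panel loci actually scored. Panel loci
#' missing from the table are dropped and the effective (intersected) size
#' is reported.
#'
#' @param lsbl_table a [lsbl_table()].
#' @param panel an [aim_panel()] or character vector of locus IDs.
#' @return A tibble with one row per branch: `panel`, `branch`,
#'   `accumulated`, `average`, `panel_size` (effective), `n_missing`.
#' @export
panel_lsbl_summary <- function(lsbl_table, panel) {
  name <- if (inherits(panel, "aim_panel")) panel$name else "panel"
  loci <- if (inherits(panel, "aim_panel")) panel$loci else as.character(panel)
  idx <- match(loci, lsbl_table$locus)
  n_missing <- sum(is.na(idx))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    stop("no panel locus present in the LSBL table", call. = FALSE)
  }
  V <- lsbl_values(lsbl_table)[idx, , drop = FALSE]
  acc <- colSums(V)
  tibble::tibble(panel = name, branch = colnames(V),
                 accumulated = unname(acc),
                 average = unname(acc) / length(idx),
                 panel_size = length(idx), n_missing = n_missing)
}

#' Select a balanced AIM panel by cumulative LSBL
#'
#' Greedy balanced selection: repeatedly find the branch with the smallest
#' accumulated LSBL so far and add the unused locus with the largest LSBL
#' on that branch (ties broken toward the smaller locus index). This keeps
#' the per-branch cumulative informativeness near-equal — the design goal
#' of LSBL-balanced panels — with any pairwise difference bounded by the
#' largest single-locus contribution selected.
#'
#' @param lsbl_table a [lsbl_table()].
#' @param n_aims panel size; must not exceed the number of scored loci.
#' @param name name for the resulting panel.
#' @return An [aim_panel()] of `n_aims` loci, in selection order.
#' @export
select_aims_lsbl <- function(lsbl_table, n_aims, name = "lsbl_balanced") {
  V <- lsbl_values(lsbl_table)
  scored <- rowSums(is.na(V)) == 0
  V <- V[scored, , drop = FALSE]
  loci <- lsbl_table$locus[scored]
  if (n_aims > nrow(V)) {
    stop("n_aims (", n_aims, ") exceeds the number of scored loci (",
         nrow(V), ")", call. = FALSE)
  }
  K <- ncol(V)
  acc <- setNames(numeric(K), colnames(V))
  used <- logical(nrow(V))
  chosen <- integer(n_aims)
  for (s in seq_len(n_aims)) {
    b <- which.min(acc)                       # first minimum: branch order
    cand <- V[, b]
    cand[used] <- -Inf
    pick <- which.max(cand)                   # which.max takes first tie
    chosen[s] <- pick
    used[pick] <- TRUE
    acc <- acc + V[pick, ]
  }
  aim_panel(loci[chosen], name)
}
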