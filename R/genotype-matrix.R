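#' Construct a genotype matrix
#'
#' The central container of the package: an `n_samples x n_loci` integer
#' matrix of reference-allele counts (0, 1 or 2 copies), with `NA` marking a
#' missing call, plus sample identifiers, locus identifiers and (optionally)
#' a per-sample population label. `NA` — never 0 — is the missing sentinel,
#' because 0 is a valid genotype.
#'
#' @param G integer matrix, samples in rows and loci in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param samples character vector of sample identifiers (defaults to the
#'   rownames of `G`).
#' @param loci character vector of unique locus identifiers (defaults to the
#'   colnames of `G`).
#' @param pop_labels optional character vector of per-sample population
#'   labels.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(G, samples = rownames(G), loci = colnames(G),
                            pop_labels = NULL) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(G)))
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(G)))
  samples <- as.character(samples)
  loci <- as.character(loci)
  if (length(samples) != nrow(G)) {
    stop("`samples` must have one entry per row of `G`", call. = FALSE)
  }
  if (length(loci) != ncol(G)) {
    stop("`loci` must have one entry per column of `G`", call. = FALSE)
  }
  if (anyDuplicated(loci)) {
    stop("locus identifiers must be unique", call. = FALSE)
  }
  bad <- !is.na(G) & !(G %in% 0:2)
  if (any(bad)) {
    stop("genotypes must be 0, 1, 2 or NA; found ",
         paste(unique(G[bad]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(pop_labels)) {
    pop_labels <- as.character(pop_labels)
    if (length(pop_labels) != nrow(G)) {
      stop("`pop_labels` must have one entry per sample", call. = FALSE)
    }
  }
  dimnames(G) <- list(samples, loci)
  structure(list(G = G, samples = samples, loci = loci,
                 pop_labels = pop_labels),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$G), " samples x ", ncol(x$G), " loci\n",
      sep = "")
  miss <- mean(is.na(x$G))
  cat("  missing: ", format(100 * miss, digits = 3), "%\n", sep = "")
  if (!is.null(x$pop_labels)) {
    tab <- table(x$pop_labels)
    cat("  populations: ",
        paste(names(tab), " (", tab, ")", sep = "", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$G)

#' Number of samples and loci
#' @param gm a `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(gm) nrow(gm$G)

#' @rdname n_samples
#' @export
n_loci <- function(gm) ncol(gm$G)

#' Per-sample call rate
#'
#' Fraction of non-missing genotype calls for each sample.
#'
#' @param gm a `genotype_matrix`.
#' @return Named numeric vector in `[0, 1]`.
#' @export
call_rate <- function(gm) {
  r <- rowMeans(!is.na(gm$G))
  names(r) <- gm$samples
  r
}

#' Summarise a genotype matrix as a tibble
#'
#' One row per sample: identifier, population label, call rate.
#'
#' @param x a `genotype_matrix`.
#' @param ... unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.genotype_matrix <- function(x, ...) {
  tibble::tibble(
    sample = x$samples,
    population = x$pop_labels %||% NA_character_,
    call_rate = unname(rowMeans(!is.na(x$G)))
  )
}

subset_samples <- function(gm, idx) {
  genotype_matrix(gm$G[idx, , drop = FALSE], gm$samples[idx], gm$loci,
                  if (!is.null(gm$pop_labels)) gm$pop_labels[idx])
}

subset_loci <- function(gm, idx) {
  genotype_matrix(gm$G[, idx, drop = FALSE], gm$samples, gm$loci[idx],
                  gm$pop_labels)
}

#' Define an AIM panel
#'
#' A panel is an ordered list of unique locus identifiers plus a name.
#'
#' @param loci character vector of locus identifiers.
#' @param name panel name.
#' @return An object of class `aim_panel`.
#' @export
aim_panel <- function(loci, name = "panel") {
  loci <- as.character(loci)
  if (length(loci) == 0) stop("a panel must contain at least one locus",
                              call. = FALSE)
  if (anyDuplicated(loci)) stop("panel loci must be unique", call. = FALSE)
  structure(list(name = name, loci = loci), class = "aim_panel")
}

#' @export
print.aim_panel <- function(x, ...) {
  cat("<aim_panel> ", x$name, ": ", length(x$loci), " loci\n", sep = "")
  invisible(x)
}

#' @export
length.aim_panel <- function(x) length(x$loci)
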