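# Panel-evaluation experiments: random-SNP resampling, fixed-panel
# evaluation, population sub-sampling, and error quantification against a
# genome-wide reference.

#' Genome-wide reference ancestry
#'
#' Supervised ancestry estimated from *all* available loci: the proxy for
#' the true genome ancestry that every reduced panel is judged against.
#'
#' @param gm a [genotype_matrix()].
#' @param freqs an [allele_freqs()] covering the loci of `gm`.
#' @param ... passed to [supervised_ancestry()].
#' @return An `ancestry_fit`.
#' @export
genome_ancestry_reference <- function(gm, freqs, ...) {
  supervised_ancestry(gm, freqs, ...)
}

# Focal ancestry bookkeeping: for a sample whose population label matches an
# ancestry label the focal component is its own ancestry; samples with other
# labels (e.g. admixed hybrids) contribute every component.
focal_components <- function(Q, pop_labels) {
  ancestries <- colnames(Q)
  rows <- list()
  for (g in sort(unique(pop_labels))) {
    idx <- pop_labels == g
    comps <- if (g %in% ancestries) g else ancestries
    for (a in comps) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, ancestry = a, sample = rownames(Q)[idx],
        value = Q[idx, a])
    }
  }
  dplyr::bind_rows(rows)
}

summarise_values <- function(df, value_col = "value") {
  v <- rlang::sym(value_col)
  dplyr::summarise(
    df,
    mean = mean(!!v), sd = sd(!!v),
    ci_low = unname(quantile(!!v, 0.025, type = 7)),
    ci_high = unname(quantile(!!v, 0.975, type = 7)),
    min = min(!!v), max = max(!!v),
    .groups = "drop"
  )
}

#' Random-SNP panel resampling experiment
#'
#' For each panel size, draws `n_reps` random locus subsets (without
#' replacement), re-estimates supervised ancestry from each subset, and
#' records per replicate the population mean of the focal ancestry
#' component (own-population membership for labelled samples; every
#' component for groups, such as admixed hybrids, whose label matches no
#' ancestry). Summaries are taken across replicates: mean, SD, percentile
#' 95% CI and min-max range — the standard per-population summary row of
#' this kind of evaluation. A panel equal to all loci therefore has zero
#' SD: there is no sampling variability left.
#'
#' @param gm a [genotype_matrix()] with population labels.
#' @param freqs an [allele_freqs()] covering the loci of `gm`.
#' @param panel_sizes integer vector of panel sizes, each `<=` the number
#'   of loci.
#' @param n_reps replicates per size (the headline experiment uses 500).
#' @param seed integer seed.
#' @param ... passed to [supervised_ancestry()].
#' @return A tibble with one row per (panel size, group, ancestry):
#'   `panel_size`, `group`, `ancestry`, `mean`, `sd`, `ci_low`, `ci_high`,
#'   `min`, `max`, `n_replicates`. The per-replicate population means are
#'   attached as attribute `replicates`.
#' @export
rsnp_resampling <- function(gm, freqs, panel_sizes, n_reps = 500,
                            seed = 1, ...) {
  stopifnot(n_reps >= 1)
  if (any(panel_sizes > n_loci(gm))) {
    stop("panel sizes must not exceed the number of loci (", n_loci(gm),
         ")", call. = FALSE)
  }
  reps <- with_seed(seed, {
    purrr::map_dfr(panel_sizes, function(size) {
      purrr::map_dfr(seq_len(n_reps), function(r) {
        loci_idx <- sample.int(n_loci(gm), size)
        sub <- subset_loci(gm, sort(loci_idx))
        fit <- supervised_ancestry(sub, freqs, ...)
        df <- focal_components(fit$Q, gm$pop_labels)
        df <- dplyr::summarise(
          dplyr::group_by(df, .data$group, .data$ancestry),
          value = mean(.data$value), .groups = "drop")
        df$panel_size <- size
        df$replicate <- r
        df
      })
    })
  })
  out <- summarise_values(
    dplyr::group_by(reps, .data$panel_size, .data$group, .data$ancestry))
  out$n_replicates <- n_reps
  attr(out, "replicates") <- reps
  out
}

#' Evaluate a fixed AIM panel against genotype data
#'
#' Restricts the data to the panel's loci, estimates supervised ancestry,
#' and summarises the focal ancestry component across the individuals of
#' each population (mean, SD, percentile 95% CI, range). The effective
#' (intersected) panel size is recorded. If a reference fit is supplied,
#' the per-ancestry error report ([panel_error()]) against it is attached
#' as attribute `error`.
#'
#' @param gm a [genotype_matrix()] with population labels.
#' @param freqs an [allele_freqs()].
#' @param panel an [aim_panel()] or character vector of loci; must overlap
#'   the data's loci.
#' @param reference optional `ancestry_fit` from
#'   [genome_ancestry_reference()].
#' @param ... passed to [supervised_ancestry()].
#' @return A tibble with one row per (group, ancestry): `panel`, `group`,
#'   `ancestry`, summary columns as in [rsnp_resampling()], `panel_size`
#'   (effective) and `n_missing_loci`. The underlying fit is attached as
#'   attribute `fit`.
#' @export
evaluate_panel <- function(gm, freqs, panel, reference = NULL, ...) {
  name <- if (inherits(panel, "aim_panel")) panel$name else "panel"
  sub <- subset_by_panel(gm, panel)
  fit <- supervised_ancestry(sub, freqs, ...)
  df <- focal_components(fit$Q, gm$pop_labels)
  out <- summarise_values(dplyr::group_by(df, .data$group, .data$ancestry))
  out <- dplyr::mutate(out, panel = name, panel_size = n_loci(sub),
                       n_missing_loci = length(attr(sub, "missing_loci")),
                       .before = 1)
  attr(out, "fit") <- fit
  if (!is.null(reference)) {
    attr(out, "error") <- panel_error(fit, reference, panel_name = name,
                                      panel_size = n_loci(sub))
  }
  out
}

#' Error of panel-based ancestry estimates against the reference
#'
#' Per ancestry component, the error is the root-mean-square deviation of
#' the panel estimates about the reference (genome-wide) values — an "SD
#' about the reference ancestry" rather than about the replicate mean. The
#' centred SD is reported alongside as a diagnostic.
#'
#' @param panel_Q an `ancestry_fit` or `N x K` matrix of panel-based
#'   estimates.
#' @param reference_Q an `ancestry_fit` or matrix of reference estimates on
#'   the same samples and aligned ancestries.
#' @param panel_name,panel_size optional metadata stored in the report.
#' @param admixed optional flag marking reports on admixed genomes.
#' @return A tibble with columns `panel`, `panel_size`, `ancestry`,
#'   `error` (RMS about the reference), `sd_centered` and `admixed`.
#' @export
panel_error <- function(panel_Q, reference_Q, panel_name = "panel",
                        panel_size = NA_integer_, admixed = FALSE) {
  if (inherits(panel_Q, "ancestry_fit")) panel_Q <- panel_Q$Q
  if (inherits(reference_Q, "ancestry_fit")) reference_Q <- reference_Q$Q
  if (!identical(dim(panel_Q), dim(reference_Q)) ||
      !identical(rownames(panel_Q), rownames(reference_Q))) {
    stop("panel and reference estimates must cover the same samples",
         call. = FALSE)
  }
  dev <- panel_Q - reference_Q
  tibble::tibble(
    panel = panel_name,
    panel_size = as.integer(panel_size),
    ancestry = colnames(panel_Q) %||% paste0("C", seq_len(ncol(panel_Q))),
    error = unname(sqrt(colMeans(dev^2))),
    sd_centered = unname(apply(dev, 2,
                               function(x) sqrt(mean((x - mean(x))^2)))),
    admixed = admixed
  )
}

#' Population sub-sampling experiment
#'
#' Measures how the precision of a *population-level* ancestry estimate
#' depends on sample size. Individuals failing the call-rate filter
#' (`min_call`, default 0.9 — profiles missing more than 10% of calls) are
#' removed first. Ancestry is estimated once per individual from the
#' panel's loci; then, for every population and every sub-sample size,
#' `n_subsamples` draws without replacement are taken and the draw mean of
#' the own-ancestry component recorded. Reported per size: the mean of the
#' draw means and the percentile (2.5%, 97.5%) bootstrap interval of the
#' draw distribution.
#'
#' @param gm a [genotype_matrix()] with population labels.
#' @param freqs an [allele_freqs()].
#' @param panel an [aim_panel()], character vector of loci, or `NULL` for
#'   all loci.
#' @param sizes sub-sample sizes; default 5 to 40 in steps of 5.
#' @param n_subsamples draws per size (the headline experiment uses 1,000).
#' @param seed integer seed.
#' @param min_call call-rate threshold applied before sub-sampling.
#' @param ... passed to [supervised_ancestry()].
#' @return A tibble with one row per (group, size): `group`, `ancestry`,
#'   `size`, `mean`, `ci_low`, `ci_high`, `n_subsamples`. Draw-level means
#'   are attached as attribute `draws`.
#' @export
sample_size_experiment <- function(gm, freqs, panel = NULL,
                                   sizes = seq(5, 40, by = 5),
                                   n_subsamples = 1000, seed = 1,
                                   min_call = 0.9, ...) {
  gm <- filter_by_call_rate(gm, min_call)
  sub <- if (is.null(panel)) gm else subset_by_panel(gm, panel)
  fit <- supervised_ancestry(sub, freqs, ...)
  df <- focal_components(fit$Q, gm$pop_labels)
  own <- df[df$group == df$ancestry, ]
  groups <- sort(unique(own$group))
  for (g in groups) {
    n_g <- sum(own$group == g)
    if (max(sizes) > n_g) {
      stop("sub-sample size ", max(sizes), " exceeds the ", n_g,
           " filtered individuals of population ", g, call. = FALSE)
    }
  }
  draws <- with_seed(seed, {
    purrr::map_dfr(groups, function(g) {
      vals <- own$value[own$group == g]
      purrr::map_dfr(sizes, function(s) {
        m <- vapply(seq_len(n_subsamples), function(r) {
          mean(vals[sample.int(length(vals), s)])
        }, numeric(1))
        tibble::tibble(group = g, ancestry = g, size = s,
                       draw = seq_len(n_subsamples), value = m)
      })
    })
  })
  out <- dplyr::summarise(
    dplyr::group_by(draws, .data$group, .data$ancestry, .data$size),
    mean = mean(.data$value),
    ci_low = unname(quantile(.data$value, 0.025)),
    ci_high = unname(quantile(.data$value, 0.975)),
    .groups = "drop")
  out$n_subsamples <- n_subsamples
  attr(out, "draws") <- draws
  out
}

#' Correlation between panel size and ancestry-estimation error
#'
#' Pearson correlation between the number of loci in a panel and its
#' per-ancestry error, computed per ancestry component and pooled over all
#' components. Constant inputs make the correlation undefined; such rows
#' are returned with `cor = NA` and `defined = FALSE` rather than an
#' error.
#'
#' @param errors a data frame of stacked [panel_error()] reports (columns
#'   `panel_size`, `ancestry`, `error`) with at least 3 distinct sizes.
#' @return A tibble with columns `ancestry` (component label or
#'   `"pooled"`), `cor`, `n` and `defined`.
#' @export
size_error_correlation <- function(errors) {
  stopifnot(all(c("panel_size", "ancestry", "error") %in% names(errors)))
  if (length(unique(errors$panel_size)) < 3) {
    stop("need reports for at least 3 distinct panel sizes", call. = FALSE)
  }
  cor_row <- function(df, label) {
    defined <- sd(df$panel_size) > 0 && sd(df$error) > 0
    tibble::tibble(ancestry = label,
                   cor = if (defined) cor(df$panel_size, df$error) else NA_real_,
                   n = nrow(df), defined = defined)
  }
  per <- purrr::map_dfr(split(errors, errors$ancestry),
                        function(df) cor_row(df, df$ancestry[[1]]))
  dplyr::bind_rows(per, cor_row(errors, "pooled"))
}
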