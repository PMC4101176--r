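#' Read genotypes from PLINK PED/MAP text or a TSV matrix
#'
#' Two plain-text dialects are supported. `ped_map` is the PLINK text layout:
#' a whitespace-delimited PED file whose first six columns are family ID,
#' sample ID, father, mother, sex and phenotype, followed by two allele
#' columns per locus; locus identifiers come from the second column of the
#' companion MAP file (chromosome, id, cM, bp — only the id is consumed, and
#' the family ID is kept as the population label). `tsv_matrix` is a
#' tab-separated matrix with a header of locus IDs, first two columns sample
#' ID and population label, and an integer body with `NA` for missing.
#'
#' Genotypes are recoded as counts of a per-locus reference allele. The
#' reference allele of each locus is the first allele observed in file order
#' — a deterministic convention; any consistent coding yields the same
#' admixture likelihood up to allele relabelling. The PED missing pair
#' `0 0` becomes a missing call.
#'
#' @param path path to the PED file (dialect `ped_map`) or the TSV file.
#' @param dialect `"ped_map"` or `"tsv_matrix"`.
#' @param map_path MAP file path; defaults to `path` with its extension
#'   replaced by `.map`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("ped_map", "tsv_matrix"),
                           map_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "ped_map") {
    read_ped_map(path, map_path %||% sub("\\.[^.]*$", ".map", path))
  } else {
    read_tsv_matrix(path)
  }
}

read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(map_path)) {
    stop("MAP file not found: ", map_path, call. = FALSE)
  }
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  loci <- vapply(strsplit(trimws(map_lines), "[ \t]+"), function(f) {
    if (length(f) < 2) {
      stop("malformed MAP line: need at least 2 fields", call. = FALSE)
    }
    f[[2]]
  }, character(1))
  L <- length(loci)

  lines <- readLines(ped_path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  n <- length(lines)
  if (n == 0) stop("PED file is empty", call. = FALSE)

  samples <- character(n)
  pops <- character(n)
  # allele characters per sample: n x 2L
  alleles <- matrix(NA_character_, n, 2L * L)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2L * L) {
      stop("malformed PED line ", line_no[i], ": expected ", 6 + 2L * L,
           " fields, found ", length(f), call. = FALSE)
    }
    pops[i] <- f[[1]]
    samples[i] <- f[[2]]
    alleles[i, ] <- f[-(1:6)]
  }

  G <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    a1 <- alleles[, 2L * l - 1L]
    a2 <- alleles[, 2L * l]
    called <- a1 != "0" & a2 != "0"
    half <- xor(a1 == "0", a2 == "0")
    if (any(half)) {
      stop("malformed PED line ", line_no[which(half)[1]],
           ": half-missing genotype at locus ", loci[l], call. = FALSE)
    }
    obs <- c(rbind(a1[called], a2[called]))
    if (length(obs) == 0) next
    ref <- obs[[1]]
    G[called, l] <- (a1[called] == ref) + (a2[called] == ref)
  }
  genotype_matrix(G, samples, loci, pops)
}

read_tsv_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("TSV matrix file is empty", call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3) {
    stop("malformed TSV header: need sample, population and >=1 locus column",
         call. = FALSE)
  }
  loci <- header[-(1:2)]
  L <- length(loci)
  body <- lines[-1]
  n <- length(body)
  samples <- character(n)
  pops <- character(n)
  G <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != L + 2) {
      stop("malformed TSV line ", i + 1, ": expected ", L + 2,
           " fields, found ", length(f), call. = FALSE)
    }
    samples[i] <- f[[1]]
    pops[i] <- f[[2]]
    vals <- suppressWarnings(as.integer(f[-(1:2)]))
    bad <- which(is.na(vals) & f[-(1:2)] != "NA")
    if (length(bad)) {
      stop("malformed TSV line ", i + 1, ": non-integer genotype '",
           f[-(1:2)][bad[1]], "'", call. = FALSE)
    }
    G[i, ] <- vals
  }
  genotype_matrix(G, samples, loci, pop_labels = pops)
}

#' Write genotypes to disk
#'
#' Inverse of [read_genotypes()] for both dialects. The TSV dialect
#' round-trips any matrix exactly. In `ped_map` the reference allele is
#' written as `A` and the alternate as `B`; because the reader re-derives
#' the reference as the first allele seen in file order, a locus whose
#' first called sample carries no reference allele reads back with flipped
#' coding (an equivalent relabelling). One read/write cycle reaches the
#' dialect's stable domain, after which round-trips are exact.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (PED path for `ped_map`).
#' @param dialect `"ped_map"` or `"tsv_matrix"`.
#' @param map_path MAP output path; defaults to `path` with extension `.map`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, dialect = c("ped_map", "tsv_matrix"),
                            map_path = NULL) {
  dialect <- match.arg(dialect)
  pops <- gm$pop_labels %||% rep("POP", n_samples(gm))
  if (dialect == "tsv_matrix") {
    header <- paste(c("sample", "population", gm$loci), collapse = "\t")
    body <- vapply(seq_len(n_samples(gm)), function(i) {
      vals <- ifelse(is.na(gm$G[i, ]), "NA", as.character(gm$G[i, ]))
      paste(c(gm$samples[i], pops[i], vals), collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
  } else {
    map_path <- map_path %||% sub("\\.[^.]*$", ".map", path)
    writeLines(paste("1", gm$loci, "0", seq_along(gm$loci)), map_path)
    code <- c("B B", "A B", "A A") # index by genotype + 1
    body <- vapply(seq_len(n_samples(gm)), function(i) {
      g <- gm$G[i, ]
      pairs <- ifelse(is.na(g), "0 0", code[g + 1L])
      paste(c(pops[i], gm$samples[i], "0", "0", "0", "-9", pairs),
            collapse = " ")
    }, character(1))
    writeLines(body, path)
  }
  invisible(path)
}

#' Read an AIM panel definition
#'
#' One locus identifier per line; blank lines and lines starting with `#`
#' are ignored.
#'
#' @param path panel file path.
#' @param name panel name; defaults to the file name without extension.
#' @return An [aim_panel()].
#' @export
read_panel <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  aim_panel(lines, name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Filter samples by genotype call rate
#'
#' Retains samples whose fraction of non-missing genotypes is at least
#' `min_call`, preserving sample order. The conventional quality threshold
#' for ancestry work is `min_call = 0.9`, i.e. dropping profiles with more
#' than 10% missing data.
#'
#' @param gm a [genotype_matrix()].
#' @param min_call minimum call-rate fraction in `[0, 1]`.
#' @return A filtered [genotype_matrix()]; warns (rather than errors) if all
#'   samples are removed.
#' @export
filter_by_call_rate <- function(gm, min_call = 0.9) {
  stopifnot(min_call >= 0, min_call <= 1)
  keep <- rowMeans(!is.na(gm$G)) >= min_call
  if (!any(keep)) {
    warning("all samples removed by call-rate filter (min_call = ",
            min_call, ")", call. = FALSE)
  }
  subset_samples(gm, which(keep))
}

#' Restrict a genotype matrix to a panel's loci
#'
#' Columns are restricted to panel loci present in `gm`, in panel order.
#' Panel loci absent from the data are reported via the `missing_loci`
#' attribute of the result, mirroring the common situation where a published
#' panel is only partially contained in a genotype database.
#'
#' @param gm a [genotype_matrix()].
#' @param panel an [aim_panel()] or character vector of locus IDs.
#' @return A [genotype_matrix()] with attribute `missing_loci` (character
#'   vector of panel loci not found in `gm`). Errors if no panel locus
#'   overlaps the data.
#' @export
subset_by_panel <- function(gm, panel) {
  loci <- if (inherits(panel, "aim_panel")) panel$loci else as.character(panel)
  idx <- match(loci, gm$loci)
  absent <- loci[is.na(idx)]
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    stop("no panel locus present in the genotype data", call. = FALSE)
  }
  out <- subset_loci(gm, idx)
  attr(out, "missing_loci") <- absent
  out
}
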