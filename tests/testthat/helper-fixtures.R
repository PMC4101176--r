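# Small fixtures built in code. All simulated datasets use fixed seeds so
# every run of the suite sees identical data.

tiny_gm <- function() {
  # 4 samples x 5 loci, two populations, one missing call
  G <- rbind(
    c(2L, 1L, 0L, 2L, 1L),
    c(2L, 2L, 0L, 1L, 0L),
    c(0L, 0L, 2L, NA, 2L),
    c(0L, 1L, 2L, 0L, 2L)
  )
  genotype_matrix(G, paste0("s", 1:4), paste0("rs", 1:5),
                  c("A", "A", "B", "B"))
}

# deterministic genotype column with given counts of 0/1/2
geno_block <- function(n0, n1, n2) {
  c(rep(0L, n0), rep(1L, n1), rep(2L, n2))
}

small_structured <- function(L = 400, n = 30, divergence = 0.15, seed = 42) {
  simulate_dataset(sim_config(L = L, K = 3, n_per_pop = n,
                              divergence = divergence, seed = seed))
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
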