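# small genotype fixtures built in code

# geno_matrix from a plain matrix with sites assigned in blocks
toy_gm <- function(g, sites_of_rows = NULL, ...) {
  g <- as.matrix(g)
  if (is.null(rownames(g))) rownames(g) <- paste0("i", seq_len(nrow(g)))
  if (is.null(colnames(g))) colnames(g) <- paste0("s", seq_len(ncol(g)))
  if (is.null(sites_of_rows)) sites_of_rows <- rep("A", nrow(g))
  geno_matrix(g, ind_meta = tibble::tibble(ind_id = rownames(g),
                                           site_id = sites_of_rows), ...)
}

# random genotype matrix for property tests
random_gm <- function(n_pops, n_per_pop, n_loci, seed,
                      missing_rate = 0) {
  set.seed(seed)
  p <- matrix(runif(n_pops * n_loci, 0.05, 0.95), n_pops, n_loci)
  g <- matrix(NA_integer_, n_pops * n_per_pop, n_loci)
  for (s in seq_len(n_pops)) {
    rows <- (s - 1) * n_per_pop + seq_len(n_per_pop)
    g[rows, ] <- rbinom(n_per_pop * n_loci, 2, rep(p[s, ], each = n_per_pop))
  }
  if (missing_rate > 0) {
    g[matrix(runif(length(g)) < missing_rate, nrow(g))] <- NA_integer_
  }
  toy_gm(g, sites_of_rows = rep(paste0("P", seq_len(n_pops)),
                                each = n_per_pop))
}

# write a small VCF text file and return its path
toy_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
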