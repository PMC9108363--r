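# deterministic in-code fixtures shared across test files

# tiny labelled dataset: 6 genes x 12 samples, two subtypes
tiny_dataset <- function(seed = 42L, n_genes = 6L, n_samples = 12L) {
  set.seed(seed)
  values <- matrix(rexp(n_genes * n_samples, rate = 0.1),
                   n_genes, n_samples,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                   sprintf("s%02d", seq_len(n_samples))))
  labels <- setNames(rep(c("alpha", "beta"), each = n_samples / 2),
                     colnames(values))
  expression_dataset(values, labels)
}

# hand-built pruned network: planted blocks with |cor| = within_cor inside
# each block, 0 elsewhere; block edges significant, the rest not
block_network <- function(block_sizes, n_noise = 0L, within_cor = 0.9,
                          subtype = "synthetic") {
  n <- sum(block_sizes) + n_noise
  genes <- sprintf("g%03d", seq_len(n))
  cor <- diag(n)
  pval <- matrix(1, n, n)
  start <- 0L
  for (b in block_sizes) {
    idx <- start + seq_len(b)
    cor[idx, idx] <- within_cor
    pval[idx, idx] <- 1e-6
    start <- start + b
  }
  diag(cor) <- 1
  diag(pval) <- 0
  sig <- pval <= 0.01
  diag(sig) <- FALSE
  dimnames(cor) <- dimnames(pval) <- dimnames(sig) <- list(genes, genes)
  structure(list(subtype = subtype, genes = genes, cor = cor, pval = pval,
                 significant = sig, n_folds = 1L, fold_size = NA_integer_,
                 alpha = 0.01),
            class = "aggregated_network")
}

# small simulation for fast end-to-end tests: 3 subtypes, modest genes
small_sim_spec <- function(seed = 1L) {
  simulation_spec(n_subtypes = 3L, sizes = c(15L, 30L, 10L), n_genes = 120L,
                  module_size = 15L, n_shared_modules = 1L, shared_size = 15L,
                  seed = seed)
}

# write a dataset to TSV files the way load_expression expects
write_tsv_fixture <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(dir, "expr.tsv")
  lp <- file.path(dir, "labels.tsv")
  df <- data.frame(gene_id = rownames(ds$values), ds$values,
                   check.names = FALSE)
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(names(ds$labels), unname(ds$labels)), lp,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  list(matrix = mp, labels = lp)
}

# independent adjusted Rand index (contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  sij <- sum_comb(as.vector(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
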