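#' Specification for a synthetic expression dataset
#'
#' Describes a latent-factor simulation with one planted co-expression
#' block per subtype (strongly co-expressed only within that subtype),
#' optional background blocks co-expressed in every subtype, and
#' independent noise genes. The default emulates a moderately imbalanced
#' four-group cohort (a control group and three tumour subtypes).
#'
#' Within its own subtype a planted gene follows
#' `baseline + within_load * z_sample + noise_sd * eps`, with one latent
#' factor `z` per sample, giving pairwise correlation
#' `within_load^2 / (within_load^2 + noise_sd^2)` inside the block
#' (0.9 at the defaults). In all other subtypes the same genes are
#' independent noise with matched marginal variance.
#'
#' @param n_subtypes number of groups `T` (default 4).
#' @param sizes per-subtype sample counts (default `c(20, 60, 12, 25)`).
#' @param n_genes total genes (default 300).
#' @param module_size genes per planted subtype block (default 25).
#' @param n_shared_modules background blocks present in every subtype
#'   (default 1).
#' @param shared_size genes per background block (default 30).
#' @param within_load latent-factor loading in (0, 1) (default 0.9).
#' @param noise_sd residual standard deviation (default 0.3).
#' @param baseline mean expression level (default 12).
#' @param seed integer seed.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_subtypes = 4L, sizes = c(20L, 60L, 12L, 25L),
                            n_genes = 300L, module_size = 25L,
                            n_shared_modules = 1L, shared_size = 30L,
                            within_load = 0.9, noise_sd = 0.3,
                            baseline = 12, seed = 1L) {
  stopifnot(length(sizes) == n_subtypes, all(sizes >= 5L),
            within_load > 0, within_load < 1, noise_sd > 0)
  if (n_subtypes * module_size + n_shared_modules * shared_size > n_genes)
    stop("planted blocks exceed the total gene count")
  structure(list(n_subtypes = as.integer(n_subtypes),
                 sizes = as.integer(sizes), n_genes = as.integer(n_genes),
                 module_size = as.integer(module_size),
                 n_shared_modules = as.integer(n_shared_modules),
                 shared_size = as.integer(shared_size),
                 within_load = within_load, noise_sd = noise_sd,
                 baseline = baseline, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate an expression dataset with planted co-expression blocks
#'
#' Generates the dataset described by a [simulation_spec()]. Values are
#' clipped at zero (the baseline keeps clipping negligible) and the
#' output is bitwise-deterministic given the seed. The returned ground
#' truth records the planted gene sets, which are pairwise disjoint.
#'
#' @param spec a [simulation_spec()].
#' @return list with `dataset` (an [expression_dataset()]) and
#'   `ground_truth` (`specific`: named list of per-subtype planted gene
#'   sets; `shared`: list of background block gene sets; `noise`: the
#'   remaining genes).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  subtype_names <- c("control", paste0("subtype", LETTERS[seq_len(spec$n_subtypes - 1L)]))
  n_samples <- sum(spec$sizes)
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  labels <- stats::setNames(rep(subtype_names, spec$sizes), sample_ids)

  # disjoint planted gene sets, then shared blocks, remainder noise
  cursor <- 0L
  specific <- lapply(seq_len(spec$n_subtypes), function(i) {
    out <- gene_ids[cursor + seq_len(spec$module_size)]
    cursor <<- cursor + spec$module_size
    out
  })
  names(specific) <- subtype_names
  shared <- lapply(seq_len(spec$n_shared_modules), function(i) {
    out <- gene_ids[cursor + seq_len(spec$shared_size)]
    cursor <<- cursor + spec$shared_size
    out
  })
  noise_genes <- gene_ids[(cursor + 1L):spec$n_genes]

  total_sd <- sqrt(spec$within_load^2 + spec$noise_sd^2)
  values <- with_seed(spec$seed, {
    # start from independent noise with the blocks' marginal variance
    v <- matrix(stats::rnorm(spec$n_genes * n_samples, sd = total_sd),
                spec$n_genes, n_samples,
                dimnames = list(gene_ids, sample_ids))
    for (s in subtype_names) {
      cols <- which(labels == s)
      z <- stats::rnorm(length(cols))
      g <- match(specific[[s]], gene_ids)
      v[g, cols] <- spec$within_load * matrix(z, length(g), length(cols),
                                              byrow = TRUE) +
        matrix(stats::rnorm(length(g) * length(cols), sd = spec$noise_sd),
               length(g), length(cols))
    }
    for (blk in shared) {
      z <- stats::rnorm(n_samples)
      g <- match(blk, gene_ids)
      v[g, ] <- spec$within_load * matrix(z, length(g), n_samples,
                                          byrow = TRUE) +
        matrix(stats::rnorm(length(g) * n_samples, sd = spec$noise_sd),
               length(g), n_samples)
    }
    pmax(v + spec$baseline, 0)
  })
  list(dataset = expression_dataset(values, labels, log_transformed = FALSE),
       ground_truth = list(specific = specific, shared = shared,
                           noise = noise_genes))
}

#' Write a simulated dataset to disk
#'
#' Emits the expression TSV, the label TSV and a ground-truth JSON into a
#' directory, in the formats [load_expression()] reads back.
#'
#' @param sim result of [simulate_expression()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  df <- data.frame(gene_id = rownames(ds$values), ds$values,
                   check.names = FALSE)
  utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(ds$labels), subtype = unname(ds$labels)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(sim$ground_truth, file.path(dir, "ground_truth.json"),
                       pretty = TRUE)
  invisible(dir)
}
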