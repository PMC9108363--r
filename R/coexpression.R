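#' Subsampling scheme for co-expression network construction
#'
#' Spearman correlations and their significance depend on sample size, so
#' networks built directly from imbalanced subtype groups are not
#' comparable. Instead each subtype network is built by drawing `F` folds of
#' `Ns` samples and aggregating the per-fold networks. `F` must be large
#' enough that every sample of the subtype is drawn at least once;
#' [make_folds()] repairs coverage deterministically if a seeded draw misses
#' a sample.
#'
#' @param n_folds number of folds `F` (positive integer).
#' @param fold_size samples drawn per fold `Ns` (positive integer).
#' @param seed integer seed for the fold draws.
#' @return an object of class `subsample_scheme`.
#' @export
subsample_scheme <- function(n_folds, fold_size, seed = 1L) {
  stopifnot(n_folds >= 1L, fold_size >= 1L)
  structure(list(n_folds = as.integer(n_folds),
                 fold_size = as.integer(fold_size),
                 seed = as.integer(seed)),
            class = "subsample_scheme")
}

#' Default subsampling scheme for a dataset
#'
#' `Ns` defaults to three quarters of the smallest subtype size (rounded
#' up, capped at `max_fold_size`): folds must be genuinely different draws
#' for the aggregation to sharpen anything, and folds of `min - 1` samples
#' would be near copies of each other for the smallest subtype. `F` for a
#' subtype of size s is `ceiling(3 * s / Ns)` - every sample expected in
#' about three folds, so coverage is near-certain before the deterministic
#' repair step - with a floor of `min_folds` so small subtypes still
#' average over enough distinct draws to damp spurious single-fold
#' significance.
#'
#' @param ds an [expression_dataset()].
#' @param subtype subtype the scheme is for (determines `F`).
#' @param fold_size `Ns`; `NULL` for the default above.
#' @param n_folds `F`; `NULL` for the default above.
#' @param max_fold_size cap on the default `Ns` (default 50).
#' @param min_folds floor on the default `F` (default 10).
#' @param seed integer seed.
#' @return a [subsample_scheme()].
#' @export
default_scheme <- function(ds, subtype, fold_size = NULL, n_folds = NULL,
                           max_fold_size = 50L, min_folds = 10L, seed = 1L) {
  sizes <- table(ds$labels)
  if (is.null(fold_size))
    fold_size <- min(ceiling(0.75 * min(sizes)), max_fold_size)
  fold_size <- as.integer(max(fold_size, 3L))
  s <- as.integer(sizes[[subtype]])
  if (is.null(n_folds))
    n_folds <- max(ceiling(3 * s / fold_size), min_folds)
  subsample_scheme(n_folds, fold_size, seed)
}

#' Draw subsampling folds covering every sample
#'
#' Draws `F` folds of `Ns` samples without replacement within each fold
#' (folds are independent of each other, so a sample may recur across
#' folds). If any sample is never drawn, unseen samples are swapped into
#' the last folds, replacing the most frequently drawn samples, until every
#' sample appears at least once. Deterministic given the scheme's seed.
#'
#' @param sample_ids character vector of sample ids.
#' @param scheme a [subsample_scheme()].
#' @return list of `F` character vectors, each of length `Ns`.
#' @export
make_folds <- function(sample_ids, scheme) {
  n <- length(sample_ids)
  if (scheme$fold_size > n)
    stop("fold size ", scheme$fold_size, " exceeds available samples (", n, ")")
  if (scheme$n_folds * scheme$fold_size < n)
    stop("F * Ns = ", scheme$n_folds * scheme$fold_size,
         " cannot cover all ", n, " samples; increase n_folds")
  folds <- with_seed(scheme$seed, {
    lapply(seq_len(scheme$n_folds),
           function(f) sample(sample_ids, scheme$fold_size, replace = FALSE))
  })
  unseen <- setdiff(sample_ids, unlist(folds))
  if (length(unseen)) {
    counts <- table(factor(unlist(folds), levels = sample_ids))
    fi <- scheme$n_folds
    for (s in unseen) {
      repeat {
        fold <- folds[[fi]]
        # replace the sample in this fold with the highest overall count
        repl <- fold[which.max(counts[fold])]
        if (counts[repl] > 1L) {
          folds[[fi]][match(repl, fold)] <- s
          counts[repl] <- counts[repl] - 1L
          counts[s] <- counts[s] + 1L
          break
        }
        fi <- if (fi == 1L) scheme$n_folds else fi - 1L
      }
      fi <- if (fi == 1L) scheme$n_folds else fi - 1L
    }
  }
  folds
}

#' Spearman co-expression network over a sample subset
#'
#' Pairwise Spearman rank correlation between all genes over the given
#' samples, with two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Ties receive average ranks. A gene constant on the subset has all its
#' correlations set to 0 with p = 1 (noted via a message).
#'
#' @param ds an [expression_dataset()].
#' @param sample_subset character vector of >= 3 sample ids.
#' @return list with symmetric matrices `cor` and `pval` (unit diagonal and
#'   zero diagonal p), plus `n_samples`.
#' @export
spearman_network <- function(ds, sample_subset) {
  if (length(sample_subset) < 3L)
    stop("need at least 3 samples for a correlation network")
  x <- ds$values[, sample_subset, drop = FALSE]
  constant <- apply(x, 1L, function(v) max(v) == min(v))
  rho <- suppressWarnings(stats::cor(t(x), method = "spearman"))
  if (any(constant)) {
    coexsub_log(sum(constant), " gene(s) constant on subset; correlations set to 0")
    rho[constant, ] <- 0
    rho[, constant] <- 0
  }
  diag(rho) <- 1
  n <- length(sample_subset)
  r2 <- pmin(rho^2, 1 - 1e-15)
  tstat <- abs(rho) * sqrt((n - 2) / (1 - r2))
  tstat[abs(rho) >= 1] <- Inf
  pval <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  if (any(constant)) {
    pval[constant, ] <- 1
    pval[, constant] <- 1
  }
  diag(pval) <- 0
  list(cor = rho, pval = pval, n_samples = n)
}

#' Build a subtype's aggregated co-expression network
#'
#' Draws folds with [make_folds()], computes a [spearman_network()] per
#' fold, and combines them: correlations by the arithmetic mean of the
#' per-fold signed values, p-values by the geometric mean
#' `(prod p_f)^(1/F)`. Per-fold p-values of 0 are clamped to machine
#' epsilon before the product so a single exact zero cannot annihilate the
#' combined score. The `significant` mask is unset until [prune_network()].
#'
#' @param ds an [expression_dataset()].
#' @param subtype subtype name.
#' @param scheme a [subsample_scheme()]; `NULL` for [default_scheme()].
#' @return an object of class `aggregated_network` with `subtype`, `genes`,
#'   `cor`, `pval`, `significant` (or `NULL`), `n_folds`, `fold_size`.
#' @export
aggregate_network <- function(ds, subtype, scheme = NULL) {
  ids <- subtype_samples(ds, subtype)
  if (is.null(scheme)) scheme <- default_scheme(ds, subtype)
  folds <- make_folds(ids, scheme)
  g <- nrow(ds$values)
  cor_sum <- matrix(0, g, g)
  logp_sum <- matrix(0, g, g)
  for (fold in folds) {
    net <- spearman_network(ds, fold)
    cor_sum <- cor_sum + net$cor
    logp_sum <- logp_sum + log(pmax(net$pval, .Machine$double.eps))
  }
  f <- length(folds)
  cor <- cor_sum / f
  pval <- exp(logp_sum / f)
  diag(cor) <- 1
  diag(pval) <- 0
  dimnames(cor) <- dimnames(pval) <- list(rownames(ds$values), rownames(ds$values))
  structure(
    list(subtype = subtype, genes = rownames(ds$values), cor = cor,
         pval = pval, significant = NULL, n_folds = f,
         fold_size = scheme$fold_size, alpha = NULL),
    class = "aggregated_network"
  )
}

#' @export
print.aggregated_network <- function(x, ...) {
  cat("aggregated_network for subtype", x$subtype, "-", length(x$genes),
      "genes,", x$n_folds, "folds of", x$fold_size, "\n")
  if (!is.null(x$significant))
    cat("significant edges:", sum(x$significant[upper.tri(x$significant)]),
        "(alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Prune an aggregated network to its significant edges
#'
#' Marks off-diagonal gene pairs with combined p-value `<= alpha` as
#' significant and removes genes left without any significant incident
#' edge.
#'
#' @param net an `aggregated_network` from [aggregate_network()].
#' @param alpha significance cutoff in (0, 1) on the combined p-value
#'   (default 0.01).
#' @return the pruned `aggregated_network`, with the `significant` mask set
#'   and `genes`/matrices restricted to connected genes.
#' @export
prune_network <- function(net, alpha = 0.01) {
  stopifnot(inherits(net, "aggregated_network"), alpha > 0, alpha <= 1)
  sig <- net$pval <= alpha
  diag(sig) <- FALSE
  degree <- rowSums(sig)
  keep <- degree > 0L
  if (!any(keep)) stop("no significant edges at alpha = ", alpha,
                       " for subtype ", net$subtype)
  net$cor <- net$cor[keep, keep, drop = FALSE]
  net$pval <- net$pval[keep, keep, drop = FALSE]
  net$significant <- sig[keep, keep, drop = FALSE]
  net$genes <- net$genes[keep]
  net$alpha <- alpha
  net
}

#' Write an aggregated network as an edge-list TSV
#'
#' One row per unordered gene pair with columns
#' `gene_a`, `gene_b`, `cor`, `pval`, `significant`. Only pairs that are
#' significant (or all pairs if the network is unpruned) are written. A
#' JSON sidecar `<path>.json` records subtype and scheme parameters.
#'
#' @param net an `aggregated_network`.
#' @param path output TSV path.
#' @param all_pairs write every pair rather than only significant ones.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, all_pairs = is.null(net$significant)) {
  pairs <- upper_pairs(length(net$genes))
  keep <- if (all_pairs) rep(TRUE, nrow(pairs)) else net$significant[pairs]
  df <- data.frame(
    gene_a = net$genes[pairs[keep, 1L]],
    gene_b = net$genes[pairs[keep, 2L]],
    cor = net$cor[pairs[keep, , drop = FALSE]],
    pval = net$pval[pairs[keep, , drop = FALSE]],
    significant = if (is.null(net$significant)) NA else net$significant[pairs[keep, , drop = FALSE]]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(subtype = net$subtype, n_folds = net$n_folds,
                  fold_size = net$fold_size, alpha = net$alpha,
                  n_genes = length(net$genes))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
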