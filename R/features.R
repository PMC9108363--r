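#' Stratified train/test split
#'
#' Draws `round(test_fraction * n)` samples (at least 1 when
#' `test_fraction > 0`) per subtype into the test set; the rest train.
#' Deterministic given the seed.
#'
#' @param ds an [expression_dataset()].
#' @param test_fraction fraction of each subtype held out (default 0.1).
#' @param seed integer seed.
#' @return list with character vectors `train` and `test`.
#' @export
split_train_test <- function(ds, test_fraction = 0.1, seed = 1L) {
  stopifnot(test_fraction >= 0, test_fraction < 1)
  test <- character(0)
  with_seed(seed, {
    for (s in subtypes(ds)) {
      ids <- subtype_samples(ds, s)
      if (length(ids) < 2L) stop("subtype ", s, " has fewer than 2 samples")
      n_test <- if (test_fraction == 0) 0L else max(1L, round(test_fraction * length(ids)))
      if (n_test >= length(ids))
        stop("test fraction leaves no training samples for subtype ", s)
      test <- c(test, sample(ids, n_test))
    }
  })
  list(train = setdiff(names(ds$labels), test), test = test)
}

# Spearman correlations of an edge list over a genes x samples submatrix:
# rank each gene's values, then Pearson on the rank rows
edge_spearman <- function(mat, pairs) {
  rk <- t(apply(mat, 1L, rank))
  rk <- rk - rowMeans(rk)
  ss <- sqrt(rowSums(rk^2))
  ia <- match(pairs[, 1L], rownames(mat))
  ib <- match(pairs[, 2L], rownames(mat))
  num <- rowSums(rk[ia, , drop = FALSE] * rk[ib, , drop = FALSE])
  den <- ss[ia] * ss[ib]
  out <- ifelse(den > 0, num / den, 0)
  unname(out)
}

#' Build reference network sets from training samples
#'
#' A reference network set holds, for each subtype `x`, the Spearman
#' correlations at `x`'s specific edges computed from `P` randomly drawn
#' training samples of `x` (the reference network). `n_sets` independent
#' seeded draws yield `n_sets` sets; featurizing one sample against several
#' sets both augments the training data and enables vote aggregation at
#' prediction time. Only training samples are ever drawn.
#'
#' @param ds an [expression_dataset()].
#' @param train_ids training sample ids.
#' @param spec result of [specificity_stage()] (specific module genes and
#'   edges per subtype).
#' @param n_ref samples per reference network `P`; `NULL` for the default
#'   `min(training subtype sizes) - 1` capped at 30.
#' @param n_sets number of reference network sets (default 10).
#' @param seed integer seed.
#' @return list of `reference_network_set` objects; each has `set_id` and,
#'   per subtype, `samples`, `genes`, `edges` (2-col matrix) and `cor`.
#' @export
build_reference_sets <- function(ds, train_ids, spec, n_ref = NULL,
                                 n_sets = 10L, seed = 1L) {
  stopifnot(n_sets >= 1L)
  train_lab <- ds$labels[train_ids]
  sizes <- table(train_lab)
  if (is.null(n_ref)) n_ref <- min(min(sizes) - 1L, 30L)
  n_ref <- as.integer(n_ref)
  if (n_ref < 3L) stop("reference size P must be at least 3")
  if (n_ref > min(sizes))
    stop("P = ", n_ref, " exceeds smallest training subtype size (",
         min(sizes), ")")
  subs <- names(spec)
  with_seed(seed, {
    lapply(seq_len(n_sets), function(set_id) {
      per_sub <- lapply(subs, function(x) {
        ids <- sample(train_ids[train_lab == x], n_ref)
        genes <- spec[[x]]$genes
        edges <- as.matrix(spec[[x]]$edges[, c("gene_a", "gene_b")])
        mat <- ds$values[genes, ids, drop = FALSE]
        list(samples = ids, genes = genes, edges = edges,
             cor = edge_spearman(mat, edges))
      })
      names(per_sub) <- subs
      structure(list(set_id = set_id, networks = per_sub),
                class = "reference_network_set")
    })
  })
}

#' Network-perturbation feature vector of one sample
#'
#' For each subtype `x`, the sample is appended to `x`'s reference samples,
#' the Spearman correlations at `x`'s specific edges are recomputed on this
#' expanded network, and the feature is the absolute correlation shift
#' `|cor' - cor|` per edge. A sample of subtype `x` barely disturbs `x`'s
#' own specific module but shifts other subtypes' modules more, which is
#' the signal the classifier learns. The per-subtype blocks are
#' concatenated in the reference set's subtype order.
#'
#' @param ds an [expression_dataset()] (gene universe of the sample).
#' @param sample_id sample id present in `ds`.
#' @param ref_set a `reference_network_set`.
#' @return named numeric vector of length `T * E`, names
#'   `<subtype>__<gene_a>__<gene_b>`, values in `[0, 2]`.
#' @export
perturb_sample <- function(ds, sample_id, ref_set) {
  stopifnot(sample_id %in% colnames(ds$values))
  blocks <- lapply(names(ref_set$networks), function(x) {
    net <- ref_set$networks[[x]]
    missing <- setdiff(net$genes, rownames(ds$values))
    if (length(missing))
      stop("sample ", sample_id, " lacks specific-module gene(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    mat <- cbind(ds$values[net$genes, net$samples, drop = FALSE],
                 ds$values[net$genes, sample_id])
    expanded <- edge_spearman(mat, net$edges)
    v <- abs(expanded - net$cor)
    names(v) <- paste(x, net$edges[, 1L], net$edges[, 2L], sep = "__")
    v
  })
  unlist(blocks)
}

# repetitions per subtype so each contributes about `target` vectors
balance_reps <- function(sizes, n_sets, target) {
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  reps <- stats::setNames(as.integer(pmin(n_sets, ceiling(target / sizes))),
                          names(sizes))
  if (any(reps * sizes < target))
    warning("balance target ", target, " unreachable for subtype(s) ",
            paste(names(sizes)[reps * sizes < target], collapse = ", "),
            " with ", n_sets, " reference sets; using the maximum achievable")
  reps
}

#' Featurize training samples with class balancing
#'
#' Each training sample is paired with one or more reference network sets
#' (seeded round-robin over the sets) so that every subtype contributes
#' approximately `balance_to` feature vectors; minority subtypes are
#' paired with more sets. This augmentation is what lets the classifier
#' see enough examples of small subtypes.
#'
#' @param ds an [expression_dataset()].
#' @param train_ids training sample ids.
#' @param ref_sets list from [build_reference_sets()].
#' @param balance_to target vectors per subtype; `"auto"` (default) uses
#'   the largest training subtype size.
#' @param seed integer seed for the round-robin offsets.
#' @return list with matrix `x` (rows = sample-set pairings), character
#'   `labels`, `sample_id`, integer `set_id`.
#' @export
featurize_training <- function(ds, train_ids, ref_sets, balance_to = "auto",
                               seed = 1L) {
  stopifnot(length(ref_sets) >= 1L)
  train_lab <- ds$labels[train_ids]
  sizes <- table(train_lab)
  target <- if (identical(balance_to, "auto")) max(sizes) else as.integer(balance_to)
  reps <- balance_reps(sizes, length(ref_sets), target)
  rows <- list(); labs <- character(0); sids <- character(0); sets <- integer(0)
  offset <- with_seed(seed, sample.int(length(ref_sets), 1L)) - 1L
  k <- 0L
  for (sid in train_ids) {
    r <- reps[[train_lab[[sid]]]]
    for (j in seq_len(r)) {
      set_idx <- ((offset + k) %% length(ref_sets)) + 1L
      k <- k + 1L
      rows[[length(rows) + 1L]] <- perturb_sample(ds, sid, ref_sets[[set_idx]])
      labs <- c(labs, train_lab[[sid]])
      sids <- c(sids, sid)
      sets <- c(sets, set_idx)
    }
  }
  x <- do.call(rbind, rows)
  rownames(x) <- NULL
  list(x = x, labels = labs, sample_id = sids, set_id = sets)
}

#' Featurize samples against every reference set
#'
#' Test or prediction-time samples are paired with all reference sets so
#' that [predict_vote()] can aggregate one vote per set.
#'
#' @param ds an [expression_dataset()].
#' @param sample_ids sample ids to featurize.
#' @param ref_sets list from [build_reference_sets()].
#' @return list with matrix `x`, character `sample_id`, integer `set_id`
#'   (and `labels` when the samples are labelled in `ds`).
#' @export
featurize_samples <- function(ds, sample_ids, ref_sets) {
  rows <- list(); sids <- character(0); sets <- integer(0)
  for (sid in sample_ids) {
    for (ref in ref_sets) {
      rows[[length(rows) + 1L]] <- perturb_sample(ds, sid, ref)
      sids <- c(sids, sid)
      sets <- c(sets, ref$set_id)
    }
  }
  x <- do.call(rbind, rows)
  rownames(x) <- NULL
  list(x = x, labels = unname(ds$labels[sids]), sample_id = sids, set_id = sets)
}

#' Write a feature matrix as TSV
#' @param feats list from [featurize_training()] or [featurize_samples()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(feats, path) {
  df <- data.frame(sample_id = feats$sample_id, set_id = feats$set_id,
                   check.names = FALSE)
  if (!is.null(feats$labels)) df$label <- feats$labels
  df <- cbind(df, as.data.frame(feats$x, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
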