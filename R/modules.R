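#' Weighted adjacency of a pruned network
#'
#' Unsigned soft-thresholded adjacency `a_ij = |cor_ij|^beta`, gated by the
#' significance mask (non-significant pairs contribute 0) with zero
#' diagonal.
#'
#' @param net a pruned `aggregated_network`.
#' @param beta positive soft threshold exponent.
#' @return symmetric adjacency matrix in `[0, 1]`.
#' @export
soft_adjacency <- function(net, beta) {
  stopifnot(inherits(net, "aggregated_network"), beta > 0)
  if (is.null(net$significant))
    stop("network must be pruned (prune_network) before adjacency")
  a <- abs(net$cor)^beta
  a[!net$significant] <- 0
  diag(a) <- 0
  a
}

# signed scale-free fit index: regress log10(frequency) on binned log10(k)
# and negate R^2 when the slope is positive (high-connectivity-heavy
# networks must not pass)
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < 3L || max(k) == min(k)) return(NA_real_)
  lk <- log10(k)
  breaks <- seq(min(lk), max(lk), length.out = n_bins + 1L)
  bin <- cut(lk, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(lk, bin, length)
  mid <- tapply(lk, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3L) return(NA_real_)
  fit <- stats::lm(log10(freq[ok]) ~ mid[ok])
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[[2L]]
  if (slope > 0) -r2 else r2
}

#' Choose the soft-threshold exponent by scale-free topology fit
#'
#' For each candidate beta, computes weighted connectivities
#' `k_i = sum_j |cor_ij|^beta` over significant edges, bins `log10(k)`,
#' and fits `log10(frequency) ~ log10(k)` by least squares; the fit index
#' is the signed R-squared (negated when the slope is positive). Returns
#' the smallest beta whose index reaches `r2_target`. When no candidate
#' reaches the target - networks dominated by a few dense cliques are not
#' scale-free at any power - the conventional unsigned-network default
#' `fallback_beta` is returned, following WGCNA practice; picking the
#' least-bad fit instead tends to land on an extreme power that erases all
#' structure.
#'
#' @param net a pruned `aggregated_network`.
#' @param candidates candidate beta values (default `1:20`).
#' @param r2_target fit index to reach (default 0.8).
#' @param fallback_beta beta used when the fit index is non-positive for
#'   every candidate (default 6).
#' @return list with `beta`, `r2`, and the per-candidate `fit_table`.
#' @export
pick_soft_threshold <- function(net, candidates = 1:20, r2_target = 0.8,
                                fallback_beta = 6) {
  stopifnot(all(candidates > 0))
  fits <- vapply(candidates, function(beta) {
    k <- rowSums(soft_adjacency(net, beta))
    scale_free_fit(k)
  }, numeric(1L))
  tab <- data.frame(beta = candidates, r2 = fits)
  if (all(is.na(fits))) {
    coexsub_log("degenerate connectivity; falling back to beta = 1")
    return(list(beta = 1, r2 = 0, fit_table = tab))
  }
  ok <- which(!is.na(fits) & fits >= r2_target)
  if (!length(ok)) {
    coexsub_log("scale-free fit below ", r2_target,
                " at every beta; using default beta = ", fallback_beta)
    return(list(beta = fallback_beta,
                r2 = max(fits, na.rm = TRUE), fit_table = tab))
  }
  idx <- ok[1L]
  list(beta = candidates[idx], r2 = fits[idx], fit_table = tab)
}

#' Topological overlap dissimilarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for the
#' weighted adjacency `a`; the returned dissimilarity is `1 - TOM` with a
#' zero diagonal. Gene pairs that share many strong neighbours are close
#' even if their direct edge is modest, which stabilises module detection.
#'
#' @param adjacency symmetric weighted adjacency with zero diagonal.
#' @return symmetric dissimilarity matrix in `[0, 1]`.
#' @export
tom_dissimilarity <- function(adjacency) {
  k <- rowSums(adjacency)
  shared <- adjacency %*% adjacency
  kmin <- outer(k, k, pmin)
  tom <- (shared + adjacency) / (kmin + 1 - adjacency)
  diag(tom) <- 1
  d <- 1 - tom
  d[d < 0] <- 0
  d
}

#' Partition a pruned network into co-expression modules
#'
#' Builds the soft-thresholded adjacency at `beta`, converts it to a
#' topological-overlap dissimilarity, clusters genes by average-linkage
#' hierarchical clustering, and cuts the tree at a fixed height. Each
#' cluster is then trimmed: a gene whose mean topological overlap with the
#' other members falls below `trim_fraction` of the cluster's internal
#' mean is moved to Module0, iterating until stable. The trim removes
#' genes chained onto a module through one or two spurious edges; because
#' the rule is relative it is insensitive to the overall TOM scale set by
#' `beta`. Clusters smaller than `min_module_size` are collected into
#' Module0 (index 0, the bin of unassigned genes); surviving modules are
#' renumbered 1..Sn by decreasing size.
#'
#' @param net a pruned `aggregated_network`.
#' @param beta soft threshold; `NULL` to pick it via
#'   [pick_soft_threshold()].
#' @param min_module_size smallest module retained (default 10, must be
#'   >= 3).
#' @param cut_height static tree-cut height on the dissimilarity dendrogram
#'   (default 0.95).
#' @param trim_fraction fraction of a cluster's mean internal topological
#'   overlap below which a member is moved to Module0 (default 0.5; 0
#'   disables trimming).
#' @return object of class `module_partition`: `subtype`, named integer
#'   `assignment` (gene -> module index, 0 = Module0), `beta`, `r2`,
#'   `n_modules`.
#' @export
detect_modules <- function(net, beta = NULL, min_module_size = 10L,
                           cut_height = 0.95, trim_fraction = 0.5) {
  stopifnot(min_module_size >= 3L)
  r2 <- NA_real_
  if (is.null(beta)) {
    pick <- pick_soft_threshold(net)
    beta <- pick$beta
    r2 <- pick$r2
  }
  genes <- net$genes
  if (length(genes) < min_module_size) {
    coexsub_log("fewer than min_module_size genes; all assigned to Module0")
    assignment <- stats::setNames(integer(length(genes)), genes)
    return(structure(list(subtype = net$subtype, assignment = assignment,
                          beta = beta, r2 = r2, n_modules = 0L),
                     class = "module_partition"))
  }
  adj <- soft_adjacency(net, beta)
  d <- tom_dissimilarity(adj)
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  # massively tied distances can leave sub-tolerance height inversions
  # that cutree rejects; repair only within floating-point noise
  if (is.unsorted(tree$height)) {
    inv <- max(cummax(tree$height) - tree$height)
    if (inv < 1e-8) tree$height <- cummax(tree$height) else
      stop("non-monotone dendrogram heights (inversion ", inv, ")")
  }
  raw <- stats::cutree(tree, h = cut_height)
  tom <- 1 - d
  if (trim_fraction > 0) {
    for (cl in unique(raw)) {
      members <- which(raw == cl)
      repeat {
        if (length(members) < 3L) break
        sub <- tom[members, members, drop = FALSE]
        mean_to_rest <- (rowSums(sub) - diag(sub)) / (length(members) - 1L)
        cutoff <- trim_fraction * mean(mean_to_rest)
        bad <- mean_to_rest < cutoff
        if (!any(bad)) break
        raw[members[bad]] <- 0L   # 0 never reaches min_module_size filter
        members <- members[!bad]
      }
    }
    raw[raw == 0L] <- max(raw) + seq_len(sum(raw == 0L))  # singletons
  }
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_module_size]
  assignment <- stats::setNames(integer(length(genes)), genes)
  if (length(big)) {
    # renumber by decreasing size; ties by original cluster label
    ord <- big[order(-sizes[big], as.integer(big))]
    for (m in seq_along(ord))
      assignment[raw == as.integer(ord[m])] <- m
  }
  structure(list(subtype = net$subtype, assignment = assignment,
                 beta = beta, r2 = r2, n_modules = length(big)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition for subtype", x$subtype, "-", x$n_modules,
      "modules over", length(x$assignment), "genes (beta =", x$beta, ")\n")
  tab <- table(x$assignment)
  cat("sizes:", paste(sprintf("M%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Genes of one module
#' @param partition a `module_partition`.
#' @param module module index (0 for Module0).
#' @return character vector of gene ids.
#' @export
module_genes <- function(partition, module) {
  names(partition$assignment)[partition$assignment == module]
}

#' Write a module partition as TSV with a JSON sidecar
#' @param partition a `module_partition`.
#' @param path output TSV path (`gene_id<TAB>module_index`).
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(gene_id = names(partition$assignment),
                   module_index = unname(partition$assignment))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(subtype = partition$subtype, beta = partition$beta,
         r2 = partition$r2, n_modules = partition$n_modules),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
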