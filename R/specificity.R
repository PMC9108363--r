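#' Overlap ratio between two gene sets
#'
#' `|source intersect target| / |source|`: the fraction of the source
#' module's genes that also cluster together in the target module.
#' Normalising by the source size removes the bias from unequal module
#' sizes.
#'
#' @param source_module character vector of gene ids (non-empty).
#' @param target_module character vector of gene ids.
#' @return a real in `[0, 1]`.
#' @export
overlap_ratio <- function(source_module, target_module) {
  if (!length(source_module)) stop("overlap_ratio: empty source module")
  length(intersect(source_module, target_module)) / length(source_module)
}

# per-module max overlap ratio against all non-Module0 modules of all other
# subtypes; Module0 is a residual bin, not a co-expression pattern, so it
# never counts as co-clustering
max_overlap_ratios <- function(partitions, s) {
  part_s <- partitions[[s]]
  mods_s <- seq_len(part_s$n_modules)
  if (!length(mods_s))
    stop("subtype ", s, " has no modules outside Module0")
  others <- setdiff(names(partitions), s)
  vapply(mods_s, function(i) {
    src <- module_genes(part_s, i)
    best <- 0
    for (t in others) {
      for (j in seq_len(partitions[[t]]$n_modules)) {
        r <- overlap_ratio(src, module_genes(partitions[[t]], j))
        if (r > best) best <- r
      }
    }
    best
  }, numeric(1L))
}

# mean signed correlation of a set of gene pairs in a subtype's network;
# pairs not significant there (or with a gene absent) contribute 0
edge_mean_in_network <- function(pairs, net) {
  if (!nrow(pairs)) return(NA_real_)
  vals <- numeric(nrow(pairs))
  ia <- match(pairs[, 1L], net$genes)
  ib <- match(pairs[, 2L], net$genes)
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok)) {
    idx <- cbind(ia[ok], ib[ok])
    sig <- net$significant[idx]
    v <- net$cor[idx]
    v[!sig] <- 0
    vals[ok] <- v
  }
  mean(vals)
}

# significant within-module gene pairs of subtype s, lexicographically
# ordered
module_edge_pairs <- function(genes, net) {
  idx <- match(genes, net$genes)
  idx <- idx[!is.na(idx)]
  if (length(idx) < 2L) return(matrix(character(0), ncol = 2L))
  sub_sig <- net$significant[idx, idx, drop = FALSE]
  sub_genes <- net$genes[idx]
  ord <- order(sub_genes, method = "radix")
  sub_sig <- sub_sig[ord, ord, drop = FALSE]
  sub_genes <- sub_genes[ord]
  up <- upper_pairs(length(sub_genes))
  keep <- sub_sig[up]
  cbind(sub_genes[up[keep, 1L]], sub_genes[up[keep, 2L]])
}

#' Score each module of a subtype for subtype specificity
#'
#' Combines two per-module ranks. Score 1 (aggregation specificity): the
#' maximal overlap ratio between the module and any non-Module0 module of
#' any other subtype, ranked ascending - genes that scatter across other
#' subtypes' partitions score best. Score 2 (correlation-gap): the mean
#' signed correlation of the module's significant edges in its own
#' network minus the same pairs' mean in each other subtype's network
#' (absent pairs counted as 0), minimised over the other subtypes and
#' ranked descending. Modules without any significant internal edge are
#' excluded with a warning.
#'
#' @param partitions named list of `module_partition`, one per subtype.
#' @param networks named list of pruned `aggregated_network`, one per
#'   subtype (same names).
#' @param s the source subtype.
#' @return a `data.frame` of class `module_specificity_table` with columns
#'   `module`, `max_overlap_ratio`, `score1`, `min_mean_gap`, `score2`,
#'   `total`.
#' @export
module_specificity <- function(partitions, networks, s) {
  stopifnot(s %in% names(partitions), s %in% names(networks))
  part_s <- partitions[[s]]
  net_s <- networks[[s]]
  mods <- seq_len(part_s$n_modules)
  ratios <- max_overlap_ratios(partitions, s)

  gaps <- rep(NA_real_, length(mods))
  for (i in mods) {
    pairs <- module_edge_pairs(module_genes(part_s, i), net_s)
    if (!nrow(pairs)) next
    own <- edge_mean_in_network(pairs, net_s)
    others <- setdiff(names(networks), s)
    diffs <- vapply(others, function(t) own - edge_mean_in_network(pairs, networks[[t]]),
                    numeric(1L))
    gaps[i] <- min(diffs)
  }
  keep <- !is.na(gaps)
  if (!all(keep))
    warning(sum(!keep), " module(s) of ", s,
            " without significant internal edges excluded from scoring")
  if (!any(keep)) stop("no scorable modules for subtype ", s)
  tab <- data.frame(
    module = mods[keep],
    max_overlap_ratio = ratios[keep],
    score1 = rank_permutation(ratios[keep]),
    min_mean_gap = gaps[keep],
    score2 = rank_permutation(gaps[keep], decreasing = TRUE)
  )
  tab$total <- tab$score1 + tab$score2
  class(tab) <- c("module_specificity_table", "data.frame")
  attr(tab, "subtype") <- s
  tab
}

#' Select the specific co-expression module from a specificity table
#'
#' The module minimising `score1 + score2`; ties are broken by the smaller
#' score 2 rank (the larger correlation gap), then by the smaller module
#' index.
#'
#' @param table a `module_specificity_table` from [module_specificity()].
#' @return the selected module index (integer).
#' @export
select_specific_module <- function(table) {
  stopifnot(nrow(table) >= 1L)
  ord <- order(table$total, table$score2, table$module)
  as.integer(table$module[ord[1L]])
}

#' Extract the most subtype-specific edges of a module
#'
#' For every significant within-module gene pair of subtype `s`, the
#' specificity margin is `delta = cor_s - max_x cor_x` over the other
#' subtypes `x`, where a pair absent (not significant, or a gene missing)
#' from subtype `x`'s network contributes 0 there. Signed correlations are
#' used throughout. The top `E` pairs by decreasing `delta` (ties broken
#' lexicographically by gene ids) are returned.
#'
#' @param genes gene ids of the specific module of `s`.
#' @param networks named list of pruned `aggregated_network` per subtype.
#' @param s source subtype name.
#' @param n_edges number of edges `E` to keep (>= 1).
#' @return object of class `specific_edge_set`: a `data.frame` with columns
#'   `gene_a`, `gene_b`, `delta`, and one `cor_<subtype>` column per
#'   subtype; attribute `subtype`.
#' @export
select_specific_edges <- function(genes, networks, s, n_edges = 100L) {
  stopifnot(n_edges >= 1L, s %in% names(networks))
  net_s <- networks[[s]]
  pairs <- module_edge_pairs(genes, net_s)
  if (nrow(pairs) < n_edges)
    stop("specific module of ", s, " has only ", nrow(pairs),
         " significant edges; ", n_edges, " requested (shortfall ",
         n_edges - nrow(pairs), ")")
  cors <- sapply(names(networks), function(t) {
    net <- networks[[t]]
    ia <- match(pairs[, 1L], net$genes)
    ib <- match(pairs[, 2L], net$genes)
    v <- numeric(nrow(pairs))
    ok <- !is.na(ia) & !is.na(ib)
    if (any(ok)) {
      idx <- cbind(ia[ok], ib[ok])
      vv <- net$cor[idx]
      vv[!net$significant[idx]] <- 0
      v[ok] <- vv
    }
    v
  })
  cors <- matrix(cors, nrow = nrow(pairs),
                 dimnames = list(NULL, names(networks)))
  other <- setdiff(names(networks), s)
  maxcor <- apply(cors[, other, drop = FALSE], 1L, max)
  delta <- cors[, s] - maxcor
  ord <- order(-delta, pairs[, 1L], pairs[, 2L], method = "radix")
  top <- ord[seq_len(n_edges)]
  out <- data.frame(gene_a = pairs[top, 1L], gene_b = pairs[top, 2L],
                    delta = delta[top], stringsAsFactors = FALSE)
  for (t in names(networks)) out[[paste0("cor_", t)]] <- cors[top, t]
  class(out) <- c("specific_edge_set", "data.frame")
  attr(out, "subtype") <- s
  out
}

#' Run the full specificity stage for every subtype
#'
#' Scores modules, selects the specific module, and extracts its top
#' specific edges for each subtype in turn.
#'
#' @param partitions named list of `module_partition` per subtype.
#' @param networks named list of pruned `aggregated_network` per subtype.
#' @param n_edges edges per subtype (`E`).
#' @return named list per subtype with elements `table`, `module` (index),
#'   `genes`, `edges` (a `specific_edge_set`).
#' @export
specificity_stage <- function(partitions, networks, n_edges = 100L) {
  out <- lapply(names(partitions), function(s) {
    tab <- module_specificity(partitions, networks, s)
    m <- select_specific_module(tab)
    genes <- module_genes(partitions[[s]], m)
    edges <- select_specific_edges(genes, networks, s, n_edges)
    list(table = tab, module = m, genes = genes, edges = edges)
  })
  names(out) <- names(partitions)
  out
}

#' Write a specific edge set as TSV
#' @param edges a `specific_edge_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_specific_edges <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
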