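# hand-built two-subtype fixture used across the scoring tests:
# subtype "s" has modules M1 (6 genes) and M2 (5 genes); subtype "t"
# re-clusters part of M2 but scatters M1
scoring_fixture <- function() {
  genes <- sprintf("g%03d", 1:30)
  part <- function(subtype, assignment) {
    structure(list(subtype = subtype, assignment = assignment,
                   beta = 6, r2 = NA_real_,
                   n_modules = max(assignment)),
              class = "module_partition")
  }
  a_s <- setNames(integer(30), genes)
  a_s[1:6] <- 1L    # M1^s
  a_s[7:11] <- 2L   # M2^s
  a_t <- setNames(integer(30), genes)
  a_t[c(7:9, 12:18)] <- 1L  # M1^t overlaps M2^s in 3 of its 5 genes
  a_t[19:28] <- 2L
  list(partitions = list(s = part("s", a_s), t = part("t", a_t)))
}

test_that("overlap_ratio is intersection over source size", {
  expect_identical(overlap_ratio(letters[1:4], letters[1:4]), 1)
  expect_identical(overlap_ratio(letters[1:4], LETTERS[1:4]), 0)
  expect_identical(overlap_ratio(letters[1:10], letters[c(1:4, 15:20)]), 0.4)
  expect_error(overlap_ratio(character(0), letters), "empty")
  # brute-force oracle on random sets
  set.seed(13)
  universe <- sprintf("x%02d", 1:40)
  for (i in 1:20) {
    src <- sample(universe, sample(1:20, 1))
    tgt <- sample(universe, sample(0:20, 1))
    hits <- sum(vapply(src, function(g) g %in% tgt, logical(1)))
    expect_equal(overlap_ratio(src, tgt), hits / length(src),
                 tolerance = 1e-12)
  }
})

test_that("max overlap ratios ignore Module0 and rank ascending as score 1", {
  fix <- scoring_fixture()
  ratios <- coexsub:::max_overlap_ratios(fix$partitions, "s")
  # M1^s genes are unassigned (Module0) in t -> ratio 0
  expect_identical(ratios[1], 0)
  # M2^s shares 3 of its 5 genes with M1^t
  expect_identical(ratios[2], 3 / 5)
})

test_that("score ranks follow sorted order with deterministic ties", {
  expect_identical(coexsub:::rank_permutation(c(0.1, 0.5, 0.3)), c(1L, 3L, 2L))
  expect_identical(coexsub:::rank_permutation(c(0.5, 0.3, 0.1), decreasing = TRUE),
                   c(1L, 2L, 3L))
  # ties go to the earlier module
  expect_identical(coexsub:::rank_permutation(c(0.2, 0.2, 0.1)), c(2L, 3L, 1L))
  set.seed(5)
  for (i in 1:10) {
    x <- runif(sample(2:12, 1))
    expect_setequal(coexsub:::rank_permutation(x), seq_along(x))
  }
})

test_that("edge means substitute 0 for pairs absent from the other network", {
  # subtype s: pairs (a,b) cor 0.8 and (c,d) cor 0.6, both significant;
  # subtype t: (a,b) significant at 0.4, (c,d) absent
  genes <- c("a", "b", "c", "d")
  mk <- function(cor_ab, cor_cd, sig_cd) {
    cor <- diag(4); pval <- matrix(1, 4, 4)
    cor[1, 2] <- cor[2, 1] <- cor_ab
    pval[1, 2] <- pval[2, 1] <- 1e-5
    cor[3, 4] <- cor[4, 3] <- cor_cd
    if (sig_cd) pval[3, 4] <- pval[4, 3] <- 1e-5
    dimnames(cor) <- dimnames(pval) <- list(genes, genes)
    diag(pval) <- 0
    sig <- pval <= 0.01; diag(sig) <- FALSE
    structure(list(subtype = "x", genes = genes, cor = cor, pval = pval,
                   significant = sig, n_folds = 1L, fold_size = NA_integer_,
                   alpha = 0.01),
              class = "aggregated_network")
  }
  net_s <- mk(0.8, 0.6, TRUE)
  net_t <- mk(0.4, 0.9, FALSE)   # (c,d) strong but not significant: counts 0
  pairs <- rbind(c("a", "b"), c("c", "d"))
  expect_equal(coexsub:::edge_mean_in_network(pairs, net_s), 0.7)
  expect_equal(coexsub:::edge_mean_in_network(pairs, net_t), 0.2)
  # delta for this module would be 0.7 - 0.2 = 0.5
  expect_equal(coexsub:::edge_mean_in_network(pairs, net_s) -
                 coexsub:::edge_mean_in_network(pairs, net_t), 0.5)
})

test_that("identical networks yield zero correlation gaps for every module", {
  sim <- simulate_expression(small_sim_spec(seed = 2L))
  ds <- sim$dataset
  s <- subtypes(ds)[1]
  net <- prune_network(aggregate_network(ds, s, default_scheme(ds, s, seed = 3L)),
                       0.01)
  part <- suppressMessages(detect_modules(net, min_module_size = 5L))
  expect_gte(part$n_modules, 1L)
  tab <- suppressWarnings(
    module_specificity(list(a = part, b = part),
                       list(a = net, b = net), "a"))
  expect_true(all(abs(tab$min_mean_gap) < 1e-12))
  expect_true(all(tab$max_overlap_ratio == 1))
})

test_that("specific-module selection minimises total with stated tie-breaks", {
  tab <- data.frame(module = 1:3, max_overlap_ratio = c(.2, .1, .3),
                    score1 = c(2L, 1L, 3L), min_mean_gap = c(.1, .5, .2),
                    score2 = c(3L, 1L, 2L))
  tab$total <- tab$score1 + tab$score2
  expect_identical(select_specific_module(tab), 2L)
  # tie on total: smaller score2 wins
  tab2 <- data.frame(module = 1:2, score1 = c(1L, 3L), score2 = c(3L, 1L))
  tab2$total <- c(4L, 4L)
  expect_identical(select_specific_module(tab2), 2L)
  # full tie: smaller module index wins
  tab3 <- data.frame(module = 1:2, score1 = c(2L, 1L), score2 = c(2L, 3L))
  tab3$total <- c(4L, 4L)
  expect_identical(select_specific_module(tab3), 1L)
  tab4 <- data.frame(module = 7L, score1 = 1L, score2 = 1L, total = 2L)
  expect_identical(select_specific_module(tab4), 7L)
})

test_that("score totals live in [2, 2 Sn] and scores are permutations", {
  sim <- simulate_expression(small_sim_spec(seed = 6L))
  ds <- sim$dataset
  subs <- subtypes(ds)
  nets <- lapply(subs, function(s)
    prune_network(aggregate_network(ds, s, default_scheme(ds, s, seed = 11L)),
                  0.01))
  names(nets) <- subs
  parts <- suppressMessages(lapply(nets, detect_modules, min_module_size = 5L))
  names(parts) <- subs
  for (s in subs) {
    tab <- module_specificity(parts, nets, s)
    sn <- nrow(tab)
    expect_setequal(tab$score1, seq_len(sn))
    expect_setequal(tab$score2, seq_len(sn))
    expect_true(all(tab$total >= 2 & tab$total <= 2 * sn))
  }
})

test_that("specific edges maximise the signed correlation margin", {
  set.seed(17)
  nets <- lapply(c(s = 1, t = 2, u = 3), function(k) {
    n <- 8L
    genes <- sprintf("g%03d", 1:8)
    m <- matrix(runif(n * n, -0.9, 0.9), n, n)
    cor <- (m + t(m)) / 2
    diag(cor) <- 1
    pval <- matrix(1e-4, n, n)
    # a few random pairs made insignificant to exercise the 0-substitution
    drop <- matrix(sample(n, 4), ncol = 2)
    pval[drop] <- 0.5; pval[drop[, 2:1]] <- 0.5
    diag(pval) <- 0
    sig <- pval <= 0.01; diag(sig) <- FALSE
    dimnames(cor) <- dimnames(pval) <- dimnames(sig) <- list(genes, genes)
    structure(list(subtype = "x", genes = genes, cor = cor, pval = pval,
                   significant = sig, n_folds = 1L, fold_size = NA_integer_,
                   alpha = 0.01),
              class = "aggregated_network")
  })
  genes <- nets$s$genes
  edges <- select_specific_edges(genes, nets, "s", n_edges = 5L)
  expect_equal(nrow(edges), 5L)
  # exhaustive oracle over all significant pairs of s
  up <- which(upper.tri(diag(8)), arr.ind = TRUE)
  cand <- up[nets$s$significant[up], , drop = FALSE]
  deltas <- apply(cand, 1L, function(ij) {
    val <- function(net) {
      if (net$significant[ij[1], ij[2]]) net$cor[ij[1], ij[2]] else 0
    }
    nets$s$cor[ij[1], ij[2]] - max(val(nets$t), val(nets$u))
  })
  expect_equal(sort(edges$delta, decreasing = TRUE),
               sort(deltas, decreasing = TRUE)[1:5], tolerance = 1e-12)
  expect_true(min(edges$delta) >= max(deltas[-order(-deltas)[1:5]]) - 1e-12)
  # requesting more edges than exist names the shortfall
  expect_error(select_specific_edges(genes, nets, "s", n_edges = 1000L),
               "shortfall")
})

test_that("a pair equally strong elsewhere has zero margin", {
  net <- prune_network(block_network(c(4L), within_cor = 0.5), 0.01)
  nets <- list(s = net, t = net)
  edges <- select_specific_edges(net$genes, nets, "s", n_edges = 6L)
  expect_true(all(edges$delta == 0))
  expect_identical(colnames(edges)[4:5], c("cor_s", "cor_t"))
})
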