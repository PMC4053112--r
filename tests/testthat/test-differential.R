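makeGroups <- function(G = 60, nA = 4, nB = 4, seed = 3,
                       effect_idx = integer(0), effect = 0) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(G * (nA + nB)), G,
                dimnames = list(sprintf("G%03d", 1:G),
                                c(paste0("A", 1:nA), paste0("B", 1:nB))))
    m[effect_idx, 1:nA] <- m[effect_idx, 1:nA] + effect
    m
  })
}

test_that("identical groups give zero fold change and zero moderated t", {
  m <- makeGroups(G = 20, seed = 1)
  m[, 5:8] <- m[, 1:4]  # groupB duplicates groupA
  res <- rankDifferential(m, paste0("A", 1:4), paste0("B", 1:4))
  expect_equal(res$log_fold_change, rep(0, 20))
  expect_equal(res$t_mod, rep(0, 20))
})

test_that("prior df 0 recovers the ordinary pooled two-sample t", {
  m <- makeGroups(seed = 5, effect_idx = 1:5, effect = 1.5)
  res <- rankDifferential(m, paste0("A", 1:4), paste0("B", 1:4),
                          prior_df = 0, prior_var = 1)
  oracle <- pooledTOracle(m[, 1:4], m[, 5:8])
  expect_equal(res$t_mod[match(names(oracle), res$gene_id)],
               unname(oracle), tolerance = 1e-12)
  # p-values then come from the ordinary t with nA + nB - 2 df
  expect_equal(res$p_value,
               2 * pt(-abs(res$t_mod), df = 6), tolerance = 1e-12)
})

test_that("prior df Inf gives the fully-shrunk closed form", {
  m <- makeGroups(seed = 6)
  s0 <- 0.8
  res <- rankDifferential(m, paste0("A", 1:4), paste0("B", 1:4),
                          prior_df = Inf, prior_var = s0)
  lfc <- rowMeans(m[, 1:4]) - rowMeans(m[, 5:8])
  oracle <- lfc / (sqrt(s0) * sqrt(1 / 4 + 1 / 4))
  expect_equal(res$t_mod[match(names(oracle), res$gene_id)],
               unname(oracle), tolerance = 1e-12)
})

test_that("estimated hyperparameters agree with limma's empirical Bayes", {
  m <- makeGroups(G = 200, nA = 5, nB = 5, seed = 9,
                  effect_idx = 1:20, effect = 2)
  res <- rankDifferential(m, paste0("A", 1:5), paste0("B", 1:5))
  design <- cbind(1, rep(c(1, 0), each = 5))
  fit <- limma::eBayes(limma::lmFit(m, design))
  idx <- match(res$gene_id, rownames(m))
  expect_equal(res$t_mod, unname(fit$t[idx, 2]), tolerance = 1e-8)
  expect_equal(res$p_value, unname(fit$p.value[idx, 2]), tolerance = 1e-8)
})

test_that("zero-variance genes stay finite through variance shrinkage", {
  m <- makeGroups(G = 30, seed = 2, effect_idx = 1:3, effect = 2)
  m["G030", ] <- c(rep(1, 4), rep(0, 4))  # constant within both groups
  res <- rankDifferential(m, paste0("A", 1:4), paste0("B", 1:4))
  row <- res[res$gene_id == "G030", ]
  expect_true(is.finite(row$t_mod))
  expect_gt(row$t_mod, 0)
})

test_that("group contracts are enforced", {
  m <- makeGroups(G = 10)
  expect_error(rankDifferential(m, "A1", paste0("B", 1:4)), "at least 2")
  expect_error(rankDifferential(m, c("A1", "A2"), c("A2", "B1")), "disjoint")
  expect_error(rankDifferential(m, c("A1", "ZZ"), paste0("B", 1:2)), "ZZ")
})

test_that("q-values with pi0 = 1 equal Benjamini-Hochberg adjustment", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      p <- c(runif(40), runif(10, 0, 1e-3))
      expect_equal(estimateQvalues(p, pi0 = 1), p.adjust(p, "BH"),
                   tolerance = 1e-14)
    }
  })
})

test_that("q-value formula matches hand evaluation with the pi0 floor", {
  # one p-value below lambda: raw pi0 estimate is 0, floored to 0.05
  expect_equal(estimateQvalues(0.01), 0.05 * 0.01)
  expect_equal(estimateQvalues(c(1, 1, 1)), c(1, 1, 1))
  expect_error(estimateQvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(estimateQvalues(numeric(0)), "nonempty")
})

test_that("q-values are invariant to input order", {
  withr::with_seed(31, {
    p <- runif(50)^2
    q <- estimateQvalues(p)
    perm <- sample(50)
    expect_equal(estimateQvalues(p[perm]), q[perm], tolerance = 1e-14)
    # nondecreasing when sorted by p
    expect_true(all(diff(q[order(p)]) >= -1e-14))
  })
})

test_that("signature selection honours direction, FDR cap and supply", {
  m <- makeGroups(G = 60, nA = 5, nB = 5, seed = 13,
                  effect_idx = 1:4, effect = 3)
  res <- rankDifferential(m, paste0("A", 1:5), paste0("B", 1:5))
  expect_length(selectSignature(res, SignatureSpec(0, 0)), 0)
  sel <- selectSignature(res, SignatureSpec(250, 250), fdr_cap = 0.05)
  # supply-limited: only genes passing the cap are returned
  expect_true(all(res$q_value[match(sel, res$gene_id)] < 0.05))
  up <- selectSignature(res, SignatureSpec(250, 0))
  expect_true(all(res$t_mod[match(up, res$gene_id)] > 0))
})

test_that("top-N selection matches an exhaustive ranking oracle", {
  planted <- sprintf("G%03d", 1:30)
  m <- makeGroups(G = 120, nA = 5, nB = 5, seed = 17,
                  effect_idx = 1:30, effect = 4)
  res <- rankDifferential(m, paste0("A", 1:5), paste0("B", 1:5))
  sel <- selectSignature(res, SignatureSpec(20, 0))
  # brute force: sort all positive-t passing genes by t, take 20
  pass <- res[res$q_value < 0.05 & res$t_mod > 0, ]
  oracle <- pass$gene_id[order(-pass$t_mod)][1:20]
  expect_setequal(sel, oracle)
  expect_true(all(sel %in% planted))
})

test_that("planted-marker sensitivity is high at effect 2, sigma 0.5, n 5", {
  hits <- vapply(1:5, function(s) {
    withr::with_seed(100 + s, {
      G <- 200; n_planted <- 30
      m <- matrix(rnorm(G * 10, sd = 0.5), G,
                  dimnames = list(sprintf("G%03d", 1:G),
                                  c(paste0("A", 1:5), paste0("B", 1:5))))
      m[1:n_planted, 1:5] <- m[1:n_planted, 1:5] + 2
    })
    res <- rankDifferential(m, paste0("A", 1:5), paste0("B", 1:5))
    sel <- selectSignature(res, SignatureSpec(n_planted, n_planted))
    mean(sprintf("G%03d", 1:n_planted) %in% sel)
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("b_stat ranks genes identically to |t_mod|", {
  m <- makeGroups(G = 150, nA = 5, nB = 5, seed = 23,
                  effect_idx = 1:10, effect = 2)
  res <- rankDifferential(m, paste0("A", 1:5), paste0("B", 1:5))
  expect_identical(order(-abs(res$t_mod)), order(-res$b_stat))
})

test_that("pairwise union runs all K(K-1)/2 comparisons and bounds hold", {
  atlas <- genCellAtlas(smallAtlasConfig())
  se <- atlas$experiment
  types <- c("NCL", "basal", "stromal")
  spec <- SignatureSpec(10, 10)
  sig <- pairwiseSignatureUnion(se, types, spec)
  comps <- attr(sig, "comparisons")
  expect_equal(nrow(comps), 3)  # K(K-1)/2 with K = 3
  expect_lte(length(sig), 20 * 3)
  expect_true(all(sig %in% rownames(se)))
  expect_error(pairwiseSignatureUnion(se, c("NCL", "nothere"), spec),
               "nothere")
})
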