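# A small centroid matrix with independent columns plus tumours built from it.
makeCentroids <- function(n_genes = 200, K = 4, seed = 5) {
  withr::with_seed(seed, {
    matrix(rnorm(n_genes * K, mean = 7), n_genes, K,
           dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                           paste0("C", seq_len(K))))
  })
}

test_that("zscale centers and scales to unit variance", {
  z <- zscale(c(1, 3))
  expect_equal(z, c(-1, 1) / sqrt(2))
  expect_equal(var(z), 1)
  withr::with_seed(2, v <- rnorm(20))
  expect_equal(zscale(zscale(v)), zscale(v), tolerance = 1e-12)
  expect_error(zscale(rep(2, 5), id = "T1"), "zero variance.*T1")
  expect_error(zscale(3), "at least 2")
})

test_that("correlation scores equal Pearson correlation", {
  cm <- makeCentroids()
  t1 <- cm[, 2]
  sc <- correlationScores(t1, cm)
  expect_equal(unname(sc[1, "C2"]), 1, tolerance = 1e-12)
  sc_neg <- correlationScores(-cm[, 3], cm)
  expect_equal(unname(sc_neg[1, "C3"]), -1, tolerance = 1e-12)
  expect_true(all(abs(sc) <= 1 + 1e-12))
})

test_that("correlation scores match the textbook Pearson oracle to 1e-10", {
  cm <- makeCentroids()
  withr::with_seed(8, {
    tumors <- matrix(rnorm(200 * 20, mean = 7, sd = 2), 200, 20,
                     dimnames = list(rownames(cm), paste0("T", 1:20)))
  })
  sc <- correlationScores(tumors, cm)
  for (j in 1:20) for (k in 1:4) {
    expect_equal(sc[j, k], pearsonOracle(tumors[, j], cm[, k]),
                 tolerance = 1e-10)
  }
})

test_that("correlation scores are invariant to affine rescaling of tumours", {
  cm <- makeCentroids()
  withr::with_seed(9, t1 <- rnorm(200, 7))
  names(t1) <- rownames(cm)
  expect_equal(correlationScores(t1, cm),
               correlationScores(3.7 * t1 + 11, cm), tolerance = 1e-12)
})

test_that("insufficient gene overlap is a guarded error", {
  cm <- makeCentroids()
  t_small <- cm[1:80, 1]  # 40% of the signature
  expect_error(correlationScores(t_small, cm), "overlap")
  expect_silent(correlationScores(cm[1:120, 1], cm, min_overlap = 0.5))
})

test_that("mixture fit recovers one-hot weights on pure tumours", {
  cm <- makeCentroids(K = 5)
  for (k in c(1, 3, 5)) {
    mx <- mixtureScores(cm[, k], cm)
    expected <- rep(0, 5); expected[k] <- 1
    expect_equal(unname(mx$coefficients[1, ]), expected, tolerance = 1e-8)
    expect_equal(unname(mx$partial_correlations[1, k]), 1, tolerance = 1e-8)
  }
})

test_that("with one centroid the partial correlation is the Pearson r", {
  cm <- makeCentroids(K = 1)
  withr::with_seed(12, t1 <- cm[, 1] + rnorm(200))
  mx <- mixtureScores(t1, cm)
  expect_equal(unname(mx$partial_correlations[1, 1]),
               pearsonOracle(t1, cm[, 1]), tolerance = 1e-10)
})

test_that("partial correlations match the residualization oracle", {
  cm <- makeCentroids(K = 4, seed = 33)
  withr::with_seed(34, {
    w <- c(0.5, 0.3, 0.15, 0.05)
    t1 <- cm %*% w + rnorm(200, sd = 0.8)
  })
  t1 <- setNames(t1[, 1], rownames(cm))
  mx <- mixtureScores(t1, cm)
  Z <- apply(cm, 2, zscale)
  y <- zscale(t1)
  for (k in 1:4) {
    ry <- resid(lm(y ~ Z[, -k] - 1))
    rx <- resid(lm(Z[, k] ~ Z[, -k] - 1))
    expect_equal(unname(mx$partial_correlations[1, k]), cor(ry, rx),
                 tolerance = 1e-8)
  }
})

test_that("collinear centroids are rejected by name", {
  cm <- makeCentroids(K = 3)
  cm[, 3] <- 2 * cm[, 1] - cm[, 2]
  expect_error(mixtureScores(cm[, 1], cm), "collinear.*C3")
})

test_that("decision tree routes pure centroid tumours correctly", {
  atlas <- genCellAtlas(smallAtlasConfig(seed = 4))
  se <- atlas$experiment
  maj <- buildMajorCentroids(se, SignatureSpec(20, 20))
  lp <- buildLPCentroids(se, SignatureSpec(20, 20))
  # a tumour equal to the true ALDH_pos mean profile over all genes
  t_lp <- atlas$means[, "ALDH_pos"]
  cl <- classifyDecisionTree(t_lp, maj, lp)
  expect_equal(cl$level1, "LP")
  expect_equal(cl$level2, "ALDH_pos")
  t_basal <- atlas$means[, "basal"]
  cl2 <- classifyDecisionTree(t_basal, maj, lp)
  expect_equal(cl2$level1, "basal")
  expect_true(is.na(cl2$level2))
  # classifier is a pure function of the score vector: argmax consistency
  sc <- correlationScores(t_basal, maj)
  expect_equal(colnames(sc)[which.max(sc[1, ])], "basal")
})

test_that("exact ties fall to the fixed priority label and are flagged", {
  # two identical centroids force an exact two-way tie
  genes <- sprintf("G%03d", 1:60)
  withr::with_seed(40, base <- rnorm(60, 7))
  cm <- cbind(stromal = base, basal = base,
              NCL = base + rnorm(60), LP_combined = base + rnorm(60))
  rownames(cm) <- genes
  maj <- CentroidSet(cm)
  lp_cm <- cbind(ALDH_neg = base, ALDH_pos = base,
                 ERBB3_neg = base + rnorm(60))
  rownames(lp_cm) <- genes
  lp <- CentroidSet(lp_cm)
  t1 <- setNames(base + 0.001 * seq_len(60), genes)
  sc <- correlationScores(t1, maj)
  # brute-force argmax oracle confirms the tie between stromal and basal
  mx <- max(sc[1, ])
  tied <- colnames(sc)[sc[1, ] == mx]
  expect_setequal(tied, c("stromal", "basal"))
  cl <- classifyDecisionTree(t1, maj, lp)
  expect_equal(cl$level1, "basal")  # later label in the priority order wins
  expect_true(cl$tie_flag)
})

test_that("intrinsic subtyping is nearest-centroid with Claudin-low pass-through", {
  ssp_m <- makeCentroids(K = 5, seed = 55)
  colnames(ssp_m) <- c("Basal-like", "Luminal A", "Luminal B", "HER2",
                       "Normal-like")
  ssp <- CentroidSet(ssp_m)
  expect_equal(unname(assignIntrinsicSubtype(ssp_m[, "HER2"], ssp)), "HER2")
  withr::with_seed(56, {
    tumors <- matrix(rnorm(200 * 10, 7), 200, 10,
                     dimnames = list(rownames(ssp_m), paste0("T", 1:10)))
  })
  got <- assignIntrinsicSubtype(tumors, ssp)
  for (j in 1:10) {
    cors <- apply(ssp_m, 2, function(cc) pearsonOracle(tumors[, j], cc))
    expect_equal(unname(got[j]), names(which.max(cors)))
  }
  got2 <- assignIntrinsicSubtype(tumors, ssp, claudin_low = c("T3", "T7"))
  expect_equal(unname(got2[c("T3", "T7")]), rep("Claudin-low", 2))
  expect_equal(got2[-c(3, 7)], got[-c(3, 7)])
  expect_error(assignIntrinsicSubtype(tumors, NULL), "SSP")
})

test_that("subtype summaries match sort-based quantile computation", {
  sc <- matrix(c(0.1, 0.2, 0.3, -0.5, 0.4, 0.0), 3, 2,
               dimnames = list(c("T1", "T2", "T3"), c("basal", "LP")))
  subtypes <- c(T1 = "LumA", T2 = "LumA", T3 = "Basal-like")
  s <- summarizeBySubtype(sc, subtypes)
  expect_equal(nrow(s), 2 * 2)  # subtypes x centroids
  one <- s[s$subtype == "Basal-like" & s$centroid == "basal", ]
  expect_equal(one$n, 1)
  expect_equal(one$median, 0.3)  # single tumour stratum
  luma <- s[s$subtype == "LumA" & s$centroid == "basal", ]
  expect_equal(luma$median, median(c(0.1, 0.2)))
  # quantile rule on [0.1, 0.2, 0.3]
  sc2 <- matrix(c(0.1, 0.2, 0.3), 3, 1,
                dimnames = list(paste0("T", 1:3), "basal"))
  s2 <- summarizeBySubtype(sc2, setNames(rep("X", 3), paste0("T", 1:3)))
  expect_equal(s2$median, 0.2)
  expect_equal(s2$q1, quantile(c(0.1, 0.2, 0.3), 0.25, names = FALSE))
  # random cohort against an independent sort-based oracle
  withr::with_seed(60, sc3 <- matrix(runif(40, -1, 1), 20, 2,
    dimnames = list(paste0("T", 1:20), c("A", "B"))))
  labs <- setNames(rep(c("g1", "g2"), 10), paste0("T", 1:20))
  s3 <- summarizeBySubtype(sc3, labs)
  v <- sort(unname(sc3[labs == "g1", "A"]))
  expect_equal(s3$median[s3$subtype == "g1" & s3$centroid == "A"],
               (v[5] + v[6]) / 2)
  expect_error(summarizeBySubtype(sc3, labs[-1]), "without subtype")
})
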