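test_that("atlas generation is a pure function of its config", {
  cfg <- smallAtlasConfig(seed = 77)
  a1 <- genCellAtlas(cfg)
  a2 <- genCellAtlas(cfg)
  expect_identical(SummarizedExperiment::assay(a1$experiment),
                   SummarizedExperiment::assay(a2$experiment))
  a3 <- genCellAtlas(smallAtlasConfig(seed = 78))
  expect_false(identical(SummarizedExperiment::assay(a1$experiment),
                         SummarizedExperiment::assay(a3$experiment)))
})

test_that("zero noise collapses samples onto their type means", {
  cfg <- atlasConfig(n_genes = 200, samples_per_type = 3,
                     marker_genes_per_type = 10, noise_sd = 0, seed = 1)
  atlas <- genCellAtlas(cfg)
  m <- SummarizedExperiment::assay(atlas$experiment)
  ct <- cellTypes(atlas$experiment)
  for (ty in unique(ct)) {
    sub <- m[, ct == ty, drop = FALSE]
    expect_equal(sub, matrix(atlas$means[, ty], nrow(sub), ncol(sub),
                             dimnames = dimnames(sub)))
  }
})

test_that("config invariants reject inconsistent structures", {
  expect_error(atlasConfig(lp_effect = 3, major_effect = 2), "lp_effect")
  expect_error(atlasConfig(n_genes = 100, marker_genes_per_type = 50),
               "exceed")
  expect_error(atlasConfig(samples_per_type = 0), "positive")
})

test_that("LP subtypes are mutually closer than to other cell types", {
  within_lp <- numeric(20); lp_to_basal <- numeric(20)
  lp_types <- attr(humanCellTypes(), "lp")
  for (s in 1:20) {
    atlas <- genCellAtlas(smallAtlasConfig(seed = 500 + s))
    cents <- atlasTruthCentroids(atlas)
    pairs <- combn(lp_types, 2)
    within_lp[s] <- mean(apply(pairs, 2, function(p)
      sqrt(sum((cents[, p[1]] - cents[, p[2]])^2))))
    lp_to_basal[s] <- mean(vapply(lp_types, function(ty)
      sqrt(sum((cents[, ty] - cents[, "basal"])^2)), numeric(1)))
  }
  expect_lt(mean(within_lp), mean(lp_to_basal))
})

test_that("tumour mixtures have unit-sum weights and a dominant component", {
  atlas <- genCellAtlas(smallAtlasConfig())
  cents <- atlasTruthCentroids(atlas)
  co <- genTumorCohort(cents, n_tumors = 100, dominant_weight = 0.7,
                       noise_sd = 0.5, seed = 11)
  expect_equal(unname(rowSums(co$weights)), rep(1, 100))
  expect_true(all(co$weights >= 0))
  # same seed reproduces; dominant_weight <= 0.5 rejected
  co2 <- genTumorCohort(cents, n_tumors = 100, dominant_weight = 0.7,
                        noise_sd = 0.5, seed = 11)
  expect_identical(co$profiles, co2$profiles)
  expect_error(genTumorCohort(cents, dominant_weight = 0.5), "dominant_weight")

  # pure noise-free tumours equal their dominant centroid
  pure <- genTumorCohort(cents, n_tumors = 5, dominant_weight = 1,
                         noise_sd = 0, seed = 3)
  for (j in 1:5)
    expect_equal(unname(pure$profiles[, j]),
                 unname(cents[, pure$labels[j]]))
})

test_that("tumours correlate best with their dominant centroid on average", {
  atlas <- genCellAtlas(smallAtlasConfig())
  cents <- atlasTruthCentroids(atlas)
  co <- genTumorCohort(cents, n_tumors = 100, dominant_weight = 0.7,
                       noise_sd = 0.5, seed = 19)
  sc <- correlationScores(co$profiles, cents)
  dom_idx <- cbind(seq_len(100), match(co$labels, colnames(sc)))
  dom_cor <- sc[dom_idx]
  other_cor <- (rowSums(sc) - dom_cor) / (ncol(sc) - 1)
  expect_gt(mean(dom_cor), mean(other_cor))
})

test_that("simulated assays follow the single-hit response probability", {
  a <- genLDAssay(true_f = 1, doses = c(10, 100), reps = 6, seed = 2)
  expect_equal(a@data$n_positive, a@data$n_tested)  # saturation
  a0 <- genLDAssay(true_f = 1e-12, doses = c(10, 100), reps = 6, seed = 2)
  expect_equal(sum(a0@data$n_positive), 0)
  # empirical positive fraction within 3 SE of 1 - exp(-f d)
  f <- 2e-3; d <- 500; reps <- 10000
  a_big <- genLDAssay(f, d, reps = reps, seed = 13)
  p_true <- 1 - exp(-f * d)
  se <- sqrt(p_true * (1 - p_true) / reps)
  expect_lt(abs(a_big@data$n_positive / reps - p_true), 3 * se)
  # determinism
  expect_identical(genLDAssay(1e-4, c(1e3, 1e4), seed = 5)@data,
                   genLDAssay(1e-4, c(1e3, 1e4), seed = 5)@data)
})

test_that("generated qPCR plates are deterministic under seed", {
  p1 <- genQPCRPlate(c(NCL = 1, S = 0.5), comparator = "NCL",
                     noise_sd = 0.2, seed = 4)
  p2 <- genQPCRPlate(c(NCL = 1, S = 0.5), comparator = "NCL",
                     noise_sd = 0.2, seed = 4)
  expect_identical(p1@wells, p2@wells)
  expect_error(genQPCRPlate(c(NCL = 1, S = -2), comparator = "NCL"),
               "positive")
  expect_error(genQPCRPlate(c(NCL = 2, S = 1), comparator = "NCL"),
               "comparator")
})
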