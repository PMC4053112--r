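# Small in-code fixtures shared across test files.

# A reduced atlas (fast) keeping the study structure: 6 human cell types,
# 3 of them LP subtypes, disjoint planted marker blocks.
smallAtlasConfig <- function(seed = 42L, noise_sd = 0.5) {
  atlasConfig(n_genes = 400, samples_per_type = 5,
              marker_genes_per_type = 20, major_effect = 2, lp_effect = 1,
              noise_sd = noise_sd, seed = seed)
}

# Write a matrix as the delimited text the readers expect.
writeTmpMatrix <- function(m, sep = "\t", ext = ".tsv", env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = env)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

writeTmpAnnotation <- function(se, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  ct <- cellTypes(se)
  write.table(data.frame(sample_id = names(ct), cell_type = unname(ct)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent Pearson oracle: the textbook sum formula, no cor()/zscale reuse.
pearsonOracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Ordinary pooled two-sample t computed directly from group summaries.
pooledTOracle <- function(a, b) {
  nA <- ncol(a); nB <- ncol(b)
  s2 <- ((nA - 1) * apply(a, 1, var) + (nB - 1) * apply(b, 1, var)) /
    (nA + nB - 2)
  (rowMeans(a) - rowMeans(b)) / sqrt(s2 * (1 / nA + 1 / nB))
}

# Map an atlas cell type to its level-1 decision-tree class.
level1Truth <- function(labels, lp_types = attr(humanCellTypes(), "lp")) {
  ifelse(labels %in% lp_types, "LP",
         ifelse(labels == "NCL", "luminal", labels))
}

# Full-gene "true" centroids of every atlas cell type (generator side).
atlasTruthCentroids <- function(atlas) {
  se <- atlas$experiment
  types <- unique(cellTypes(se))
  vapply(types, function(ty) buildCentroid(se, ty), numeric(nrow(se)))
}
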