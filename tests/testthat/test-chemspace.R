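test_that("MACCS fingerprints match the public key definitions on reference molecules", {
  fp <- maccs_fingerprint(c(methane = "C", benzene = "c1ccccc1",
                            caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C"))
  expect_equal(ncol(fp), 166)
  # bit sets computed from the packaged key definitions and cross-checked
  # against an independent toolkit implementation of the same public keys
  expect_equal(which(fp["methane", ] == 1), 160)
  expect_equal(which(fp["benzene", ] == 1), c(162, 163, 165))
  expect_equal(sum(fp["caffeine", ]), 46)
  expect_true(fp["caffeine", 125] == 1)  # two aromatic rings
})

test_that("fingerprints are canonical-form invariant and aromaticity-sensitive", {
  fp <- maccs_fingerprint(c(a = "C1=CC=CC=C1", b = "c1ccccc1", cyh = "C1CCCCC1"))
  expect_equal(fp["a", ], fp["b", ])
  # benzene vs cyclohexane differ at aromaticity-dependent keys
  expect_true(any(fp["b", ] != fp["cyh", ]))
  expect_equal(unname(fp["b", 162]), 1L)   # aromatic key
  expect_equal(unname(fp["cyh", 162]), 0L)
  # multi-fragment key
  fp2 <- maccs_fingerprint("[Na+].[Cl-]")
  expect_equal(unname(fp2[1, 166]), 1L)
})

test_that("tanimoto similarity follows intersection over union", {
  x <- c(1, 1, 0, 1)
  expect_equal(tanimoto(x, x), 1)
  expect_equal(tanimoto(c(1, 1, 0), c(0, 0, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 0), c(0, 1, 1)), 1 / 3)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), class = "bitterspace_validation_error")
})

test_that("pairwise distances are metric on bit vectors", {
  fps <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0))
  D <- pairwise_distances(fps, "euclidean")
  expect_equal(unname(D["a", "c"]), 0)
  expect_equal(unname(D["a", "b"]), sqrt(2))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  # triangle inequality over random bit vectors
  set.seed(7)
  X <- matrix(rbinom(30 * 20, 1, 0.4), 30, 20)
  D <- pairwise_distances(X, "euclidean")
  for (i in 1:10) {
    trip <- sample(30, 3)
    expect_lte(D[trip[1], trip[2]],
               D[trip[1], trip[3]] + D[trip[3], trip[2]] + 1e-12)
  }
  # jaccard distance is 1 - tanimoto
  Dj <- pairwise_distances(X, "jaccard")
  expect_equal(unname(Dj[1, 2]), 1 - tanimoto(X[1, ], X[2, ]))
  expect_error(pairwise_distances(X[1, , drop = FALSE]),
               class = "bitterspace_validation_error")
})

test_that("perplexity calibration hits the target entropy and normalizes", {
  # three equidistant points: conditional distributions are forced uniform
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  P3 <- perplexity_calibration(D3, 2)
  expect_equal(unname(P3[upper.tri(P3)]), rep(1 / 6, 3))
  expect_equal(unname(diag(P3)), rep(0, 3))

  set.seed(11)
  X <- matrix(rnorm(40 * 5), 40, 5)
  D <- pairwise_distances(X, "euclidean")
  target <- 8
  P <- perplexity_calibration(D, target)
  expect_equal(sum(P), 1, tolerance = 1e-12)
  expect_equal(P, t(P))
  # recompute each row's conditional perplexity from the fitted bandwidths
  beta <- attr(P, "beta")
  for (i in sample(40, 8)) {
    w <- exp(-D[i, -i]^2 * beta[i])
    p <- w / sum(w)
    H <- -sum(p[p > 0] * log(p[p > 0]))
    expect_equal(exp(H), target, tolerance = 1e-4)
  }
})

test_that("tsne_embed is deterministic, pulls duplicates together, and reduces KL", {
  # 5 points: two identical, three far away at distinct distances
  pts <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 0), d = c(0, 7), e = c(9, 9))
  D <- pairwise_distances(pts)
  # perplexity must stay above 2: for points outside the duplicated pair the
  # two equidistant copies bound the reachable entropy from below by log(2)
  P <- perplexity_calibration(D, 2.5)
  prm <- tsne_params(perplexity = 2.5, iterations = 600, seed = 4)
  rownames(P) <- rownames(pts)
  emb <- tsne_embed(P, prm, ids = rownames(pts))
  d_ab <- dist(emb$coords[c("a", "b"), ])[1]
  for (other in c("c", "d", "e")) {
    expect_lt(d_ab, dist(emb$coords[c("a", other), ])[1])
    expect_lt(d_ab, dist(emb$coords[c("b", other), ])[1])
  }
  # bit-identical rerun
  emb2 <- tsne_embed(P, prm, ids = rownames(pts))
  expect_identical(emb$coords, emb2$coords)
  # centered output, nonnegative KL
  expect_lt(max(abs(colMeans(emb$coords))), 1e-8)
  expect_gte(emb$kl_final, 0)
})

test_that("KL decreases after the exaggeration phase on random input", {
  set.seed(21)
  X <- matrix(rbinom(60 * 40, 1, 0.3), 60, 40)
  P <- perplexity_calibration(pairwise_distances(X), 12)
  emb <- tsne_embed(P, tsne_params(perplexity = 12, iterations = 1000, seed = 2))
  tr <- emb$kl_trace
  expect_lte(tr[["1000"]], tr[["300"]] + 0.01)
  expect_lte(tr[["1000"]], tr[["500"]] + 0.01)
})

test_that("embedding is equivariant to input permutation via id-keyed seeding", {
  set.seed(31)
  X <- matrix(rbinom(20 * 30, 1, 0.3), 20, 30,
              dimnames = list(sprintf("m%02d", 1:20), NULL))
  P <- perplexity_calibration(pairwise_distances(X), 4)
  rownames(P) <- colnames(P) <- rownames(X)
  prm <- tsne_params(perplexity = 4, iterations = 400, seed = 9)
  emb <- tsne_embed(P, prm)
  perm <- sample(20)
  emb_p <- tsne_embed(P[perm, perm], prm)
  expect_identical(emb_p$coords[rownames(emb$coords), ], emb$coords)
})

test_that("embed_dataset composes the full chemical-space stage", {
  cfg <- generator_config(n_compounds = 12, seed = 3)
  out <- synthesize_dataset(cfg)
  emb <- embed_dataset(out$dataset, tsne_params(perplexity = 3, iterations = 300, seed = 5))
  expect_equal(dim(emb$coords), c(12, 2))
  expect_equal(rownames(emb$coords), out$dataset$compounds$compound_id)
  expect_true(is.finite(emb$kl_final))
  # a duplicated compound becomes its twin's nearest neighbor
  comp <- data.frame(
    compound_id = c("caffeine", "DUP", "quinine", "egcg", "toluene", "octane",
                    "pyridine", "thiophene", "glucose", "phenol"),
    name = "x",
    smiles = c("Cn1cnc2c1c(=O)n(C)c(=O)n2C", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
               "COc1ccc2nccc(C(O)C3CC4CCN3CC4C=C)c2c1",
               "Oc1cc(O)c2c(c1)OC(c1cc(O)c(O)c(O)c1)C(OC(=O)c1cc(O)c(O)c(O)c1)C2",
               "Cc1ccccc1", "CCCCCCCC", "c1ccncc1", "c1ccsc1",
               "OCC1OC(O)C(O)C(O)C1O", "Oc1ccccc1"),
    superclass = "x", is_food = TRUE, tested_all_receptors = TRUE)
  act <- matrix(1L, 10, 1, dimnames = list(NULL, "TAS2R14"))
  ds2 <- activity_dataset(comp, act)
  emb2 <- embed_dataset(ds2, tsne_params(perplexity = 2.5, iterations = 400, seed = 5))
  D2 <- as.matrix(dist(emb2$coords))
  nn_of_first <- names(which.min(D2["caffeine", -1]))
  expect_equal(nn_of_first, "DUP")
})

test_that("well-separated fingerprint clusters are recovered in the embedding", {
  set.seed(13)
  base <- rbind(c(rep(1, 40), rep(0, 80)),
                c(rep(0, 40), rep(1, 40), rep(0, 40)),
                c(rep(0, 80), rep(1, 40)))
  lab <- rep(1:3, each = 20)
  X <- base[lab, ]
  flip <- matrix(rbinom(length(X), 1, 0.03), nrow(X))
  X <- abs(X - flip)
  rownames(X) <- sprintf("p%02d", seq_len(nrow(X)))
  P <- perplexity_calibration(pairwise_distances(X), 8)
  rownames(P) <- colnames(P) <- rownames(X)
  emb <- tsne_embed(P, tsne_params(perplexity = 8, iterations = 800, seed = 17))
  km <- kmeans(emb$coords, centers = 3, nstart = 20)
  expect_gte(rand_index(km$cluster, lab), 0.9)
})
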