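test_that("toy structures are deterministic, self-avoiding chains", {
  st <- makeToyStructure(5, seed = 1)
  expect_equal(nAtoms(st), 10L)
  expect_equal(length(unique(atoms(st)$resno)), 5L)
  expect_identical(coords(makeToyStructure(5, seed = 1)), coords(st))

  # brute-force pairwise separation check
  for (n in c(2L, 7L, 30L)) {
    d <- as.matrix(stats::dist(coords(makeToyStructure(n, seed = 7))))
    diag(d) <- Inf
    expect_gt(min(d), 0.2)
  }
  # consecutive Calpha spacing is the canonical 0.38 nm (up to jitter)
  ca <- coords(makeToyStructure(12, seed = 2))[seq(1, 24, 2), ]
  step <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(step - 0.38) < 0.05))

  expect_error(makeToyStructure(1), class = "e2dyn_invalid_argument")
})

test_that("Gaussian ensembles realise the prescribed spectrum", {
  fx <- internalBasis(10, k = 5, seed = 3)
  lam <- c(1, 0, 0, 0, 0)

  # zero spectrum: every frame equals the mean exactly
  ens0 <- sampleGaussianEnsemble(fx$mean, rep(0, 5), fx$basis, 10, seed = 1)
  for (f in 1:10) {
    expect_equal(coords(ens0)[f, , ], coords(fx$mean), tolerance = 0)
  }

  # law of large numbers along the single active mode
  ens <- sampleGaussianEnsemble(fx$mean, lam, fx$basis, 10000, seed = 2)
  x <- e2dyn:::.flatCoords(ens)
  p <- sweep(x, 2, e2dyn:::.flatten(coords(fx$mean))) %*% fx$basis[, 1]
  expect_lt(abs(stats::var(as.vector(p)) - 1), 0.05)

  # different seeds: different frames, same mean within 3 standard errors
  ensA <- sampleGaussianEnsemble(fx$mean, lam, fx$basis, 4000, seed = 10)
  ensB <- sampleGaussianEnsemble(fx$mean, lam, fx$basis, 4000, seed = 11)
  expect_false(identical(coords(ensA), coords(ensB)))
  pA <- e2dyn:::.flatCoords(ensA) %*% fx$basis[, 1]
  pB <- e2dyn:::.flatCoords(ensB) %*% fx$basis[, 1]
  se <- sqrt(1 / 4000 + 1 / 4000)
  expect_lt(abs(mean(pA) - mean(pB)), 3 * se)

  # non-orthonormal basis is rejected
  bad <- fx$basis
  bad[, 1] <- bad[, 1] * 1.01
  expect_error(sampleGaussianEnsemble(fx$mean, lam, bad, 5, seed = 1),
               class = "e2dyn_invalid_argument")
})

test_that("variant families carry exact subspace ground truth", {
  spec <- spectrumSpec(decaySpectrum(8), nAtoms = 12, seed = 4)

  # no perturbation: identical subspaces
  fam0 <- makeVariantFamily(spec, list(perturbationSpec(angle = 0)),
                            nFrames = 5, seed = 1)
  expect_equal(fam0$groundTruthRmsip[2], 1, tolerance = 1e-12)

  # pure swap preserves the span but relocates the best-matching PC
  famSwap <- makeVariantFamily(spec,
                               list(perturbationSpec(angle = 0,
                                                     swapMap = list(c(1, 4)))),
                               nFrames = 5, seed = 1)
  expect_equal(famSwap$groundTruthRmsip[2], 1, tolerance = 1e-12)
  bm <- bestMatchPC(famSwap$bases[[1]][, 1], famSwap$bases[[2]], kMax = 8)
  expect_identical(bm$bestMatch, 4L)
  expect_gt(bm$bestOverlap, 0.999)

  # right-angle rotation of every mode: orthogonal essential subspaces
  fam90 <- makeVariantFamily(spec, list(perturbationSpec(angle = pi / 2)),
                             nFrames = 5, seed = 1, D = 8)
  expect_lt(fam90$groundTruthRmsip[2], 1e-10)

  # emitted ground truth equals the direct inner-product formula
  V <- fam90$bases[[1]]; W <- fam90$bases[[2]]
  direct <- sqrt(sum(crossprod(V[, 1:8], W[, 1:8])^2) / 8)
  expect_equal(fam90$groundTruthRmsip[2], direct, tolerance = 1e-12)

  expect_error(
    makeVariantFamily(spec, list(perturbationSpec(swapMap = list(c(1, 50)))),
                      nFrames = 5),
    class = "e2dyn_invalid_argument")
  expect_error(perturbationSpec(swapMap = list(c(1, 2), c(2, 3))),
               class = "e2dyn_invalid_argument")
  expect_error(perturbationSpec(angle = 2), class = "e2dyn_invalid_argument")
})

test_that("variant family ensembles are reproducible and replicate-aware", {
  spec <- spectrumSpec(decaySpectrum(4), nAtoms = 8, seed = 2)
  fam1 <- makeVariantFamily(spec, list(perturbationSpec(angle = 0.5)),
                            nFrames = 20, nReplicates = 2, seed = 9)
  fam2 <- makeVariantFamily(spec, list(perturbationSpec(angle = 0.5)),
                            nFrames = 20, nReplicates = 2, seed = 9)
  expect_identical(coords(fam1$ensembles[[2]]), coords(fam2$ensembles[[2]]))
  expect_equal(nFrames(fam1$ensembles[[1]]), 40L)
  expect_identical(unique(replicateIds(fam1$ensembles[[1]])), c(1L, 2L))
})

test_that("cosine trajectories put all variance on the chosen mode", {
  fx <- internalBasis(6, k = 1, seed = 5)
  mode <- fx$basis[, 1]
  ens <- makeCosineTrajectory(mode, amplitude = 0.2, nFrames = 1000,
                              mean = fx$mean)

  x <- e2dyn:::.flatCoords(ens)
  xc <- sweep(x, 2, colMeans(x))
  sub <- pcaDecompose(crossprod(xc) / nrow(xc))
  expect_gt(abs(sum(eigenvectors(sub)[, 1] * mode)), 0.999)

  p <- xc %*% mode
  expect_equal(cosineContent(p, 1), 1, tolerance = 1e-3)

  ens2 <- makeCosineTrajectory(mode, amplitude = 0.4, nFrames = 1000,
                               mean = fx$mean)
  x2 <- e2dyn:::.flatCoords(ens2)
  xc2 <- sweep(x2, 2, colMeans(x2))
  sub2 <- pcaDecompose(crossprod(xc2) / nrow(xc2))
  expect_equal(eigenvalues(sub2)[1] / eigenvalues(sub)[1], 4,
               tolerance = 1e-6)

  expect_error(makeCosineTrajectory(rep(0, 18), 0.1, 100),
               class = "e2dyn_invalid_argument")
  expect_error(makeCosineTrajectory(mode, 0.1, 3),
               class = "e2dyn_invalid_argument")
})

test_that("designed contact series reproduce their occupancy exactly", {
  pat <- c(rep(TRUE, 3), rep(FALSE, 7))
  ens <- makeContactSeries(pat, 0.30, 0.80)
  ser <- distanceSeries(ens, 1L, 2L, mode = "named-pair")
  expect_equal(distances(ser), ifelse(pat, 0.30, 0.80))
  expect_error(makeContactSeries(logical(0)), class = "e2dyn_invalid_argument")
  expect_error(makeContactSeries(pat, 0.8, 0.3),
               class = "e2dyn_invalid_argument")
})

test_that("homolog sets emit exact alignment ground truth", {
  hs <- makeHomologSet(2, seed = 1, nResidues = 10)
  expect_equal(length(hs$sharedColumns), 10L)

  del <- makeHomologSet(2, indelSpec = list(NULL, list(deletions = 5L)),
                        seed = 1, nResidues = 10)
  expect_false(5L %in% del$sharedColumns)
  expect_equal(length(del$sharedColumns), 9L)

  ins <- makeHomologSet(3, indelSpec = list(list(insertions = 4L), NULL, NULL),
                        seed = 1, nResidues = 10)
  expect_equal(msaWidth(ins$msa), 11L)
  expect_equal(length(ins$sharedColumns), 10L)  # common core unchanged
  # the non-owner rows carry a gap in the inserted column
  inserted <- setdiff(seq_len(11L), ins$sharedColumns)
  expect_equal(ins$msa@ali["sys2", inserted], "-", ignore_attr = TRUE)

  expect_error(
    makeHomologSet(2, indelSpec = list(NULL, list(deletions = 1:9)),
                   seed = 1, nResidues = 10),
    class = "e2dyn_invalid_argument")
})
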