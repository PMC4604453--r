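test_that("Kabsch superposition recovers exact transforms", {
  a <- coords(makeToyStructure(10, seed = 1))

  # identical sets: zero rmsd, identity rotation
  fit <- kabschSuperpose(a, a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)

  # a known rigid motion is inverted exactly
  set.seed(42)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  b <- a %*% rot + rep(c(1, -2, 0.5), each = nrow(a))
  fit2 <- kabschSuperpose(a, b)
  expect_lt(max(abs(fit2$rotation - rot)), 1e-8)
  expect_lt(fit2$rmsd, 1e-10)
  expect_lt(max(abs(e2dyn:::.applyFit(a, fit2) - b)), 1e-8)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-10)

  expect_error(kabschSuperpose(a[1:2, ], a[1:2, ]),
               class = "e2dyn_invalid_argument")
  expect_error(kabschSuperpose(a, a, weights = rep(0, nrow(a))),
               class = "e2dyn_invalid_argument")
})

test_that("Kabsch rmsd matches the bio3d fitting oracle", {
  set.seed(7)
  a <- matrix(rnorm(150), ncol = 3)
  b <- matrix(rnorm(150), ncol = 3)
  fit <- kabschSuperpose(a, b)

  oracle <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(b)), mobile = as.vector(t(a))))
  oracleRmsd <- sqrt(mean(rowSums((matrix(oracle, ncol = 3, byrow = TRUE) -
                                     b)^2)))
  expect_equal(fit$rmsd, oracleRmsd, tolerance = 1e-6)
})

test_that("covariance construction satisfies its algebraic identities", {
  fx <- internalBasis(8, k = 4, seed = 6)
  lam <- decaySpectrum(4, lambda1 = 0.05)

  # identical frames: zero matrix
  still <- TrajectoryEnsemble(
    matrix(rep(e2dyn:::.flatten(coords(fx$mean)), 5), nrow = 5, byrow = TRUE),
    topology = fx$mean)
  cv0 <- buildCovariance(still)
  expect_lt(max(abs(cv0$covariance)), 1e-24)

  # trace identity: tr(C) = sum |dx|^2 / T about the iterated mean, with
  # frames fitted exactly as the two-pass procedure prescribes
  ens <- sampleGaussianEnsemble(fx$mean, lam, fx$basis, 200, seed = 3)
  cv <- buildCovariance(ens)
  flat <- e2dyn:::.flatCoords(ens)
  fitted <- e2dyn:::.superposeFlat(flat, flat[1, ])
  fitted <- e2dyn:::.superposeFlat(flat, colMeans(fitted))
  msf <- sum(sweep(fitted, 2, colMeans(fitted))^2) / nrow(fitted)
  expect_equal(sum(diag(cv$covariance)), msf, tolerance = 1e-10)
  expect_equal(colMeans(fitted), cv$mean, tolerance = 1e-12)

  # uniform (Calpha-only) mass weighting rescales by the carbon mass
  cvm <- buildCovariance(ens, massWeighting = TRUE)
  expect_equal(cvm$covariance, cv$covariance * 12.011, tolerance = 1e-10)

  expect_error(buildCovariance(ens[1, ]), class = "e2dyn_invalid_argument")
})

test_that("eigendecomposition honours ordering, signs and reconstruction", {
  # identity covariance: unit eigenvalues, equal variance fractions
  subI <- pcaDecompose(diag(6))
  expect_equal(eigenvalues(subI), rep(1, 6))
  expect_equal(varianceFractions(subI), rep(1 / 6, 6))

  # rank-1: lambda1 = |v|^2, the rest zero
  v <- c(3, 0, 0, 4, 0, 0)
  sub1 <- pcaDecompose(v %*% t(v))
  expect_equal(eigenvalues(sub1)[1], 25, tolerance = 1e-10)
  expect_equal(eigenvalues(sub1)[-1], rep(0, 5), tolerance = 1e-10)
  expect_equal(varianceExplained(sub1, 1), 1)

  # spectral reconstruction
  set.seed(8)
  m <- matrix(rnorm(100), 10)
  covar <- crossprod(m) / 10
  sub <- pcaDecompose(covar)
  rec <- eigenvectors(sub) %*% diag(eigenvalues(sub)) %*% t(eigenvectors(sub))
  expect_lt(max(abs(rec - covar)), 1e-8)

  # deterministic sign convention
  expect_true(all(apply(eigenvectors(sub), 2, function(col) {
    col[which.max(abs(col))] > 0
  })))

  asym <- covar
  asym[1, 2] <- asym[1, 2] + 1e-4
  expect_error(pcaDecompose(asym), class = "e2dyn_invalid_argument")
})

test_that("essential dynamics agrees with the bio3d PCA oracle", {
  fx <- internalBasis(8, k = 6, seed = 9)
  ens <- sampleGaussianEnsemble(fx$mean, decaySpectrum(6, 0.05), fx$basis,
                                300, seed = 12)
  cv <- buildCovariance(ens)
  sub <- pcaDecompose(cv)

  # feed bio3d the same fitted frames; it divides by n-1, we divide by n
  flat <- e2dyn:::.flatCoords(ens)
  fitted <- e2dyn:::.superposeFlat(flat, flat[1, ])
  fitted <- e2dyn:::.superposeFlat(flat, colMeans(fitted))
  oracle <- bio3d::pca.xyz(fitted)
  n <- nrow(fitted)
  k <- 6
  expect_equal(eigenvalues(sub)[1:k], oracle$L[1:k] * (n - 1) / n,
               tolerance = 1e-8)
  for (i in 1:k) {
    expect_gt(abs(sum(eigenvectors(sub)[, i] * oracle$U[, i])), 0.9999)
  }
})

test_that("projections reproduce the spectrum and vanish at the mean", {
  fx <- internalBasis(10, k = 5, seed = 10)
  lam <- decaySpectrum(5, 0.05)
  ens <- sampleGaussianEnsemble(fx$mean, lam, fx$basis, 2000, seed = 13)
  sub <- essentialDynamics(ens)

  p <- projectOnto(ens, sub, k = 5)
  sampleVar <- apply(p, 2, function(col) mean(col^2) - mean(col)^2)
  # the projection refits frames onto the final mean, so the identity with
  # the eigenvalues holds to the two-pass fitting residual, not exactly
  expect_lt(max(abs(sampleVar - eigenvalues(sub)[1:5]) /
                  eigenvalues(sub)[1:5]), 1e-3)
  expect_lt(max(abs(sampleVar - lam) / lam), 0.15)

  meanEns <- TrajectoryEnsemble(matrix(meanCoords(sub), 1), nAtoms = 10)
  expect_lt(max(abs(projectOnto(meanEns, sub, k = 3))), 1e-10)

  expect_identical(ncol(projectOnto(ens, sub, k = 0)), 0L)
  expect_error(projectOnto(ens[, 1:4], sub, k = 2),
               class = "e2dyn_consistency_error")
})

test_that("eigenvalues are invariant under rigid motion of all frames", {
  fx <- internalBasis(9, k = 4, seed = 11)
  ens <- sampleGaussianEnsemble(fx$mean, decaySpectrum(4, 0.05), fx$basis,
                                150, seed = 14)
  sub <- essentialDynamics(ens)

  set.seed(15)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  a <- coords(ens)
  for (f in seq_len(dim(a)[1])) {
    a[f, , ] <- a[f, , ] %*% rot + rep(c(0.4, -1, 2), each = dim(a)[2])
  }
  subRot <- essentialDynamics(TrajectoryEnsemble(a, topology = topology(ens)))
  lam <- eigenvalues(sub)[1:4]
  expect_lt(max(abs(eigenvalues(subRot)[1:4] - lam) / lam), 1e-8)
})

test_that("variance explained follows the cumulative spectrum", {
  covar <- diag(c(4, 3, 2, 1))
  sub <- pcaDecompose(covar)
  expect_equal(varianceExplained(sub, 2), 0.7)
  expect_equal(varianceExplained(sub, 4), 1.0)
  expect_error(varianceExplained(sub, 0), class = "e2dyn_invalid_argument")
  expect_error(varianceExplained(sub, 5), class = "e2dyn_invalid_argument")
})
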