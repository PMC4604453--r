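test_that("macro-trajectory assembly trims replicates and keeps provenance", {
  fx <- internalBasis(6, k = 3, seed = 1)
  lam <- decaySpectrum(3, 0.02)
  reps <- lapply(1:2, function(r) {
    sampleGaussianEnsemble(fx$mean, lam, fx$basis, 100, seed = r,
                           replicate = r)
  })

  macro <- preprocessMacroTrajectory(reps, trim = 10)
  expect_equal(nFrames(macro), 180L)
  expect_identical(replicateIds(macro), rep(1:2, each = 90L))
  # frames are the post-trim frames of each replicate, in order
  expect_equal(coords(macro)[1, , ], coords(reps[[1]])[11, , ])
  expect_equal(coords(macro)[91, , ], coords(reps[[2]])[11, , ])

  expect_equal(nFrames(preprocessMacroTrajectory(reps, trim = 0)), 200L)
  # fractional trim: 10% of each replicate
  expect_equal(nFrames(preprocessMacroTrajectory(reps, trim = 0.1)), 180L)

  # a single ensemble with replicate ids is split on those ids
  joined <- preprocessMacroTrajectory(macro, trim = 40)
  expect_equal(nFrames(joined), 100L)

  err <- tryCatch(preprocessMacroTrajectory(reps, trim = 100), error = identity)
  expect_s3_class(err, "e2dyn_invalid_argument")
  expect_match(conditionMessage(err), "replicate 1")
})

test_that("Shrake-Rupley SASA matches analytic spheres", {
  oneAtom <- function(el) {
    Structure(data.frame(serial = 1L, elety = el, element = el,
                         resid = "X", resno = 1L, chain = "A"),
              matrix(0, 1, 3))
  }
  probe <- 0.14
  for (el in c("C", "O", "S")) {
    r <- e2dyn:::.vdwRadii[[el]] + probe
    a960 <- sasaShrakeRupley(oneAtom(el), 1L, nPoints = 960)
    expect_lt(abs(a960 - 4 * pi * r^2) / (4 * pi * r^2), 0.02)
    a3840 <- sasaShrakeRupley(oneAtom(el), 1L, nPoints = 3840)
    expect_lt(abs(a3840 - 4 * pi * r^2) / (4 * pi * r^2), 0.01)
  }

  two <- function(sep) {
    Structure(data.frame(serial = 1:2, elety = "C", element = "C",
                         resid = "X", resno = 1:2, chain = "A"),
              rbind(c(0, 0, 0), c(sep, 0, 0)))
  }
  rExt <- e2dyn:::.vdwRadii[["C"]] + probe
  full <- 4 * pi * rExt^2

  # coincident atoms: complete burial
  expect_lt(sasaShrakeRupley(two(0), 1L), 1e-6)
  # beyond 2(r+probe): no occlusion, both atoms fully exposed
  far <- sasaShrakeRupley(two(2 * rExt + 0.01), 1:2)
  expect_lt(abs(far - 2 * full) / (2 * full), 0.02)

  # approach is monotone within point-sampling noise
  seps <- seq(2 * rExt, 0, length.out = 9)
  areas <- vapply(seps, function(s) sasaShrakeRupley(two(s), 1L), numeric(1))
  expect_true(all(diff(areas) <= 0.02 * full))
  expect_lt(areas[length(areas)], 1e-6)

  bad <- Structure(data.frame(serial = 1L, elety = "ZZ", element = "ZZ",
                              resid = "X", resno = 1L, chain = "A"),
                   matrix(0, 1, 3))
  err <- tryCatch(sasaShrakeRupley(bad, 1L), error = identity)
  expect_s3_class(err, "e2dyn_configuration_error")
  expect_match(conditionMessage(err), "ZZ")
  expect_error(sasaShrakeRupley(two(1), integer()),
               class = "e2dyn_invalid_argument")
})

test_that("per-replicate SASA summaries aggregate frame values", {
  pat <- c(TRUE, TRUE, FALSE, FALSE)
  ens <- makeContactSeries(pat, 0.2, 5)  # far apart = both exposed
  ens@replicate <- c(1L, 1L, 2L, 2L)
  res <- sasaSeries(ens, 1L, nPoints = 240)
  expect_equal(nrow(res$perFrame), 4L)
  expect_equal(res$byReplicate$n, c(2, 2))
  # bound frames occlude, unbound frames do not
  expect_lt(res$byReplicate$mean[1], res$byReplicate$mean[2])
})

test_that("distance series match a brute-force pairwise oracle", {
  st <- makeToyStructure(6, seed = 2)
  fx <- internalBasis(12, k = 4, seed = 2)
  ens <- sampleGaussianEnsemble(st, decaySpectrum(4, 0.01),
                                randomOrthonormalBasis(36, 4, seed = 3),
                                nFrames = 25, seed = 4)
  groupA <- selectAtoms(st, resno = 1)      # CA + CB of residue 1
  groupB <- selectAtoms(st, resno = c(4, 5))
  ser <- distanceSeries(ens, groupA, groupB, mode = "min-heavy")

  a <- coords(ens)
  oracle <- vapply(seq_len(25), function(f) {
    min(apply(expand.grid(groupA, groupB), 1, function(p) {
      sqrt(sum((a[f, p[1], ] - a[f, p[2], ])^2))
    }))
  }, numeric(1))
  expect_equal(distances(ser), oracle, tolerance = 1e-12)

  # fixed two-atom geometry gives a constant series
  fixed <- makeContactSeries(rep(TRUE, 10), 0.35, 0.9)
  expect_equal(distances(distanceSeries(fixed, 1L, 2L, "named-pair")),
               rep(0.35, 10))

  # distances are invariant under rigid motion of every frame
  set.seed(5)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  b <- a
  for (f in seq_len(dim(b)[1])) {
    b[f, , ] <- b[f, , ] %*% rot + rep(c(1, 2, 3), each = dim(b)[2])
  }
  serRot <- distanceSeries(TrajectoryEnsemble(b, topology = st),
                           groupA, groupB, mode = "min-heavy")
  expect_lt(max(abs(distances(serRot) - distances(ser))), 1e-10)

  expect_error(distanceSeries(ens, groupA, groupA),
               class = "e2dyn_selection_error")
  expect_error(distanceSeries(ens, integer(), groupB),
               class = "e2dyn_selection_error")
  expect_error(distanceSeries(ens, groupA, groupB, mode = "named-pair"),
               class = "e2dyn_selection_error")
})

test_that("contact persistence reproduces designed occupancies", {
  pat <- c(rep(TRUE, 3), rep(FALSE, 7))
  ser <- distanceSeries(makeContactSeries(pat, 0.30, 0.80), 1L, 2L,
                        "named-pair")
  expect_equal(persistence(contactPersistence(ser, cutoff = 0.48)), 0.3)

  # the ion pair seen in every frame / in no frame
  expect_equal(persistence(contactPersistence(rep(0.38, 50), 0.48)), 1.0)
  expect_equal(persistence(contactPersistence(rep(0.70, 50), 0.48)), 0.0)

  # frame reordering leaves persistence unchanged
  set.seed(6)
  shuffled <- sample(distances(ser))
  expect_equal(persistence(contactPersistence(shuffled, 0.48)), 0.3)

  expect_error(contactPersistence(ser, cutoff = 0),
               class = "e2dyn_invalid_argument")
})

test_that("hydrogen-bond criterion gates contacts on geometry", {
  # donor N, hydrogen H on the N-A axis, acceptor O: ideal 180 degree bond
  mk <- function(hShift) {
    at <- data.frame(serial = 1:3, elety = c("N", "H", "O"),
                     element = c("N", "H", "O"), resid = "X",
                     resno = c(1L, 1L, 2L), chain = "A")
    xyz <- rbind(c(0, 0, 0), c(0.1, hShift, 0), c(0.3, 0, 0))
    TrajectoryEnsemble(matrix(as.vector(t(xyz)), 1),
                       topology = Structure(at, xyz))
  }
  lin <- mk(0)
  serL <- distanceSeries(lin, 1L, 3L, "named-pair")
  okL <- contactPersistence(serL, cutoff = 0.48,
                            hbond = list(ensemble = lin, donor = 1L,
                                         hydrogen = 2L, acceptor = 3L))
  expect_equal(persistence(okL), 1.0)

  # bent far past the 120 degree threshold: rejected
  bent <- mk(0.4)
  serB <- distanceSeries(bent, 1L, 3L, "named-pair")
  okB <- contactPersistence(serB, cutoff = 0.48,
                            hbond = list(ensemble = bent, donor = 1L,
                                         hydrogen = 2L, acceptor = 3L))
  expect_equal(persistence(okB), 0.0)

  expect_error(
    contactPersistence(serL, cutoff = 0.48,
                       hbond = list(ensemble = lin, donor = 1L,
                                    acceptor = 3L)),
    class = "e2dyn_configuration_error")
})
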