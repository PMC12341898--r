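refPlan <- function(nu = 6.9e-7, Nd = 1e10, d1 = 0.5)
    treatmentPlan(bs1 = 1, ds1 = d1, m = 1, nu = nu, detectionSize = Nd)

test_that("neutral clone size distribution collapses onto the SFS form", {
    plan <- treatmentPlan(bs1 = 1, ds1 = 0, m = 1, nu = 0.01,
                          detectionSize = 1000)
    expect_equal(csdDetection(c(1, 5), plan),
                 2 * 0.01 * 1000 / c(1 * 2, 5 * 6))
    # nu = 0: no clones
    plan0 <- treatmentPlan(bs1 = 1, ds1 = 0, m = 1, nu = 0,
                           detectionSize = 1000)
    expect_equal(csdDetection(1:3, plan0), rep(0, 3))
    # neutral-case equivalence csd/nu = sfs/m at identical rates
    planD <- treatmentPlan(bs1 = 1, ds1 = 0.4, m = 2, nu = 1e-4,
                           detectionSize = 5e4)
    expect_equal(csdDetection(c(2, 10, 40), planD) / 1e-4,
                 sfsDetection(c(2, 10, 40), 1, ratePair(1, 0.4), 5e4),
                 tolerance = 1e-6)
})

test_that("non-neutral clone quadrature matches the neutral closed form", {
    # quadrature with equal rates must agree with the series (large Nd)
    plan <- treatmentPlan(bs1 = 1, ds1 = 0.3, br1 = 1, dr1 = 0.3, m = 1,
                          nu = 1e-5, detectionSize = 1e6)
    neutral <- csdDetection(c(1, 4, 12), plan)
    # force the quadrature path by a microscopic rate perturbation
    planP <- treatmentPlan(bs1 = 1, ds1 = 0.3, br1 = 1 + 1e-9, dr1 = 0.3,
                           m = 1, nu = 1e-5, detectionSize = 1e6)
    quad <- csdDetection(c(1, 4, 12), planP)
    expect_equal(quad, neutral, tolerance = 0.02)
})

test_that("simulated clone ensembles track the detection CSD", {
    plan <- treatmentPlan(bs1 = 1, ds1 = 0.2, m = 0, nu = 0.002,
                          detectionSize = 5000)
    ens <- runEnsemble(plan, 150, baseSeed = 13)
    mat <- ensembleSpectra(ens, csdFromTree, 5000)
    mbar <- rowMeans(mat); sdev <- apply(mat, 1, sd)
    th <- csdDetection(1:8, plan)
    # ensemble means inside the 1-sigma band of realizations
    expect_true(all(abs(mbar[1:8] - th) <= sdev[1:8]))
})

test_that("CSD after treatment has the right limits", {
    plan <- treatmentPlan(bs1 = 1, ds1 = 0, bs2 = 0.1, ds2 = 1,
                          br2 = 1, dr2 = 0.1, m = 1, nu = 1e-4,
                          detectionSize = 1e4, treatmentDuration = 2)
    # tf = 0 reproduces the detection CSD
    expect_equal(csdAfterTreatment(c(1, 3, 9), plan, "pre", tf = 0),
                 csdDetection(c(1, 3, 9), plan))
    # dying sensitive source: the new-clone influx integral vanishes
    planDead <- treatmentPlan(bs1 = 1, ds1 = 0, bs2 = 0.01, ds2 = 3,
                              br2 = 1, dr2 = 0.1, m = 1, nu = 1e-4,
                              detectionSize = 1e4, treatmentDuration = 2)
    newp <- csdAfterTreatment(1:3, planDead, "new")
    expect_lt(sum(newp), 0.05 * sum(csdAfterTreatment(1:3, planDead,
                                                      "pre")))
    # total = new + pre
    expect_equal(csdAfterTreatment(c(2, 6), plan, "total"),
                 csdAfterTreatment(c(2, 6), plan, "new") +
                     csdAfterTreatment(c(2, 6), plan, "pre"))
})

test_that("clone-ordering samples are deterministic and well-formed", {
    plan <- refPlan()
    s1 <- sampleCloneOrdering(plan, 500, seed = 9)
    s2 <- sampleCloneOrdering(plan, 500, seed = 9)
    expect_identical(s1, s2)
    expect_true(all(s1$T1 <= s1$T2))
    expect_true(all(s1$V1 > 0 & s1$V2 > 0))
    expect_equal(s1$delta, s1$size1 - s1$size2)
    expect_warning(sampleCloneOrdering(
        treatmentPlan(bs1 = 1, ds1 = 0, m = 1, nu = 1e-9,
                      detectionSize = 1e6), 10, seed = 1), "small")
})

test_that("drift lets the second clone overtake in about a third of cases", {
    s <- sampleCloneOrdering(refPlan(), 4e4, seed = 101)
    fracNeg <- mean(s$delta < 0)
    expect_lt(abs(fracNeg - 1 / 3), 0.05)
    # simulator cross-check at matched small-scale parameters
    planSim <- treatmentPlan(bs1 = 1, ds1 = 0, m = 0, nu = 0.01,
                             detectionSize = 1000)
    ens <- runEnsemble(planSim, 400, baseSeed = 6)
    over <- vapply(ens, function(r) {
        cl <- csdFromTree(r@tree)@clones
        if (nrow(cl) >= 2) cl$size[2] > cl$size[1] else NA
    }, logical(1))
    fracSim <- mean(over, na.rm = TRUE)
    fracSampler <- mean(sampleCloneOrdering(planSim, 4e4,
                                            seed = 7)$delta < 0)
    nEff <- sum(!is.na(over))
    se <- sqrt(fracSim * (1 - fracSim) / nEff)
    expect_lt(abs(fracSim - fracSampler), 3 * se)
})

test_that("largest-clone law has exact mass, median and simulated shape", {
    # the density telescopes to one (substitute u = 1/kappa)
    expect_equal(integrate(function(u) {
        k <- 1 / u
        largestClone(3, k, "density") * k^2
    }, 0, 1)$value, 1, tolerance = 1e-8)
    expect_equal(largestClone(1, query = "median"), 2)
    expect_equal(largestClone(5, 1e9, "cdf"), 1, tolerance = 1e-7)
    expect_error(largestClone(2, 0.5, "density"), "kappa")
    # simulated maxima against the closed-form CDF
    plan <- treatmentPlan(bs1 = 1, ds1 = 0, m = 0, nu = 0.01,
                          detectionSize = 1000)
    mx <- vapply(runEnsemble(plan, 300, baseSeed = 15), function(r)
        max(csdFromTree(r@tree)@clones$size), numeric(1))
    A <- largestCloneA(plan)
    ks <- suppressWarnings(
        ks.test(mx, function(q) largestClone(A, pmax(q, 1), "cdf")))
    expect_lt(unname(ks$statistic), 0.1)
})

test_that("Landau density is normalized with a 1/x^2 tail", {
    expect_equal(integrate(dlandau, -7, 60)$value +
                     integrate(function(x) dlandau(x), 60, Inf)$value,
                 1, tolerance = 1e-4)
    expect_equal(qlandau(0.5), 1.35578, tolerance = 1e-4)
    expect_equal(1e4^2 * dlandau(1e4), 1, tolerance = 0.01)
    expect_gt(dlandau(-0.22), dlandau(1))  # unimodal around the mode
    expect_equal(dlandau(-10), 0)
})

test_that("largest clone is subdominant to the resistant total", {
    plan <- refPlan()
    kmed <- largestClone(largestCloneA(plan), query = "median")
    Rmed <- resistantTotalDistribution(plan, query = "median")
    expect_lt(kmed, Rmed)
    # largest-clone median fraction is nearly invariant in Nd over 100x
    f1 <- largestClone(largestCloneA(refPlan(Nd = 1e8)),
                       query = "median") / 1e8
    f2 <- largestClone(largestCloneA(refPlan(Nd = 1e10)),
                       query = "median") / 1e10
    expect_equal(f1, f2, tolerance = 0.01)
    # resistant-total median fraction weakly increases with Nd
    r1 <- resistantTotalDistribution(refPlan(Nd = 1e8),
                                     query = "median") / 1e8
    r2 <- resistantTotalDistribution(refPlan(Nd = 1e10),
                                     query = "median") / 1e10
    expect_gt(r2, r1)
    expect_lt(r2 / r1, 2)
    # the scaled density integrates to one over R
    p <- integrate(function(R) resistantTotalDistribution(plan, R),
                   0, 5e7)$value
    expect_equal(p, 1, tolerance = 0.05)
})

test_that("costly resistance pulls the first two clone sizes together", {
    # cost enters through the resistant growth rate before treatment:
    # slower clones forget their arrival-order advantage
    ratios <- vapply(c(0, 0.2, 0.4), function(cost) {
        plan <- treatmentPlan(bs1 = 1, ds1 = 0, br1 = 1 - cost, dr1 = 0,
                              m = 0, nu = 0.01, detectionSize = 800)
        ens <- runEnsemble(plan, 250, baseSeed = 33)
        sz <- vapply(ens, function(r) {
            cl <- csdFromTree(r@tree)@clones
            if (nrow(cl) >= 2) c(cl$size[1], cl$size[2]) else c(NA, NA)
        }, numeric(2))
        stats::median(sz[1, ], na.rm = TRUE) /
            stats::median(sz[2, ], na.rm = TRUE)
    }, numeric(1))
    expect_true(all(diff(ratios) < 0))
    expect_gt(ratios[1], ratios[3] + 0.2)
})

test_that("compound resistant spectrum matches eradicated-sensitive trees", {
    plan <- treatmentPlan(bs1 = 1, ds1 = 0, br1 = 1, dr1 = 0, bs2 = 0,
                          ds2 = 1, br2 = 1, dr2 = 0, m = 1, nu = 0.005,
                          detectionSize = 500, treatmentDuration = 6)
    ens <- runEnsemble(plan, 100, baseSeed = 21,
                       conditionOnFinalSurvival = TRUE)
    Nr <- mean(vapply(ens, function(r)
        sum(r@tree@alive & r@tree@type == 1L), numeric(1)))
    mat <- ensembleSpectra(ens, sfsFromTree, 2000)
    mbar <- rowMeans(mat); sdev <- apply(mat, 1, sd)
    th <- compoundResistantSFS(1:20, 1, ratePair(1, 0), Nr)
    expect_true(all(abs(mbar[1:20] - th) <= pmax(sdev[1:20],
                                                 3 * sdev[1:20] /
                                                     sqrt(100))))
    # identical formula to the detection SFS at the resistant size
    expect_equal(compoundResistantSFS(1:5, 2, ratePair(1, 0.3), 1e4),
                 sfsDetection(1:5, 2, ratePair(1, 0.3), 1e4))
})

test_that("subset-sum peaks are predicted, merged and tree-extracted", {
    # single clone
    p1 <- predictSfsPeaks(500, list(list(clones = 1, count = 3)))
    expect_equal(p1$k, 500); expect_equal(p1$height, 3)
    # two clones with shared ancestry
    p2 <- predictSfsPeaks(c(300, 200), list(
        list(clones = 1, count = 7), list(clones = 2, count = 4),
        list(clones = c(1, 2), count = 5)))
    expect_equal(p2$k, c(200, 300, 500))
    expect_equal(p2$height, c(4, 7, 5))
    # colliding subset sums merge
    p3 <- predictSfsPeaks(c(100, 100), list(
        list(clones = 1, count = 1), list(clones = 2, count = 2)))
    expect_equal(p3$k, 100); expect_equal(p3$height, 3)
    expect_error(predictSfsPeaks(rep(1, 16), list()), "K > 15")
    # tree-extracted shared counts land on subset sums of the clone sizes
    plan <- treatmentPlan(bs1 = 1, ds1 = 0, br1 = 1, dr1 = 0, bs2 = 0,
                          ds2 = 2, br2 = 1, dr2 = 0, m = 2, nu = 0.01,
                          detectionSize = 120, treatmentDuration = 5)
    res <- simulateTumor(plan, seed = 12, conditionOnFinalSurvival = TRUE)
    sh <- cloneSharedCounts(res@tree)
    expect_gt(nrow(sh$clones), 0)
    pk <- predictSfsPeaks(sh$clones$size, sh$shared)
    s <- sfsFromTree(res@tree)
    # every predicted peak mass is present in the realized spectrum
    for (i in seq_len(nrow(pk)))
        expect_gte(spectrumCounts(s)[pk$k[i]], pk$height[i])
})

test_that("scMB mixtures overlay sensitive and resistant peaks", {
    sens <- scmbFromDivisional(divisionalMeanfield(1, 5, N = 1000), m = 2)
    clones <- data.frame(size = c(400, 100), lambda = c(40, 40))
    mix <- scmbMixture(clones, m = 2, sensitive = sens)
    expect_equal(sum(spectrumCounts(mix)), 1500, tolerance = 1e-4)
    # equal clone rates merge into one resistant peak beside the
    # sensitive peak at j = 2 * 10 = 20; resistant peak near 2 * 40 = 80
    M <- spectrumCounts(mix)
    expect_gt(M[21], M[51])
    expect_gt(M[81], M[51])
    # zero resistant cells reduces to the homogeneous distribution
    mix0 <- scmbMixture(data.frame(size = numeric(0),
                                   lambda = numeric(0)), m = 2,
                        sensitive = sens, jmax = 200)
    nS <- length(spectrumCounts(sens))
    expect_equal(spectrumCounts(mix0)[1:nS], spectrumCounts(sens))
})
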