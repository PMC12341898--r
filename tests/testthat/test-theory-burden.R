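test_that("detection SFS matches closed-form evaluations", {
    # d = 0 reduces to 2 m Nd / (k(k+1))
    expect_equal(sfsDetection(1, 1, ratePair(1, 0), 100), 100)
    expect_equal(sfsDetection(1:5, 2, ratePair(1, 0), 100),
                 2 * 2 * 100 / ((1:5) * (2:6)))
    # d/b = 1/2 series sums to 2(1 + log(1/2)) at k = 1, times 2 m Nd
    expect_equal(sfsDetection(1, 1, ratePair(1, 0.5), 1),
                 2 * 2 * (1 + log(0.5)), tolerance = 1e-10)
    # exponent-2 power law in the far tail
    r <- sfsDetection(2000, 1, ratePair(1, 0.3), 1e4) /
        sfsDetection(1000, 1, ratePair(1, 0.3), 1e4)
    expect_equal(r, 0.25, tolerance = 0.005)
    # integral, series and tail modes agree where they should
    expect_equal(sfsDetection(7, 1, ratePair(1, 0.5), 1e4,
                              mode = "integral"),
                 sfsDetection(7, 1, ratePair(1, 0.5), 1e4),
                 tolerance = 1e-6)
    expect_equal(sfsDetection(500, 1, ratePair(1, 0.5), 1e4,
                              mode = "tail"),
                 sfsDetection(500, 1, ratePair(1, 0.5), 1e4),
                 tolerance = 1e-2)
    expect_error(sfsDetection(1, 1, ratePair(1, 1), 100), "supercritical")
})

test_that("new-mutation SFS quadrature matches the constant-population form", {
    k <- c(1, 2, 5, 10, 25)
    quad <- sfsNewGeneral(k, 1, ratePair(1, 1), tf = 3, N0 = 1000,
                          conditionOnSurvival = FALSE)
    closed <- sfsConstantNew(k, 1, 1, 3, 1000)
    expect_equal(quad, closed, tolerance = 1e-3)
    # no elapsed time or no births: nothing new
    expect_equal(sfsNewGeneral(k, 1, ratePair(1, 1), 0, 100), rep(0, 5))
    expect_equal(sfsNewGeneral(k, 1, ratePair(0, 1), 2, 100), rep(0, 5))
})

test_that("preexisting SFS mapping reduces to identity and pure death", {
    init <- sfsDetection(1:2000, 1, ratePair(1, 0.2), 2000)
    expect_equal(sfsPreGeneral(c(1, 7), init, ratePair(0, 1), 0), init[c(1, 7)])
    # pure-death mapping approaches the closed form as k grows
    pre <- sfsPreGeneral(c(20, 50), init, ratePair(0, 1), tf = log(2),
                         N0 = 2000)
    pd <- sfsPureDeath(c(20, 50), 1, ratePair(1, 0.2), 1000)
    expect_equal(pre[1], pd[1], tolerance = 0.05)
    expect_equal(pre[2], pd[2], tolerance = 0.05)
    # the k^-2 tail is maintained through pure-death treatment
    expect_equal(sfsPureDeath(400, 1, ratePair(1, 0.2), 1e3) /
                 sfsPureDeath(200, 1, ratePair(1, 0.2), 1e3),
                 0.25, tolerance = 0.01)
})

test_that("ensemble-mean spectra stay inside the 1-sigma bands", {
    # growth to detection (Fig 2a regime at desk scale)
    plan <- treatmentPlan(bs1 = 1, ds1 = 0.2, m = 1, detectionSize = 1000)
    ens <- runEnsemble(plan, 150, baseSeed = 11)
    mat <- ensembleSpectra(ens, sfsFromTree, 1000)
    mbar <- rowMeans(mat); sdev <- apply(mat, 1, sd)
    th <- sfsDetection(1:30, 1, ratePair(1, 0.2), 1000)
    expect_true(all(abs(mbar[1:30] - th) <= pmax(sdev[1:30],
                                                 3 * sdev[1:30] /
                                                     sqrt(150))))
    # E[S_k] = m E[W_k] (regression slope is m within 5%)
    wbar <- rowMeans(vapply(ens, function(r) {
        w <- sfsFromTree(r@tree)@widths
        length(w) <- 1000; w[is.na(w)] <- 0; w
    }, numeric(1000)))
    slope <- sum(mbar[1:100] * wbar[1:100]) / sum(wbar[1:100]^2)
    expect_equal(slope, 1, tolerance = 0.05)
})

test_that("treated-population mean spectra match Theorem-1 predictions", {
    # constant disease (Fig 2e regime at desk scale): new + pre components
    plan <- treatmentPlan(bs1 = 1, ds1 = 0, bs2 = 1, ds2 = 1, m = 1,
                          detectionSize = 300, treatmentDuration = 2)
    ens <- runEnsemble(plan, 150, baseSeed = 23,
                       conditionOnFinalSurvival = TRUE)
    mat <- ensembleSpectra(ens, sfsFromTree, 600)
    mbar <- rowMeans(mat); sdev <- apply(mat, 1, sd)
    k <- 1:25
    init <- sfsDetection(1:300, 1, ratePair(1, 0), 300)
    th <- sfsNewGeneral(k, 1, ratePair(1, 1), 2, 300) +
        sfsPreGeneral(k, init, ratePair(1, 1), 2)
    expect_true(all(abs(mbar[k] - th) <= pmax(sdev[k],
                                              3 * sdev[k] / sqrt(150))))
})

test_that("burden closed forms match their limits and each other", {
    expect_equal(tmbDetection(1, ratePair(1, 1e-12), 1e3, mode = "limit"),
                 2000)
    expect_equal(tmbDetection(1, ratePair(1, 0.5), 1e3, mode = "limit"),
                 2 * 1e3 * 2 * log(2))
    # full finite-Nd form approaches the limit for large Nd
    expect_equal(tmbDetection(1, ratePair(1, 0.5), 1e6),
                 tmbDetection(1, ratePair(1, 0.5), 1e6, mode = "limit"),
                 tolerance = 1e-3)
    # measured at equal size, more death means more burden
    tm <- vapply(c(0, 0.3, 0.6, 0.9), function(d)
        tmbDetection(1, ratePair(1, d), 1e3, mode = "limit"), numeric(1))
    expect_true(all(diff(tm) > 0))
    # constant-population new burden and the series identity with Eq-13
    expect_equal(tmbNewAfter(1, ratePair(1, 1), 1e3, 1e3, 9),
                 2000 * log(10))
    expect_equal(sum(sfsConstantNew(1:200000, 1, 1, 9, 1e3)),
                 tmbNewAfter(1, ratePair(1, 1), 1e3, 1e3, 9),
                 tolerance = 1e-6)
    # general Nd' = 1 reduces to the detection formula
    td <- firstPassageMean(ratePair(1, 0.5), 1e3)
    expect_equal(tmbNewAfter(1, ratePair(1, 0.5), 1, 1e3, td),
                 tmbDetection(1, ratePair(1, 0.5), 1e3))
    expect_equal(tmbNewAfter(1, ratePair(0, 1), 1e3, 1e2, 3), 0)
})

test_that("preexisting-burden heuristic has the right limits and accuracy", {
    expect_equal(tmbPreAfter(100, 0.5), 100 * log(2))
    expect_equal(tmbPreAfter(100, 1e-12), 100, tolerance = 1e-6)
    expect_error(tmbPreAfter(100, 1), "alpha")
    # exact identity for d1 = 0: the k^-2 spectrum telescopes onto the
    # closed form, sum_k (1 - a^k) / (k(k+1)) = (1-a)/a log(1/(1-a))
    init0 <- sfsDetection(1:20000, 1, ratePair(1, 0), 20000)
    for (tf in c(0.5, 1.5)) {
        alpha <- extinctionProbability(ratePair(0.4, 1), tf)
        exact <- tmbGeneral("pre", rates = ratePair(0.4, 1), tf = tf,
                            N0 = 20000, initialSFS = init0,
                            conditionOnSurvival = FALSE)
        expect_equal(tmbPreAfter(sum(init0), alpha), exact,
                     tolerance = 1e-4)
    }
    # heuristic extension to d1 > 0: within 10% of the exact sum
    for (d1 in c(0.2, 0.5)) {
        init <- sfsDetection(1:5000, 1, ratePair(1, d1), 5000)
        for (tf in c(0.5, 1.5)) {
            alpha <- extinctionProbability(ratePair(0.4, 1), tf)
            exact <- tmbGeneral("pre", rates = ratePair(0.4, 1), tf = tf,
                                N0 = 5000, initialSFS = init,
                                conditionOnSurvival = FALSE)
            expect_equal(tmbPreAfter(sum(init), alpha), exact,
                         tolerance = 0.1)
        }
    }
})

test_that("Theorem-2 quadrature agrees with spectrum summation", {
    tg <- tmbGeneral("new", m = 1, rates = ratePair(1, 1), tf = 2, N0 = 50)
    sg <- sum(sfsNewGeneral(1:400, 1, ratePair(1, 1), 2, 50))
    expect_equal(tg, sg, tolerance = 0.01)
    expect_equal(tmbGeneral("new", m = 1, rates = ratePair(0, 1), tf = 2,
                            N0 = 50), 0)
    init <- c(5, 3, 2)
    expect_equal(tmbGeneral("pre", rates = ratePair(1, 0.5), tf = 0,
                            N0 = 3, initialSFS = init), sum(init))
})

test_that("variance heuristic tracks pure-birth fixed-size simulations", {
    plan <- treatmentPlan(bs1 = 1, ds1 = 0, m = 1, detectionSize = 1000)
    mat <- ensembleSpectra(runEnsemble(plan, 600, baseSeed = 29),
                           sfsFromTree, 1000)
    # heuristic (1 + m) E[S_k] at a mid-tail frequency
    k <- 20
    expect_equal(var(mat[k, ]),
                 sfsVarianceDetection(k, 1, ratePair(1, 0), 1000),
                 tolerance = 0.2)
    # exact singleton variance m E[W_1] = m Nd, below the heuristic
    expect_equal(var(mat[1, ]), 1 * 1000, tolerance = 0.2)
    expect_lt(var(mat[1, ]),
              sfsVarianceDetection(1, 1, ratePair(1, 0), 1000))
})

test_that("resistance risk follows 1 - (1 - pr)^B", {
    expect_equal(resistanceRisk(0, 0.1), 0)
    expect_equal(resistanceRisk(1e4, 0), 0)
    expect_equal(resistanceRisk(1e4, 1e-4), 1 - (1 - 1e-4)^1e4)
    expect_equal(resistanceRisk(5, 1), 1)
    expect_error(resistanceRisk(-1, 0.5), "B")
})
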