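test_that("homogeneous pattern yields a near-constant fitted intensity", {
    withr::with_seed(1, { x <- runif(500); y <- runif(500) })
    m <- fitIntensity(x, y, spatialWindow())
    expect_identical(m@degree, 3L)
    # the non-intercept coefficients are jointly compatible with zero
    # (Wald test; the cubic basis makes the individual z's collinear)
    b <- m@coefficients[-1]; V <- m@vcov[-1, -1]
    W <- drop(t(b) %*% solve(V) %*% b)
    expect_gt(pchisq(W, df = length(b), lower.tail = FALSE), 0.01)
})

test_that("a planted linear intensity trend is recovered", {
    # oracle: rejection-sample log lambda = b0 + 2x with spatstat
    withr::with_seed(2, {
        pts <- spatstat.random::rpoint(500,
            function(x, y) exp(2 * x), win = spatstat.geom::owin())
    })
    m <- fitIntensity(pts$x, pts$y, spatialWindow())
    # the raw cubic-basis coefficient is collinear, so test it against its
    # own CI, and test the identifiable functional: the mean d/dx of the
    # fitted log intensity over the window, which must recover the slope 2
    expect_lt(abs(m@coefficients[2] - 2), 2.5 * sqrt(diag(m@vcov))[2])
    gx <- seq(0.05, 0.95, by = 0.05)
    grid <- expand.grid(x = gx, y = gx)
    eps <- 1e-4
    slope <- mean((log(intensity(m, grid$x + eps, grid$y)) -
                   log(intensity(m, grid$x - eps, grid$y))) / (2 * eps))
    expect_lt(abs(slope - 2), 0.5)
})

test_that("sparse cell types fall back to the quadratic model", {
    withr::with_seed(3, { x <- runif(8); y <- runif(8) })
    m <- fitIntensity(x, y, spatialWindow())
    expect_identical(m@degree, 2L)
    expect_length(m@coefficients, 6L)
})

test_that("M-H sample under constant intensity passes the quadrat test", {
    m <- new("IntensityModel", cellType = "t", degree = 2L,
             coefficients = c(log(1000), 0, 0, 0, 0, 0),
             window = spatialWindow(), maxLogIntensity = log(1000),
             vcov = NULL)
    s <- sampleIntensityMH(m, 1000, iterations = 30000, seed = 5)
    expect_length(s$x, 1000)
    expect_true(all(containsPoints(spatialWindow(), s$x, s$y)))
    cnt <- table(factor(ceiling(s$x * 5), levels = 1:5),
                 factor(ceiling(s$y * 5), levels = 1:5))
    p <- chisq.test(as.vector(cnt))$p.value
    expect_gt(p, 0.01)
})

test_that("M-H sample follows a planted exponential trend in x", {
    win <- spatialWindow()
    m <- new("IntensityModel", cellType = "t", degree = 2L,
             coefficients = c(0, 3, 0, 0, 0, 0), window = win,
             maxLogIntensity = 3, vcov = NULL)
    s <- sampleIntensityMH(m, 1500, iterations = 40000, seed = 6)
    breaks <- seq(0, 1, by = 0.1)
    cnt <- tabulate(cut(s$x, breaks, labels = FALSE), 10)
    lam_int <- diff(exp(3 * breaks) / 3)  # integral of e^{3x} per strip
    expect_gt(cor(cnt, lam_int), 0.9)
})

test_that("degenerate M-H requests behave", {
    withr::with_seed(7, { x <- runif(50); y <- runif(50) })
    m <- fitIntensity(x, y, spatialWindow())
    s <- sampleIntensityMH(m, 0, iterations = 10)
    expect_length(s$x, 0)
})

test_that("uniform allocation respects per-region type counts", {
    part <- partitionUnitSquare(2, 10, seed = 1)
    nbt <- data.frame(region = c("1", "2"), cell_type = c("A", "B"),
                      n = c(50, 50))
    pool <- allocateUniform(part, nbt, seed = 2)
    cells <- as.data.frame(poolCells(pool))
    expect_identical(nrow(cells), 100L)
    expect_identical(as.integer(table(cells$cell_type)[c("A", "B")]),
                     c(50L, 50L))
    # labels respect regions: every point inside its region's mask window
    for (r in c("1", "2")) {
        w <- partitionRegionWindow(part, as.integer(r))
        i <- cells$region == r
        expect_true(all(containsPoints(w, cells$x[i], cells$y[i])))
    }
    empty <- allocateUniform(spatialWindow(),
                             data.frame(cell_type = "A", n = 0))
    expect_identical(nrow(poolCells(empty)), 0L)
})

test_that("overlap removal enforces the minimum distance", {
    # coincident points: exactly one survives
    keep <- removeOverlaps(c(0.5, 0.5), c(0.5, 0.5), 0.1, seed = 1)
    expect_length(keep, 1L)
    # zero distance: identity
    expect_identical(removeOverlaps(runif(20), runif(20), 0), 1:20)
    # fine lattice: brute-force pairwise check of the survivors
    g <- expand.grid(x = seq(0, 1, length.out = 10),
                     y = seq(0, 1, length.out = 10))
    keep <- removeOverlaps(g$x, g$y, 0.15, seed = 2)
    d <- as.matrix(dist(g[keep, ]))
    expect_true(all(d[upper.tri(d)] >= 0.15))
    # every removed point has a kept point within min_distance
    removed <- setdiff(seq_len(nrow(g)), keep)
    dd <- FNN::get.knnx(g[keep, ], g[removed, ], k = 1)$nn.dist
    expect_true(all(dd < 0.15))
    # idempotence
    keep2 <- removeOverlaps(g$x[keep], g$y[keep], 0.15, seed = 3)
    expect_identical(keep2, seq_along(keep))
})

test_that("intensity models round-trip through JSON", {
    withr::with_seed(8, { x <- runif(60); y <- runif(60) })
    m <- fitIntensity(x, y, estimateWindow(x, y, "convex"), cell_type = "T")
    f <- withr::local_tempfile(fileext = ".json")
    writeIntensityModel(m, f)
    m2 <- readIntensityModel(f)
    expect_equal(m2@coefficients, m@coefficients)
    expect_identical(m2@degree, m@degree)
    expect_equal(windowArea(m2@window), windowArea(m@window),
                 tolerance = 1e-8)
    expect_equal(intensity(m2, 0.4, 0.6), intensity(m, 0.4, 0.6))
})
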