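test_that("K = 1 labels the whole grid as one region", {
    p <- partitionUnitSquare(1, 20)
    expect_true(all(regionLabels(p) == 1L))
    expect_identical(sum(regionLabels(p) == 1L), 400L)
})

test_that("partitions cover the grid with connected regions", {
    # fixed-size checks plus the exhaustive tiny grid
    p <- partitionUnitSquare(3, 20, seed = 11)
    lab <- regionLabels(p)
    expect_identical(sort(unique(as.vector(lab))), 1:3)
    for (k in 1:3) expect_true(flood_connected(lab == k))
    p2 <- partitionUnitSquare(2, 2, seed = 5)
    lab2 <- regionLabels(p2)
    expect_identical(sum(tabulate(lab2, 2)), 4L)
    for (k in 1:2) expect_true(flood_connected(lab2 == k))
})

test_that("connectivity holds across a seed sweep of K and B", {
    grid <- expand.grid(K = c(2, 3, 5), B = c(5, 20))
    for (s in 1:100) {
        g <- grid[(s - 1) %% nrow(grid) + 1, ]
        lab <- regionLabels(partitionUnitSquare(g$K, g$B, seed = s))
        expect_false(anyNA(lab))
        for (k in seq_len(g$K))
            expect_true(flood_connected(lab == k),
                        info = sprintf("seed %d K %d B %d", s, g$K, g$B))
    }
})

test_that("K beyond the border pixel count errors", {
    expect_error(partitionUnitSquare(5, 2), "border")
})

test_that("rectangle window matches the direct bounding box", {
    withr::with_seed(1, { x <- runif(200); y <- runif(200) })
    w <- estimateWindow(x, y, "rectangle")
    expect_equal(windowArea(w), diff(range(x)) * diff(range(y)))
    expect_gt(windowArea(w), 0.9)
    expect_lte(windowArea(w), 1.0)
})

test_that("delaunay window strictly contains every input point", {
    withr::with_seed(2, { x <- runif(200); y <- runif(200) })
    w <- estimateWindow(x, y, "delaunay")
    expect_true(all(containsPoints(w, x, y)))
    wc <- estimateWindow(x, y, "convex")
    expect_true(all(containsPoints(wc, x, y)))
})

test_that("delaunay window hugs a concave (U-shaped) cloud tighter than the hull", {
    withr::with_seed(3, {
        n <- 100
        x <- c(runif(n, 0, 0.3), runif(n, 0.7, 1), runif(n, 0, 1))
        y <- c(runif(n, 0, 1), runif(n, 0, 1), runif(n, 0, 0.2))
    })
    wd <- estimateWindow(x, y, "delaunay")
    wc <- estimateWindow(x, y, "convex")
    expect_lt(windowArea(wd), windowArea(wc))
    ws <- estimateWindow(x, y, "sectioned_convex", sections = 3)
    expect_true(all(containsPoints(ws, x, y)))
})

test_that("delaunay window area is non-decreasing in outlier_sd", {
    withr::with_seed(4, { x <- runif(150); y <- runif(150) })
    areas <- vapply(c(1, 2, 3, 5), function(s)
        windowArea(estimateWindow(x, y, "delaunay", outlier_sd = s)),
        numeric(1))
    expect_true(all(diff(areas) >= -1e-12))
})

test_that("region windows are disjoint and preserve the union", {
    withr::with_seed(5, {
        x <- c(runif(80, 0, 0.48), runif(80, 0.52, 1))
        y <- c(runif(80), runif(80))
    })
    reg <- rep(c("r1", "r2"), each = 80)
    wins <- estimateRegionWindows(x, y, reg, seed = 1, method = "convex")
    expect_named(wins, c("r1", "r2"))
    raw1 <- estimateWindow(x[reg == "r1"], y[reg == "r1"], "convex")
    raw2 <- estimateWindow(x[reg == "r2"], y[reg == "r2"], "convex")
    ov <- spatstat.geom::intersect.owin(wins$r1@win, wins$r2@win,
                                        fatal = FALSE)
    ov_area <- if (is.null(ov) || spatstat.geom::is.empty(ov)) 0 else
        spatstat.geom::area.owin(ov)
    expect_lt(ov_area, 1e-9)
    # polygon-algebra oracle: union of resolved windows = union of raw ones
    u_res <- spatstat.geom::union.owin(wins$r1@win, wins$r2@win)
    u_raw <- spatstat.geom::union.owin(raw1@win, raw2@win)
    expect_equal(spatstat.geom::area.owin(u_res),
                 spatstat.geom::area.owin(u_raw), tolerance = 1e-6)
    # single region reduces to estimateWindow
    w1 <- estimateRegionWindows(x[reg == "r1"], y[reg == "r1"],
                                rep("r1", 80), method = "convex")
    expect_equal(windowArea(w1$r1), windowArea(raw1))
    expect_error(estimateRegionWindows(c(1, 2), c(1, 2), c("a", "b")),
                 "fewer than 3")
})

test_that("windows serialize to WKT and partitions to TSV", {
    w <- estimateWindow(runif(30), runif(30), "convex")
    expect_match(windowWKT(w), "^POLYGON\\(")
    f <- withr::local_tempfile(fileext = ".tsv")
    writePartition(partitionUnitSquare(2, 5, seed = 1), f)
    tab <- as.matrix(read.delim(f, header = FALSE))
    expect_identical(dim(tab), c(5L, 5L))
    expect_true(all(tab %in% 1:2))
})
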