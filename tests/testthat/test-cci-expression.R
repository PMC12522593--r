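test_that("spatial-dependence estimates are calibrated under the null", {
    fx <- planted_expression_fixture(mu = 0, seed = 1)
    g <- buildNeighborGraph(fx$cells$x, fx$cells$y, "distance", 0.06)
    est <- estimateSpatialDependence(fx$initial, fx$cells$cell_type, g,
                                     "A", "B", n_perm = 400, seed = 2)
    expect_identical(nrow(est), 40L)
    expect_lt(abs(median(est$log2fc)), 0.1)
    # permutation p-values are discrete, so ignore the KS ties warning
    ks <- suppressWarnings(ks.test(est$p_value, "punif")$p.value)
    expect_gt(ks, 0.01)
})

test_that("a planted neighbor effect is recovered on the log2 scale", {
    fx <- planted_expression_fixture(mu = 0.5, seed = 3)
    g <- buildNeighborGraph(fx$cells$x, fx$cells$y, "distance", 0.06)
    est <- estimateSpatialDependence(fx$counts, fx$cells$cell_type, g,
                                     "A", "B", n_perm = 400, seed = 4)
    hit <- est$gene %in% fx$spec$genes
    expect_lt(abs(median(est$log2fc[hit]) - 0.5 / log(2)), 0.15)
    expect_lt(abs(median(est$log2fc[!hit])), 0.1)
})

test_that("tiny receiver groups are skipped with a message", {
    counts <- matrix(1L, 3, 5,
                     dimnames = list(paste0("g", 1:3), paste0("c", 1:5)))
    # one receiver adjacent to the sender, one not: both groups too small
    x <- c(0, 0.01, 0.9, 0.5, 0.6); y <- rep(0, 5)
    types <- c("A", "B", "B", "A", "A")
    g <- buildNeighborGraph(x, y, "distance", 0.05)
    expect_message(
        est <- estimateSpatialDependence(counts, types, g, "A", "B",
                                         n_perm = 10),
        "too small")
    expect_identical(nrow(est), 0L)
})

test_that("gene-pair enrichment finds a planted co-expression boost", {
    withr::with_seed(5, {
        n <- 300
        cells <- data.frame(x = runif(n), y = runif(n),
                            cell_type = rep(c("A", "B"), length.out = n),
                            region = "1")
        genes <- sprintf("g%02d", 1:20)
        counts <- matrix(rnbinom(20 * n, mu = 5, size = 2), 20, n,
                         dimnames = list(genes, NULL))
    })
    # a tight interaction radius keeps the qualifying subset well below
    # half the cells, so adjacent pairs contrast with non-adjacent ones
    spec <- list(kind = "gene_pair", perturbed_type = "A",
                 neighbor_type = "B", distance_threshold = 0.03,
                 gene_m = "g01", gene_n = "g02", bidirectional = TRUE,
                 effect_mean = 1.0, effect_sd = 0)
    dl <- accumulateDelta(cells, list(spec), genes, seed = 6)
    boosted <- applyDelta(counts, dl)
    g <- buildNeighborGraph(cells$x, cells$y, "distance", 0.03)
    pairs <- data.frame(ligand = c("g01", "g03"), receptor = c("g02", "g04"))
    est <- estimateGenePairCCI(boosted, cells$cell_type, g, pairs,
                               "A", "B", n_perm = 400, seed = 7)
    planted <- est[est$gene_m == "g01", ]
    null_pair <- est[est$gene_m == "g03", ]
    expect_gt(planted$log2fc_product, 0)
    expect_lt(planted$p_value, 0.05)
    expect_gt(null_pair$p_value, 0.05)
    # empty pair list and absent genes
    empty <- estimateGenePairCCI(boosted, cells$cell_type, g,
                                 pairs[0, ], "A", "B")
    expect_identical(nrow(empty), 0L)
    expect_message(
        est2 <- estimateGenePairCCI(boosted, cells$cell_type, g,
                                    data.frame(l = "nope", r = "g02"),
                                    "A", "B", n_perm = 10),
        "absent")
    expect_identical(nrow(est2), 0L)
})

test_that("delta accumulation is exact at sigma = 0 and additive", {
    cells <- data.frame(x = runif(30), y = runif(30),
                        cell_type = rep(c("k", "o"), 15),
                        region = rep(c("r1", "r2"), each = 15))
    genes <- paste0("g", 1:5)
    # empty spec list: all zero
    d0 <- accumulateDelta(cells, list(), genes)
    expect_true(all(deltaValues(d0) == 0))
    # one regional spec, sigma = 0: exact entries
    spec <- list(kind = "regional", region = "r1", perturbed_type = "k",
                 genes = c("g1", "g2"), effect_mean = 0.7, effect_sd = 0)
    d1 <- accumulateDelta(cells, list(spec), genes)
    n_k_r1 <- sum(cells$cell_type == "k" & cells$region == "r1")
    expect_identical(sum(deltaValues(d1) == 0.7), n_k_r1 * 2L)
    expect_identical(sum(deltaValues(d1) != 0), n_k_r1 * 2L)
    # overlapping specs add
    spec2 <- modifyList(spec, list(effect_mean = 0.3, genes = list("g1")))
    spec3 <- modifyList(spec, list(effect_mean = 0.4, genes = list("g1")))
    d2 <- accumulateDelta(cells, list(spec2, spec3), genes)
    vals <- deltaValues(d2)[, "g1"]
    expect_true(all(abs(vals[vals != 0] - 0.7) < 1e-12))
    # unknown names error before mutation
    expect_error(accumulateDelta(cells, list(modifyList(spec,
        list(perturbed_type = "zz"))), genes), "unknown perturbed_type")
    expect_error(accumulateDelta(cells, list(modifyList(spec,
        list(genes = list("nope")))), genes), "unknown gene")
})

test_that("gene_fraction draws are seeded and recorded", {
    cells <- data.frame(x = runif(20), y = runif(20), cell_type = "k",
                        region = "r")
    genes <- paste0("g", 1:50)
    spec <- list(kind = "regional", perturbed_type = "k",
                 gene_fraction = 0.2, effect_mean = 1, effect_sd = 0)
    d1 <- accumulateDelta(cells, list(spec), genes, seed = 9)
    d2 <- accumulateDelta(cells, list(spec), genes, seed = 9)
    expect_identical(deltaProvenance(d1)[[1]]$genes,
                     deltaProvenance(d2)[[1]]$genes)
    expect_length(deltaProvenance(d1)[[1]]$genes, 10L)
})

test_that("count updates follow the log1p closed form and its guards", {
    # identity: delta zero, no cap, no depth match
    init <- matrix(rpois(60, 8), 6, 10,
                   dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
    storage.mode(init) <- "integer"
    out <- applyDelta(init, matrix(0, 10, 6))
    expect_identical(out, init)
    # zero counts cannot be pushed negative
    m0 <- matrix(0L, 1, 1)
    expect_identical(applyDelta(m0, matrix(-2, 1, 1))[1, 1], 0L)
    # but can rise under positive perturbation
    expect_gt(applyDelta(m0, matrix(2, 1, 1))[1, 1], 0L)
    # hand-evaluated closed form: round(11 * e^0.5 - 1) = 17
    expect_identical(applyDelta(matrix(10L, 1, 1),
                                matrix(0.5, 1, 1))[1, 1], 17L)
})

test_that("depth matching restores the initial total within 0.1%", {
    withr::with_seed(10, {
        init <- matrix(rnbinom(2000, mu = 6, size = 2), 20, 100)
        delta <- matrix(rnorm(100 * 20, 0.3, 0.2), 100, 20)
    })
    out <- applyDelta(init, delta, match_depth = TRUE)
    expect_lt(abs(sum(out) - sum(init)) / sum(init), 1e-3)
    # cap bounds extremes
    capd <- applyDelta(init, delta + 5, cap_max = TRUE)
    expect_lte(max(capd), max(5 * quantile(init, 0.975), max(init)) + 0.5)
})

test_that("every nonzero delta entry is attributable to a recorded spec", {
    fx <- planted_expression_fixture(mu = 0.4, seed = 11)
    dv <- deltaValues(fx$delta)
    prov <- deltaProvenance(fx$delta)
    touched <- matrix(FALSE, nrow(dv), ncol(dv),
                      dimnames = dimnames(dv))
    for (r in prov) touched[r$cells, r$genes] <- TRUE
    expect_true(all(touched[dv != 0]))
})

test_that("planted pair correlation grows with the effect size", {
    # each A cell paired with its nearest B cell; interacting pairs are
    # jointly boosted, so the mixture of interacting and non-interacting
    # pairs becomes increasingly correlated as the effect size grows;
    # averaged over replicate maps to suppress sampling noise
    one_curve <- function(seed) {
        withr::with_seed(seed, {
            n <- 300
            cells <- data.frame(x = runif(n), y = runif(n),
                                cell_type = rep(c("A", "B"),
                                                length.out = n),
                                region = "1")
            genes <- c("gm", "gn")
            counts <- matrix(rnbinom(2 * n, mu = 5, size = 10), 2, n,
                             dimnames = list(genes, NULL))
        })
        ai <- which(cells$cell_type == "A")
        bi <- which(cells$cell_type == "B")
        nb <- FNN::get.knnx(cells[bi, c("x", "y")],
                            cells[ai, c("x", "y")], k = 1)$nn.index[, 1]
        b_of <- bi[nb]
        vapply(seq(0, 0.5, by = 0.1), function(mu) {
            spec <- list(kind = "gene_pair", perturbed_type = "A",
                         neighbor_type = "B", distance_threshold = 0.03,
                         gene_m = "gm", gene_n = "gn", bidirectional = TRUE,
                         effect_mean = mu, effect_sd = 0)
            out <- applyDelta(counts,
                accumulateDelta(cells, list(spec), c("gm", "gn"),
                                seed = seed + 1))
            cor(out["gm", ai], out["gn", b_of])
        }, numeric(1))
    }
    cors <- rowMeans(vapply(1:5, one_curve, numeric(6)))
    fit <- lm(cors ~ seq(0, 0.5, by = 0.1))
    expect_gt(coef(fit)[2], 0)
    expect_gt(cors[6], cors[1])
})

test_that("perturbation specs round-trip through TSV", {
    specs <- list(
        list(kind = "regional", region = "r1", perturbed_type = "k",
             genes = c("g1", "g2"), effect_mean = 0.7, effect_sd = 0),
        list(kind = "gene_pair", perturbed_type = "A", neighbor_type = "B",
             distance_threshold = 0.1, gene_m = "gm", gene_n = "gn",
             bidirectional = TRUE, effect_mean = 0.5, effect_sd = 0.1))
    f <- withr::local_tempfile(fileext = ".tsv")
    writePerturbationSpecs(specs, f)
    back <- readPerturbationSpecs(f)
    expect_identical(back[[1]]$genes, c("g1", "g2"))
    expect_identical(back[[2]]$gene_m, "gm")
    expect_true(back[[2]]$bidirectional)
    expect_equal(back[[2]]$effect_sd, 0.1)
})
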