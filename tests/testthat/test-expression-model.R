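test_that("the marginal fit recovers planted ZINB parameters", {
    withr::with_seed(1, {
        y <- ifelse(runif(5000) < 0.3, 0L,
                    rnbinom(5000, mu = 5, size = 2))
    })
    fit <- fitMarginal(y)
    expect_identical(fit$family, "zinb")
    expect_lt(abs(fit$pi - 0.3) / 0.3, 0.10)
    expect_lt(abs(fit$mu - 5) / 5, 0.10)
    expect_lt(abs(fit$size - 2) / 2, 0.10)
})

test_that("degenerate and equidispersed genes fall down the family ladder", {
    # all zeros: structural zeros only, draws all zero
    fit0 <- fitMarginal(integer(10))
    expect_identical(fit0$mu, 0)
    expect_equal(fit0$pi, 1)
    expect_true(all(qzinb(runif(50), fit0$pi, fit0$mu, fit0$size) == 0))
    # Poisson data: no overdispersion component retained
    withr::with_seed(2, y <- rpois(4000, 3))
    fit <- fitMarginal(y)
    expect_true(fit$family %in% c("poisson", "zip"))
    expect_lt(abs((1 - fit$pi) * fit$mu - 3) / 3, 0.05)
    expect_error(fitMarginal(integer(0)), "at least 2")
})

test_that("copula correlation is recovered and the estimate is a valid correlation", {
    withr::with_seed(3, {
        z <- mvtnorm::rmvnorm(2000, sigma = rbind(c(1, .6), c(.6, 1)))
        counts <- rbind(qnbinom(pnorm(z[, 1]), mu = 4, size = 2),
                        qnbinom(pnorm(z[, 2]), mu = 8, size = 1))
    })
    rownames(counts) <- c("g1", "g2")
    marg <- do.call(rbind, lapply(1:2, function(g) fitMarginal(counts[g, ])))
    sig <- fitCopulaCorrelation(counts, marg, seed = 4)
    expect_gt(sig[1, 2], 0.5)
    expect_lt(sig[1, 2], 0.7)
    expect_equal(diag(sig), c(g1 = 1, g2 = 1))
    expect_equal(sig, t(sig))
    ev <- eigen(sig, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
})

test_that("independent genes give near-zero latent correlations", {
    withr::with_seed(5, {
        counts <- matrix(rnbinom(6 * 2000, mu = 5, size = 2), 6, 2000,
                         dimnames = list(paste0("g", 1:6), NULL))
    })
    marg <- do.call(rbind, lapply(1:6, function(g) fitMarginal(counts[g, ])))
    sig <- fitCopulaCorrelation(counts, marg, seed = 6)
    off <- sig[upper.tri(sig)]
    expect_lt(max(abs(off)), 0.1)
})

test_that("constant genes are replaced by identity rows with a warning", {
    counts <- rbind(g1 = rep(3L, 50), g2 = rpois(50, 4), g3 = rpois(50, 4))
    marg <- data.frame(gene = paste0("g", 1:3), family = "poisson",
                       pi = 0, mu = c(3, 4, 4), size = Inf)
    expect_warning(sig <- fitCopulaCorrelation(counts, marg, seed = 1),
                   "constant")
    expect_equal(unname(sig[1, 2:3]), c(0, 0))
})

test_that("stratified subsampling caps each stratum", {
    types <- rep(c("A", "B"), c(100, 5000))
    idx <- subsampleCells(types, cap = 2500, seed = 1)
    expect_identical(sum(types[idx] == "A"), 100L)
    expect_identical(sum(types[idx] == "B"), 2500L)
    expect_identical(subsampleCells(types, cap = 2500, seed = 1), idx)
    regions <- rep(c("r1", "r2"), length.out = length(types))
    idx2 <- subsampleCells(types, regions, cap = 30, seed = 2)
    expect_true(all(table(paste(types, regions)[idx2]) <= 30))
})

test_that("simulated counts preserve the fitted marginals (moments oracle)", {
    marg <- data.frame(gene = c("a", "b"), family = "zinb",
                       pi = c(0.3, 0.1), mu = c(5, 2), size = c(2, 1))
    model <- new("CellTypeExpressionModel", cellType = "T",
                 region = NA_character_, marginals = marg, sigma = NULL)
    y <- drawCounts(model, 5000, seed = 7)
    for (g in 1:2) {
        m_theo <- (1 - marg$pi[g]) * marg$mu[g]
        v_nb <- marg$mu[g] + marg$mu[g]^2 / marg$size[g]
        v_theo <- (1 - marg$pi[g]) * (v_nb + marg$pi[g] * marg$mu[g]^2)
        z_theo <- marg$pi[g] +
            (1 - marg$pi[g]) * dnbinom(0, mu = marg$mu[g], size = marg$size[g])
        se_m <- sqrt(v_theo / 5000)
        se_z <- sqrt(z_theo * (1 - z_theo) / 5000)
        expect_lt(abs(mean(y[g, ]) - m_theo), 3 * se_m)
        expect_lt(abs(mean(y[g, ] == 0) - z_theo), 3 * se_z)
    }
})

test_that("depth factor scales totals linearly", {
    marg <- data.frame(gene = paste0("g", 1:5), family = "nb", pi = 0,
                       mu = c(2, 5, 1, 8, 3), size = 2)
    model <- new("CellTypeExpressionModel", cellType = "T",
                 region = NA_character_, marginals = marg, sigma = NULL)
    y1 <- drawCounts(model, 5000, depth_factor = 1, seed = 8)
    y2 <- drawCounts(model, 5000, depth_factor = 2, seed = 9)
    ratio <- sum(y2) / sum(y1)
    expect_gt(ratio, 1.9); expect_lt(ratio, 2.1)
})

test_that("planted copula correlation survives into the counts", {
    sig <- diag(3); sig[1, 2] <- sig[2, 1] <- 0.8
    marg <- data.frame(gene = paste0("g", 1:3), family = "nb", pi = 0,
                       mu = 5, size = 2)
    model <- new("CellTypeExpressionModel", cellType = "T",
                 region = NA_character_, marginals = marg, sigma = sig)
    y <- drawCounts(model, 5000, seed = 10)
    expect_gt(cor(y[1, ], y[2, ], method = "spearman"), 0.5)
    expect_lt(abs(cor(y[1, ], y[3, ], method = "spearman")), 0.1)
})

test_that("correlation round-trips through draw and re-fit", {
    for (rho in c(0.3, 0.6, 0.9)) {
        sig <- rbind(c(1, rho), c(rho, 1))
        marg <- data.frame(gene = c("a", "b"), family = "zinb",
                           pi = c(0.2, 0.2), mu = c(5, 3), size = c(2, 2))
        model <- new("CellTypeExpressionModel", cellType = "T",
                     region = NA_character_, marginals = marg, sigma = sig)
        y <- drawCounts(model, 2000, seed = round(100 * rho))
        marg_hat <- do.call(rbind,
            lapply(1:2, function(g) fitMarginal(y[g, ])))
        sig_hat <- fitCopulaCorrelation(y, marg_hat,
                                        seed = round(100 * rho) + 1)
        expect_lt(abs(sig_hat[1, 2] - rho), 0.1)
    }
})

test_that("expression models round-trip through disk", {
    fx <- generateReference("expression_only", n_cells = 120, n_genes = 15,
                            seed = 11)
    counts <- SummarizedExperiment::assay(fx$reference, "counts")
    model <- fitExpressionModel(counts[, 1:60], "A", seed = 12)
    dir <- withr::local_tempdir()
    writeExpressionModel(model, dir)
    back <- readExpressionModel(dir)
    expect_equal(back@marginals$mu, model@marginals$mu)
    expect_identical(back@marginals$family, model@marginals$family)
    expect_equal(unname(back@sigma), unname(model@sigma), tolerance = 1e-8)
})
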