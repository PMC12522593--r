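#' @include AllClasses.R AllGenerics.R utils.R zinb.R
NULL

#' Estimate the latent Gaussian copula correlation of count marginals
#'
#' Maps each gene's counts to latent normal scores and takes their sample
#' correlation across cells. The default \code{"conditional_mean"} scores
#' are the conditional expectations of the latent normal given the
#' observed count, E[Z | y] (the truncated-normal mean over the count's
#' latent bin) -- a deterministic, polyserial-style transform whose
#' correlation tracks the latent correlation closely even with the heavy
#' ties of sparse counts. The \code{"randomized"} alternative is the
#' distributional transform u = F(y - 1) + V (F(y) - F(y - 1)),
#' V ~ U(0, 1) (seeded); its sample correlation attenuates strong latent
#' correlations somewhat more. A non-PSD estimate is projected to the
#' nearest correlation matrix; constant genes get an identity row/column
#' with a warning.
#'
#' @param counts gene x cell integer matrix (>= 2 genes, >= 3 cells).
#' @param marginals data.frame of fitted marginals as returned by
#'   [fitMarginal()], one row per gene in matrix order.
#' @param method \code{"conditional_mean"} (default) or
#'   \code{"randomized"}.
#' @param seed optional integer seed (used by the randomized transform
#'   only).
#' @return correlation matrix (unit diagonal, symmetric PSD) with attribute
#'   \code{"psd_repaired"} marking whether projection was applied.
#' @export
fitCopulaCorrelation <- function(counts, marginals,
                                 method = c("conditional_mean", "randomized"),
                                 seed = NULL) {
    method <- match.arg(method)
    G <- nrow(counts); n <- ncol(counts)
    .assert(G >= 2L, "need at least 2 genes")
    .assert(n >= 3L, "need at least 3 cells")
    .assert(nrow(marginals) == G, "one marginal per gene required")
    .with_seed(seed, {
        z <- matrix(NA_real_, n, G)
        const <- logical(G)
        for (g in seq_len(G)) {
            y <- counts[g, ]
            if (stats::var(y) == 0) { const[g] <- TRUE; z[, g] <- 0; next }
            mg <- marginals[g, ]
            Fy <- pmin(pmax(pzinb(y, mg$pi, mg$mu, mg$size), 1e-12),
                       1 - 1e-12)
            Fy1 <- pmin(pmax(pzinb(y - 1, mg$pi, mg$mu, mg$size), 1e-12),
                        1 - 1e-12)
            if (method == "conditional_mean") {
                a <- stats::qnorm(Fy1); b <- stats::qnorm(Fy)
                z[, g] <- (stats::dnorm(a) - stats::dnorm(b)) /
                    pmax(Fy - Fy1, 1e-12)
            } else {
                u <- Fy1 + stats::runif(n) * (Fy - Fy1)
                z[, g] <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
            }
        }
        sigma <- suppressWarnings(stats::cor(z))
        sigma[!is.finite(sigma)] <- 0
        if (any(const)) {
            warning(sum(const), " constant gene(s): identity row/column used",
                    call. = FALSE)
            sigma[const, ] <- 0; sigma[, const] <- 0
        }
        diag(sigma) <- 1
        repaired <- FALSE
        ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < -1e-8) {
            sigma <- as.matrix(Matrix::nearPD(sigma, corr = TRUE)$mat)
            repaired <- TRUE
        }
        dimnames(sigma) <- list(rownames(counts), rownames(counts))
        attr(sigma, "psd_repaired") <- repaired
        sigma
    })
}

#' Subsample cells for model fitting
#'
#' Caps the number of cells used per (cell type, region) stratum, trading a
#' negligible accuracy loss for large speedups on big references.
#'
#' @param cell_types cell-type label per cell.
#' @param regions optional region label per cell.
#' @param cap maximum cells per stratum (default 2500).
#' @param seed optional integer seed.
#' @return sorted integer vector of retained cell indices.
#' @export
subsampleCells <- function(cell_types, regions = NULL, cap = 2500L,
                           seed = NULL) {
    .assert(cap >= 1L, "cap must be >= 1")
    strat <- if (is.null(regions)) as.character(cell_types)
        else paste(cell_types, regions, sep = "\r")
    .with_seed(seed, {
        idx <- unlist(lapply(split(seq_along(strat), strat), function(i)
            if (length(i) <= cap) i else sample(i, cap)), use.names = FALSE)
        sort(idx)
    })
}

#' Fit the expression model of one cell type (optionally one region)
#'
#' Fits a ZINB marginal per gene ([fitMarginal()]) and, optionally, the
#' Gaussian-copula gene-gene correlation ([fitCopulaCorrelation()]) on the
#' cells of one stratum.
#'
#' @param counts gene x cell matrix restricted to the stratum's cells.
#' @param cell_type,region stratum labels (region NA when unstratified).
#' @param use_correlation fit the copula correlation (default TRUE).
#' @param seed optional integer seed (randomized transform).
#' @return a \linkS4class{CellTypeExpressionModel}.
#' @export
fitExpressionModel <- function(counts, cell_type, region = NA_character_,
                               use_correlation = TRUE, seed = NULL) {
    .assert(nrow(counts) >= 1L && ncol(counts) >= 2L,
        "need >= 1 gene and >= 2 cells")
    marg <- do.call(rbind, lapply(seq_len(nrow(counts)), function(g)
        fitMarginal(counts[g, ])))
    marg <- cbind(gene = rownames(counts), marg)
    rownames(marg) <- NULL
    sigma <- if (use_correlation && nrow(counts) >= 2L && ncol(counts) >= 3L)
        fitCopulaCorrelation(counts, marg, seed = seed) else NULL
    if (!is.null(sigma)) attr(sigma, "psd_repaired") <- NULL
    new("CellTypeExpressionModel", cellType = as.character(cell_type),
        region = as.character(region), marginals = marg, sigma = sigma)
}

#' Draw correlated counts from a fitted expression model
#'
#' Generates the initial read counts: latent normals Z ~ N(0, Sigma) (or
#' independent when correlation is off), uniforms U = Phi(Z), and counts
#' via the inverse marginal CDF, Y = F^{-1}_{ZINB}(U), which preserves each
#' gene's marginal regardless of Sigma. \code{depth_factor} rescales the NB
#' mean of every marginal (structural-zero probabilities unchanged),
#' emulating a different sequencing depth.
#'
#' @param model a \linkS4class{CellTypeExpressionModel}.
#' @param n_cells number of cells to draw (>= 0).
#' @param depth_factor sequencing-depth multiplier (default 1, no change).
#' @param use_correlation use the model's Sigma when present (default TRUE).
#' @param seed optional integer seed.
#' @return gene x cell integer matrix.
#' @export
drawCounts <- function(model, n_cells, depth_factor = 1,
                       use_correlation = TRUE, seed = NULL) {
    .assert(n_cells >= 0L, "n_cells must be >= 0")
    .assert(depth_factor > 0, "depth_factor must be positive")
    marg <- model@marginals
    G <- nrow(marg)
    out <- matrix(0L, G, n_cells,
                  dimnames = list(marg$gene, if (n_cells > 0)
                      sprintf("cell%d", seq_len(n_cells))))
    if (n_cells == 0L) return(out)
    .with_seed(seed, {
        Z <- if (use_correlation && !is.null(model@sigma))
            mvtnorm::rmvnorm(n_cells, sigma = model@sigma,
                             checkSymmetry = FALSE)
        else matrix(stats::rnorm(n_cells * G), n_cells, G)
        U <- stats::pnorm(Z)
        U <- pmin(pmax(U, 1e-12), 1 - 1e-12)
        for (g in seq_len(G))
            out[g, ] <- as.integer(qzinb(U[, g], marg$pi[g],
                                         marg$mu[g] * depth_factor,
                                         marg$size[g]))
        out
    })
}

#' Serialize / read a fitted expression model
#'
#' Writes the marginals as JSON and the correlation matrix as a TSV into a
#' directory, so fitting and generation can be separated and repeated
#' simulations avoid refitting.
#'
#' @param model a \linkS4class{CellTypeExpressionModel}.
#' @param dir output directory.
#' @export
writeExpressionModel <- function(model, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    marg <- model@marginals
    marg$size[is.infinite(marg$size)] <- -1  # JSON-safe sentinel for Inf
    jsonlite::write_json(list(cell_type = model@cellType,
                              region = model@region, marginals = marg),
                         file.path(dir, "marginals.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(model@sigma))
        utils::write.table(model@sigma, file.path(dir, "sigma.tsv"),
                           sep = "\t", quote = FALSE, col.names = NA)
    invisible(dir)
}

#' @rdname writeExpressionModel
#' @export
readExpressionModel <- function(dir) {
    j <- jsonlite::read_json(file.path(dir, "marginals.json"),
                             simplifyVector = TRUE)
    marg <- as.data.frame(j$marginals)
    marg$size[marg$size < 0] <- Inf
    sigma <- NULL
    sf <- file.path(dir, "sigma.tsv")
    if (file.exists(sf)) {
        sigma <- as.matrix(utils::read.delim(sf, row.names = 1L,
                                             check.names = FALSE))
        dimnames(sigma) <- list(rownames(sigma), rownames(sigma))
    }
    new("CellTypeExpressionModel", cellType = j$cell_type,
        region = if (is.null(j$region)) NA_character_ else j$region,
        marginals = marg, sigma = sigma)
}
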