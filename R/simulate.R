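#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Estimate CCI parameters from a paired reference
#'
#' Convenience wrapper running all three built-in estimators on a paired
#' reference: cell-type colocalization enrichment
#' ([estimateColocalization()]), spatial dependence of gene expression for
#' every ordered type pair ([estimateSpatialDependence()]), and, when a
#' ligand-receptor pair list is given, gene-gene interactions between
#' neighboring cells ([estimateGenePairCCI()]). The resulting tables can be
#' fed back as simulation specs.
#'
#' @param reference a paired \linkS4class{CCIReference}.
#' @param neighbor_method,neighbor_param neighbor graph construction
#'   (default knn, k = 6).
#' @param lr_pairs optional 2-column data.frame of ligand-receptor pairs.
#' @param type_pairs optional 2-column matrix/data.frame of ordered
#'   (sender, receiver) type pairs to test; default all ordered pairs.
#' @param n_perm permutations (default 1000).
#' @param seed optional integer seed.
#' @return list with \code{colocalization}, \code{spatial_dependence},
#'   \code{gene_pair} tables.
#' @export
estimateCCI <- function(reference, neighbor_method = "knn",
                        neighbor_param = 6, lr_pairs = NULL,
                        type_pairs = NULL, n_perm = 1000L, seed = NULL) {
    .assert(scenario(reference) == "paired",
        "CCI estimation requires a paired reference")
    cd <- as.data.frame(cellMeta(reference))
    counts <- SummarizedExperiment::assay(reference, "counts")
    g <- buildNeighborGraph(cd$x, cd$y, neighbor_method, neighbor_param)
    types <- as.character(cd$cell_type)
    coloc <- estimateColocalization(g, types, n_perm = n_perm, seed = seed)
    if (is.null(type_pairs)) {
        tt <- cellTypes(reference)
        type_pairs <- expand.grid(sender = tt, receiver = tt,
                                  stringsAsFactors = FALSE)
    }
    sd_list <- lapply(seq_len(nrow(type_pairs)), function(i)
        estimateSpatialDependence(counts, types, g,
                                  type_pairs[i, 1L], type_pairs[i, 2L],
                                  n_perm = n_perm, seed = seed))
    gp <- NULL
    if (!is.null(lr_pairs)) {
        gp_list <- lapply(seq_len(nrow(type_pairs)), function(i)
            estimateGenePairCCI(counts, types, g, lr_pairs,
                                type_pairs[i, 1L], type_pairs[i, 2L],
                                n_perm = n_perm, seed = seed))
        gp <- do.call(rbind, gp_list)
    }
    list(colocalization = coloc,
         spatial_dependence = do.call(rbind, sd_list),
         gene_pair = gp)
}

# Stage 1 for a paired reference: estimate windows, fit per-type intensity
# models, sample new coordinates (M-H), drop overlaps, then apply CCI
# selection if colocalization specs are present.
.stage1_paired <- function(cd, p) {
    types <- unique(as.character(cd$cell_type))
    win <- estimateWindow(cd$x, cd$y, method = p$window_method,
                          buffer_radius = p$buffer_radius)
    targets <- table(factor(cd$cell_type, levels = types))
    strengths <- vapply(p$colocalization_specs, function(s) s$strength,
                        numeric(1))
    lam <- if (length(strengths))
        computeInflationRatio(strengths, p$inflation, p$evenness) else 1
    parts <- lapply(types, function(t) {
        i <- cd$cell_type == t
        m <- fitIntensity(cd$x[i], cd$y[i], win, cell_type = t)
        n_t <- ceiling(lam * targets[[t]])
        pt <- sampleIntensityMH(m, n_t, iterations = p$mh_iterations)
        data.frame(x = pt$x, y = pt$y, cell_type = t, region = "1")
    })
    pool_df <- do.call(rbind, parts)
    keep <- removeOverlaps(pool_df$x, pool_df$y, p$min_cell_distance)
    pool_df <- pool_df[keep, , drop = FALSE]
    pool <- new("CellPool", cells = DataFrame(pool_df))
    cells <- if (length(strengths)) {
        tg <- pmin(as.integer(targets),
                   table(factor(pool_df$cell_type, levels = types)))
        sel <- selectCellsWithCCI(pool, p$colocalization_specs,
                                  targets = structure(as.integer(tg),
                                                      names = types),
                                  alpha_star = p$evenness_alpha_star,
                                  neighbor_method = p$neighbor_method,
                                  neighbor_param = p$neighbor_param)
        as.data.frame(poolCells(sel))
    } else {
        # thin the surviving pool uniformly back to the targets
        out <- lapply(types, function(t) {
            i <- which(pool_df$cell_type == t)
            n_t <- min(length(i), targets[[t]])
            pool_df[sample(i, n_t), , drop = FALSE]
        })
        do.call(rbind, out)
    }
    list(cells = cells, window = win)
}

# Stage 1 de novo: partition the unit square and place cells uniformly,
# through the inflation/selection machinery when CCI is requested.
.stage1_denovo <- function(ref_types, p) {
    K <- p$n_regions
    part <- if (K > 1L) partitionUnitSquare(K, p$grid_size) else NULL
    windows <- if (is.null(part)) spatialWindow() else part
    nbt <- p$cells_per_region_per_type
    if (length(nbt) == 0L) {
        tt <- table(ref_types)
        nbt_df <- do.call(rbind, lapply(as.character(seq_len(K)), function(r)
            data.frame(region = r, cell_type = names(tt),
                       n = ceiling(as.integer(tt) / K))))
    } else {
        nbt_df <- do.call(rbind, lapply(names(nbt), function(r)
            data.frame(region = r, cell_type = names(nbt[[r]]),
                       n = as.integer(unlist(nbt[[r]])))))
    }
    strengths <- vapply(p$colocalization_specs, function(s) s$strength,
                        numeric(1))
    if (length(strengths)) {
        lam <- computeInflationRatio(strengths, p$inflation, p$evenness)
        pool_df <- nbt_df; pool_df$n <- ceiling(lam * pool_df$n)
        pool <- allocateUniform(windows, pool_df)
        targets <- tapply(nbt_df$n, nbt_df$cell_type, sum)
        sel <- selectCellsWithCCI(pool, p$colocalization_specs,
                                  targets = structure(as.integer(targets),
                                                      names = names(targets)),
                                  alpha_star = p$evenness_alpha_star,
                                  neighbor_method = p$neighbor_method,
                                  neighbor_param = p$neighbor_param)
        cells <- as.data.frame(poolCells(sel))
    } else {
        cells <- as.data.frame(poolCells(allocateUniform(windows, nbt_df)))
    }
    keep <- removeOverlaps(cells$x, cells$y, p$min_cell_distance)
    list(cells = cells[keep, , drop = FALSE], window = spatialWindow(),
         partition = part)
}

#' Run a full two-stage simulation
#'
#' Orchestrates the whole simulator. Stage 1 produces the spatial map:
#' de novo (random-walk region partition + uniform allocation) for
#' expression-only references; window estimation, per-type Poisson
#' point-process fits and Metropolis-Hastings sampling for paired
#' references; the reference spatial map is inherited for unpaired
#' references. Colocalization specs route the allocation through pool
#' inflation and CCI-aware selection; overlapping cells are removed.
#' Stage 2 fits per-cell-type ZINB-copula expression models (on a capped
#' subsample of reference cells), draws initial counts for the simulated
#' cells, accumulates the CCI/regional perturbation matrix and applies it
#' under the configured constraints. Output is single-cell, or aggregated
#' to multi-cell spots.
#'
#' @param reference a \linkS4class{CCIReference}.
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{cells} (metadata data.frame), \code{counts}
#'   (gene x cell integer matrix), \code{ground_truth} (applied-effect
#'   record), \code{models}, \code{window}, and for multi-cell output
#'   \code{spots} (a \linkS4class{SpotGrid}).
#' @export
simulateSRT <- function(reference, config) {
    p <- config@params
    counts_ref <- SummarizedExperiment::assay(reference, "counts")
    cd <- as.data.frame(cellMeta(reference))
    .with_seed(p$seed, {
        st1 <- switch(scenario(reference),
            paired = .stage1_paired(cd, p),
            expression_only = .stage1_denovo(as.character(cd$cell_type), p),
            unpaired = {
                spc <- as.data.frame(spatialCells(reference))
                spc$region <- if ("region" %in% colnames(spc))
                    as.character(spc$region) else "1"
                list(cells = spc[, c("x", "y", "cell_type", "region")],
                     window = estimateWindow(spc$x, spc$y,
                                             method = p$window_method,
                                             buffer_radius = p$buffer_radius))
            })
        cells <- st1$cells
        cells$cell_id <- sprintf("sim%05d", seq_len(nrow(cells)))
        # Stage 2: per-type expression models on a capped subsample
        types <- unique(as.character(cells$cell_type))
        keep <- subsampleCells(cd$cell_type,
                               cap = p$max_cells_per_type_per_region)
        models <- lapply(types, function(t) {
            i <- intersect(keep, which(cd$cell_type == t))
            .assert(length(i) >= 2L,
                "reference has fewer than 2 cells of type %s", t)
            fitExpressionModel(counts_ref[, i, drop = FALSE], t,
                               use_correlation = p$use_correlation)
        })
        names(models) <- types
        sim_counts <- matrix(0L, nrow(counts_ref), nrow(cells),
                             dimnames = list(rownames(counts_ref),
                                             cells$cell_id))
        for (t in types) {
            i <- which(cells$cell_type == t)
            sim_counts[, i] <- drawCounts(models[[t]], length(i),
                                          depth_factor = p$depth_factor,
                                          use_correlation = p$use_correlation)
        }
        pspecs <- c(p$expression_cci_specs, p$gene_pair_cci_specs,
                    p$regional_specs)
        delta <- accumulateDelta(cells, pspecs, rownames(counts_ref))
        final <- applyDelta(sim_counts, delta, cap_max = p$cap_max_counts,
                            match_depth = p$match_depth)
        truth <- list(colocalization_specs = p$colocalization_specs,
                      perturbation_specs = pspecs,
                      delta_provenance = lapply(deltaProvenance(delta),
                          function(r) r[setdiff(names(r), "effects")]),
                      seed = p$seed)
        out <- list(cells = cells, counts = final, ground_truth = truth,
                    models = models, window = st1$window)
        if (p$output_resolution == "multi_cell") {
            out$spots <- aggregateMultiCell(cells$x, cells$y, final,
                                            st1$window, p$n_squares)
        }
        out
    })
}

#' Write the results of [simulateSRT()] to a directory
#'
#' @param sim result list from [simulateSRT()].
#' @param out_dir output directory.
#' @param resolution which resolution to write (defaults to what was
#'   simulated).
#' @return invisibly, the files written.
#' @export
writeSimulationResult <- function(sim, out_dir, resolution = NULL) {
    if (is.null(resolution))
        resolution <- if (!is.null(sim$spots)) "multi_cell" else "single_cell"
    if (resolution == "multi_cell") {
        .assert(!is.null(sim$spots), "simulation has no multi-cell output")
        ctr <- spotCenters(sim$spots)
        meta <- data.frame(spot_id = colnames(spotCounts(sim$spots)),
                           x = ctr[, 1L], y = ctr[, 2L],
                           n_cells = sim$spots@cellsPerSpot)
        writeSimulation(meta, spotCounts(sim$spots), out_dir,
                        resolution = "multi_cell",
                        ground_truth = sim$ground_truth)
    } else {
        writeSimulation(sim$cells, sim$counts, out_dir,
                        resolution = "single_cell",
                        ground_truth = sim$ground_truth)
    }
}
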