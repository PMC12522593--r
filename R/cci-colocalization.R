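#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Build a neighbor graph over cells
#'
#' Three strategies for defining neighboring cells on a slide:
#' \code{"knn"} (k-nearest neighbors, symmetrized: an edge exists if either
#' cell selects the other), \code{"delaunay"} (Delaunay triangulation
#' edges, optionally pruned of outlier edges exceeding the mean edge length
#' by \code{prune_sd} standard deviations), and \code{"distance"} (all
#' pairs closer than a radius).
#'
#' @param x,y cell coordinates (>= 2 cells).
#' @param method \code{"knn"}, \code{"delaunay"}, or \code{"distance"}.
#' @param parameter k for knn (>= 1, < number of cells); the radius for
#'   distance; ignored for delaunay.
#' @param prune_sd if non-NULL and method is delaunay, remove edges longer
#'   than mean + \code{prune_sd} * SD.
#' @return a \linkS4class{NeighborGraph}.
#' @examples
#' g <- buildNeighborGraph(c(0, 1, 2), c(0, 0, 0), "knn", 1)
#' graphEdges(g)
#' @export
buildNeighborGraph <- function(x, y, method = c("knn", "delaunay", "distance"),
                               parameter = NULL, prune_sd = NULL) {
    method <- match.arg(method)
    n <- length(x)
    .assert(n >= 2L, "need at least 2 cells")
    edges <- switch(method,
        knn = {
            k <- as.integer(parameter)
            .assert(!is.na(k) && k >= 1L, "knn needs parameter k >= 1")
            .assert(k < n, "k (%d) must be smaller than the number of cells (%d)",
                    k, n)
            nn <- FNN::get.knn(cbind(x, y), k = k)$nn.index
            e <- cbind(rep(seq_len(n), k), as.vector(nn))
            cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
        },
        distance = {
            r <- as.numeric(parameter)
            .assert(!is.na(r) && r > 0, "distance method needs a radius > 0")
            bb <- spatstat.geom::owin(range(x) + c(-r, r), range(y) + c(-r, r))
            pp <- spatstat.geom::ppp(x, y, window = bb, checkdup = FALSE)
            cp <- spatstat.geom::closepairs(pp, rmax = r, what = "indices",
                                            twice = FALSE)
            cbind(pmin(cp$i, cp$j), pmax(cp$i, cp$j))
        },
        delaunay = {
            .assert(n >= 3L, "delaunay needs at least 3 cells")
            dd <- deldir::deldir(x, y)
            e <- cbind(dd$delsgs$ind1, dd$delsgs$ind2)
            if (!is.null(prune_sd)) {
                len <- sqrt((x[e[, 1L]] - x[e[, 2L]])^2 +
                            (y[e[, 1L]] - y[e[, 2L]])^2)
                e <- e[len <= mean(len) + prune_sd * stats::sd(len), ,
                       drop = FALSE]
            }
            cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
        })
    edges <- unique(edges[edges[, 1L] != edges[, 2L], , drop = FALSE])
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    storage.mode(edges) <- "integer"
    new("NeighborGraph", method = method,
        parameter = if (is.null(parameter) || method == "delaunay")
            NA_real_ else as.numeric(parameter),
        edges = edges, n = as.integer(n))
}

#' Estimate cell-type colocalization by permutation enrichment
#'
#' For every unordered cell-type pair, counts how often the pair appears
#' across the edges of a neighbor graph, compares it with the expectation
#' under \code{n_perm} random shuffles of the cell-type labels, and reports
#' the enrichment score (log2 observed/expected neighbor frequency;
#' positive = attraction, negative = inhibition) with a two-sided
#' permutation p-value (probability of a permuted count as or more extreme
#' than observed, with the +1 correction). When either frequency is zero a
#' pseudo-count of 0.5 keeps the enrichment finite; such rows are flagged.
#' Types with no cells are skipped with a message.
#'
#' @param graph a \linkS4class{NeighborGraph}.
#' @param types cell-type label per cell (length \code{graph@n}).
#' @param n_perm number of label permutations (default 2000).
#' @param seed optional integer seed.
#' @return data.frame with columns \code{type_a}, \code{type_b},
#'   \code{observed}, \code{expected}, \code{enrichment}, \code{p_value},
#'   \code{pseudo}.
#' @export
estimateColocalization <- function(graph, types, n_perm = 2000L, seed = NULL) {
    .assert(length(types) == graph@n,
        "types length (%d) must match graph size (%d)", length(types), graph@n)
    f <- factor(types)
    .assert(nlevels(f) >= 2L, "need at least 2 cell types present")
    empty <- levels(f)[tabulate(f, nlevels(f)) == 0L]
    if (length(empty)) {
        message("skipping cell type(s) with no cells: ",
                paste(empty, collapse = ", "))
        f <- droplevels(f)
    }
    ti <- as.integer(f)
    TT <- nlevels(f)
    e <- graph@edges
    .assert(nrow(e) > 0L, "graph has no edges")
    key <- function(a, b) (pmin(a, b) - 1L) * TT + pmax(a, b)
    nkey <- TT * TT
    obs <- tabulate(key(ti[e[, 1L]], ti[e[, 2L]]), nkey)
    .with_seed(seed, {
        perm <- matrix(0L, n_perm, nkey)
        for (p in seq_len(n_perm)) {
            tp <- ti[sample.int(length(ti))]
            perm[p, ] <- tabulate(key(tp[e[, 1L]], tp[e[, 2L]]), nkey)
        }
        pairs <- which(upper.tri(matrix(0, TT, TT), diag = TRUE),
                       arr.ind = TRUE)
        out <- lapply(seq_len(nrow(pairs)), function(r) {
            a <- pairs[r, 1L]; b <- pairs[r, 2L]
            k <- key(a, b)
            o <- obs[k]; ex <- mean(perm[, k])
            pseudo <- (o == 0L || ex == 0)
            enr <- if (pseudo) log2((o + 0.5) / (ex + 0.5)) else log2(o / ex)
            pv <- (1 + sum(abs(perm[, k] - ex) >= abs(o - ex))) / (n_perm + 1)
            data.frame(type_a = levels(f)[a], type_b = levels(f)[b],
                       observed = o, expected = ex, enrichment = enr,
                       p_value = pv, pseudo = pseudo)
        })
        do.call(rbind, out)
    })
}

#' Pool inflation ratio for CCI-aware cell selection
#'
#' Computes the inflation ratio lambda = (sum_j eta (1 + |a_j|))^(1 + nu)
#' over the colocalization patterns j with strengths a_j; the cell pool
#' from which cells are later selected has size ceiling(lambda * target).
#' Stronger attraction/inhibition, greater required evenness, and a larger
#' inflation parameter all enlarge the pool. With no patterns the empty sum
#' degenerates and lambda = max(1, eta^(1 + nu)); a ratio below 1 is
#' clamped to 1 with a warning (the pool cannot be smaller than the
#' target).
#'
#' @param strengths numeric vector of colocalization strengths a_j (may be
#'   empty).
#' @param eta inflation parameter (> 0; default 1.5).
#' @param nu evenness parameter (default 0).
#' @return the scalar inflation ratio.
#' @examples
#' computeInflationRatio(3, eta = 2)     # 2 * (1 + 3) = 8
#' computeInflationRatio(1, eta = 1, nu = 1)  # (1 * 2)^2 = 4
#' @export
computeInflationRatio <- function(strengths = numeric(0), eta = 1.5, nu = 0) {
    .assert(eta > 0, "eta must be positive")
    lam <- if (length(strengths) == 0L) max(1, eta^(1 + nu))
        else (sum(eta * (1 + abs(strengths))))^(1 + nu)
    if (lam < 1) {
        warning("inflation ratio ", format(lam),
                " clamped to 1 (pool cannot be smaller than the target)",
                call. = FALSE)
        lam <- 1
    }
    lam
}

# Neighborhood densities on a pool graph, normalized to be scale-free:
# d[i, t] = (type-t neighbors of cell i) / (pool-mean type-t neighbor
# count), i.e. the local density of type t relative to its slide-wide
# average; dstar[i] = degree / mean degree. A unit strength then moves the
# selection log-odds by one for each relative-density unit.
.neighborhood_densities <- function(edges, ti, TT, n) {
    deg <- tabulate(c(edges[, 1L], edges[, 2L]), n)
    if (nrow(edges)) {
        ci <- c(edges[, 1L], edges[, 2L])          # cell
        tt <- c(ti[edges[, 2L]], ti[edges[, 1L]])  # neighbor's type
        cnt <- matrix(tabulate((tt - 1L) * n + ci, n * TT), n, TT)
    } else cnt <- matrix(0, n, TT)
    d <- sweep(cnt, 2L, pmax(colMeans(cnt), 1e-12), "/")
    dstar <- if (mean(deg) > 0) deg / mean(deg) else rep(0, n)
    list(d = d, dstar = dstar)
}

# Relative densities of pool cells against a reference configuration:
# among the k nearest reference cells of each pool cell, the count of each
# type divided by its pool-wide mean count.
.densities_vs_reference <- function(cells, ref, levels_f, k) {
    k <- min(as.integer(k), nrow(ref))
    nn <- FNN::get.knnx(cbind(ref$x, ref$y), cbind(cells$x, cells$y),
                        k = k)$nn.index
    ti_ref <- match(ref$cell_type, levels_f)
    n <- nrow(cells); TT <- length(levels_f)
    tt <- matrix(ti_ref[nn], n, k)
    cnt <- vapply(seq_len(TT), function(t) rowSums(tt == t), numeric(n))
    d <- sweep(cnt, 2L, pmax(colMeans(cnt), 1e-12), "/")
    deg <- rep(k, n)
    list(d = d, dstar = deg / mean(deg))
}

#' Select cells from an inflated pool under colocalization constraints
#'
#' Implements CCI-aware cell selection. Neighborhood densities are
#' computed on the pool, and each cell i of type c receives a selection
#' probability on the logit scale,
#' logit(Prob_ic) = mu1 + mu2 + mu3 + alpha_c, where mu1 accumulates
#' same-type attraction/inhibition (sum of a_j * d_{i, c_j} over same-type
#' patterns), mu2 accumulates cross-type effects (a*_j * d_{i, l_j}), mu3 =
#' d*_i * alpha_star controls cell-distribution evenness, and the
#' per-type nuisance alpha_c is solved numerically (monotone 1-D root
#' finding) so the mean selection probability of type c equals
#' target_c / pool_c. Exactly target_c cells per type are then sampled
#' without replacement with probability proportional to the remaining
#' weights.
#'
#' Densities d are relative local densities: the count of type-t cells in
#' the neighborhood divided by its pool-wide mean, so strengths are
#' scale-free. With \code{iterations > 1} the selection is made
#' self-consistent: after the first draw, densities are recomputed for
#' every pool cell against the previously selected configuration and the
#' selection is redrawn. This coordinates mutual attraction between types
#' (each type concentrates where the other actually ended up, not where
#' the pool happened to fluctuate) and sharpens planted patterns.
#'
#' @param pool a \linkS4class{CellPool}.
#' @param specs list of colocalization specs, each a named list with
#'   \code{type_a}, \code{type_b}, \code{strength} (attraction > 0,
#'   inhibition < 0).
#' @param targets named integer vector: cells to select per type; each must
#'   not exceed the pool count of that type.
#' @param alpha_star evenness weight (default 0).
#' @param neighbor_method,neighbor_param graph construction on the pool
#'   (defaults: knn with k = 6).
#' @param iterations self-consistency iterations (default 3).
#' @param contact_k neighborhood size (nearest configuration cells) for the
#'   iterated densities; small by design, reflecting the cell-contact scale
#'   at which colocalization acts (default 3). This knob calibrates the
#'   planted signal level.
#' @param seed optional integer seed.
#' @return a \linkS4class{CellPool} of the selected cells, with the
#'   selection probabilities in column \code{selection_prob}.
#' @export
selectCellsWithCCI <- function(pool, specs = list(), targets,
                               alpha_star = 0, neighbor_method = "knn",
                               neighbor_param = 6, iterations = 3L,
                               contact_k = 3L, seed = NULL) {
    cells <- as.data.frame(pool@cells)
    n <- nrow(cells)
    f <- factor(cells$cell_type)
    ti <- as.integer(f); TT <- nlevels(f)
    pool_n <- tabulate(ti, TT)
    .assert(all(names(targets) %in% levels(f)),
        "targets name cell types absent from the pool")
    tg <- structure(rep(0L, TT), names = levels(f))
    tg[names(targets)] <- as.integer(targets)
    .assert(all(tg <= pool_n),
        "pool has fewer cells than the target for some type")
    for (s in specs)
        .assert(s$type_a %in% levels(f) && s$type_b %in% levels(f),
            "colocalization spec names unknown cell type(s)")
    if (length(specs) == 0L) iterations <- 1L
    g <- buildNeighborGraph(cells$x, cells$y, neighbor_method, neighbor_param)
    kdens <- max(1L, as.integer(contact_k))
    nd_pool <- .neighborhood_densities(g@edges, ti, TT, n)
    # per-type logit from densities nd (nd_inh used for same-type
    # inhibition: anchored to the static pool so self-avoidance cannot
    # oscillate between complementary patterns across iterations)
    type_base <- function(k, nd, nd_inh) {
        i <- which(ti == k)
        b <- nd$dstar[i] * alpha_star                   # mu3
        for (s in specs) {
            a <- s$strength
            ia <- match(s$type_a, levels(f)); ib <- match(s$type_b, levels(f))
            if (ia == ib && ia == k) {                  # mu1: same-type
                src <- if (a < 0) nd_inh else nd
                b <- b + a * src$d[i, ia]
            } else if (ia == k && ib != k) {            # mu2: cross-type
                b <- b + a * nd$d[i, ib]
            } else if (ib == k && ia != k) {
                b <- b + a * nd$d[i, ia]
            }
        }
        b
    }
    solve_and_draw <- function(k, b) {
        i <- which(ti == k)
        ratio <- tg[k] / pool_n[k]
        if (tg[k] == 0L) return(list(idx = integer(0), prob = numeric(0)))
        if (tg[k] == pool_n[k]) return(list(idx = i, prob = rep(1, length(i))))
        fk <- function(alpha) mean(stats::plogis(b + alpha)) - ratio
        sol <- stats::uniroot(fk, lower = -50, upper = 50, tol = 1e-12,
                              extendInt = "upX")
        prob <- stats::plogis(b + sol$root)
        .assert(any(prob > 0),
            "unsolvable selection weights (all zero) for type %s", levels(f)[k])
        drawn <- i[sample.int(length(i), tg[k], prob = prob)]
        list(idx = drawn, prob = prob[match(drawn, i)])
    }
    .with_seed(seed, {
        # pass 1: densities from the pool itself
        picks <- lapply(seq_len(TT), function(k)
            solve_and_draw(k, type_base(k, nd_pool, nd_pool)))
        # later passes: Gauss-Seidel, each type re-drawn against the
        # current configuration (immediately updated)
        for (it in seq_len(max(0L, iterations - 1L))) {
            for (k in seq_len(TT)) {
                cur <- cells[unlist(lapply(picks, `[[`, "idx")), ,
                             drop = FALSE]
                nd_cur <- .densities_vs_reference(cells, cur, levels(f),
                                                  kdens)
                picks[[k]] <- solve_and_draw(k, type_base(k, nd_cur, nd_pool))
            }
        }
        sel <- unlist(lapply(picks, `[[`, "idx"))
        out <- cells[sort(sel), , drop = FALSE]
        out$selection_prob <-
            unlist(lapply(picks, `[[`, "prob"))[order(sel)]
        rownames(out) <- NULL
        new("CellPool", cells = DataFrame(out))
    })
}
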