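#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Estimate CCI effects on spatial dependence of gene expression
#'
#' For one ordered sender -> receiver cell-type pair, splits the receiver
#' cells into those with at least one sender neighbor (by the supplied
#' graph) and those with none, and reports, per gene, the enrichment score
#' log2 fold change of mean expression between the two groups (a
#' pseudo-count of 1 on the group means guards sparse genes), with a
#' permutation p-value obtained by shuffling the neighbor/non-neighbor
#' assignment among the receiver cells.
#'
#' @param counts gene x cell integer matrix.
#' @param cell_types cell-type label per cell (columns of \code{counts}).
#' @param graph a \linkS4class{NeighborGraph} on the same cells.
#' @param sender,receiver cell-type names.
#' @param n_perm permutations (default 1000).
#' @param seed optional integer seed.
#' @return data.frame with columns \code{sender_type}, \code{receiver_type},
#'   \code{gene}, \code{log2fc}, \code{p_value}; zero rows (with a message)
#'   when either group has fewer than 2 cells.
#' @export
estimateSpatialDependence <- function(counts, cell_types, graph, sender,
                                      receiver, n_perm = 1000L, seed = NULL) {
    .assert(ncol(counts) == graph@n, "counts and graph sizes differ")
    .assert(all(c(sender, receiver) %in% cell_types),
        "sender/receiver type absent from the data")
    e <- graph@edges
    is_send <- cell_types == sender
    has_sender <- logical(ncol(counts))
    has_sender[e[is_send[e[, 2L]], 1L]] <- TRUE
    has_sender[e[is_send[e[, 1L]], 2L]] <- TRUE
    recv <- which(cell_types == receiver)
    nb <- recv[has_sender[recv]]
    non <- setdiff(recv, nb)
    if (length(nb) < 2L || length(non) < 2L) {
        message("skipping ", sender, " -> ", receiver,
                ": neighbor/non-neighbor receiver group too small (",
                length(nb), "/", length(non), ")")
        return(data.frame(sender_type = character(0),
                          receiver_type = character(0), gene = character(0),
                          log2fc = numeric(0), p_value = numeric(0)))
    }
    R <- counts[, recv, drop = FALSE]
    m <- length(recv); k <- length(nb)
    ind_obs <- recv %in% nb
    l2fc <- function(ind) {
        m1 <- R %*% ind / sum(ind)
        m0 <- R %*% (1 - ind) / sum(1 - ind)
        log2((m1 + 1) / (m0 + 1))
    }
    obs <- drop(l2fc(as.numeric(ind_obs)))
    .with_seed(seed, {
        IND <- vapply(seq_len(n_perm), function(p) {
            z <- numeric(m); z[sample.int(m, k)] <- 1; z
        }, numeric(m))
        M1 <- R %*% IND / k
        M0 <- R %*% (1 - IND) / (m - k)
        permL <- log2((M1 + 1) / (M0 + 1))
        pv <- (1 + rowSums(abs(permL) >= abs(obs))) / (n_perm + 1)
        data.frame(sender_type = sender, receiver_type = receiver,
                   gene = rownames(counts), log2fc = obs, p_value = pv,
                   row.names = NULL)
    })
}

#' Estimate CCI effects on gene-gene interactions between neighboring cells
#'
#' For each ligand-receptor gene pair (m, n) and one ordered sender ->
#' receiver type pair, compares the mean product of gene m in the sender
#' cell and gene n in the receiver cell over adjacent sender-receiver cell
#' pairs against non-adjacent pairs, as the enrichment score log2 fold
#' change of the product (pseudo-count 1 on the means). Permutation
#' p-values come from redrawing the adjacent pair set at random. Pairs with
#' a gene absent from the matrix are skipped with a message. The gene-pair
#' list keeps the number of tests manageable; bundled or user-supplied LR
#' lists both work.
#'
#' @param counts gene x cell integer matrix.
#' @param cell_types cell-type label per cell.
#' @param graph a \linkS4class{NeighborGraph}.
#' @param pair_list data.frame whose first two columns are the sender-side
#'   and receiver-side gene of each pair.
#' @param sender,receiver cell-type names.
#' @param n_perm permutations (default 1000).
#' @param seed optional integer seed.
#' @return data.frame with columns \code{sender_type}, \code{receiver_type},
#'   \code{gene_m}, \code{gene_n}, \code{log2fc_product}, \code{p_value}.
#' @export
estimateGenePairCCI <- function(counts, cell_types, graph, pair_list, sender,
                                receiver, n_perm = 1000L, seed = NULL) {
    .assert(ncol(counts) == graph@n, "counts and graph sizes differ")
    empty <- data.frame(sender_type = character(0),
                        receiver_type = character(0), gene_m = character(0),
                        gene_n = character(0), log2fc_product = numeric(0),
                        p_value = numeric(0))
    if (nrow(pair_list) == 0L) return(empty)
    S <- which(cell_types == sender); Rc <- which(cell_types == receiver)
    .assert(length(S) > 0L && length(Rc) > 0L,
        "sender/receiver type absent from the data")
    e <- graph@edges
    keep <- (cell_types[e[, 1L]] == sender & cell_types[e[, 2L]] == receiver) |
            (cell_types[e[, 2L]] == sender & cell_types[e[, 1L]] == receiver)
    ep <- e[keep, , drop = FALSE]
    swap <- cell_types[ep[, 1L]] != sender
    adj_s <- ifelse(swap, ep[, 2L], ep[, 1L])
    adj_r <- ifelse(swap, ep[, 1L], ep[, 2L])
    n_adj <- length(adj_s)
    n_self <- if (sender == receiver) length(S) else 0L
    N_tot <- length(S) * length(Rc) - n_self
    if (n_adj < 2L || N_tot - n_adj < 2L) {
        message("skipping ", sender, " -> ", receiver,
                ": too few adjacent or non-adjacent cell pairs")
        return(empty)
    }
    .with_seed(seed, {
        sidx <- matrix(sample(S, n_adj * n_perm, replace = TRUE), n_adj)
        ridx <- matrix(sample(Rc, n_adj * n_perm, replace = TRUE), n_adj)
        out <- lapply(seq_len(nrow(pair_list)), function(r) {
            gm <- as.character(pair_list[r, 1L])
            gn <- as.character(pair_list[r, 2L])
            if (!gm %in% rownames(counts) || !gn %in% rownames(counts)) {
                message("skipping pair ", gm, " - ", gn,
                        ": gene absent from the matrix")
                return(NULL)
            }
            ym <- counts[gm, ]; yn <- counts[gn, ]
            tot <- sum(ym[S]) * sum(yn[Rc]) -
                if (n_self) sum(ym[S] * yn[S]) else 0
            sum_adj <- sum(ym[adj_s] * yn[adj_r])
            m1 <- sum_adj / n_adj
            m0 <- (tot - sum_adj) / (N_tot - n_adj)
            obs <- log2((m1 + 1) / (m0 + 1))
            pm <- matrix(ym[sidx] * yn[ridx], n_adj)
            s1 <- colSums(pm) / n_adj
            s0 <- (tot - colSums(pm)) / (N_tot - n_adj)
            permL <- log2((s1 + 1) / (s0 + 1))
            pv <- (1 + sum(abs(permL) >= abs(obs))) / (n_perm + 1)
            data.frame(sender_type = sender, receiver_type = receiver,
                       gene_m = gm, gene_n = gn, log2fc_product = obs,
                       p_value = pv)
        })
        out <- Filter(Negate(is.null), out)
        if (length(out)) do.call(rbind, out) else empty
    })
}

# cells of perturbed type k in region r with a type-l cell within distance c
.qualifying_cells <- function(cells, k_type, l_type, dist_thr, region = NULL) {
    ki <- which(cells$cell_type == k_type &
                (if (is.null(region)) TRUE else cells$region %in% region))
    li <- which(cells$cell_type == l_type)
    if (!length(ki) || !length(li)) return(integer(0))
    nn <- FNN::get.knnx(cbind(cells$x[li], cells$y[li]),
                        cbind(cells$x[ki], cells$y[ki]), k = 1L)
    ki[nn$nn.dist[, 1L] <= dist_thr]
}

.resolve_genes <- function(spec, genes, what = "genes") {
    if (!is.null(spec[[what]])) {
        g <- as.character(unlist(spec[[what]]))
        miss <- setdiff(g, genes)
        .assert(length(miss) == 0L, "unknown gene(s): %s",
                paste(miss, collapse = ", "))
        match(g, genes)
    } else {
        frac <- spec$gene_fraction
        .assert(!is.null(frac) && frac > 0 && frac <= 1,
            "spec needs either genes or gene_fraction in (0, 1]")
        sort(sample.int(length(genes), max(1L, round(frac * length(genes)))))
    }
}

#' Accumulate the cumulative perturbation matrix
#'
#' Builds the n_cells x n_genes change matrix on the log-count scale: it
#' starts at zero and, for each perturbation spec in turn, adds effect
#' sizes drawn from N(effect_mean, effect_sd^2) at the affected
#' (cell, gene) positions:
#' \describe{
#'   \item{spatial_dependence}{cells of \code{perturbed_type} in
#'     \code{region} (if given) having a \code{neighbor_type} cell within
#'     \code{distance_threshold} get independent draws at the spec's genes;}
#'   \item{gene_pair}{qualifying perturbed-type cells get one draw at
#'     \code{gene_m}; if \code{bidirectional}, qualifying neighbor-type
#'     cells get the same drawn value (shared with their nearest qualifying
#'     partner) at \code{gene_n};}
#'   \item{regional}{all perturbed-type cells in \code{region} get
#'     independent draws at the spec's genes.}
#' }
#' Genes may be named explicitly or drawn as a \code{gene_fraction} of the
#' gene universe (uniformly without replacement, seeded, recorded in the
#' provenance). Effects from overlapping specs add. Unknown genes, types
#' or regions raise an error before any mutation.
#'
#' @param cells data.frame with columns \code{x}, \code{y},
#'   \code{cell_type}, and (when region-restricted specs are used)
#'   \code{region}.
#' @param specs list of perturbation specs; each a named list with
#'   \code{kind} ("spatial_dependence", "gene_pair", "regional") and the
#'   fields above (\code{effect_sd} defaults to 0).
#' @param genes character vector: the gene universe (row order of the
#'   count matrix the matrix will be applied to).
#' @param seed optional integer seed.
#' @return a \linkS4class{DeltaMatrix}.
#' @export
accumulateDelta <- function(cells, specs = list(), genes, seed = NULL) {
    cells <- as.data.frame(cells)
    n <- nrow(cells); G <- length(genes)
    delta <- matrix(0, n, G, dimnames = list(NULL, genes))
    prov <- list()
    all_types <- unique(as.character(cells$cell_type))
    all_regions <- if ("region" %in% colnames(cells))
        unique(as.character(cells$region)) else character(0)
    for (s in specs) {   # validate everything before mutating
        .assert(!is.null(s$kind) &&
                s$kind %in% c("spatial_dependence", "gene_pair", "regional"),
            "spec kind must be spatial_dependence, gene_pair or regional")
        .assert(s$perturbed_type %in% all_types,
            "unknown perturbed_type '%s'", s$perturbed_type)
        if (s$kind != "regional")
            .assert(s$neighbor_type %in% all_types,
                "unknown neighbor_type '%s'", s$neighbor_type)
        if (!is.null(s$region))
            .assert(all(s$region %in% all_regions),
                "unknown region in spec")
        for (gg in c(s$genes, s$gene_m, s$gene_n))
            .assert(all(as.character(unlist(gg)) %in% genes),
                "unknown gene(s) in spec")
    }
    .with_seed(seed, {
        for (si in seq_along(specs)) {
            s <- specs[[si]]
            mu <- s$effect_mean
            sdv <- if (is.null(s$effect_sd)) 0 else s$effect_sd
            if (s$kind == "regional") {
                gi <- .resolve_genes(s, genes)
                ci <- which(cells$cell_type == s$perturbed_type &
                            (if (is.null(s$region)) TRUE else
                             cells$region %in% s$region))
                eff <- matrix(stats::rnorm(length(ci) * length(gi), mu, sdv),
                              length(ci), length(gi))
                delta[ci, gi] <- delta[ci, gi] + eff
                prov[[si]] <- list(kind = s$kind, cells = ci,
                                   genes = genes[gi], effects = eff)
            } else if (s$kind == "spatial_dependence") {
                gi <- .resolve_genes(s, genes)
                ci <- .qualifying_cells(cells, s$perturbed_type,
                                        s$neighbor_type,
                                        s$distance_threshold, s$region)
                eff <- matrix(stats::rnorm(length(ci) * length(gi), mu, sdv),
                              length(ci), length(gi))
                if (length(ci)) delta[ci, gi] <- delta[ci, gi] + eff
                prov[[si]] <- list(kind = s$kind, cells = ci,
                                   genes = genes[gi], effects = eff)
            } else {  # gene_pair
                gm <- match(as.character(s$gene_m), genes)
                gn <- match(as.character(s$gene_n), genes)
                ci <- .qualifying_cells(cells, s$perturbed_type,
                                        s$neighbor_type,
                                        s$distance_threshold, s$region)
                eff <- stats::rnorm(length(ci), mu, sdv)
                if (length(ci)) delta[ci, gm] <- delta[ci, gm] + eff
                rec <- list(kind = s$kind, cells = ci,
                            genes = genes[gm], effects = eff)
                if (isTRUE(s$bidirectional)) {
                    cj <- .qualifying_cells(cells, s$neighbor_type,
                                            s$perturbed_type,
                                            s$distance_threshold, s$region)
                    if (length(cj) && length(ci)) {
                        # partner draw: nearest qualifying perturbed-type cell
                        nn <- FNN::get.knnx(
                            cbind(cells$x[ci], cells$y[ci]),
                            cbind(cells$x[cj], cells$y[cj]), k = 1L)
                        eff2 <- eff[nn$nn.index[, 1L]]
                        delta[cj, gn] <- delta[cj, gn] + eff2
                        rec$cells_bidir <- cj
                        rec$genes_bidir <- genes[gn]
                        rec$effects_bidir <- eff2
                    }
                }
                prov[[si]] <- rec
            }
        }
    })
    new("DeltaMatrix", values = delta, provenance = prov)
}

#' Apply the perturbation matrix to initial counts
#'
#' Updates the initial read counts with the cumulative log-scale changes:
#' updated = expm1(log1p(initial) + Delta), floored at zero (so a negative
#' perturbation cannot push a zero count below zero, while a positive one
#' can lift it), optionally capped at max(5 x the 97.5th percentile of all
#' initial entries, max(initial)) to bound extreme genes, optionally
#' rescaled by total(initial)/total(updated) to match the initial
#' sequencing depth, and finally rounded to the nearest integer.
#'
#' @param initial gene x cell integer matrix.
#' @param delta a \linkS4class{DeltaMatrix} (cells x genes) or a numeric
#'   matrix in the same orientation.
#' @param cap_max cap extreme values (default FALSE).
#' @param match_depth rescale to the initial total count (default FALSE).
#' @return gene x cell integer matrix.
#' @examples
#' m <- matrix(10L, 1, 1)
#' applyDelta(m, matrix(0.5, 1, 1))  # round(11 * exp(0.5) - 1) = 17
#' @export
applyDelta <- function(initial, delta, cap_max = FALSE, match_depth = FALSE) {
    dv <- if (is(delta, "DeltaMatrix")) delta@values else delta
    .assert(nrow(initial) == ncol(dv) && ncol(initial) == nrow(dv),
        "initial (genes x cells) and delta (cells x genes) are not conformable")
    upd <- expm1(log1p(initial) + t(dv))
    upd[upd < 0] <- 0
    if (cap_max) {
        cap <- max(5 * stats::quantile(initial, 0.975), max(initial))
        upd[upd > cap] <- cap
    }
    if (match_depth) {
        tot <- sum(upd)
        if (tot > 0) upd <- upd * (sum(initial) / tot)
    }
    out <- .round_half_up(upd)
    if (match_depth && sum(out) != sum(initial) && sum(out) > 0) {
        # largest-remainder correction so rounding cannot drift the depth
        r <- sum(initial) - sum(out)
        if (r > 0) {
            i <- order(upd - out, decreasing = TRUE)[seq_len(r)]
            out[i] <- out[i] + 1
        } else {
            elig <- which(out > 0)
            i <- elig[order(out[elig] - upd[elig],
                            decreasing = TRUE)][seq_len(min(-r, length(elig)))]
            out[i] <- out[i] - 1
        }
    }
    storage.mode(out) <- "integer"
    dimnames(out) <- dimnames(initial)
    out
}

#' Write / read perturbation specs as TSV
#'
#' Estimated effects and de novo patterns are interchangeable inputs; this
#' pair of helpers round-trips a spec list through a flat TSV whose columns
#' mirror the spec fields.
#'
#' @param specs list of perturbation specs (see [accumulateDelta()]).
#' @param path TSV path.
#' @export
writePerturbationSpecs <- function(specs, path) {
    rows <- lapply(specs, function(s) data.frame(
        kind = s$kind,
        region = if (is.null(s$region)) NA else
            paste(s$region, collapse = ","),
        perturbed_type = s$perturbed_type,
        neighbor_type = if (is.null(s$neighbor_type)) NA else s$neighbor_type,
        distance_threshold = if (is.null(s$distance_threshold)) NA else
            s$distance_threshold,
        genes = if (is.null(s$genes)) NA else
            paste(unlist(s$genes), collapse = ","),
        gene_fraction = if (is.null(s$gene_fraction)) NA else s$gene_fraction,
        gene_m = if (is.null(s$gene_m)) NA else s$gene_m,
        gene_n = if (is.null(s$gene_n)) NA else s$gene_n,
        bidirectional = isTRUE(s$bidirectional),
        effect_mean = s$effect_mean,
        effect_sd = if (is.null(s$effect_sd)) 0 else s$effect_sd))
    utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writePerturbationSpecs
#' @export
readPerturbationSpecs <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(tab)), function(i) {
        r <- tab[i, ]
        s <- list(kind = r$kind, perturbed_type = r$perturbed_type,
                  effect_mean = r$effect_mean, effect_sd = r$effect_sd)
        if (!is.na(r$region)) s$region <- strsplit(r$region, ",")[[1L]]
        if (!is.na(r$neighbor_type)) s$neighbor_type <- r$neighbor_type
        if (!is.na(r$distance_threshold))
            s$distance_threshold <- r$distance_threshold
        if (!is.na(r$genes)) s$genes <- strsplit(r$genes, ",")[[1L]]
        if (!is.na(r$gene_fraction)) s$gene_fraction <- r$gene_fraction
        if (!is.na(r$gene_m)) s$gene_m <- r$gene_m
        if (!is.na(r$gene_n)) s$gene_n <- r$gene_n
        if (isTRUE(r$bidirectional)) s$bidirectional <- TRUE
        s
    })
}
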