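# Shared fixtures and independent oracles for the test suite.

# Independent flood-fill connectivity oracle (queue-based; deliberately a
# different implementation from anything in the package).
flood_connected <- function(mask) {
    cells <- which(mask, arr.ind = TRUE)
    if (nrow(cells) <= 1L) return(TRUE)
    key <- function(i, j) paste(i, j)
    todo <- list(cells[1L, ])
    seen <- new.env()
    assign(key(cells[1L, 1L], cells[1L, 2L]), TRUE, envir = seen)
    while (length(todo)) {
        cur <- todo[[1L]]; todo <- todo[-1L]
        for (d in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
            i <- cur[1L] + d[1L]; j <- cur[2L] + d[2L]
            if (i < 1L || j < 1L || i > nrow(mask) || j > ncol(mask)) next
            if (!mask[i, j]) next
            if (!is.null(seen[[key(i, j)]])) next
            assign(key(i, j), TRUE, envir = seen)
            todo <- c(todo, list(c(i, j)))
        }
    }
    length(ls(seen)) == nrow(cells)
}

# Two-type spatial map with NB baseline counts and a planted neighbor
# effect: receivers (type B) with a sender (type A) within `radius` get
# `mu` added on the log1p scale for the first `n_genes_hit` genes.
planted_expression_fixture <- function(n_cells = 400, n_genes = 40,
                                       mu = 0.5, radius = 0.06,
                                       n_genes_hit = 10, seed = 1) {
    withr::with_seed(seed, {
        cells <- data.frame(
            x = runif(n_cells), y = runif(n_cells),
            cell_type = rep(c("A", "B"), length.out = n_cells),
            region = "1")
        genes <- sprintf("g%02d", seq_len(n_genes))
        counts <- matrix(rnbinom(n_genes * n_cells, mu = 5, size = 2),
                         n_genes, n_cells,
                         dimnames = list(genes, sprintf("c%d", 1:n_cells)))
        spec <- list(kind = "spatial_dependence", perturbed_type = "B",
                     neighbor_type = "A", distance_threshold = radius,
                     genes = genes[seq_len(n_genes_hit)],
                     effect_mean = mu, effect_sd = 0)
        dl <- accumulateDelta(cells, list(spec), genes)
        list(cells = cells, initial = counts,
             counts = applyDelta(counts, dl), delta = dl, spec = spec,
             genes = genes)
    })
}

# Map with a planted same-type cluster: type "A" cells concentrated in a
# corner blob, other types uniform.
clustered_map_fixture <- function(n_clustered = 60, n_background = 140,
                                  seed = 1) {
    withr::with_seed(seed, {
        data.frame(
            x = c(runif(n_clustered, 0, 0.25), runif(n_background)),
            y = c(runif(n_clustered, 0, 0.25), runif(n_background)),
            cell_type = c(rep("A", n_clustered),
                          rep(c("B", "C"), length.out = n_background)))
    })
}
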