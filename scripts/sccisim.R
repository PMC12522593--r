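#!/usr/bin/env Rscript
# Command-line front end.
#
#   Rscript scripts/sccisim.R simulate --config FILE --out DIR [--seed N]
#   Rscript scripts/sccisim.R estimate --config FILE --expression F \
#           --metadata F --out DIR [--lr-pairs F]
#   Rscript scripts/sccisim.R fixtures --scenario S --out DIR [--seed N]
#
# `simulate` reads a YAML parameter file plus the reference files named in
# it (keys expression_path, metadata_path, optional spatial_path), runs the
# two-stage simulation, and writes metadata/counts/ground truth.
# `estimate` runs the CCI estimators on a paired reference and writes the
# estimated parameter tables. `fixtures` writes a synthetic reference
# bundle with known ground truth.

suppressPackageStartupMessages(library(SpatialCCIsim))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
    stop("usage: sccisim.R <simulate|estimate|fixtures> [options]")
cmd <- args[1L]; args <- args[-1L]
opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}

if (cmd == "simulate") {
    cfg_path <- opt("--config"); out_dir <- opt("--out", "sim_out")
    stopifnot(!is.null(cfg_path))
    cfg <- readConfig(cfg_path)
    seed <- opt("--seed")
    if (!is.null(seed)) cfg@params$seed <- as.integer(seed)
    raw <- yaml::read_yaml(cfg_path)
    stopifnot(!is.null(raw$expression_path), !is.null(raw$metadata_path))
    ref <- readReference(raw$expression_path, raw$metadata_path,
                         raw$spatial_path)
    sim <- simulateSRT(ref, cfg)
    writeSimulationResult(sim, out_dir)
    cat("simulated", nrow(sim$cells), "cells x", nrow(sim$counts),
        "genes ->", out_dir, "\n")
} else if (cmd == "estimate") {
    out_dir <- opt("--out", "estimates")
    expr <- opt("--expression"); meta <- opt("--metadata")
    if (is.null(expr)) {   # allow the paths to come from a config file
        raw <- yaml::read_yaml(opt("--config"))
        expr <- raw$expression_path; meta <- raw$metadata_path
    }
    ref <- readReference(expr, meta)
    lr <- opt("--lr-pairs")
    lr_tab <- if (!is.null(lr)) utils::read.delim(lr) else NULL
    est <- estimateCCI(ref, lr_pairs = lr_tab,
                       seed = as.integer(opt("--seed", "1")))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(est$colocalization,
                       file.path(out_dir, "colocalization.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(est$spatial_dependence,
                       file.path(out_dir, "spatial_dependence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(est$gene_pair))
        utils::write.table(est$gene_pair,
                           file.path(out_dir, "gene_pair.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    cat("estimates written to", out_dir, "\n")
} else if (cmd == "fixtures") {
    sc <- opt("--scenario", "paired"); out_dir <- opt("--out", "fixture")
    seed <- as.integer(opt("--seed", "1"))
    fx <- generateReference(sc, seed = seed)
    counts <- SummarizedExperiment::assay(fx$reference, "counts")
    writeSimulation(as.data.frame(cellMeta(fx$reference)), counts, out_dir,
                    ground_truth = fx$truth[c("scenario", "targets", "seed")])
    if (sc == "unpaired")
        utils::write.table(as.data.frame(spatialCells(fx$reference)),
                           file.path(out_dir, "spatial_cells.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    cat("fixture (", sc, ") written to ", out_dir, "\n", sep = "")
} else {
    stop("unknown subcommand: ", cmd)
}
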