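#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a CCIReference from in-memory objects
#'
#' @param counts gene x cell non-negative integer matrix with row (gene) and
#'   column (cell) names.
#' @param cells data.frame/DataFrame of per-cell metadata with at least
#'   \code{cell_id} and \code{cell_type}; optional \code{x}, \code{y},
#'   \code{region}.
#' @param spatialCells optional data.frame of an unpaired spatial reference
#'   (\code{cell_id}, \code{cell_type}, \code{x}, \code{y}, optional
#'   \code{region}).
#' @param scenario one of \code{"paired"}, \code{"expression_only"},
#'   \code{"unpaired"}; if \code{NULL}, inferred: a spatial table forces
#'   \code{"unpaired"}, complete x/y columns force \code{"paired"}, otherwise
#'   \code{"expression_only"}.
#' @return a validated \linkS4class{CCIReference}.
#' @export
CCIReference <- function(counts, cells, spatialCells = NULL, scenario = NULL) {
    counts <- as.matrix(counts)
    cells <- as.data.frame(cells)
    .assert(ncol(counts) == nrow(cells),
        "counts has %d cells (columns) but metadata has %d rows",
        ncol(counts), nrow(cells))
    .assert("cell_type" %in% colnames(cells),
        "cell metadata must contain a 'cell_type' column")
    if (!"cell_id" %in% colnames(cells))
        cells$cell_id <- if (!is.null(colnames(counts))) colnames(counts) else
            sprintf("cell%d", seq_len(nrow(cells)))
    if (is.null(colnames(counts))) colnames(counts) <- cells$cell_id
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("gene%d", seq_len(nrow(counts)))
    if (is.null(scenario)) {
        scenario <- if (!is.null(spatialCells)) "unpaired"
            else if (all(c("x", "y") %in% colnames(cells)) &&
                     !anyNA(cells$x) && !anyNA(cells$y)) "paired"
            else "expression_only"
    }
    spc <- if (is.null(spatialCells)) DataFrame() else DataFrame(as.data.frame(spatialCells))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = DataFrame(cells))
    new("CCIReference", se, scenario = scenario, spatialCells = spc)
}

.read_table <- function(path, ...) {
    .assert(file.exists(path), "file not found: %s", path)
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE, ...)
}

.read_counts <- function(path) {
    if (grepl("\\.mtx$", path)) {
        m <- as.matrix(Matrix::readMM(path))
        dirn <- dirname(path)
        gf <- file.path(dirn, "genes.tsv"); cf <- file.path(dirn, "barcodes.tsv")
        if (file.exists(gf)) rownames(m) <- readLines(gf)
        if (file.exists(cf)) colnames(m) <- readLines(cf)
        return(m)
    }
    tab <- .read_table(path)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- tab[[1L]]
    storage.mode(m) <- if (all(m == round(m))) "integer" else "double"
    m
}

#' Read and validate reference data
#'
#' Reads a gene x cell count matrix (TSV with gene ids in the first column
#' and cell ids as header, or MatrixMarket \code{.mtx} with sidecar
#' \code{genes.tsv}/\code{cells.tsv}), a cell metadata TSV, and optionally a
#' second spatial-only cell table for the unpaired scenario. The scenario is
#' inferred from what is present; all container invariants are checked
#' (dimension agreement, integer non-negative counts, matching cell-type
#' sets for unpaired input).
#'
#' @param expression_path path to the count matrix.
#' @param metadata_path path to the cell metadata TSV (needs
#'   \code{cell_type}; optional \code{cell_id}, \code{x}, \code{y},
#'   \code{region}).
#' @param spatial_path optional path to the unpaired spatial reference TSV.
#' @return a \linkS4class{CCIReference}.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' ref <- generateReference("paired", n_cells = 50, n_genes = 10, seed = 1)
#' writeSimulation(as.data.frame(cellMeta(ref$reference)),
#'                 SummarizedExperiment::assay(ref$reference), dir)
#' ref2 <- readReference(file.path(dir, "counts.tsv"),
#'                       file.path(dir, "cells.tsv"))
#' scenario(ref2)
#' @export
readReference <- function(expression_path, metadata_path, spatial_path = NULL) {
    counts <- .read_counts(expression_path)
    .assert(all(counts >= 0), "negative counts in %s", expression_path)
    .assert(all(counts == round(counts)),
        "non-integer counts in %s (real-valued input is rejected, not rounded)",
        expression_path)
    cells <- .read_table(metadata_path)
    .assert("cell_type" %in% colnames(cells),
        "metadata %s lacks a 'cell_type' column", metadata_path)
    spc <- if (!is.null(spatial_path)) .read_table(spatial_path) else NULL
    CCIReference(counts, cells, spatialCells = spc)
}

#' Write a simulated dataset to disk
#'
#' Writes (i) the cell/spot metadata as \code{cells.tsv} (or
#' \code{spots.tsv}), (ii) the count matrix both as a dense TSV
#' (\code{counts.tsv}) and as MatrixMarket (\code{counts.mtx} +
#' \code{genes.tsv}/\code{barcodes.tsv} id sidecars), and (iii), when
#' ground truth is supplied, a machine-readable JSON sidecar
#' (\code{ground_truth.json}) recording every applied CCI/regional effect,
#' so simulated data can serve as a benchmark with known truth.
#'
#' @param cells data.frame of cell (or spot) metadata.
#' @param counts gene x cell (or gene x spot) matrix.
#' @param out_dir output directory (created if needed).
#' @param resolution \code{"single_cell"} or \code{"multi_cell"} (controls
#'   metadata file name only).
#' @param ground_truth optional list of applied effects (serialized to JSON).
#' @return invisibly, the vector of files written.
#' @export
writeSimulation <- function(cells, counts, out_dir,
                            resolution = c("single_cell", "multi_cell"),
                            ground_truth = NULL) {
    resolution <- match.arg(resolution)
    if (!dir.exists(out_dir))
        if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
            stop("cannot create output directory: ", out_dir, call. = FALSE)
    cells <- as.data.frame(cells)
    counts <- as.matrix(counts)
    .assert(ncol(counts) == nrow(cells),
        "counts (%d columns) and metadata (%d rows) are not conformable",
        ncol(counts), nrow(cells))
    meta_name <- if (resolution == "multi_cell") "spots.tsv" else "cells.tsv"
    files <- character(0)
    f <- file.path(out_dir, meta_name)
    utils::write.table(cells, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "counts.tsv")
    utils::write.table(
        data.frame(gene = rownames(counts), counts, check.names = FALSE),
        f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "counts.mtx")
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), f)
    writeLines(rownames(counts), file.path(out_dir, "genes.tsv"))
    writeLines(colnames(counts), file.path(out_dir, "barcodes.tsv"))
    files <- c(files, f, file.path(out_dir, "genes.tsv"),
               file.path(out_dir, "barcodes.tsv"))
    if (!is.null(ground_truth)) {
        f <- file.path(out_dir, "ground_truth.json")
        jsonlite::write_json(ground_truth, f, auto_unbox = TRUE, digits = NA,
                             null = "null")
        files <- c(files, f)
    }
    invisible(files)
}
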