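#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("matrix_OR_NULL", c("matrix", "NULL"))

#' CCIReference: expression + cell metadata for one simulation scenario
#'
#' The central input container. It extends
#' \linkS4class{SummarizedExperiment}: the \code{"counts"} assay holds the
#' gene x cell integer matrix and \code{colData} holds per-cell metadata
#' (\code{cell_id}, \code{cell_type}, optional \code{x}, \code{y},
#' \code{region}). The \code{scenario} slot records which of the three
#' supported input situations the bundle represents:
#' \describe{
#'   \item{paired}{expression and coordinates measured on the same cells
#'     (a single-cell SRT dataset);}
#'   \item{expression_only}{counts without any spatial information
#'     (scRNAseq/snRNAseq);}
#'   \item{unpaired}{counts from one source plus a separate spatial map of
#'     typed cells (\code{spatialCells}) from another source. The spatial
#'     table must use the same cell-type vocabulary as the expression data.}
#' }
#'
#' @slot scenario character, one of \code{"paired"},
#'   \code{"expression_only"}, \code{"unpaired"}.
#' @slot spatialCells \linkS4class{DataFrame} of the unpaired spatial
#'   reference (columns \code{cell_id}, \code{cell_type}, \code{x},
#'   \code{y}, optional \code{region}); zero rows unless
#'   \code{scenario == "unpaired"}.
#'
#' @seealso [readReference()], [generateReference()]
#' @export
setClass("CCIReference",
    contains = "SummarizedExperiment",
    slots = c(scenario = "character", spatialCells = "DFrame"))

.valid_CCIReference <- function(object) {
    msg <- NULL
    sc <- object@scenario
    if (length(sc) != 1L || !sc %in% c("paired", "expression_only", "unpaired"))
        msg <- c(msg, "scenario must be one of 'paired', 'expression_only', 'unpaired'")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return(c(msg, "a 'counts' assay is required"))
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cts != round(cts)))
        msg <- c(msg, "counts must be integers (real-valued input is rejected, not rounded)")
    cd <- SummarizedExperiment::colData(object)
    if (!"cell_type" %in% colnames(cd))
        return(c(msg, "colData must contain a 'cell_type' column"))
    ct <- as.character(cd$cell_type)
    if (any(is.na(ct) | !nzchar(ct))) msg <- c(msg, "cell types must be non-empty")
    if (identical(sc, "paired")) {
        if (!all(c("x", "y") %in% colnames(cd)))
            msg <- c(msg, "scenario 'paired' requires x and y columns in colData")
        else if (anyNA(cd$x) || anyNA(cd$y))
            msg <- c(msg, "scenario 'paired' requires complete x and y coordinates")
    }
    if (identical(sc, "unpaired")) {
        spc <- object@spatialCells
        if (nrow(spc) == 0L)
            msg <- c(msg, "scenario 'unpaired' requires a spatialCells table")
        else {
            if (!all(c("cell_type", "x", "y") %in% colnames(spc)))
                msg <- c(msg, "spatialCells needs cell_type, x, y columns")
            else if (!setequal(unique(as.character(spc$cell_type)), unique(ct)))
                msg <- c(msg,
                    "unpaired spatial reference must share the same cell-type set as the expression reference")
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("CCIReference", .valid_CCIReference)

#' SpatialWindow: the polygonal region of a slide that contains cells
#'
#' Thin S4 wrapper around a \code{spatstat.geom::owin} observation window
#' (polygonal or binary-mask), which supplies area computation, containment
#' tests and polygon set algebra.
#'
#' @slot win an \code{owin} object.
#' @export
setClass("SpatialWindow", slots = c(win = "ANY"))

setValidity("SpatialWindow", function(object) {
    if (!spatstat.geom::is.owin(object@win)) return("win must be an owin")
    if (!(spatstat.geom::area.owin(object@win) > 0)) return("window must have positive area")
    TRUE
})

#' RegionPartition: a B x B labeling of the unit square into K regions
#'
#' @slot labels integer matrix (B x B) with values in 1..K; entry [i, j] is
#'   the pixel whose x-range is ((j-1)/B, j/B) and y-range ((i-1)/B, i/B).
#' @slot K number of regions.
#' @export
setClass("RegionPartition",
    slots = c(labels = "matrix", K = "integer"))

setValidity("RegionPartition", function(object) {
    lab <- object@labels
    if (nrow(lab) != ncol(lab)) return("labels must be a square grid")
    if (anyNA(lab)) return("every pixel must be labeled")
    if (!all(lab %in% seq_len(object@K))) return("labels must lie in 1..K")
    for (k in seq_len(object@K))
        if (!.grid_connected(lab == k))
            return(sprintf("region %d is not 4-connected", k))
    TRUE
})

#' IntensityModel: log-polynomial Poisson point-process intensity
#'
#' Parametric inhomogeneous Poisson intensity for one cell type,
#' log lambda(x, y) = polynomial in (x, y) of degree 2 or 3 (6 or 10
#' coefficients, ordered 1, x, y, x^2, y^2, xy[, x^3, x^2 y, x y^2, y^3]).
#'
#' @slot cellType character.
#' @slot degree integer, 2 or 3.
#' @slot coefficients numeric, length 6 (degree 2) or 10 (degree 3).
#' @slot window a \linkS4class{SpatialWindow}.
#' @slot maxLogIntensity numeric; maximum of the fitted log-intensity over a
#'   fine grid on the window, used to form the Metropolis-Hastings scaling
#'   constant.
#' @slot vcov asymptotic covariance of the coefficients (inverse observed
#'   information), or NULL when unavailable.
#' @export
setClass("IntensityModel",
    slots = c(cellType = "character", degree = "integer",
              coefficients = "numeric", window = "SpatialWindow",
              maxLogIntensity = "numeric", vcov = "matrix_OR_NULL"))

setValidity("IntensityModel", function(object) {
    want <- if (object@degree == 2L) 6L else if (object@degree == 3L) 10L else NA_integer_
    if (is.na(want)) return("degree must be 2 or 3")
    if (length(object@coefficients) != want)
        return(sprintf("degree %d requires %d coefficients", object@degree, want))
    if (!all(is.finite(object@coefficients))) return("coefficients must be finite")
    TRUE
})

#' CellPool: typed cells with coordinates and region labels
#'
#' @slot cells DataFrame with columns x, y, cell_type, region.
#' @export
setClass("CellPool", slots = c(cells = "DFrame"))

setValidity("CellPool", function(object) {
    need <- c("x", "y", "cell_type", "region")
    if (!all(need %in% colnames(object@cells)))
        return(paste("cells must have columns", paste(need, collapse = ", ")))
    TRUE
})

#' NeighborGraph: undirected adjacency between cells on a slide
#'
#' @slot method "knn", "delaunay" or "distance".
#' @slot parameter k (knn) or radius (distance); NA for delaunay.
#' @slot edges 2-column integer matrix of unordered cell-index pairs (i < j).
#' @slot n number of cells the graph was built on.
#' @export
setClass("NeighborGraph",
    slots = c(method = "character", parameter = "numeric",
              edges = "matrix", n = "integer"))

setValidity("NeighborGraph", function(object) {
    e <- object@edges
    if (ncol(e) != 2L) return("edges must have two columns")
    if (nrow(e) > 0L) {
        if (any(e[, 1L] == e[, 2L])) return("self-edges are not allowed")
        if (any(e < 1L) || any(e > object@n)) return("edge endpoints out of range")
        if (any(e[, 1L] > e[, 2L])) return("edges must be stored with i < j")
        if (anyDuplicated(e)) return("duplicate edges")
    }
    TRUE
})

#' CellTypeExpressionModel: ZINB marginals + copula correlation for one stratum
#'
#' Per-gene marginal count models for one cell type (optionally one region),
#' plus an optional latent Gaussian correlation matrix coupling the genes.
#' Marginals are stored as a data.frame with one row per gene and columns
#' \code{gene}, \code{family} ("zinb", "nb", "zip", "poisson"), \code{pi}
#' (structural-zero probability), \code{mu} (NB mean), \code{size}
#' (dispersion; variance = mu + mu^2/size; Inf for Poisson-type families).
#'
#' @slot cellType character.
#' @slot region character; NA when the model is not region-stratified.
#' @slot marginals data.frame as described above.
#' @slot sigma correlation matrix over genes (unit diagonal, PSD) or NULL.
#' @export
setClass("CellTypeExpressionModel",
    slots = c(cellType = "character", region = "character",
              marginals = "data.frame", sigma = "matrix_OR_NULL"))

setValidity("CellTypeExpressionModel", function(object) {
    m <- object@marginals
    need <- c("gene", "family", "pi", "mu", "size")
    if (!all(need %in% colnames(m)))
        return(paste("marginals must have columns", paste(need, collapse = ", ")))
    if (!all(m$family %in% c("zinb", "nb", "zip", "poisson")))
        return("unknown marginal family")
    if (any(m$pi < 0 | m$pi > 1)) return("pi must lie in [0, 1]")
    if (any(m$mu < 0)) return("mu must be non-negative")
    if (any(m$size <= 0)) return("size must be positive")
    s <- object@sigma
    if (!is.null(s)) {
        if (nrow(s) != nrow(m) || ncol(s) != nrow(m))
            return("sigma dimension must match the number of genes")
        if (max(abs(diag(s) - 1)) > 1e-8) return("sigma must have unit diagonal")
        if (max(abs(s - t(s))) > 1e-8) return("sigma must be symmetric")
    }
    TRUE
})

#' DeltaMatrix: cumulative log-scale perturbations with provenance
#'
#' Tracks the cumulative CCI and regional effects on log counts: an
#' n_cells x n_genes matrix initialized at zero, to which each perturbation
#' specification adds draws from N(mu, sigma^2) at its affected
#' (cell, gene) positions. The provenance list records, per spec, the
#' affected cell indices, gene indices, and the drawn effects, so every
#' nonzero entry of the final matrix is attributable.
#'
#' @slot values numeric matrix, cells x genes, log-scale changes.
#' @slot provenance list of records (one per applied spec).
#' @export
setClass("DeltaMatrix",
    slots = c(values = "matrix", provenance = "list"))

#' SpotGrid: multi-cell (spot-level) aggregation of a single-cell simulation
#'
#' @slot counts gene x spot matrix of summed counts.
#' @slot centers 2-column matrix of spot-center coordinates.
#' @slot cellsPerSpot integer vector, cells aggregated into each spot.
#' @slot squareSize side length of the square spots.
#' @export
setClass("SpotGrid",
    slots = c(counts = "matrix", centers = "matrix",
              cellsPerSpot = "integer", squareSize = "numeric"))

setValidity("SpotGrid", function(object) {
    if (ncol(object@counts) != nrow(object@centers))
        return("one center per spot required")
    if (length(object@cellsPerSpot) != ncol(object@counts))
        return("cellsPerSpot length must equal number of spots")
    TRUE
})

#' SimulationConfig: one fully specified simulation run
#'
#' Holds every parameter governing a run, with documented defaults filled in.
#' Constructed by [readConfig()] or [simulationConfig()]; a config together
#' with its seed fully determines the simulated output.
#'
#' @slot params named list of parameters; see [simulationConfig()] for the
#'   complete catalogue and defaults.
#' @export
setClass("SimulationConfig", slots = c(params = "list"))
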