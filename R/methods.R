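#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname CCIReference-class
#' @export
setMethod("scenario", "CCIReference", function(object) object@scenario)

#' @rdname CCIReference-class
#' @export
setMethod("spatialCells", "CCIReference", function(object) object@spatialCells)

#' @rdname CCIReference-class
#' @export
setMethod("cellTypes", "CCIReference", function(object)
    sort(unique(as.character(SummarizedExperiment::colData(object)$cell_type))))

#' @rdname CCIReference-class
#' @export
setMethod("cellMeta", "CCIReference", function(object)
    SummarizedExperiment::colData(object))

setMethod("show", "CCIReference", function(object) {
    cat("CCIReference (scenario: ", object@scenario, ")\n", sep = "")
    cat("  ", nrow(object), " genes x ", ncol(object), " cells; ",
        length(cellTypes(object)), " cell types\n", sep = "")
    if (object@scenario == "unpaired")
        cat("  unpaired spatial map: ", nrow(object@spatialCells),
            " cells\n", sep = "")
    invisible(NULL)
})

#' @rdname windowArea
#' @export
setMethod("windowArea", "SpatialWindow", function(object)
    spatstat.geom::area.owin(object@win))

#' @rdname containsPoints
#' @export
setMethod("containsPoints", "SpatialWindow", function(object, x, y)
    spatstat.geom::inside.owin(x, y, object@win))

setMethod("show", "SpatialWindow", function(object) {
    cat("SpatialWindow of area", format(windowArea(object)), "\n")
    invisible(NULL)
})

#' @rdname RegionPartition-class
#' @export
setMethod("regionLabels", "RegionPartition", function(object) object@labels)

setMethod("show", "RegionPartition", function(object) {
    B <- nrow(object@labels)
    sizes <- tabulate(object@labels, nbins = object@K)
    cat("RegionPartition: ", B, " x ", B, " grid, K = ", object@K,
        " connected regions\n  pixel counts: ",
        paste(sizes, collapse = ", "), "\n", sep = "")
    invisible(NULL)
})

# Evaluate log-intensity at locations (vectorized polynomial basis).
.poly_basis <- function(x, y, degree) {
    b <- cbind(1, x, y, x^2, y^2, x * y)
    if (degree == 3L) b <- cbind(b, x^3, x^2 * y, x * y^2, y^3)
    b
}

#' @describeIn IntensityModel-class intensity lambda(x, y) of the fitted
#'   Poisson point-process model.
#' @param object,x,y,... see generic.
#' @export
setMethod("intensity", "IntensityModel", function(object, x, y, ...) {
    exp(drop(.poly_basis(x, y, object@degree) %*% object@coefficients))
})

setMethod("show", "IntensityModel", function(object) {
    cat("IntensityModel for cell type '", object@cellType, "' (degree ",
        object@degree, ")\n  max log-intensity ",
        format(object@maxLogIntensity), "\n", sep = "")
    invisible(NULL)
})

#' @rdname CellPool-class
#' @export
setMethod("poolCells", "CellPool", function(object) object@cells)

setMethod("show", "CellPool", function(object) {
    tab <- table(object@cells$cell_type)
    cat("CellPool: ", nrow(object@cells), " cells (",
        paste(names(tab), tab, sep = ":", collapse = ", "), ")\n", sep = "")
    invisible(NULL)
})

#' @rdname NeighborGraph-class
#' @export
setMethod("graphEdges", "NeighborGraph", function(object) object@edges)

setMethod("show", "NeighborGraph", function(object) {
    cat("NeighborGraph (", object@method, "): ", object@n, " cells, ",
        nrow(object@edges), " edges\n", sep = "")
    invisible(NULL)
})

setMethod("show", "CellTypeExpressionModel", function(object) {
    fam <- table(object@marginals$family)
    cat("CellTypeExpressionModel for '", object@cellType, "'",
        if (!is.na(object@region)) paste0(" (region ", object@region, ")"),
        ": ", nrow(object@marginals), " genes\n  families: ",
        paste(names(fam), fam, sep = ":", collapse = ", "),
        "\n  correlation: ",
        if (is.null(object@sigma)) "none" else "Gaussian copula", "\n",
        sep = "")
    invisible(NULL)
})

#' @rdname DeltaMatrix-class
#' @export
setMethod("deltaValues", "DeltaMatrix", function(object) object@values)

#' @rdname DeltaMatrix-class
#' @export
setMethod("deltaProvenance", "DeltaMatrix", function(object) object@provenance)

setMethod("show", "DeltaMatrix", function(object) {
    cat("DeltaMatrix: ", nrow(object@values), " cells x ",
        ncol(object@values), " genes; ", sum(object@values != 0),
        " nonzero entries from ", length(object@provenance),
        " perturbation spec(s)\n", sep = "")
    invisible(NULL)
})

#' @rdname SpotGrid-class
#' @export
setMethod("spotCounts", "SpotGrid", function(object) object@counts)

#' @rdname SpotGrid-class
#' @export
setMethod("spotCenters", "SpotGrid", function(object) object@centers)

setMethod("show", "SpotGrid", function(object) {
    cat("SpotGrid: ", ncol(object@counts), " spots (square side ",
        format(object@squareSize), "), ", sum(object@cellsPerSpot),
        " cells aggregated\n", sep = "")
    invisible(NULL)
})

#' @rdname SimulationConfig-class
#' @export
setMethod("configParam", "SimulationConfig", function(object, name) {
    .assert(name %in% names(object@params), "unknown config parameter '%s'", name)
    object@params[[name]]
})

setMethod("show", "SimulationConfig", function(object) {
    p <- object@params
    cat("SimulationConfig (scenario: ", p$scenario, ")\n", sep = "")
    cat("  K = ", p$n_regions, ", B = ", p$grid_size,
        ", resolution: ", p$output_resolution, "\n", sep = "")
    nspec <- vapply(p[c("colocalization_specs", "expression_cci_specs",
                        "gene_pair_cci_specs", "regional_specs")],
                    length, integer(1))
    cat("  specs: ", paste(names(nspec), nspec, sep = "=", collapse = ", "),
        "\n", sep = "")
    invisible(NULL)
})
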