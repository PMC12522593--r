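#' @include AllClasses.R
NULL

#' @rdname CCIReference-class
#' @param object,x an object.
#' @export
setGeneric("scenario", function(object) standardGeneric("scenario"))

#' @rdname CCIReference-class
#' @export
setGeneric("spatialCells", function(object) standardGeneric("spatialCells"))

#' @rdname CCIReference-class
#' @export
setGeneric("cellTypes", function(object) standardGeneric("cellTypes"))

#' @rdname CCIReference-class
#' @export
setGeneric("cellMeta", function(object) standardGeneric("cellMeta"))

#' Area of a spatial window
#' @param object a \linkS4class{SpatialWindow}.
#' @export
setGeneric("windowArea", function(object) standardGeneric("windowArea"))

#' Points-in-window containment test
#' @param object a \linkS4class{SpatialWindow}.
#' @param x,y coordinate vectors.
#' @export
setGeneric("containsPoints",
    function(object, x, y) standardGeneric("containsPoints"))

#' Evaluate a model at locations
#' @param object a model object.
#' @param x,y coordinate vectors.
#' @param ... further arguments.
#' @export
setGeneric("intensity", function(object, x, y, ...) standardGeneric("intensity"))

#' @rdname CellPool-class
#' @param object a \linkS4class{CellPool}.
#' @export
setGeneric("poolCells", function(object) standardGeneric("poolCells"))

#' @rdname NeighborGraph-class
#' @param object a \linkS4class{NeighborGraph}.
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' @rdname RegionPartition-class
#' @param object a \linkS4class{RegionPartition}.
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))

#' @rdname DeltaMatrix-class
#' @param object a \linkS4class{DeltaMatrix}.
#' @export
setGeneric("deltaValues", function(object) standardGeneric("deltaValues"))

#' @rdname DeltaMatrix-class
#' @export
setGeneric("deltaProvenance", function(object) standardGeneric("deltaProvenance"))

#' @rdname SpotGrid-class
#' @param object a \linkS4class{SpotGrid}.
#' @export
setGeneric("spotCounts", function(object) standardGeneric("spotCounts"))

#' @rdname SpotGrid-class
#' @export
setGeneric("spotCenters", function(object) standardGeneric("spotCenters"))

#' @rdname SimulationConfig-class
#' @param object a \linkS4class{SimulationConfig}.
#' @param name parameter name.
#' @export
setGeneric("configParam", function(object, name) standardGeneric("configParam"))
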