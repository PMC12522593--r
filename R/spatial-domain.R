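#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Partition the unit square into K connected regions by random walk
#'
#' Used when no spatial reference is available. The unit square is divided
#' into a \code{B x B} pixel grid; \code{K} starting pixels are drawn at
#' random from the border pixels (those with fewer than four edge-sharing
#' neighbors); regions then grow cyclically, one pixel per region per
#' round, each time annexing a uniformly chosen unassigned edge-sharing
#' neighbor. A region stops growing once all its neighboring pixels are
#' assigned; the algorithm terminates when every pixel is labeled. The
#' construction yields K connected regions of similar sizes.
#'
#' @param K number of regions (>= 1, at most the number of border pixels).
#' @param B grid size (>= 2); larger B gives smoother region boundaries
#'   (default 20).
#' @param seed optional integer seed.
#' @return a \linkS4class{RegionPartition}.
#' @examples
#' part <- partitionUnitSquare(K = 3, B = 20, seed = 1)
#' table(regionLabels(part))
#' @export
partitionUnitSquare <- function(K, B = 20L, seed = NULL) {
    K <- as.integer(K); B <- as.integer(B)
    .assert(B >= 2L, "B must be >= 2")
    n_border <- 4L * B - 4L
    .assert(K >= 1L, "K must be >= 1")
    .assert(K <= n_border, "K (%d) exceeds the number of border pixels (%d)",
            K, n_border)
    lab <- matrix(NA_integer_, B, B)
    if (K == 1L) {
        lab[] <- 1L
        return(new("RegionPartition", labels = lab, K = 1L))
    }
    .with_seed(seed, {
        # border pixels have fewer than four edge-sharing neighbors
        border <- which(row(lab) %in% c(1L, B) | col(lab) %in% c(1L, B))
        seeds <- sample(border, K)
        lab[seeds] <- seq_len(K)
        active <- rep(TRUE, K)
        moves <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
        while (anyNA(lab) && any(active)) {
            for (k in seq_len(K)) {
                if (!active[k]) next
                mem <- which(lab == k, arr.ind = TRUE)
                cand <- NULL
                for (m in seq_len(4L)) {
                    pts <- cbind(mem[, 1L] + moves[m, 1L],
                                 mem[, 2L] + moves[m, 2L])
                    ok <- pts[, 1L] >= 1L & pts[, 1L] <= B &
                          pts[, 2L] >= 1L & pts[, 2L] <= B
                    pts <- pts[ok, , drop = FALSE]
                    if (nrow(pts))
                        cand <- rbind(cand,
                            pts[is.na(lab[pts]), , drop = FALSE])
                }
                if (is.null(cand) || nrow(cand) == 0L) {
                    active[k] <- FALSE
                    next
                }
                cand <- unique(cand)
                pick <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
                lab[pick] <- k
            }
        }
    })
    .assert(!anyNA(lab), "partition failed to cover the grid")
    new("RegionPartition", labels = lab, K = K)
}

#' Region windows from a partition
#'
#' Converts one region of a \linkS4class{RegionPartition} of the unit
#' square into a binary-mask \linkS4class{SpatialWindow}.
#'
#' @param partition a \linkS4class{RegionPartition}.
#' @param k region label.
#' @return a \linkS4class{SpatialWindow}.
#' @export
partitionRegionWindow <- function(partition, k) {
    lab <- partition@labels
    .assert(k >= 1L && k <= partition@K, "region %d out of range", k)
    m <- lab == k
    win <- spatstat.geom::owin(c(0, 1), c(0, 1), mask = m)
    new("SpatialWindow", win = win)
}

# Counter-clockwise polygon owin from raw vertices.
.owin_poly <- function(x, y) {
    a <- sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y) / 2
    if (a < 0) { x <- rev(x); y <- rev(y) }
    spatstat.geom::owin(poly = list(x = x, y = y))
}

.convex_owin <- function(x, y) {
    h <- grDevices::chull(x, y)
    .owin_poly(x[h], y[h])
}

# Union a list of owins (divide and conquer keeps polyclip calls balanced).
.union_owins <- function(wins) {
    while (length(wins) > 1L) {
        nxt <- vector("list", ceiling(length(wins) / 2))
        for (i in seq_along(nxt)) {
            a <- wins[[2L * i - 1L]]
            nxt[[i]] <- if (2L * i <= length(wins))
                spatstat.geom::union.owin(a, wins[[2L * i]]) else a
        }
        wins <- nxt
    }
    wins[[1L]]
}

.delaunay_window <- function(x, y, buffer_radius, outlier_sd) {
    # buffer: four points on the compass directions around each cell center,
    # so boundary cells end up strictly inside the extracted frame
    bx <- c(x, x + buffer_radius, x - buffer_radius, x, x)
    by <- c(y, y, y, y + buffer_radius, y - buffer_radius)
    keep <- !duplicated(cbind(bx, by))
    dd <- deldir::deldir(bx[keep], by[keep])
    tl <- deldir::triang.list(dd)
    .assert(length(tl) > 0L, "degenerate geometry: no Delaunay triangles")
    # prune triangles containing an outlier edge (> mean + outlier_sd * SD);
    # the structural buffer edges (length <= 2 * buffer_radius) are excluded
    # from the mean/SD so they cannot drag the threshold down
    elen <- with(dd$delsgs, sqrt((x1 - x2)^2 + (y1 - y2)^2))
    real <- elen[elen > 2 * buffer_radius]
    if (length(real) < 2L) real <- elen
    thr <- mean(real) + outlier_sd * stats::sd(real)
    tri_max_edge <- vapply(tl, function(tr) {
        xs <- tr$x; ys <- tr$y
        max(sqrt(diff(c(xs, xs[1L]))^2 + diff(c(ys, ys[1L]))^2))
    }, numeric(1))
    tl <- tl[tri_max_edge <= thr]
    if (length(tl) == 0L)
        stop("empty triangulation after outlier-edge pruning; ",
             "raise outlier_sd", call. = FALSE)
    .union_owins(lapply(tl, function(tr) .owin_poly(tr$x, tr$y)))
}

#' Estimate the spatial window of a set of cells
#'
#' Data-driven estimation of the slide window from cell-center coordinates.
#' The default \code{"delaunay"} method adds a small circular buffer (four
#' points at radius \code{buffer_radius}) around each cell so boundary
#' cells fall strictly inside the window, builds the Delaunay triangulation
#' of the augmented point set, removes triangles containing an outlier edge
#' (longer than mean + \code{outlier_sd} standard deviations of all edge
#' lengths), and returns the outer frame (the boundary of the union of the
#' surviving triangles, holes preserved). This captures complex, concave
#' slide shapes. Faster approximations: \code{"rectangle"} (axis-aligned
#' bounding box), \code{"convex"} (convex hull), and
#' \code{"sectioned_convex"} (equal-width vertical sections, convex hull
#' per section, union), which trades accuracy for speed on elongated
#' concave shapes.
#'
#' @param x,y cell-center coordinates.
#' @param method one of \code{"delaunay"}, \code{"rectangle"},
#'   \code{"convex"}, \code{"sectioned_convex"}.
#' @param buffer_radius buffer circle radius in coordinate units
#'   (default 5e-4).
#' @param outlier_sd outlier-edge threshold in standard deviations
#'   (default 3).
#' @param sections number of vertical sections for
#'   \code{"sectioned_convex"} (clamped to 2..5).
#' @return a \linkS4class{SpatialWindow}.
#' @examples
#' set.seed(1)
#' w <- estimateWindow(runif(200), runif(200), method = "rectangle")
#' windowArea(w)
#' @export
estimateWindow <- function(x, y,
                           method = c("delaunay", "rectangle", "convex",
                                      "sectioned_convex"),
                           buffer_radius = 5e-4, outlier_sd = 3,
                           sections = 3L) {
    method <- match.arg(method)
    .assert(length(x) == length(y), "x and y lengths differ")
    if (method %in% c("delaunay", "convex", "sectioned_convex")) {
        .assert(length(x) >= 3L, "need at least 3 points for %s", method)
        .assert(stats::sd(x) > 0 || stats::sd(y) > 0,
                "degenerate geometry: points are coincident")
    } else .assert(length(x) >= 2L, "need at least 2 points")
    win <- switch(method,
        rectangle = spatstat.geom::owin(range(x), range(y)),
        convex = .convex_owin(x, y),
        sectioned_convex = {
            sections <- min(5L, max(2L, as.integer(sections)))
            br <- seq(min(x), max(x), length.out = sections + 1L)
            pad <- diff(range(x)) * 0.01  # overlap so borders stay interior
            hulls <- lapply(seq_len(sections), function(s) {
                i <- x >= br[s] - pad & x <= br[s + 1L] + pad
                if (sum(i) < 3L) return(NULL)
                # hair of dilation: polygon clipping snaps vertices to a
                # grid, which can push hull-boundary points epsilon-outside
                spatstat.geom::dilation.owin(.convex_owin(x[i], y[i]),
                                             1e-6 * max(diff(range(x)),
                                                        diff(range(y))))
            })
            hulls <- Filter(Negate(is.null), hulls)
            .assert(length(hulls) > 0L, "no section has >= 3 points")
            .union_owins(hulls)
        },
        delaunay = .delaunay_window(x, y, buffer_radius, outlier_sd))
    new("SpatialWindow", win = win)
}

#' Estimate one window per spatial region
#'
#' Applies [estimateWindow()] to each region's cells separately, then
#' resolves small overlaps between region windows (introduced by the
#' buffer extension): each overlap polygon is assigned wholly to one of
#' its two regions, chosen uniformly at random (seeded), so region windows
#' are disjoint while their union is preserved.
#'
#' @param x,y cell coordinates.
#' @param region region label per cell.
#' @param seed optional integer seed for overlap assignment.
#' @param ... passed on to [estimateWindow()].
#' @return named list of \linkS4class{SpatialWindow}, one per region.
#' @export
estimateRegionWindows <- function(x, y, region, seed = NULL, ...) {
    region <- as.character(region)
    regs <- sort(unique(region))
    for (r in regs)
        .assert(sum(region == r) >= 3L,
                "region '%s' has fewer than 3 points", r)
    wins <- lapply(regs, function(r)
        estimateWindow(x[region == r], y[region == r], ...)@win)
    names(wins) <- regs
    .with_seed(seed, {
        if (length(wins) > 1L) {
            for (i in seq_len(length(wins) - 1L)) for (j in (i + 1L):length(wins)) {
                ov <- spatstat.geom::intersect.owin(wins[[i]], wins[[j]],
                                                    fatal = FALSE)
                if (is.null(ov) || spatstat.geom::is.empty(ov) ||
                    spatstat.geom::area.owin(ov) <= 0) next
                if (stats::runif(1) < 0.5)
                    wins[[j]] <- spatstat.geom::setminus.owin(wins[[j]], ov)
                else
                    wins[[i]] <- spatstat.geom::setminus.owin(wins[[i]], ov)
            }
        }
    })
    lapply(wins, function(w) new("SpatialWindow", win = w))
}

#' Serialize a window boundary as WKT
#'
#' @param window a \linkS4class{SpatialWindow}.
#' @return a WKT POLYGON/MULTIPOLYGON string (rectangles and masks are
#'   converted to their boundary polygon first).
#' @export
windowWKT <- function(window) {
    w <- .as_owin(window)
    if (w$type != "polygonal") w <- spatstat.geom::as.polygonal(w)
    rings <- lapply(w$bdry, function(p) {
        x <- c(p$x, p$x[1L]); y <- c(p$y, p$y[1L])
        paste0("(", paste(sprintf("%.10g %.10g", x, y), collapse = ", "), ")")
    })
    shoelace <- function(p) sum(p$x * c(p$y[-1L], p$y[1L]) -
                                c(p$x[-1L], p$x[1L]) * p$y) / 2
    holes <- vapply(w$bdry, function(p) shoelace(p) < 0, logical(1))
    if (!any(holes) && length(rings) > 1L)
        paste0("MULTIPOLYGON(",
               paste(vapply(rings, function(r) paste0("(", r, ")"),
                            character(1)), collapse = ", "), ")")
    else
        paste0("POLYGON(", paste(unlist(rings), collapse = ", "), ")")
}

#' Write a region partition as a B x B integer TSV
#'
#' @param partition a \linkS4class{RegionPartition}.
#' @param path output path.
#' @export
writePartition <- function(partition, path) {
    utils::write.table(partition@labels, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
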