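#' @include AllClasses.R AllGenerics.R utils.R
NULL

# Quadrature grid over a window: midpoints of grid cells inside the window
# plus the per-cell area, for numerical integration of the intensity.
.window_quadrature <- function(win, ngrid = 100L) {
    xr <- win$xrange; yr <- win$yrange
    dx <- diff(xr) / ngrid; dy <- diff(yr) / ngrid
    gx <- xr[1L] + (seq_len(ngrid) - 0.5) * dx
    gy <- yr[1L] + (seq_len(ngrid) - 0.5) * dy
    gr <- expand.grid(x = gx, y = gy)
    ok <- spatstat.geom::inside.owin(gr$x, gr$y, win)
    list(x = gr$x[ok], y = gr$y[ok], cell_area = dx * dy)
}

# Berman-Turner device: maximize the Poisson point-process likelihood as a
# weighted Poisson GLM over data points plus dummy quadrature points, with
# counting weights sharing each grid cell's area among its points.
.fit_ppp_degree <- function(x, y, win, degree, ngrid = 100L) {
    xr <- win$xrange; yr <- win$yrange
    dx <- diff(xr) / ngrid; dy <- diff(yr) / ngrid
    cell_of <- function(px, py) {
        i <- pmin(pmax(floor((px - xr[1L]) / dx), 0), ngrid - 1L)
        j <- pmin(pmax(floor((py - yr[1L]) / dy), 0), ngrid - 1L)
        j * ngrid + i + 1L
    }
    quad <- .window_quadrature(win, ngrid)
    cd <- cell_of(x, y); cq <- cell_of(quad$x, quad$y)
    npc <- tabulate(cd, ngrid * ngrid)        # data points per grid cell
    w <- c(dx * dy / (npc[cd] + 1L), dx * dy / (npc[cq] + 1L))
    yresp <- c(1 / w[seq_along(x)], rep(0, length(cq)))
    X <- rbind(.poly_basis(x, y, degree),
               .poly_basis(quad$x, quad$y, degree))
    fit <- suppressWarnings(stats::glm.fit(X, yresp, weights = w,
                                           family = stats::poisson()))
    info <- crossprod(X, X * (w * fit$fitted.values))
    vc <- try(solve(info), silent = TRUE)
    list(par = unname(fit$coefficients),
         convergence = if (isTRUE(fit$converged) &&
                           !anyNA(fit$coefficients)) 0L else 1L,
         vcov = if (inherits(vc, "try-error")) NULL else vc,
         message = NULL)
}

#' Fit a log-polynomial Poisson point-process intensity
#'
#' Maximizes the inhomogeneous Poisson point-process log-likelihood
#' sum_i log lambda(x_i, y_i) - int_W lambda over the coefficients of a
#' polynomial log-intensity, log lambda(x, y) = beta_0 + beta_1 x +
#' beta_2 y + ... Degree 3 (10 terms) is used for cell types with more
#' than ten cells; degree 2 (6 terms) otherwise, to avoid overfitting
#' sparse types. The window integral is evaluated by midpoint quadrature
#' on a grid restricted to the window. The maximum fitted log-intensity
#' over a fine (200 x 200) grid is stored for the Metropolis-Hastings
#' scaling constant.
#'
#' @param x,y coordinates of the cells of one cell type (>= 2 points).
#' @param window a \linkS4class{SpatialWindow} containing the points.
#' @param cell_type label stored in the model.
#' @param ngrid quadrature grid resolution per axis (default 100).
#' @return an \linkS4class{IntensityModel}.
#' @examples
#' w <- spatialWindow()
#' set.seed(1)
#' m <- fitIntensity(runif(200), runif(200), w)
#' intensity(m, 0.5, 0.5)
#' @export
fitIntensity <- function(x, y, window, cell_type = "cell", ngrid = 100L) {
    .assert(length(x) >= 2L, "need at least 2 points to fit an intensity")
    win <- .as_owin(window)
    degree <- if (length(x) > 10L) 3L else 2L
    fit <- .fit_ppp_degree(x, y, win, degree, ngrid)
    if (degree == 3L && (fit$convergence != 0L || is.null(fit$vcov))) {
        degree <- 2L   # singular/non-converged cubic fit: quadratic fallback
        fit <- .fit_ppp_degree(x, y, win, degree, ngrid)
    }
    .assert(fit$convergence == 0L, "intensity fit did not converge")
    vc <- fit$vcov
    eval_grid <- .window_quadrature(win, 200L)
    maxlog <- max(drop(.poly_basis(eval_grid$x, eval_grid$y, degree) %*%
                       fit$par))
    new("IntensityModel", cellType = cell_type, degree = degree,
        coefficients = fit$par,
        window = if (is(window, "SpatialWindow")) window else
            new("SpatialWindow", win = win),
        maxLogIntensity = maxlog, vcov = vc)
}

# Fast approximate containment on a raster mask (exact test applied to the
# final sample).
.mask_lookup <- function(win, dimyx = 256L) {
    m <- spatstat.geom::as.mask(win, dimyx = dimyx)
    list(m = m$m, x0 = m$xrange[1L], y0 = m$yrange[1L],
         dx = m$xstep, dy = m$ystep, nr = nrow(m$m), nc = ncol(m$m))
}

.mask_inside <- function(lk, x, y) {
    j <- floor((x - lk$x0) / lk$dx) + 1
    i <- floor((y - lk$y0) / lk$dy) + 1
    ok <- i >= 1 & i <= lk$nr & j >= 1 & j <= lk$nc
    ok[ok] <- lk$m[cbind(i[ok], j[ok])]
    ok
}

# Rejection sampler for lambda on the window (vectorized batches); used for
# chain initialization and the exact-count top-up. Acceptance probability is
# lambda / c with c >= max lambda over the window.
.reject_sample <- function(model, n, c_log) {
    win <- model@window@win
    xr <- win$xrange; yr <- win$yrange
    out_x <- numeric(0); out_y <- numeric(0)
    while (length(out_x) < n) {
        m <- max(2L * (n - length(out_x)), 64L)
        px <- stats::runif(m, xr[1L], xr[2L])
        py <- stats::runif(m, yr[1L], yr[2L])
        ok <- spatstat.geom::inside.owin(px, py, win)
        px <- px[ok]; py <- py[ok]
        if (!length(px)) next
        lp <- drop(.poly_basis(px, py, model@degree) %*% model@coefficients)
        acc <- stats::runif(length(px)) < exp(lp - c_log)
        out_x <- c(out_x, px[acc]); out_y <- c(out_y, py[acc])
    }
    list(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

#' Sample cell coordinates from a fitted intensity by Metropolis-Hastings
#'
#' Runs a spatial birth/death/shift Metropolis-Hastings chain whose
#' stationary law is the Poisson point process with the model's intensity
#' (internally rescaled so the expected count matches \code{n_target}).
#' Moves are proposed with equal probability: a birth at a uniform location
#' u is accepted with probability min(1, lambda(u) |W| / (n + 1)); the
#' death of a uniformly chosen point x with min(1, n / (lambda(x) |W|));
#' a uniform shift of a point to u with min(1, lambda(u) / lambda(x)).
#' After the iteration budget the configuration is adjusted to exactly
#' \code{n_target} points: surplus points are thinned uniformly at random
#' (retained points already carry the intensity), deficits are filled by
#' rejection draws accepted with probability lambda / c, where the scaling
#' constant c = exp(max fitted log-intensity) * 1.05 bounds the intensity
#' from above.
#'
#' @param model an \linkS4class{IntensityModel}.
#' @param n_target number of points to return (>= 0).
#' @param iterations chain length (default 500000).
#' @param seed optional integer seed.
#' @return list with coordinate vectors \code{x}, \code{y}, all strictly
#'   inside the model window.
#' @export
sampleIntensityMH <- function(model, n_target, iterations = 500000L,
                              seed = NULL) {
    .assert(n_target >= 0L, "n_target must be >= 0")
    if (n_target == 0L) return(list(x = numeric(0), y = numeric(0)))
    win <- model@window@win
    area <- spatstat.geom::area.owin(win)
    .assert(area > 0, "window has zero area")
    quad <- .window_quadrature(win, 100L)
    co <- model@coefficients
    lam_int <- quad$cell_area *
        sum(exp(drop(.poly_basis(quad$x, quad$y, model@degree) %*% co)))
    scale_log <- log(n_target) - log(lam_int)  # aim E[n] at n_target
    c_log <- model@maxLogIntensity + scale_log + log(1.05)
    lk <- .mask_lookup(win)
    xr <- win$xrange; yr <- win$yrange
    wx <- diff(xr); wy <- diff(yr)
    loglam1 <- function(x, y) {  # scalar log intensity (rescaled)
        b <- c(1, x, y, x * x, y * y, x * y)
        if (model@degree == 3L)
            b <- c(b, x^3, x * x * y, x * y * y, y^3)
        sum(b * co) + scale_log
    }
    .with_seed(seed, {
        init <- .reject_sample(model, max(n_target, 1L), c_log - scale_log)
        px <- init$x; py <- init$y
        lg <- vapply(seq_along(px), function(i) loglam1(px[i], py[i]),
                     numeric(1))
        la <- log(area)
        moves <- sample.int(3L, iterations, replace = TRUE)
        ur1 <- stats::runif(iterations, xr[1L], xr[2L])
        ur2 <- stats::runif(iterations, yr[1L], yr[2L])
        uacc <- log(stats::runif(iterations))
        for (it in seq_len(iterations)) {
            mv <- moves[it]
            n <- length(px)
            if (mv == 1L) {               # birth
                ux <- ur1[it]; uy <- ur2[it]
                if (!.mask_inside(lk, ux, uy)) next
                ll <- loglam1(ux, uy)
                if (uacc[it] < ll + la - log(n + 1)) {
                    px <- c(px, ux); py <- c(py, uy); lg <- c(lg, ll)
                }
            } else if (mv == 2L) {        # death
                if (n <= 1L) next
                i <- sample.int(n, 1L)
                if (uacc[it] < log(n) - lg[i] - la) {
                    px <- px[-i]; py <- py[-i]; lg <- lg[-i]
                }
            } else {                      # shift
                i <- sample.int(n, 1L)
                ux <- ur1[it]; uy <- ur2[it]
                if (!.mask_inside(lk, ux, uy)) next
                ll <- loglam1(ux, uy)
                if (uacc[it] < ll - lg[i]) {
                    px[i] <- ux; py[i] <- uy; lg[i] <- ll
                }
            }
        }
        # exact containment: the raster lookup can admit boundary slivers
        ok <- spatstat.geom::inside.owin(px, py, win)
        px <- px[ok]; py <- py[ok]
        n <- length(px)
        if (n > n_target) {
            keep <- sample.int(n, n_target)
            px <- px[keep]; py <- py[keep]
        } else if (n < n_target) {
            add <- .reject_sample(model, n_target - n, c_log - scale_log)
            px <- c(px, add$x); py <- c(py, add$y)
        }
        list(x = px, y = py)
    })
}

#' Uniformly allocate cells within regions
#'
#' De novo allocation when no spatial reference exists: cells of each type
#' are placed uniformly at random within their region's window.
#'
#' @param windows a named list of \linkS4class{SpatialWindow} (one per
#'   region), a single \linkS4class{SpatialWindow}, or a
#'   \linkS4class{RegionPartition} of the unit square.
#' @param n_by_type data.frame with columns \code{region},
#'   \code{cell_type}, \code{n} giving target counts (counts >= 0). With a
#'   single window, \code{region} may be omitted.
#' @param seed optional integer seed.
#' @return a \linkS4class{CellPool}.
#' @examples
#' pool <- allocateUniform(spatialWindow(),
#'     data.frame(cell_type = c("A", "B"), n = c(30, 20)), seed = 1)
#' pool
#' @export
allocateUniform <- function(windows, n_by_type, seed = NULL) {
    if (is(windows, "RegionPartition")) {
        part <- windows
        windows <- lapply(seq_len(part@K), function(k)
            partitionRegionWindow(part, k))
        names(windows) <- as.character(seq_len(part@K))
    }
    if (is(windows, "SpatialWindow")) windows <- list("1" = windows)
    n_by_type <- as.data.frame(n_by_type)
    if (!"region" %in% colnames(n_by_type))
        n_by_type$region <- names(windows)[1L]
    n_by_type$region <- as.character(n_by_type$region)
    .assert(all(n_by_type$n >= 0), "counts must be >= 0")
    .assert(all(n_by_type$region %in% names(windows)),
        "unknown region in n_by_type")
    .with_seed(seed, {
        parts <- lapply(seq_len(nrow(n_by_type)), function(i) {
            n <- n_by_type$n[i]
            if (n == 0L) return(NULL)
            w <- windows[[n_by_type$region[i]]]@win
            p <- spatstat.random::runifpoint(n, win = w)
            data.frame(x = p$x, y = p$y,
                       cell_type = n_by_type$cell_type[i],
                       region = n_by_type$region[i])
        })
        df <- do.call(rbind, Filter(Negate(is.null), parts))
        if (is.null(df))
            df <- data.frame(x = numeric(0), y = numeric(0),
                             cell_type = character(0), region = character(0))
        new("CellPool", cells = DataFrame(df))
    })
}

#' Remove overlapping cells
#'
#' Enforces a minimum center-to-center distance, mimicking physical
#' non-overlap of cells: points are visited in a random (seeded) order and
#' a point is kept only if no already-kept point lies within
#' \code{min_distance}; so within each conflict cluster all but one cell
#' are randomly deleted. Every removed point has a kept point within
#' \code{min_distance}, and the operation is idempotent.
#'
#' @param x,y coordinates.
#' @param min_distance minimum allowed pairwise distance (>= 0).
#' @param seed optional integer seed.
#' @return integer vector of kept indices (in original order).
#' @export
removeOverlaps <- function(x, y, min_distance, seed = NULL) {
    .assert(min_distance >= 0, "min_distance must be >= 0")
    n <- length(x)
    if (n <= 1L || min_distance == 0) return(seq_len(n))
    bb <- spatstat.geom::owin(range(x) + c(-1, 1) * min_distance,
                              range(y) + c(-1, 1) * min_distance)
    pp <- spatstat.geom::ppp(x, y, window = bb, checkdup = FALSE)
    cp <- spatstat.geom::closepairs(pp, rmax = min_distance,
                                    what = "indices", twice = TRUE)
    if (length(cp$i) == 0L) return(seq_len(n))
    nbr <- split(cp$j, factor(cp$i, levels = seq_len(n)))
    .with_seed(seed, {
        ord <- sample.int(n)
        keep <- logical(n)
        for (i in ord)
            keep[i] <- !any(keep[nbr[[i]]])
        which(keep)
    })
}

#' Serialize an intensity model to JSON
#'
#' Writes coefficients, degree, cell type, the M-H scaling information and
#' the window boundary, so model fitting and data generation can be run
#' separately.
#'
#' @param model an \linkS4class{IntensityModel}.
#' @param path output JSON path.
#' @export
writeIntensityModel <- function(model, path) {
    w <- spatstat.geom::as.polygonal(model@window@win)
    jsonlite::write_json(list(
        cell_type = model@cellType,
        degree = model@degree,
        coefficients = model@coefficients,
        max_log_intensity = model@maxLogIntensity,
        window_wkt = windowWKT(model@window),
        window_rings = lapply(w$bdry, function(p) list(x = p$x, y = p$y))),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeIntensityModel
#' @export
readIntensityModel <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    rings <- j$window_rings
    if (is.data.frame(rings)) rings <- split(rings, seq_len(nrow(rings)))
    poly <- lapply(rings, function(p)
        list(x = unlist(p$x), y = unlist(p$y)))
    win <- spatstat.geom::owin(poly = poly)
    new("IntensityModel", cellType = j$cell_type,
        degree = as.integer(j$degree), coefficients = j$coefficients,
        window = new("SpatialWindow", win = win),
        maxLogIntensity = j$max_log_intensity, vcov = NULL)
}
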