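# Internal helpers shared across modules.

# 4-connectivity check of a logical grid (flood fill from the first TRUE).
.grid_connected <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) <= 1L) return(TRUE)
    nr <- nrow(mask); nc <- ncol(mask)
    visited <- matrix(FALSE, nr, nc)
    stack <- idx[1L, , drop = FALSE]
    visited[stack] <- TRUE
    count <- 1L
    while (nrow(stack) > 0L) {
        cur <- stack[nrow(stack), ]
        stack <- stack[-nrow(stack), , drop = FALSE]
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
            i <- cur[1L] + d[1L]; j <- cur[2L] + d[2L]
            if (i >= 1L && i <= nr && j >= 1L && j <= nc &&
                mask[i, j] && !visited[i, j]) {
                visited[i, j] <- TRUE
                count <- count + 1L
                stack <- rbind(stack, c(i, j))
            }
        }
    }
    count == nrow(idx)
}

# Scoped seeding: set the RNG state for the duration of the calling function
# only, so library code does not clobber the user's RNG stream. A NULL seed
# leaves the current stream untouched.
.with_seed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

.assert <- function(cond, msg, ...) {
    if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Round half away from zero (counts are non-negative here, so floor(x + .5)).
.round_half_up <- function(x) floor(x + 0.5)

# owin helpers -----------------------------------------------------------

.as_owin <- function(window) {
    if (is(window, "SpatialWindow")) window@win else window
}

#' Construct a SpatialWindow
#'
#' @param win an \code{spatstat.geom::owin}, or missing to use \code{xrange}/
#'   \code{yrange}.
#' @param xrange,yrange numeric(2) ranges for a rectangular window.
#' @return a \linkS4class{SpatialWindow}.
#' @examples
#' w <- spatialWindow(xrange = c(0, 1), yrange = c(0, 1))
#' windowArea(w)
#' @export
spatialWindow <- function(win = NULL, xrange = c(0, 1), yrange = c(0, 1)) {
    if (is.null(win)) win <- spatstat.geom::owin(xrange, yrange)
    new("SpatialWindow", win = win)
}
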