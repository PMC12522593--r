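#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Aggregate single cells into multi-cell spots
#'
#' Emulates spot-based SRT platforms: the window's bounding box is tiled
#' into an s x s grid of equal squares with s = ceiling(sqrt(n_squares))
#' (the closest square layout with s^2 >= n_squares); each cell inside the
#' window is assigned to its square; expression is summed per square and
#' the spot coordinate is the square's center. Squares that intersect the
#' window are retained even when empty (zero counts); squares wholly
#' outside the window are dropped. Users are advised to choose
#' \code{n_squares} so spots cover roughly 0-40 cells.
#'
#' @param x,y cell coordinates.
#' @param counts gene x cell matrix.
#' @param window a \linkS4class{SpatialWindow}.
#' @param n_squares requested number of squares (>= 1).
#' @return a \linkS4class{SpotGrid}. Total spot counts equal the total
#'   counts of all in-window cells.
#' @export
aggregateMultiCell <- function(x, y, counts, window, n_squares) {
    .assert(n_squares >= 1L, "n_squares must be >= 1")
    win <- .as_owin(window)
    s <- ceiling(sqrt(n_squares))
    xr <- win$xrange; yr <- win$yrange
    side <- max(diff(xr), diff(yr)) / s
    inw <- spatstat.geom::inside.owin(x, y, win)
    ix <- pmin(pmax(floor((x - xr[1L]) / side) + 1L, 1L), s)
    iy <- pmin(pmax(floor((y - yr[1L]) / side) + 1L, 1L), s)
    cellspot <- (iy - 1L) * s + ix
    grid <- expand.grid(ix = seq_len(s), iy = seq_len(s))
    cx <- xr[1L] + (grid$ix - 0.5) * side
    cy <- yr[1L] + (grid$iy - 0.5) * side
    # a square is kept if it intersects the window (tested on the square
    # polygon), or contains a cell
    keep <- vapply(seq_len(nrow(grid)), function(i) {
        sq <- spatstat.geom::owin(xr[1L] + c(grid$ix[i] - 1L, grid$ix[i]) * side,
                                  yr[1L] + c(grid$iy[i] - 1L, grid$iy[i]) * side)
        ov <- spatstat.geom::intersect.owin(sq, win, fatal = FALSE)
        !is.null(ov) && !spatstat.geom::is.empty(ov) &&
            spatstat.geom::area.owin(ov) > 0
    }, logical(1))
    keep <- keep | seq_len(nrow(grid)) %in% cellspot[inw]
    spot_ids <- which(keep)
    spot_counts <- matrix(0, nrow(counts), length(spot_ids),
                          dimnames = list(rownames(counts),
                                          sprintf("spot%d", spot_ids)))
    cps <- tabulate(match(cellspot[inw], spot_ids), length(spot_ids))
    if (any(inw)) {
        agg <- rowsum(t(counts[, inw, drop = FALSE]), cellspot[inw])
        cols <- match(as.integer(rownames(agg)), spot_ids)
        spot_counts[, cols] <- t(agg)
    }
    storage.mode(spot_counts) <- storage.mode(counts)
    new("SpotGrid", counts = spot_counts,
        centers = cbind(x = cx[spot_ids], y = cy[spot_ids]),
        cellsPerSpot = cps, squareSize = side)
}

#' Spatial coverage metrics between simulated and reference windows
#'
#' Area-based fidelity of a simulated spatial window against the reference:
#' total coverage (area(sim)/area(ref), ideal 100), overlap with the
#' reference (area(sim intersect ref)/area(ref), ideal 100),
#' reference-only area (ideal 0) and simulation-only area (ideal 0), all
#' as percentages of the reference area.
#'
#' @param sim_window,ref_window \linkS4class{SpatialWindow}s.
#' @return named numeric vector \code{total}, \code{overlap},
#'   \code{ref_only}, \code{sim_only} (percent).
#' @export
coverageMetrics <- function(sim_window, ref_window) {
    sw <- .as_owin(sim_window); rw <- .as_owin(ref_window)
    ra <- spatstat.geom::area.owin(rw)
    .assert(ra > 0, "reference window has zero area")
    sa <- spatstat.geom::area.owin(sw)
    ov <- spatstat.geom::intersect.owin(sw, rw, fatal = FALSE)
    oa <- if (is.null(ov) || spatstat.geom::is.empty(ov)) 0 else
        spatstat.geom::area.owin(ov)
    c(total = 100 * sa / ra,
      overlap = 100 * oa / ra,
      ref_only = 100 * (ra - oa) / ra,
      sim_only = 100 * (sa - oa) / ra)
}

#' Absolute and relative bias of simulated against reference values
#'
#' AB = simulated - reference; RB = (simulated - reference)/reference,
#' reported in percent. Elements with a zero reference have undefined RB
#' (NA, flagged via the \code{rb_defined} column).
#'
#' @param sim_values,ref_values equal-length numeric vectors.
#' @return list with the per-element data.frame (\code{ab}, \code{rb_pct},
#'   \code{rb_defined}) and medians \code{median_ab}, \code{median_rb_pct}.
#' @export
biasMetrics <- function(sim_values, ref_values) {
    .assert(length(sim_values) == length(ref_values),
        "sim and ref lengths differ")
    ab <- sim_values - ref_values
    ok <- ref_values != 0
    rb <- rep(NA_real_, length(ab))
    rb[ok] <- 100 * ab[ok] / ref_values[ok]
    list(per_element = data.frame(ab = ab, rb_pct = rb, rb_defined = ok),
         median_ab = stats::median(ab),
         median_rb_pct = stats::median(rb, na.rm = TRUE))
}

#' Effect-size recovery: correlation and MSE
#'
#' Fidelity of CCI effect sizes re-estimated from simulated data against
#' the effects estimated from the reference.
#'
#' @param sim_effects,ref_effects equal-length numeric vectors (>= 3).
#' @return named numeric vector \code{pearson_r}, \code{mse}.
#' @export
effectRecoveryMetrics <- function(sim_effects, ref_effects) {
    .assert(length(sim_effects) == length(ref_effects),
        "effect vectors differ in length")
    .assert(length(sim_effects) >= 3L, "need at least 3 effect sizes")
    .assert(stats::sd(sim_effects) > 0 && stats::sd(ref_effects) > 0,
        "correlation undefined for constant effect vectors")
    c(pearson_r = stats::cor(sim_effects, ref_effects),
      mse = mean((sim_effects - ref_effects)^2))
}

.f1_score <- function(predicted, truth, universe) {
    tp <- length(intersect(predicted, truth))
    if (tp == 0L) return(0)
    prec <- tp / length(predicted)
    rec <- tp / length(truth)
    2 * prec * rec / (prec + rec)
}

#' Benchmark LR-interaction predictions against ground truth
#'
#' Scores a set of predicted ligand-receptor interaction keys (e.g.
#' "ligand|receptor|sender_type|receiver_type") against the simulated
#' ground truth over a declared universe of candidate interactions:
#' balanced accuracy = (sensitivity + specificity)/2, and the normalized
#' F1 = observed F1 divided by the mean F1 of \code{n_shuffles} random
#' predictions of the same size drawn from the universe. With zero true
#' positives both the F1 and its normalized version are 0.
#'
#' @param predicted,truth character vectors, subsets of \code{universe}.
#' @param universe character vector of all candidate interaction keys.
#' @param n_shuffles permutations for the F1 normalization (default 100).
#' @param seed optional integer seed.
#' @return named numeric vector \code{balanced_accuracy},
#'   \code{normalized_f1}, \code{f1}.
#' @export
benchmarkMetrics <- function(predicted, truth, universe, n_shuffles = 100L,
                             seed = NULL) {
    .assert(length(universe) > 0L, "empty universe")
    universe <- unique(universe)
    predicted <- unique(predicted); truth <- unique(truth)
    .assert(all(predicted %in% universe), "predictions outside the universe")
    .assert(all(truth %in% universe), "truth outside the universe")
    tp <- length(intersect(predicted, truth))
    fn <- length(setdiff(truth, predicted))
    fp <- length(setdiff(predicted, truth))
    tn <- length(universe) - tp - fn - fp
    tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    bacc <- mean(c(tpr, tnr), na.rm = TRUE)
    f1 <- .f1_score(predicted, truth, universe)
    nf1 <- 0
    if (f1 > 0) {
        perm_f1 <- .with_seed(seed, vapply(seq_len(n_shuffles), function(i)
            .f1_score(sample(universe, length(predicted)), truth, universe),
            numeric(1)))
        mpf <- mean(perm_f1)
        nf1 <- if (mpf > 0) f1 / mpf else 0
    }
    c(balanced_accuracy = bacc, normalized_f1 = nf1, f1 = f1)
}
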