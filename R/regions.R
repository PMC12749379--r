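# Exact algebra on unions of half-open arcs of the crank circle.
#
# A region_set is the shared representation of every stimulation region and
# RoA: an ordered set of disjoint, non-adjacent half-open arcs
# [start, end) with 0 <= start < end <= 360.  Half-open arcs make adjacent
# regions tile the circle without double counting, so the four confusion
# measures partition the 360 degrees exactly.  Arcs are stored split at
# 0/360; wraparound is permitted in input.

arc_merge_tol <- 1e-9

#' Construct a set of circular arcs
#'
#' Builds a normalised arc set on the crank circle from raw half-open arcs
#' `[start, end)` in degrees.  Input arcs may wrap (e.g. `c(350, 370)` or
#' `c(350, 10)`), overlap, touch or be empty; normalisation splits wrapping
#' arcs at 0/360, merges overlapping and adjacent arcs, drops empty ones and
#' sorts by start.  An arc whose span is 360 degrees or more becomes the
#' full circle.
#'
#' @param arcs A two-column matrix (or a length-2 vector, or a list of
#'   length-2 vectors) of `start`, `end` degrees.  An `end` below its
#'   `start` is read as wrapping through 0/360.
#' @return An object of class `region_set`: a normalised two-column matrix.
#' @examples
#' region_set(c(350, 370))              # {[0,10), [350,360)}
#' region_set(rbind(c(0, 50), c(40, 100)))
#' region_measure(region_set(NULL))     # empty set, measure 0
#' @export
region_set <- function(arcs = NULL) {
  if (is.null(arcs) || (is.matrix(arcs) && nrow(arcs) == 0L)) {
    return(new_region(matrix(numeric(0), ncol = 2)))
  }
  if (is.list(arcs) && !is.data.frame(arcs)) arcs <- do.call(rbind, arcs)
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs)
  if (is.numeric(arcs) && is.null(dim(arcs))) arcs <- matrix(arcs, ncol = 2, byrow = TRUE)
  if (!is.numeric(arcs) || ncol(arcs) != 2L || any(!is.finite(arcs)))
    stop_fescycle("bad_region", "arcs must be finite numeric [start, end) pairs")
  start <- arcs[, 1]
  end <- arcs[, 2]
  span <- end - start
  span[span < 0] <- span[span < 0] %% 360  # end < start wraps forward
  span <- pmin(span, 360)
  start <- start %% 360
  keep <- span > 0
  start <- start[keep]
  span <- span[keep]
  # split wrapping arcs at 0/360
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_along(start)) {
    s <- start[i]
    e <- s + span[i]
    if (e <= 360 + arc_merge_tol) {
      out <- rbind(out, c(s, min(e, 360)))
    } else {
      out <- rbind(out, c(s, 360), c(0, e - 360))
    }
  }
  if (nrow(out) == 0L) return(new_region(out))
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  merged <- out[1, , drop = FALSE]
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      j <- nrow(merged)
      if (out[i, 1] <= merged[j, 2] + arc_merge_tol) {
        merged[j, 2] <- max(merged[j, 2], out[i, 2])
      } else {
        merged <- rbind(merged, out[i, , drop = FALSE])
      }
    }
  }
  new_region(merged)
}

new_region <- function(m) {
  colnames(m) <- c("start", "end")
  rownames(m) <- NULL
  class(m) <- c("region_set", class(m))
  m
}

as_region <- function(x) {
  if (inherits(x, "region_set")) x else region_set(x)
}

#' The empty region and the full circle
#' @return A `region_set`.
#' @export
empty_region <- function() region_set(NULL)

#' @rdname empty_region
#' @export
full_circle <- function() region_set(c(0, 360))

#' Total angular measure of a region
#'
#' @param x A `region_set` (or raw arcs, normalised first).
#' @return Arc length in degrees, in `[0, 360]`.
#' @export
region_measure <- function(x) {
  x <- as_region(x)
  if (nrow(x) == 0L) 0 else sum(x[, 2] - x[, 1])
}

#' Set operations on circular arc sets
#'
#' Standard set semantics on the circle under the half-open arc convention.
#' `region_complement()` satisfies
#' `region_measure(x) + region_measure(region_complement(x)) == 360`
#' exactly up to the `1e-9` endpoint tolerance; De Morgan's laws and the
#' inclusion-exclusion identity hold for arbitrary inputs.
#' `region_rotate()` shifts every endpoint by `delta` degrees mod 360
#' (measure preserving; rotating twice by 180 is the identity).
#'
#' @param x,y `region_set` objects (or raw arcs).
#' @param delta Rotation in degrees.
#' @return A `region_set`.
#' @examples
#' a <- region_set(c(0, 100)); b <- region_set(c(50, 150))
#' region_intersect(a, b)                       # [50, 100)
#' region_measure(region_union(a, b)) +
#'   region_measure(region_intersect(a, b))     # == 100 + 100
#' @export
region_union <- function(x, y) {
  region_set(rbind(unclass(as_region(x)), unclass(as_region(y))))
}

#' @rdname region_union
#' @export
region_complement <- function(x) {
  x <- as_region(x)
  if (nrow(x) == 0L) return(full_circle())
  bounds <- c(0, as.vector(t(unclass(x))), 360)
  gaps <- matrix(bounds, ncol = 2, byrow = TRUE)
  region_set(gaps[gaps[, 2] - gaps[, 1] > arc_merge_tol, , drop = FALSE])
}

#' @rdname region_union
#' @export
region_intersect <- function(x, y) {
  x <- as_region(x)
  y <- as_region(y)
  if (nrow(x) == 0L || nrow(y) == 0L) return(empty_region())
  pieces <- list()
  for (i in seq_len(nrow(x))) {
    s <- pmax(x[i, 1], y[, 1])
    e <- pmin(x[i, 2], y[, 2])
    keep <- e - s > arc_merge_tol
    if (any(keep)) pieces[[length(pieces) + 1L]] <- cbind(s[keep], e[keep])
  }
  if (!length(pieces)) empty_region() else region_set(do.call(rbind, pieces))
}

#' @rdname region_union
#' @export
region_diff <- function(x, y) {
  region_intersect(x, region_complement(y))
}

#' @rdname region_union
#' @export
region_rotate <- function(x, delta) {
  x <- as_region(x)
  if (nrow(x) == 0L) return(x)
  region_set(cbind(x[, 1] + delta, x[, 2] + delta))
}

#' Arc membership
#'
#' Tests crank angles for membership under the half-open `[start, end)`
#' convention: an arc's start angle is inside, its end angle is not.
#'
#' @param x A `region_set`.
#' @param q Crank angle(s) in degrees (normalised mod 360).
#' @return A logical vector along `q`.
#' @export
region_contains <- function(x, q) {
  x <- as_region(x)
  q <- norm_deg(q)
  if (nrow(x) == 0L) return(rep(FALSE, length(q)))
  vapply(q, function(a) any(x[, 1] <= a & a < x[, 2]), logical(1))
}

#' Number of contiguous components on the circle
#'
#' Counts maximal contiguous arcs, treating a pair that touches across the
#' 0/360 seam as a single component (the normalised storage splits such an
#' arc in two).
#'
#' @param x A `region_set`.
#' @return A non-negative integer.
#' @export
region_components <- function(x) {
  x <- as_region(x)
  n <- nrow(x)
  if (n == 0L) return(0L)
  wrap <- n > 1L && x[1, 1] <= arc_merge_tol && x[n, 2] >= 360 - arc_merge_tol
  if (region_measure(x) >= 360 - arc_merge_tol) return(1L)
  as.integer(n - wrap)
}

# start of a contiguous region in circular terms (the start of the arc that
# is not preceded by region across the seam); NA for empty or multi-component
region_circular_start <- function(x) {
  x <- as_region(x)
  if (region_components(x) != 1L) return(NA_real_)
  n <- nrow(x)
  if (n > 1L && x[1, 1] <= arc_merge_tol && x[n, 2] >= 360 - arc_merge_tol)
    x[n, 1] else x[1, 1]
}

#' @export
print.region_set <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<region_set: empty>\n")
  } else {
    arcs <- apply(unclass(x), 1, function(a) sprintf("[%.4g, %.4g)", a[1], a[2]))
    cat(sprintf("<region_set: %s; measure %.4g deg>\n",
                paste(arcs, collapse = " u "), region_measure(x)))
  }
  invisible(x)
}

#' Serialise a region to / from a JSON document
#'
#' Writes `{"target": ..., "direction": "cw"|"ccw", "side": "right"|"left",
#' "arcs": [[start, end], ...]}` with endpoints in degrees in normalised
#' form (4 decimal places), and reads it back.
#'
#' @param x A `region_set`.
#' @param path File path.
#' @param target,direction,side Metadata labels stored in the document.
#' @return `write_region_json()` returns `path` invisibly;
#'   `read_region_json()` returns a list with elements `target`,
#'   `direction`, `side` and `region` (a `region_set`).
#' @export
write_region_json <- function(x, path, target = "region",
                              direction = c("cw", "ccw"),
                              side = c("right", "left")) {
  direction <- match.arg(direction)
  side <- match.arg(side)
  x <- as_region(x)
  arcs <- lapply(seq_len(nrow(x)),
                 function(i) round(as.numeric(x[i, ]), 4))
  doc <- list(target = target, direction = direction, side = side,
              arcs = arcs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_region_json
#' @export
read_region_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  arcs <- doc$arcs
  if (is.list(arcs)) arcs <- do.call(rbind, arcs)
  if (is.null(arcs) || length(arcs) == 0L) {
    reg <- empty_region()
  } else {
    reg <- region_set(matrix(as.numeric(arcs), ncol = 2))
  }
  list(target = doc$target, direction = doc$direction, side = doc$side,
       region = reg)
}
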