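#' Parameter search-space bounds
#'
#' Lower and upper limits per model parameter, defining the box over
#' which support points are placed. All limits must be strictly positive
#' with `lower < upper`.
#'
#' @param ... Named length-2 numeric vectors `c(lower, upper)`, e.g.
#'   `ke = c(0.001, 2)`.
#' @return An object of class `param_bounds`: a named list of
#'   `c(lower, upper)` pairs.
#' @export
#' @examples
#' param_bounds(ke = c(0.001, 2), v = c(125, 625))
param_bounds <- function(...) {
  b <- list(...)
  if (length(b) == 1L && is.list(b[[1]]) && is.null(names(b)))
    b <- b[[1]]
  if (is.null(names(b)) || any(names(b) == ""))
    stop("all bounds must be named")
  for (nm in names(b)) {
    x <- as.numeric(b[[nm]])
    if (length(x) != 2L || !all(is.finite(x)) || x[1] <= 0 || x[1] >= x[2])
      stop("invalid bounds for '", nm, "': need 0 < lower < upper")
    b[[nm]] <- x
  }
  structure(b, class = "param_bounds")
}

#' @export
print.param_bounds <- function(x, ...) {
  cat("<parameter bounds>\n")
  for (nm in names(x))
    cat(sprintf("  %-4s [%g, %g]\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

bounds_matrix <- function(bounds) {
  m <- vapply(bounds, identity, numeric(2))
  rownames(m) <- c("lower", "upper")
  m
}

# map points to [0,1]^d using the bounds box
scale_to_unit <- function(points, bounds) {
  m <- bounds_matrix(bounds)
  sweep(sweep(points, 2, m["lower", ], "-"), 2,
        m["upper", ] - m["lower", ], "/")
}
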