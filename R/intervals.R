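#' Ordered disjoint genomic intervals
#'
#' An `interval_set` is the package's representation of a set of 1-based,
#' inclusive, pairwise-disjoint intervals on a single chromosome, used for
#' donor-region fragments, QTL support regions and the atomic bins of the
#' sequential inference. Construction normalizes the input: intervals are
#' sorted, and overlapping or book-ended (adjacent) intervals are merged, so
#' two sets covering the same base pairs always have identical representation.
#' Set operations are delegated to \pkg{IRanges}, whose integer-range model
#' matches the 1-based inclusive convention used here.
#'
#' @param start,end integer vectors of equal length; `start <= end` pairwise.
#' @return An object of class `interval_set` with fields `start` and `end`.
#' @examples
#' a <- interval_set(c(1, 5), c(4, 10))   # normalizes to [1, 10]
#' b <- interval_set(5, 20)
#' ivs_symdiff(a, b)                      # [11, 20]
#' @export
interval_set <- function(start = integer(), end = integer()) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end)) {
    stop("start and end must have equal length")
  }
  if (anyNA(start) || anyNA(end)) stop("interval bounds must not be NA")
  if (any(start < 1)) stop("coordinates are 1-based: start must be >= 1")
  if (any(end < start)) stop("interval end must be >= start")
  if (length(start) == 0) {
    return(structure(list(start = integer(), end = integer()),
                     class = "interval_set"))
  }
  .from_iranges(IRanges::reduce(.as_iranges(start, end)))
}

.as_iranges <- function(start, end) {
  IRanges::IRanges(start = as.integer(start), end = as.integer(end))
}

.ivs_iranges <- function(x) .as_iranges(x$start, x$end)

.from_iranges <- function(ir) {
  structure(list(start = as.integer(IRanges::start(ir)),
                 end = as.integer(IRanges::end(ir))),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  n <- length(x$start)
  cat(sprintf("<interval_set: %d interval%s, %s bp>\n",
              n, if (n == 1) "" else "s",
              format(ivs_length(x), big.mark = ",")))
  if (n > 0) {
    cat(paste0("  [", format(x$start, big.mark = ","), ", ",
               format(x$end, big.mark = ","), "]\n"), sep = "")
  }
  invisible(x)
}

#' @export
format.interval_set <- function(x, ...) {
  if (ivs_is_empty(x)) return("{}")
  paste0("{", paste0("[", x$start, ",", x$end, "]", collapse = " "), "}")
}

#' Interval-set algebra
#'
#' Union, intersection, set difference and symmetric difference of two
#' `interval_set` objects, interpreting each as the set of integer base pairs
#' it covers. Results are canonically normalized. `ivs_length()` returns the
#' total number of base pairs covered (inclusive); it is the edge weight used
#' by the minimum spanning tree over strains.
#'
#' @param a,b `interval_set` objects on the same chromosome.
#' @return `interval_set`, except `ivs_length()` which returns a number and
#'   `ivs_is_empty()` / `ivs_equal()` which return a logical.
#' @export
ivs_union <- function(a, b) {
  .check_ivs(a); .check_ivs(b)
  .from_iranges(IRanges::reduce(c(.ivs_iranges(a), .ivs_iranges(b))))
}

#' @rdname ivs_union
#' @export
ivs_intersect <- function(a, b) {
  .check_ivs(a); .check_ivs(b)
  .from_iranges(IRanges::intersect(.ivs_iranges(a), .ivs_iranges(b)))
}

#' @rdname ivs_union
#' @export
ivs_setdiff <- function(a, b) {
  .check_ivs(a); .check_ivs(b)
  .from_iranges(IRanges::setdiff(.ivs_iranges(a), .ivs_iranges(b)))
}

#' @rdname ivs_union
#' @export
ivs_symdiff <- function(a, b) {
  ivs_union(ivs_setdiff(a, b), ivs_setdiff(b, a))
}

#' @rdname ivs_union
#' @export
ivs_length <- function(a) {
  .check_ivs(a)
  if (length(a$start) == 0) return(0)
  sum(a$end - a$start + 1)
}

#' @rdname ivs_union
#' @export
ivs_is_empty <- function(a) {
  .check_ivs(a)
  length(a$start) == 0
}

#' @rdname ivs_union
#' @export
ivs_equal <- function(a, b) {
  .check_ivs(a); .check_ivs(b)
  length(a$start) == length(b$start) &&
    all(a$start == b$start) && all(a$end == b$end)
}

#' Does the set cover a position?
#'
#' @param a an `interval_set`.
#' @param pos numeric vector of 1-based positions.
#' @return logical vector, one element per position.
#' @export
ivs_covers <- function(a, pos) {
  .check_ivs(a)
  vapply(pos, function(p) any(a$start <= p & p <= a$end), logical(1))
}

.check_ivs <- function(x) {
  if (!inherits(x, "interval_set")) {
    stop("expected an interval_set; got ", class(x)[1])
  }
  invisible(x)
}
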