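#' Lazy on-disk matrix handle for backed .h5mu reads
#'
#' `H5BackedMatrix` objects stand in for a modality's `X` (or a layer)
#' when a file is opened with `read_h5mu(path, backed = TRUE)`. They carry
#' the file path, the in-file dataset/group path, the matrix shape and the
#' storage kind (`"dense"` or `"csr"`), and satisfy the matrix read
#' contract — `dim()`, row/column slicing with `[`, full materialisation —
#' without touching matrix content until asked.
#'
#' @name H5BackedMatrix
#' @aliases is_backed materialize
NULL

new_backed <- function(file, name, shape, kind) {
  structure(list(file = file, name = name, shape = as.integer(shape), kind = kind),
            class = "H5BackedMatrix")
}

#' @param x any object.
#' @return `is_backed()`: `TRUE` for an `H5BackedMatrix`.
#' @rdname H5BackedMatrix
#' @export
is_backed <- function(x) inherits(x, "H5BackedMatrix")

#' @export
dim.H5BackedMatrix <- function(x) x$shape

#' @export
print.H5BackedMatrix <- function(x, ...) {
  cat(sprintf("H5BackedMatrix  %d x %d (%s) <%s::%s>\n",
              x$shape[1], x$shape[2], x$kind, x$file, x$name))
  invisible(x)
}

#' Materialise a backed matrix in memory
#'
#' @param x an `H5BackedMatrix` (in-memory matrices pass through).
#' @return A dense matrix, or a `dgRMatrix` for row-sparse storage.
#' @rdname H5BackedMatrix
#' @export
materialize <- function(x) UseMethod("materialize")

#' @export
materialize.default <- function(x) x

#' @export
materialize.H5BackedMatrix <- function(x) {
  if (x$kind == "dense") {
    t(h5read_tracked(x$file, x$name))
  } else {
    methods::new("dgRMatrix",
                 p = as.integer(h5read_tracked(x$file, paste0(x$name, "/indptr"))),
                 j = as.integer(h5read_tracked(x$file, paste0(x$name, "/indices"))),
                 x = as.double(h5read_tracked(x$file, paste0(x$name, "/data"))),
                 Dim = x$shape)
  }
}

#' @export
`[.H5BackedMatrix` <- function(x, i, j, drop = FALSE) {
  n <- x$shape[1]; d <- x$shape[2]
  if (missing(i)) i <- seq_len(n)
  if (missing(j)) j <- seq_len(d)
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) && (min(i) < 1L || max(i) > n)) stop("row index out of range")
  if (length(j) && (min(j) < 1L || max(j) > d)) stop("column index out of range")
  if (x$kind == "dense") {
    # stored transposed on disk; hyperslab wants sorted unique indices
    si <- sort(unique(i)); sj <- sort(unique(j))
    blk <- h5read_tracked(x$file, x$name, index = list(sj, si))
    out <- t(blk)[match(i, si), match(j, sj), drop = FALSE]
  } else {
    indptr <- as.integer(h5read_tracked(x$file, paste0(x$name, "/indptr")))
    rows <- lapply(i, function(r) {
      lo <- indptr[r] + 1L; hi <- indptr[r + 1L]
      if (hi < lo) return(list(j = integer(), x = double()))
      list(j = as.integer(h5read_tracked(x$file, paste0(x$name, "/indices"),
                                         index = list(lo:hi))) + 1L,
           x = as.double(h5read_tracked(x$file, paste0(x$name, "/data"),
                                        index = list(lo:hi))))
    })
    out <- matrix(0, length(i), d)
    for (r in seq_along(rows))
      if (length(rows[[r]]$j)) out[r, rows[[r]]$j] <- rows[[r]]$x
    out <- out[, j, drop = FALSE]
  }
  if (drop && (length(i) == 1L || length(j) == 1L)) drop(out) else out
}

#' @export
as.matrix.H5BackedMatrix <- function(x, ...) {
  m <- materialize(x)
  if (inherits(m, "sparseMatrix")) as.matrix(m) else m
}
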