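#' @import methods
#' @importFrom stats quantile rnorm runif rbeta rpois sd setNames
#' @importFrom utils write.csv
NULL

## Internal argument checks --------------------------------------------------

.assertScalarNum <- function(x, name, lower = -Inf, upper = Inf) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a finite numeric scalar", name),
             call. = FALSE)
    if (x < lower || x > upper)
        stop(sprintf("'%s' must lie in [%s, %s], got %s", name,
                     format(lower), format(upper), format(x)), call. = FALSE)
    invisible(x)
}

.assertCount <- function(x, name, lower = 0L) {
    .assertScalarNum(x, name, lower = lower)
    if (x != round(x))
        stop(sprintf("'%s' must be an integer, got %s", name, format(x)),
             call. = FALSE)
    invisible(as.integer(x))
}

.assertGrayImage <- function(x, name = deparse(substitute(x))) {
    if (!is.matrix(x) || !is.numeric(x) || any(!is.finite(x)))
        stop(sprintf("'%s' must be a numeric matrix of finite intensities",
                     name), call. = FALSE)
    if (nrow(x) < 1L || ncol(x) < 1L)
        stop(sprintf("'%s' must have positive dimensions", name),
             call. = FALSE)
    invisible(x)
}

## Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        set.seed(NULL)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

## Minimal NPY v1.0 serialization (float64, C order) -------------------------

#' Write a numeric matrix as an NPY array file
#'
#' Serializes a matrix as a version 1.0 NPY file (float64, C order), the
#' lossless floating-point sidecar format used by \code{\link{writeCorrectedImage}}.
#' Image matrices follow the package convention \code{[x + 1, y + 1]} (first
#' index = column, second = row); on disk the array is stored row-major with
#' shape \code{(height, width)} so that generic NPY readers see the image in
#' conventional row/column order.
#'
#' @param x numeric matrix (width x height, package convention).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readNpy}}
#' @export
writeNpy <- function(x, path) {
    .assertGrayImage(x, "x")
    shape <- sprintf("(%d, %d)", ncol(x), nrow(x))
    header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }",
                      shape)
    ## pad so magic(6)+ver(2)+len(2)+header is a multiple of 64, ending in \n
    total <- 10L + nchar(header) + 1L
    pad <- (64L - total %% 64L) %% 64L
    header <- paste0(header, strrep(" ", pad), "\n")
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
    writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
    writeBin(charToRaw(header), con)
    ## column-major over (width, height) == row-major over (height, width)
    writeBin(as.numeric(x), con, size = 8L, endian = "little")
    invisible(path)
}

#' Read an NPY array file written by \code{\link{writeNpy}}
#'
#' Supports the subset of NPY v1.0 this package writes: float64, C order,
#' 2-D shape.
#'
#' @param path NPY file path.
#' @return numeric matrix in the package's width x height convention.
#' @export
readNpy <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", 8L)
    if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY")))))
        stop("not an NPY file: ", path, call. = FALSE)
    hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little",
                    signed = FALSE)
    header <- rawToChar(readBin(con, "raw", hlen))
    if (!grepl("'<f8'", header) || grepl("True", header))
        stop("unsupported NPY header: ", header, call. = FALSE)
    m <- regmatches(header, regexec("\\((\\d+), (\\d+)\\)", header))[[1]]
    h <- as.integer(m[2]); w <- as.integer(m[3])
    vals <- readBin(con, "numeric", w * h, size = 8L, endian = "little")
    matrix(vals, nrow = w, ncol = h)
}
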