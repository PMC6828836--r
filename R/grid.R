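#' Regular concentration grid
#'
#' A `conc_field` holds PM2.5 concentrations (ug/m3) on a regular square grid.
#' Cells are `res` km wide; cell (i, j) has its centre at
#' `(xmin + (i - 0.5) * res, ymin + (j - 0.5) * res)` and values are stored in
#' an `nx` x `ny` matrix (x runs along rows). Values are cell means; the grid
#' lives in projected km coordinates.
#'
#' @param values numeric matrix (`nx` x `ny`) of concentrations, all finite
#'   and non-negative.
#' @param xmin,ymin lower-left corner of the grid (km).
#' @param res cell size in km (default 1, i.e. 1-km^2 cells).
#' @param label temporal label, e.g. a date, `"annual mean, 2015"` or
#'   `"5-year mean"`.
#' @return An object of class `conc_field`.
#' @export
conc_field <- function(values, xmin = 0, ymin = 0, res = 1, label = "") {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    stop("conc_field values must be finite numerics")
  }
  if (any(values < 0)) stop("conc_field values must be non-negative")
  if (res <= 0) stop("res must be positive")
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res,
         nx = nrow(values), ny = ncol(values), label = label),
    class = "conc_field"
  )
}

#' @export
print.conc_field <- function(x, ...) {
  cat(sprintf("<conc_field> %dx%d cells, %.0f-km res, origin (%g, %g)\n",
              x$nx, x$ny, x$res, x$xmin, x$ymin))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  cat(sprintf("  values: min %.4g, mean %.4g, max %.4g\n",
              min(x$values), mean(x$values), max(x$values)))
  invisible(x)
}

# cell-centre coordinate vectors
field_xs <- function(field) field$xmin + (seq_len(field$nx) - 0.5) * field$res
field_ys <- function(field) field$ymin + (seq_len(field$ny) - 0.5) * field$res

#' Look up the cell containing a point
#'
#' @param field a [conc_field].
#' @param x,y point coordinates (km).
#' @return integer vector `c(ix, iy)` of cell indices.
#' @export
cell_index <- function(field, x, y) {
  ix <- floor((x - field$xmin) / field$res) + 1L
  iy <- floor((y - field$ymin) / field$res) + 1L
  if (ix < 1L || ix > field$nx || iy < 1L || iy > field$ny) {
    stop(sprintf("point (%g, %g) lies outside the grid", x, y))
  }
  c(ix, iy)
}

#' Concentration at a point (value of the containing cell)
#'
#' @inheritParams cell_index
#' @return numeric scalar.
#' @export
field_value_at <- function(field, x, y) {
  ij <- cell_index(field, x, y)
  field$values[ij[1], ij[2]]
}

#' @export
as.data.frame.conc_field <- function(x, ...) {
  data.frame(
    x = rep(field_xs(x), times = x$ny),
    y = rep(field_ys(x), each = x$nx),
    value = as.vector(x$values)
  )
}

#' Write / read a concentration field as CSV
#'
#' Long-format CSV with columns `x`, `y`, `value` plus a header comment
#' carrying the grid metadata, written at full double precision so that the
#' grid round-trips bit-exactly.
#'
#' @param field a [conc_field].
#' @param path file path.
#' @return `write_field_csv` returns `path` invisibly; `read_field_csv`
#'   returns a [conc_field].
#' @export
write_field_csv <- function(field, path) {
  meta <- sprintf("# conc_field xmin=%s ymin=%s res=%s nx=%d ny=%d label=%s",
                  format(field$xmin, digits = 17), format(field$ymin, digits = 17),
                  format(field$res, digits = 17), field$nx, field$ny, field$label)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("x,y,value", con)
  df <- as.data.frame(field)
  writeLines(sprintf("%s,%s,%s",
                     format(df$x, digits = 17, trim = TRUE),
                     format(df$y, digits = 17, trim = TRUE),
                     format(df$value, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  meta <- readLines(path, n = 1)
  kv <- regmatches(meta, gregexpr("[a-z]+=[^ ]*", meta))[[1]]
  get <- function(key) sub(paste0(key, "="), "", kv[startsWith(kv, paste0(key, "="))])
  nx <- as.integer(get("nx")); ny <- as.integer(get("ny"))
  df <- utils::read.csv(path, skip = 1)
  conc_field(matrix(df$value, nrow = nx, ncol = ny),
             xmin = as.numeric(get("xmin")), ymin = as.numeric(get("ymin")),
             res = as.numeric(get("res")),
             label = sub(".*label=", "", meta))  # label may contain spaces
}

# 2-D linear convolution via FFT.
# A is an na x ma matrix, K an odd-dimensioned kernel whose centre element is
# K[(nk+1)/2, (mk+1)/2]; returns a matrix the size of A where
# out[i, j] = sum_s A[s] * K[i - s + centre]. Zero padding outside A.
fft_convolve2d <- function(A, K) {
  nk <- nrow(K); mk <- ncol(K)
  if (nk %% 2 == 0 || mk %% 2 == 0) stop("kernel dimensions must be odd")
  na <- nrow(A); ma <- ncol(A)
  n <- na + nk - 1L; m <- ma + mk - 1L
  pa <- matrix(0, n, m); pa[seq_len(na), seq_len(ma)] <- A
  pk <- matrix(0, n, m); pk[seq_len(nk), seq_len(mk)] <- K
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) / (n * m)
  ci <- (nk + 1L) %/% 2L; cj <- (mk + 1L) %/% 2L
  out <- full[ci:(ci + na - 1L), cj:(cj + ma - 1L), drop = FALSE]
  # FFT round-off can leave tiny negatives where the true value is zero
  out[out < 0 & out > -1e-9 * max(abs(out), 1e-300)] <- 0
  out
}
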