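# Small input helpers for the command-line interface and for users working
# from plain-text files.

#' Build a reference CDF
#'
#' Returns a CDF function for use with \code{\link{kuiper_statistic}} /
#' \code{\link{kuiper_test}}.  Named distributions: \code{"uniform01"},
#' \code{"normal"} (with \code{mean}, \code{sd}) and \code{"exponential"}
#' (with \code{rate}).  Alternatively a two-column table of \code{(x, F(x))}
#' points (a data frame, matrix, or path to a CSV/whitespace file) defines a
#' piecewise-linear CDF, clamped to 0 below the first point and 1 above the
#' last.
#'
#' @param spec distribution name or two-column table/file path.
#' @param mean,sd,rate parameters of the named distributions.
#' @return A function mapping numeric vectors to [0, 1].
#' @examples
#' F <- kuiper_reference_cdf("normal", mean = 1, sd = 2)
#' F(1)
#' @export
kuiper_reference_cdf <- function(spec, mean = 0, sd = 1, rate = 1) {
  if (is.character(spec) && length(spec) == 1L &&
      spec %in% c("uniform01", "normal", "exponential")) {
    return(switch(spec,
      uniform01 = function(x) stats::punif(x),
      normal = function(x) stats::pnorm(x, mean = mean, sd = sd),
      exponential = function(x) stats::pexp(x, rate = rate)))
  }
  tab <- if (is.character(spec)) utils::read.table(spec, header = FALSE,
                                                   sep = "", dec = ".",
                                                   comment.char = "#")
         else as.data.frame(spec)
  if (ncol(tab) < 2L)
    stop_kuiper("a tabulated CDF needs two columns: x and F(x)",
                "kuiperq_data_error")
  xs <- as.numeric(tab[[1]]); Fs <- as.numeric(tab[[2]])
  o <- order(xs); xs <- xs[o]; Fs <- Fs[o]
  if (any(Fs < 0) || any(Fs > 1) || is.unsorted(Fs))
    stop_kuiper("tabulated F(x) must be nondecreasing within [0, 1]",
                "kuiperq_data_error")
  f <- stats::approxfun(xs, Fs, yleft = 0, yright = 1, ties = "ordered")
  function(x) f(x)
}

#' Read a column of observations from a plain-text or CSV file
#'
#' One value per line, or a named/indexed column of a delimited file.
#' @param file path.
#' @param column optional column name or index; if missing, the file is read
#'   as a single column (a header line is skipped automatically when the
#'   first field is not numeric).
#' @return Numeric vector.
#' @export
kuiper_read_observations <- function(file, column = NULL) {
  if (is.null(column)) {
    first <- readLines(file, n = 1L)
    has_header <- is.na(suppressWarnings(as.numeric(strsplit(
      first, "[,;\t ]+")[[1]][1])))
    vals <- utils::read.table(file, header = has_header, sep = "",
                              comment.char = "#")[[1]]
  } else {
    tab <- utils::read.csv(file)
    vals <- tab[[column]]
  }
  vals <- as.numeric(vals)
  if (any(is.na(vals)))
    stop_kuiper("non-numeric values in observation file", "kuiperq_data_error")
  vals
}
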