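#' Saudi Arabia COVID-19 mortality-rate series
#'
#' The 27 daily mortality rates (4-30 August 2021, WHO dashboard) used as
#' the worked real-data example throughout the package.  All values lie in
#' the open unit interval, the support of the MKTL model.
#'
#' @return Numeric vector of length 27.
#' @examples
#' x <- covid_mortality()
#' range(x)
#' @export
covid_mortality <- function() {
  read_mortality_sample(
    system.file("extdata", "saudi_covid_mortality.txt", package = "mktl"))
}

#' Read a unit-interval sample from a text or CSV file
#'
#' Reads one numeric value per line (`format = "txt"`) or the first column
#' of a CSV (`format = "csv"`; a non-numeric header row is skipped).
#' Values outside the open unit interval are rejected with their line
#' numbers.
#'
#' @param path File path.
#' @param format `"txt"` or `"csv"`; guessed from the file extension by
#'   default.
#' @return A validated numeric vector.
#' @export
read_mortality_sample <- function(path, format = c("auto", "txt", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort(paste0("empty file: ", path))
  offset <- 0L
  if (format == "csv") {
    first <- strsplit(lines, ",")[[1]][1]
    if (is.na(suppressWarnings(as.numeric(first)))) {
      lines <- lines[-1L]          # header
      offset <- 1L
      if (!length(lines)) abort(paste0("no data rows in: ", path))
    }
    tokens <- vapply(strsplit(lines, ","), `[`, character(1), 1L)
  } else {
    tokens <- trimws(lines)
  }
  x <- suppressWarnings(as.numeric(tokens))
  if (anyNA(x)) {
    bad <- which(is.na(x)) + offset
    abort(paste0("non-numeric value on line ",
                 paste(head(bad, 5L), collapse = ", "), " of ", path))
  }
  out_of_range <- which(x <= 0 | x >= 1)
  if (length(out_of_range)) {
    abort(paste0("values must lie strictly inside (0, 1); offending line ",
                 paste(head(out_of_range + offset, 5L), collapse = ", "),
                 " of ", path))
  }
  x
}

#' Full analysis report for a unit-interval sample
#'
#' Runs the complete MKTL analysis pipeline on one sample - maximum
#' likelihood and/or Bayesian fits, goodness of fit at the MLE, and fuzzy
#' reliability at the fitted parameters - and collects everything in a
#' self-describing list that serializes cleanly to JSON.
#'
#' @inheritParams mktl_fit_mle
#' @param methods Subset of `c("mle", "bayes")`.
#' @param band Optional [fuzzy_band()]; if supplied, fuzzy reliability is
#'   evaluated at each `gamma` for every fitted method.
#' @param gamma Cut levels for the fuzzy reliability block.
#' @param seed Seed for the Bayesian fit.
#' @param n_iter,burn_in,B Passed to [mktl_fit_bayes()].
#' @return A list of class `"mktl_report"` with components `estimates`
#'   (tibble: method, term, estimate, std.error, conf.low, conf.high),
#'   `gof` (tibble), `fuzzy` (tibble or `NULL`) and `meta` (seed, options,
#'   package version).
#' @examples
#' rep <- mktl_report(covid_mortality(), band = fuzzy_band(0.12, 0.25))
#' rep$estimates
#' @export
mktl_report <- function(data, col = NULL, methods = "mle", band = NULL,
                        gamma = c(0.3, 0.6, 0.9), seed = NULL,
                        level = 0.95, n_iter = 10000L, burn_in = 2000L,
                        B = 1000L) {
  x <- extract_sample(data, col)
  validate_sample(x, n_min = 3L)
  if (!all(methods %in% c("mle", "bayes")))
    abort('`methods` must be a subset of c("mle", "bayes").')

  fits <- list()
  mle <- mktl_fit_mle(x, level = level)
  if ("mle" %in% methods) fits$mle <- mle
  if ("bayes" %in% methods)
    fits$bayes <- mktl_fit_bayes(x, n_iter = n_iter, burn_in = burn_in,
                                 seed = seed, B = B, level = level)

  estimates <- purrr::imap_dfr(fits, function(f, m)
    dplyr::mutate(tidy(f), method = m, .before = 1L))
  fuzzy <- NULL
  if (!is.null(band)) {
    fuzzy <- purrr::imap_dfr(fits, function(f, m)
      dplyr::mutate(fuzzy_reliability(f$theta, f$beta, band, gamma),
                    method = m, .before = 1L))
  }
  structure(list(
    estimates = estimates,
    gof = mktl_gof(mle),
    fuzzy = fuzzy,
    meta = list(
      n = length(x), methods = methods, seed = seed, level = level,
      n_iter = if ("bayes" %in% methods) n_iter else NULL,
      burn_in = if ("bayes" %in% methods) burn_in else NULL,
      package_version = as.character(utils::packageVersion("mktl")),
      r_version = R.version.string
    )
  ), class = "mktl_report")
}

#' @export
print.mktl_report <- function(x, ...) {
  cat("MKTL analysis report (n =", x$meta$n, ")\n\nEstimates:\n")
  print(x$estimates)
  cat("\nGoodness of fit at the MLE:\n")
  print(x$gof)
  if (!is.null(x$fuzzy)) {
    cat("\nFuzzy reliability:\n")
    print(x$fuzzy)
  }
  invisible(x)
}
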