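#' Convert calendar dates to decimal years
#'
#' All sampling and node dates in the package are decimal years. A calendar day
#' is mapped to the middle of that day, so `"2014-07-01"` in a 365-day year
#' becomes `2014 + 181.5/365 = 2014.497`.
#'
#' @param x a `Date`, or a character vector parseable by [as.Date()].
#' @return numeric vector of decimal years.
#' @examples
#' decimal_year("2014-07-01")
#' @export
decimal_year <- function(x) {
  d <- as.Date(x)
  yr <- as.integer(format(d, "%Y"))
  yday <- as.integer(format(d, "%j"))
  ndays <- ifelse((yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0, 366, 365)
  yr + (yday - 0.5) / ndays
}

#' Convert decimal years back to calendar dates
#'
#' Inverse companion of [decimal_year()]; returns the calendar day whose
#' midpoint is nearest the decimal year.
#'
#' @param x numeric vector of decimal years.
#' @return a `Date` vector.
#' @export
calendar_date <- function(x) {
  yr <- floor(x)
  ndays <- ifelse((yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0, 366, 365)
  yday <- pmin(pmax(round((x - yr) * ndays + 0.5), 1), ndays)
  as.Date(yday - 1, origin = as.Date(paste0(yr, "-01-01")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a temporarily seeded RNG stream, restoring the caller's
## RNG state afterwards. seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

DNA_BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chr <- function(s) {
  vapply(strsplit(s, ""), function(b) paste(rev(COMPLEMENT[b]), collapse = ""), "")
}
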