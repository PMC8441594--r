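#' Construct and validate a life table
#'
#' A life table maps integer age to the annual probability of death `qx`.
#' Ages must be contiguous integers, `qx` in \[0, 1\], and the terminal age
#' carries `qx = 1` (life ends at the assumed maximum age).
#'
#' @param age Integer ages, contiguous.
#' @param qx Annual death probabilities.
#' @return A data.frame of class `life_table` with columns `age`, `qx`.
#' @export
life_table <- function(age, qx) {
  if (length(age) != length(qx)) stop("age and qx lengths differ")
  if (any(age != round(age))) stop("ages must be integers")
  o <- order(age)
  age <- age[o]; qx <- qx[o]
  if (any(diff(age) != 1)) stop("ages must be contiguous")
  if (any(qx < 0 | qx > 1)) stop("qx must be in [0, 1]")
  if (qx[length(qx)] != 1)
    stop("terminal age must have qx = 1 (absorbing end of life)")
  out <- data.frame(age = as.integer(age), qx = qx)
  class(out) <- c("life_table", "data.frame")
  out
}

#' Read a life table from CSV
#'
#' Strict parser for the documented interchange format: header `age,qx`,
#' one row per integer age, contiguous ages, terminal `qx = 1`.
#'
#' @param path CSV path.
#' @return A `life_table`.
#' @export
read_life_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(tab)))
    stop("life table must have columns 'age' and 'qx'")
  life_table(tab$age, tab$qx)
}

#' @rdname read_life_table
#' @param lt A `life_table`.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt)[, c("age", "qx")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default synthetic life-table specification
#'
#' Gompertz-Makeham hazard parameters calibrated so that remaining life
#' expectancy at age 55 is about 25 years, in line with 2017 Argentine
#' all-sex mortality. A real national life table in the same CSV format
#' substitutes without code change.
#'
#' @return List with `makeham_a`, `gompertz_b`, `gompertz_c`, `max_age`.
#' @export
default_life_table_spec <- function() {
  list(makeham_a = 5e-4, gompertz_b = 2.3e-5, gompertz_c = 0.10,
       max_age = 100L)
}

#' Generate a synthetic Gompertz-Makeham life table
#'
#' Annual death probability `qx(age) = 1 - exp(-(a + b * exp(c * age)))`,
#' with `qx` forced to 1 at `max_age`. Hazards that exceed certainty before
#' the terminal age are clamped to 1 with a warning.
#'
#' @param spec As [default_life_table_spec()].
#' @param min_age First tabulated age (default 0).
#' @return A `life_table` covering `min_age .. max_age`.
#' @export
generate_life_table <- function(spec = default_life_table_spec(),
                                min_age = 0L) {
  with(spec, {
    if (makeham_a < 0 || gompertz_b < 0 || gompertz_c <= 0 || max_age <= min_age)
      stop("invalid life-table spec")
    ages <- seq.int(min_age, max_age)
    qx <- 1 - exp(-(makeham_a + gompertz_b * exp(gompertz_c * ages)))
    if (any(qx[-length(qx)] >= 1)) {
      warning("hazard reaches certainty before max_age; clamping qx to 1")
      qx <- pmin(qx, 1)
    }
    qx[length(qx)] <- 1
    life_table(ages, qx)
  })
}

#' Remaining life expectancy from a life table
#'
#' Standard life-table recursion with deaths credited half a year of
#' exposure (uniform deaths within the year).
#'
#' @param lt A `life_table`.
#' @param age Starting age (integer, within the table).
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(lt, age) {
  i <- match(age, lt$age)
  if (is.na(i)) stop("age not covered by life table")
  qx <- lt$qx[i:nrow(lt)]
  lx <- cumprod(c(1, 1 - qx))[seq_along(qx)]
  dx <- lx * qx
  sum(lx * (1 - qx)) + 0.5 * sum(dx)
}
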