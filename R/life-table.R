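#' Period life table
#'
#' A life table is a data frame with one row per single year of age and the
#' annual probability of death `qx` at that age. Ages must be contiguous
#' integers and probabilities in `[0, 1]`. Background (non-breast-cancer)
#' mortality in the cohort model is looked up here by completed years of age.
#'
#' @param age Integer vector of contiguous ages (years).
#' @param qx Annual death probabilities, same length as `age`.
#' @return A `life_table` (also a `data.frame` with columns `age`, `qx`).
#' @export
life_table <- function(age, qx) {
  age <- as.integer(age)
  if (length(age) == 0L || length(age) != length(qx)) {
    stop("`age` and `qx` must be non-empty and the same length", call. = FALSE)
  }
  if (any(diff(age) != 1L)) {
    stop("`age` must be contiguous single-year classes", call. = FALSE)
  }
  if (any(!is.finite(qx)) || any(qx < 0) || any(qx > 1)) {
    stop("`qx` must be probabilities in [0, 1]", call. = FALSE)
  }
  structure(data.frame(age = age, qx = as.numeric(qx)),
            class = c("life_table", "data.frame"))
}

#' Read a life table from CSV
#'
#' Expects the dialect written by [write_life_table()]: a header line
#' `age,annual_death_prob` and one row per single year of age. Lines starting
#' with `#` are comments.
#'
#' @param path Path to the CSV file.
#' @return A [life_table()].
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  if (!identical(names(df), c("age", "annual_death_prob"))) {
    stop("life table CSV must have header 'age,annual_death_prob' (got: ",
         paste(names(df), collapse = ","), ")", call. = FALSE)
  }
  bad <- which(!is.finite(df$annual_death_prob) | df$annual_death_prob < 0 |
                 df$annual_death_prob > 1)
  if (length(bad)) {
    stop("invalid annual_death_prob at data row ", bad[1], call. = FALSE)
  }
  life_table(df$age, df$annual_death_prob)
}

#' Write a life table to CSV
#'
#' @param lt A [life_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  # full double precision so read_life_table() round-trips bit-identically
  writeLines(c("age,annual_death_prob",
               sprintf("%d,%.17g", lt$age, lt$qx)), path)
  invisible(path)
}

#' Monthly background death probability at a given age
#'
#' Looks up the annual death probability at `floor(age)` and converts it to a
#' constant monthly probability, `1 - (1 - q)^(1/12)`. Ages beyond the table's
#' coverage are an error; the model never extrapolates mortality silently.
#'
#' @param lt A [life_table()].
#' @param age Age in (possibly fractional) years. Vectorised.
#' @return Monthly death probability.
#' @export
monthly_background_death_prob <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  yr <- floor(age)
  idx <- match(yr, lt$age)
  if (anyNA(idx)) {
    stop("age ", yr[which(is.na(idx))[1]], " outside life-table coverage (",
         min(lt$age), "-", max(lt$age), ")", call. = FALSE)
  }
  1 - (1 - lt$qx[idx])^(1 / 12)
}

# monthly background hazard rate, same lookup; Inf where q = 1
monthly_background_death_rate <- function(lt, age) {
  q <- lt$qx[match(floor(age), lt$age)]
  ifelse(q >= 1, Inf, -log1p(-q) / 12)
}

#' Remaining life expectancy from a life table
#'
#' Deterministic life-table expectation from exact age `from` with a
#' trapezoidal within-year correction and an exponential tail beyond the last
#' tabulated age. Used for sanity checks on bundled and synthetic tables.
#'
#' @param lt A [life_table()].
#' @param from Starting age (integer year present in the table).
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(lt, from = 0) {
  stopifnot(inherits(lt, "life_table"))
  q <- lt$qx[lt$age >= from]
  if (length(q) == 0L) stop("`from` beyond table coverage", call. = FALSE)
  lx <- cumprod(c(1, 1 - q))
  py <- (lx[-length(lx)] + lx[-1]) / 2
  tail_q <- q[length(q)]
  sum(py) + lx[length(lx)] * if (tail_q > 0) 1 / tail_q else 0
}

#' Bundled synthetic 2018 US female life table
#'
#' Returns the packaged life-table fixture used for base-case analyses: a
#' synthetic, smooth approximation of the 2018 US female period life table
#' (log-linear interpolation of annual death probabilities through age knots
#' matching the published table; it is a constructed stand-in, not a
#' transcription). Covers ages 0-110; summary life expectancies agree with
#' published 2018 values to within about half a year.
#'
#' @return A [life_table()] covering ages 0-110.
#' @export
us_life_table_2018_female <- function() {
  path <- system.file("extdata", "synthetic_us_life_table_2018_female.csv",
                      package = "olaparibCEA")
  if (path == "") stop("bundled life-table fixture is missing", call. = FALSE)
  read_life_table(path)
}
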