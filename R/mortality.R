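#' General-population mortality schedule
#'
#' Holds age/year/sex-specific mortality rates of the whole population (the
#' prevalence-weighted mixture of diseased and disease-free mortality) on a
#' rectangular grid, with bilinear interpolation in age and year inside the
#' grid and constant (nearest-node) extrapolation at the edges. Lookup at a
#' grid node returns the stored value exactly.
#'
#' @param data data frame with columns `year`, `sex`, `age`, `rate` (deaths
#'   per person-year); every sex must carry a complete age-by-year grid and
#'   each (year, sex, age) combination must be unique.
#' @return An object of class `mortality_schedule`.
#' @seealso [mortality_at()], [generate_mortality_schedule()],
#'   [read_mortality()]
#' @export
mortality_schedule <- function(data) {
  req <- c("year", "sex", "age", "rate")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("mortality data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(data$year, data$sex, data$age)
  if (anyDuplicated(key))
    stop("duplicate (year, sex, age) combination: ",
         key[duplicated(key)][1], call. = FALSE)
  if (any(!is.finite(data$rate)) || any(data$rate < 0))
    stop("mortality rates must be finite and nonnegative", call. = FALSE)
  sexes <- sort(unique(data$sex))
  ages <- sort(unique(data$age))
  years <- sort(unique(data$year))
  grids <- lapply(sexes, function(s) {
    d <- data[data$sex == s, ]
    m <- matrix(NA_real_, length(ages), length(years),
                dimnames = list(ages, years))
    m[cbind(match(d$age, ages), match(d$year, years))] <- d$rate
    if (anyNA(m))
      stop("incomplete mortality grid for sex ", s,
           ": every (age, year) node needs a rate", call. = FALSE)
    m
  })
  names(grids) <- sexes
  structure(list(ages = ages, years = years, sexes = sexes, grids = grids),
            class = "mortality_schedule")
}

#' Interpolated mortality rate lookup
#'
#' @param schedule a [mortality_schedule()].
#' @param age,year numeric vectors (recycled); clamped to the grid range
#'   (constant extrapolation at the edges).
#' @param sex a single sex label present in the schedule.
#' @return Mortality rates per person-year.
#' @export
mortality_at <- function(schedule, age, year, sex) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  if (!sex %in% schedule$sexes)
    stop("sex '", sex, "' not present in the mortality schedule", call. = FALSE)
  n <- max(length(age), length(year))
  age <- rep_len(as.numeric(age), n)
  year <- rep_len(as.numeric(year), n)
  g <- schedule$grids[[sex]]
  ax <- .interp_index(schedule$ages, age)
  yx <- .interp_index(schedule$years, year)
  (1 - ax$w) * ((1 - yx$w) * g[cbind(ax$lo, yx$lo)] + yx$w * g[cbind(ax$lo, yx$hi)]) +
    ax$w      * ((1 - yx$w) * g[cbind(ax$hi, yx$lo)] + yx$w * g[cbind(ax$hi, yx$hi)])
}

# clamped linear interpolation indices/weights along one grid axis
.interp_index <- function(grid, x) {
  if (length(grid) == 1L)
    return(list(lo = rep(1L, length(x)), hi = rep(1L, length(x)),
                w = rep(0, length(x))))
  x <- pmin(pmax(x, grid[1]), grid[length(grid)])
  hi <- findInterval(x, grid, rightmost.closed = TRUE) + 1L
  hi <- pmin(pmax(hi, 2L), length(grid))
  lo <- hi - 1L
  w <- (x - grid[lo]) / (grid[hi] - grid[lo])
  list(lo = lo, hi = hi, w = w)
}

#' @export
print.mortality_schedule <- function(x, ...) {
  cat(sprintf("Mortality schedule: ages %g-%g, years %g-%g, sexes: %s\n",
              min(x$ages), max(x$ages), min(x$years), max(x$years),
              paste(x$sexes, collapse = ", ")))
  invisible(x)
}

#' As a data frame
#' @param x a [mortality_schedule()].
#' @param ... unused.
#' @export
as.data.frame.mortality_schedule <- function(x, ...) {
  do.call(rbind, lapply(x$sexes, function(s) {
    g <- expand.grid(age = x$ages, year = x$years)
    data.frame(year = g$year, sex = s, age = g$age,
               rate = as.vector(x$grids[[s]]))
  }))
}
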