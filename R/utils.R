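#' Round half-up for report parity
#'
#' Demographic reports conventionally round 0.05 up to 0.1; base R's
#' [round()] uses banker's rounding. Used only at presentation, never inside
#' a computation. Defined for non-negative values (all report quantities are).
#'
#' @param x numeric vector, non-negative.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(86.538, 1)  # 86.5
#' round_half_up(0.25, 1)    # 0.3
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# derive a sub-stream seed from a base seed and a fixed field offset,
# kept below 2^31 so it is always a valid R integer
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * offset) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Construct an age-group layout
#'
#' Age groups are described by their starting ages; interval lengths are the
#' differences, and the final group is open-ended (length `Inf`).
#'
#' @param starts ascending vector of interval starting ages (years).
#' @return data.frame with columns `age_start` and `n` (years; `Inf` on the
#'   terminal open-ended row).
#' @export
#' @examples
#' age_groups(c(0, 1, seq(5, 95, 5)))
age_groups <- function(starts) {
  if (length(starts) < 2L) stopf("need at least two age-group starts")
  if (any(diff(starts) <= 0)) stopf("age-group starts must be strictly ascending")
  data.frame(age_start = starts, n = c(diff(starts), Inf))
}

#' Standard abridged age layout (0, 1, 5, 10, ..., open)
#'
#' @param max_age start of the open-ended terminal group.
#' @return an age-group data.frame as from [age_groups()].
#' @export
abridged_ages <- function(max_age = 95) {
  age_groups(c(0, 1, seq(5, max_age, 5)))
}

# validate an age-group data.frame (contiguity is implied by construction via
# age_groups(); external CSVs may violate it)
check_age_groups <- function(g, where = "age groups") {
  if (!all(c("age_start", "n") %in% names(g))) {
    stopf("%s must have columns age_start and n", where)
  }
  k <- nrow(g)
  if (k < 2L) stopf("%s: need at least two rows", where)
  if (any(duplicated(g$age_start))) {
    stopf("%s: duplicated age_start at row %d", where,
          which(duplicated(g$age_start))[1L])
  }
  if (is.unsorted(g$age_start, strictly = TRUE)) {
    stopf("%s: age_start must be strictly ascending", where)
  }
  closed <- g$n[-k]
  if (any(!is.finite(closed)) || any(closed <= 0)) {
    stopf("%s: closed intervals must have finite positive length", where)
  }
  if (is.finite(g$n[k])) {
    stopf("%s: terminal row must be open-ended (n = Inf)", where)
  }
  gaps <- g$age_start[-1L] - (g$age_start[-k] + closed)
  if (any(abs(gaps) > 1e-9)) {
    stopf("%s: non-contiguous at row %d (gap of %g years)", where,
          which(abs(gaps) > 1e-9)[1L] + 1L, gaps[abs(gaps) > 1e-9][1L])
  }
  invisible(g)
}

# interval midpoints; the open-ended terminal group uses start + 5
age_midpoints <- function(g, open_offset = 5) {
  k <- nrow(g)
  mid <- g$age_start + g$n / 2
  mid[k] <- g$age_start[k] + open_offset
  mid
}
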