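# shared helpers

#' Round half away from zero
#'
#' Report-table rounding convention: halves round away from zero
#' (so 0.45 -> 0.5 at one decimal), unlike [base::round()]'s banker's
#' rounding. Used for the percentage columns of summary tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits`.
#' @export
#' @examples
#' round_half_up(c(0.45, -0.45, 19.35), 1)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# is x a scalar probability in [0,1]?
is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration field `%s`: %s", field, msg),
        class = "rsigcut_config_error")
}

# binary 0/1 vector from various encodings of the death outcome
as_died <- function(died) {
  if (is.logical(died)) return(as.integer(died))
  if (is.character(died) || is.factor(died)) {
    return(as.integer(as.character(died) == "died"))
  }
  if (!all(died %in% c(0, 1, NA))) {
    abort("`died` must be 0/1, logical, or 'died'/'survived'")
  }
  as.integer(died)
}

check_two_classes <- function(died) {
  if (length(unique(died[!is.na(died)])) < 2L) {
    abort("both outcome classes (deaths and survivors) must be present",
          class = "rsigcut_one_class_error")
  }
  invisible(TRUE)
}
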