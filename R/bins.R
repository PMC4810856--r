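#' Time-bin schemes
#'
#' A bin scheme is an ordered table of contiguous, non-overlapping time bins
#' running from older to younger, with ages in Ma. Bins follow a half-open
#' convention: an age `a` belongs to the bin with bounds `(older, younger)`
#' iff `younger < a <= older`, i.e. the older bound is inclusive, so ages
#' falling exactly on a boundary belong to the bin whose older bound they
#' equal. The single exception is the youngest bin, which also contains its
#' own younger bound (otherwise the scheme's endpoint would belong to no bin).
#'
#' @param labels Character vector of bin labels (old to young).
#' @param older,younger Numeric vectors of bin bounds in Ma.
#' @param name Scheme name.
#' @return A `bin_scheme`: a data.frame with columns `label`, `older`,
#'   `younger`, `midpoint` and attribute `name`.
#' @examples
#' bin_scheme(c("b1", "b2"), older = c(155, 145), younger = c(145, 135))
#' @export
bin_scheme <- function(labels, older, younger, name = "custom") {
  stopifnot(length(labels) == length(older), length(older) == length(younger))
  if (any(duplicated(labels))) stop("bin labels must be unique")
  if (any(older <= younger)) stop("each bin's older bound must exceed its younger bound")
  n <- length(older)
  if (n > 1L) {
    if (any(diff(older) >= 0) || any(diff(younger) >= 0)) {
      stop("bins must be ordered strictly older to younger")
    }
    if (any(abs(younger[-n] - older[-1L]) > 1e-9)) {
      stop("bins must be contiguous: each younger bound must equal the next older bound")
    }
  }
  out <- data.frame(
    label = as.character(labels), older = as.numeric(older),
    younger = as.numeric(younger),
    midpoint = (as.numeric(older) + as.numeric(younger)) / 2,
    stringsAsFactors = FALSE
  )
  attr(out, "name") <- name
  class(out) <- c("bin_scheme", "data.frame")
  out
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("Bin scheme '%s': %d bins spanning %.1f-%.1f Ma\n",
              attr(x, "name"), nrow(x), x$older[1L], x$younger[nrow(x)]))
  print.data.frame(x, ...)
  invisible(x)
}

# Stage boundary ages (Ma), GTS2012. Used by both built-in schemes.
.jk_stage_table <- function() {
  data.frame(
    label = c("Hettangian", "Sinemurian", "Pliensbachian", "Toarcian",
              "Aalenian", "Bajocian", "Bathonian", "Callovian", "Oxfordian",
              "Kimmeridgian", "Tithonian",
              "Berriasian", "Valanginian", "Hauterivian", "Barremian",
              "Aptian", "Albian", "Cenomanian", "Turonian", "Coniacian",
              "Santonian", "Campanian", "Maastrichtian"),
    older = c(201.3, 199.3, 190.8, 182.7, 174.1, 170.3, 168.3, 166.1, 163.5,
              157.3, 152.1,
              145.0, 139.8, 133.9, 130.8, 126.3, 113.0, 100.5, 93.9, 89.8,
              86.3, 83.6, 72.1),
    younger = c(199.3, 190.8, 182.7, 174.1, 170.3, 168.3, 166.1, 163.5, 157.3,
                152.1, 145.0,
                139.8, 133.9, 130.8, 126.3, 113.0, 100.5, 93.9, 89.8, 86.3,
                83.6, 72.1, 66.0),
    stringsAsFactors = FALSE
  )
}

#' Built-in stage-level bin scheme (23 stages, 201.3-66 Ma)
#'
#' Jurassic plus Cretaceous stages with GTS2012 boundary ages. Alternate
#' boundary tables can be supplied via [bin_scheme()] or [read_bin_scheme()];
#' every analysis takes the scheme as an argument so substitutes are drop-in.
#'
#' @return A [bin_scheme] of 23 stage bins.
#' @export
stage_bins <- function() {
  st <- .jk_stage_table()
  bin_scheme(st$label, st$older, st$younger, name = "stage")
}

#' Built-in composite ~10-Myr bin scheme (J1-J6, K1-K8)
#'
#' Fourteen approximately 10-Myr bins built by pooling adjacent stages
#' (GTS2012 ages). The groupings are approximations: stage durations do not
#' divide evenly into 10-Myr blocks, so individual bins range from about 6 to
#' 13 Myr. J6 is the Tithonian; K2 is the Hauterivian-Barremian; K3 the
#' Aptian.
#'
#' @return A [bin_scheme] of 14 composite bins.
#' @export
tenmyr_bins <- function() {
  bin_scheme(
    labels = c("J1", "J2", "J3", "J4", "J5", "J6",
               "K1", "K2", "K3", "K4", "K5", "K6", "K7", "K8"),
    older = c(201.3, 190.8, 182.7, 174.1, 163.5, 152.1,
              145.0, 133.9, 126.3, 113.0, 100.5, 89.8, 83.6, 72.1),
    younger = c(190.8, 182.7, 174.1, 163.5, 152.1, 145.0,
                133.9, 126.3, 113.0, 100.5, 89.8, 83.6, 72.1, 66.0),
    name = "tenmyr"
  )
}

#' Read a bin scheme from CSV
#'
#' Expects columns `label`, `older`, `younger` (ages in Ma, rows ordered
#' old to young).
#'
#' @param path CSV file path.
#' @param name Scheme name (defaults to the file name).
#' @return A [bin_scheme].
#' @export
read_bin_scheme <- function(path, name = NULL) {
  if (!file.exists(path)) stop("bin scheme file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "older", "younger")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("bin scheme file lacks column(s): ", paste(miss, collapse = ", "))
  bin_scheme(df$label, df$older, df$younger,
             name = name %||% sub("\\.csv$", "", basename(path)))
}

#' Locate the bin containing an age
#'
#' Applies the half-open membership rule (older bound inclusive; the
#' youngest bin additionally contains its younger bound).
#'
#' @param scheme A [bin_scheme].
#' @param age Numeric vector of ages in Ma.
#' @return Integer vector of bin indices (`NA` where outside the scheme).
#' @export
bin_of_age <- function(scheme, age) {
  n <- nrow(scheme)
  vapply(age, function(a) {
    if (is.na(a)) return(NA_integer_)
    hit <- which(a <= scheme$older & (a > scheme$younger |
                   (seq_len(n) == n & a >= scheme$younger)))
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1L))
}

# Bin indices whose age span intersects the interval [age_min, age_max].
# Intersection follows the half-open rule: bin i is touched iff
# age_max > younger_i (or, for the youngest bin, age_max >= younger_i)
# and age_min <= older_i.
candidate_bins <- function(scheme, age_max, age_min) {
  n <- nrow(scheme)
  top_ok <- age_max > scheme$younger
  top_ok[n] <- age_max >= scheme$younger[n]
  which(top_ok & age_min <= scheme$older)
}

bin_durations <- function(scheme) scheme$older - scheme$younger
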