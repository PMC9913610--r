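#' Read calving records from delimited text
#'
#' Expected columns: \code{cow, calving_date, herd, season} (ISO dates).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return data.frame with parsed dates.
#' @export
read_calving_records <- function(path, sep = ",") {
  rec <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(rec) <- tolower(names(rec))
  req <- c("cow", "calving_date", "herd", "season")
  if (!all(req %in% names(rec))) {
    stop("calving record file must have columns: ", paste(req, collapse = ", "))
  }
  rec$calving_date <- as.Date(rec$calving_date)
  rec
}

# months between two dates on the average-month scale
.months_between <- function(from, to) {
  as.numeric(to - from) / (365.25 / 12)
}

#' Reproductive efficiency per calving
#'
#' For a cow's n-th calving at age \eqn{t_n} months, the default time-ratio
#' form is
#' \deqn{Re_n = 100 \,\frac{afc_{opt} + (n-1)\, ci_{opt}}{t_n},}
#' the percentage of the optimal reproductive progress (first calving at
#' \code{afc_opt} months, one calf every \code{ci_opt} months thereafter)
#' the cow has actually realized. A count-ratio variant,
#' \eqn{100\, n / (1 + \lfloor (t_n - afc_{opt})/ci_{opt} \rfloor)} (realized
#' over optimal parity count at that age), is selectable via
#' \code{formula = "count"}. With \code{cap = TRUE} values above 100 (cows
#' ahead of the optimal schedule) are truncated to 100.
#'
#' @param records data.frame of calving records (\code{cow, calving_date,
#'   herd, season}).
#' @param birth_dates data.frame with columns \code{cow, birth_date}
#'   (character or Date).
#' @param afc_opt Optimal age at first calving, months (default 24).
#' @param ci_opt Optimal calving interval, months (default 12).
#' @param cap Truncate Re at 100 (default TRUE).
#' @param formula \code{"time"} (default) or \code{"count"}.
#' @return data.frame with one row per calving: \code{cow, Cn, age_months,
#'   Re, herd, year, season, calving_date}. Cows with non-increasing calving
#'   dates are dropped with a warning naming them.
#' @export
compute_re <- function(records, birth_dates, afc_opt = 24, ci_opt = 12,
                       cap = TRUE, formula = c("time", "count")) {
  formula <- match.arg(formula)
  records$calving_date <- as.Date(records$calving_date)
  bd <- as.Date(birth_dates$birth_date)
  names(bd) <- as.character(birth_dates$cow)
  # stable sort by cow: the record order within a cow is taken as the
  # calving order, so out-of-order dates are detected, not silently fixed
  records <- records[order(records$cow), , drop = FALSE]
  miss <- setdiff(unique(records$cow), names(bd))
  if (length(miss)) {
    stop("no birth date for cows: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  cn <- stats::ave(rep(1, nrow(records)), records$cow, FUN = cumsum)
  prev <- c(as.Date(NA), records$calving_date[-nrow(records)])
  nonmono <- cn > 1 & as.numeric(records$calving_date - prev) <= 0
  bad_cows <- unique(records$cow[nonmono])
  if (length(bad_cows)) {
    warning("dropping ", length(bad_cows),
            " cow(s) with non-increasing calving dates: ",
            paste(utils::head(bad_cows, 5), collapse = ", "))
    keep <- !(records$cow %in% bad_cows)
    records <- records[keep, , drop = FALSE]
    cn <- cn[keep]
  }
  age <- .months_between(bd[as.character(records$cow)], records$calving_date)
  if (any(age <= 0)) stop("calving at or before birth for cow(s): ",
                          paste(unique(records$cow[age <= 0])[1:3], collapse = ", "))
  re <- switch(formula,
    time  = 100 * (afc_opt + (cn - 1) * ci_opt) / age,
    count = 100 * cn / pmax(1, 1 + floor((age - afc_opt) / ci_opt)))
  if (cap) re <- pmin(re, 100)
  data.frame(cow = records$cow, Cn = as.integer(cn), age_months = age,
             Re = re, herd = records$herd,
             year = as.integer(format(records$calving_date, "%Y")),
             season = records$season,
             calving_date = records$calving_date,
             stringsAsFactors = FALSE)
}

#' Herd-year-season contemporary group codes
#'
#' Deterministic concatenation \code{herd_year_season}. Groups smaller than
#' \code{min_size} are flagged in the \code{"small_groups"} attribute.
#'
#' @param herd,year,season Parallel vectors; a missing value in any of them
#'   drops the record (with a message).
#' @param min_size Minimum group size before flagging (default 3).
#' @return Character vector of codes (NA for dropped records), with
#'   attribute \code{"small_groups"}.
#' @export
assign_hys <- function(herd, year, season, min_size = 3) {
  ok <- !(is.na(herd) | is.na(year) | is.na(season))
  if (any(!ok)) message(sum(!ok), " record(s) missing herd/year/season dropped")
  code <- rep(NA_character_, length(herd))
  code[ok] <- paste(herd[ok], year[ok], season[ok], sep = "_")
  tab <- table(code[ok])
  attr(code, "small_groups") <- names(tab)[tab < min_size]
  code
}

#' Structural filters for the analysis table
#'
#' Drops records beyond \code{max_cn} calvings (trajectory analyses use
#' parities 1..9) and rows with missing fields; attaches a before/after
#' count report.
#'
#' @param recs data.frame from [compute_re()] with an \code{HYS} column.
#' @param max_cn Highest calving number retained (default 9).
#' @param drop_incomplete Drop rows with any NA (default TRUE).
#' @return Filtered data.frame with attribute \code{"filter_report"}.
#' @export
filter_records <- function(recs, max_cn = 9, drop_incomplete = TRUE) {
  n0 <- nrow(recs)
  n_cn <- sum(recs$Cn > max_cn)
  recs <- recs[recs$Cn <= max_cn, , drop = FALSE]
  n_inc <- 0L
  if (drop_incomplete) {
    cc <- stats::complete.cases(recs)
    n_inc <- sum(!cc)
    recs <- recs[cc, , drop = FALSE]
  }
  if (!nrow(recs)) stop("no records left after filtering")
  attr(recs, "filter_report") <- data.frame(
    stage = c("input", "cn_gt_max", "incomplete", "retained"),
    n = c(n0, n_cn, n_inc, nrow(recs)))
  recs
}

#' Descriptive statistics with coefficient of variation
#'
#' @param values Numeric vector (NAs removed), n >= 2.
#' @return One-row data.frame: mean, sd, min, max, cv_pct
#'   (\code{100 * sd / mean}; NA when the mean is 0).
#' @export
descriptive_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  data.frame(mean = m, sd = s, min = min(values), max = max(values),
             cv_pct = if (m == 0) NA_real_ else 100 * s / m)
}
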