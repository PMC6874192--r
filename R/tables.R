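# Packaged study tables and the agreement statistics reported with them.
# table1: twelve fields with both Monte Carlo and pencil-beam (TPS) factors;
# table2: twenty-six pencil-beam plan factors with their CPSF products.

.table_md5 <- c(
  table1 = "6ae6a8ba87ad130ceb782464352fb440",
  table2 = "2739cd14183207a1f2502913f9753fac"
)

#' Load a packaged study table
#'
#' Transcribed factor tables shipped with the package, integrity-checked
#' against a stored checksum.
#'
#' @param name `"table1"` (12 field records, MC and TPS CSF/PSF) or
#'   `"table2"` (26 plan records, CSF/PSF/CPSF).
#' @param path Optional explicit CSV path (checksum still enforced for the
#'   packaged names).
#' @return Data frame of records.
#' @export
load_table_fixture <- function(name = c("table1", "table2"), path = NULL) {
  name <- match.arg(name)
  path <- path %||% system.file("extdata", paste0(name, ".csv"),
                                package = "protoscatter")
  if (!nzchar(path) || !file.exists(path)) stop_fixture("fixture %s not installed", name)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.table_md5[[name]]))) {
    stop_fixture("fixture %s is corrupted (checksum mismatch)", name)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- if (name == "table1") c("tps_csf", "mc_csf", "tps_psf", "mc_psf")
          else c("csf", "psf", "cpsf")
  if (any(df[cols] <= 0.8) || any(df[cols] >= 1.2)) {
    stop_fixture("fixture %s has factors outside (0.8, 1.2)", name)
  }
  df
}

#' Mean absolute difference in percentage points
#'
#' Mean of `|a_i - b_i| * 100`: the factor-difference convention that
#' reproduces the reported site means (absolute percentage points of the
#' factor, not relative percent). The unrounded value is returned; round to
#' one decimal for reporting.
#'
#' @param a,b Equal-length factor vectors.
#' @return Mean absolute difference in percentage points (unrounded).
#' @export
mean_abs_pp_difference <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("length mismatch")
  if (length(a) < 1L) stop_invalid("need at least one pair")
  mean(abs(a - b)) * 100
}

#' Maximum absolute difference in percentage points
#'
#' @param a,b Equal-length factor vectors.
#' @return Max of `|a_i - b_i| * 100`.
#' @export
max_abs_pp_difference <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("length mismatch")
  if (length(a) < 1L) stop_invalid("need at least one pair")
  max(abs(a - b)) * 100
}

#' Range of a factor column over record sets
#'
#' @param records Data frame (or rbind of data frames) of records.
#' @param column Column name.
#' @return Named numeric `c(min, max)`.
#' @export
factor_range <- function(records, column) {
  if (!column %in% names(records)) stop_invalid("unknown column: %s", column)
  v <- records[[column]]
  if (length(v) == 0L) stop_invalid("no records")
  c(min = min(v), max = max(v))
}

#' Recompute the CPSF product of plan records
#'
#' @param records Data frame with `csf` and `psf` columns (table2 layout), or
#'   a single row.
#' @return `round(csf * psf, 3)` per record.
#' @export
recompute_cpsf <- function(records) {
  round(records$csf * records$psf, 3)
}

#' Per-site mean MC-vs-TPS differences
#'
#' @param t1 The table1 data frame.
#' @param column `"psf"` or `"csf"`.
#' @return Named vector of mean absolute percentage-point differences by site
#'   (unrounded), plus the relative-percent convention as attribute
#'   `relative_pct`.
#' @export
site_mean_differences <- function(t1, column = c("psf", "csf")) {
  column <- match.arg(column)
  tps <- t1[[paste0("tps_", column)]]
  mc <- t1[[paste0("mc_", column)]]
  sites <- unique(t1$site)
  pp <- vapply(sites, function(s) {
    sel <- t1$site == s
    mean_abs_pp_difference(tps[sel], mc[sel])
  }, 0)
  rel <- vapply(sites, function(s) {
    sel <- t1$site == s
    mean(abs(tps[sel] - mc[sel]) / mc[sel]) * 100
  }, 0)
  names(pp) <- sites
  attr(pp, "relative_pct") <- stats::setNames(rel, sites)
  pp
}

#' All study-table agreement statistics
#'
#' Recomputes, from the packaged tables, every agreement statistic quoted
#' with them: PSF and CSF value ranges, per-site mean MC-vs-TPS differences,
#' the largest discrepancies, and the CPSF closure of the plan table.
#'
#' @return Named list of statistics.
#' @export
table_report <- function() {
  t1 <- load_table_fixture("table1")
  t2 <- load_table_fixture("table2")
  psf_all <- c(t1$tps_psf, t2$psf)
  csf_all <- c(t1$tps_csf, t2$csf)
  psf_site <- site_mean_differences(t1, "psf")
  csf_site <- site_mean_differences(t1, "csf")
  list(
    n_fields_compared = nrow(t1),
    n_plan_records = nrow(t2),
    psf_range = factor_range(data.frame(x = psf_all), "x"),
    csf_range = factor_range(data.frame(x = csf_all), "x"),
    psf_site_mean_pp = psf_site,
    csf_site_mean_pp = csf_site,
    max_psf_diff_pp = max_abs_pp_difference(t1$tps_psf, t1$mc_psf),
    max_csf_diff_pp = max_abs_pp_difference(t1$tps_csf, t1$mc_csf),
    mean_csf_diff_pp = mean_abs_pp_difference(t1$tps_csf, t1$mc_csf),
    cpsf_max_closure_err = max(abs(recompute_cpsf(t2) - t2$cpsf))
  )
}
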