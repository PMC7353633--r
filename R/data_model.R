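#' @keywords internal
"_PACKAGE"

#' Compositional variables measured on every milk sample
#'
#' The seven routine FTIR milk-composition parameters used throughout the
#' package, in canonical order: protein, fat, total solids (ts), solids-non-fat
#' (snf) and lactose in \% w/w; density in g/L; freezing-point depression
#' (fpd) in degrees Celsius, stored as a positive magnitude.
#'
#' @format Character vector of length 7.
#' @export
composition_vars <- c("protein", "fat", "ts", "snf", "lactose", "density", "fpd")

#' Production-area codes used in the market survey
#'
#' N = Central North, NE = Northeast, NW = Northwest, E = East, S = South.
#'
#' @format Character vector.
#' @export
area_levels <- c("N", "NE", "NW", "E", "S", "UNKNOWN")

.origin_levels <- c("control", "market", "adulterated", "synthetic")

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "milkscreen")
  if (!nzchar(path) || !file.exists(path)) {
    stop("bundled fixture '", file, "' not found; broken installation", call. = FALSE)
  }
  path
}

#' Validate a table of milk composition records
#'
#' Checks the hard physical invariants of a composition table: all \% w/w
#' fields within [0, 100], density in (1000, 1060) g/L, FPD magnitude in
#' (0, 1) degrees C, and solids-non-fat strictly below total solids. The closure
#' check fat + snf ~ ts is soft: deviations beyond `closure_tol` raise a
#' warning only, since pooled samples measured by FTIR do not close exactly.
#'
#' @param records data.frame with at least the columns in
#'   [composition_vars]. `sample_id`, `area`, `province`, `origin` columns are
#'   checked when present.
#' @param closure_tol tolerance (\% w/w) for the soft fat + snf vs ts check.
#' @return `records`, invisibly. Errors on hard-invariant violations.
#' @export
validate_records <- function(records, closure_tol = 0.3) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(composition_vars, names(records))
  if (length(missing)) {
    stop("missing composition variables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) return(invisible(records))
  pct <- c("protein", "fat", "ts", "snf", "lactose")
  for (v in pct) {
    x <- records[[v]]
    if (any(!is.finite(x)) || any(x < 0) || any(x > 100)) {
      stop("variable '", v, "' outside [0, 100] % w/w", call. = FALSE)
    }
  }
  if (any(records$density <= 1000 | records$density >= 1060)) {
    stop("density outside (1000, 1060) g/L", call. = FALSE)
  }
  if (any(records$fpd <= 0 | records$fpd >= 1)) {
    stop("fpd outside (0, 1) degrees C", call. = FALSE)
  }
  if (any(records$snf >= records$ts)) {
    stop("solids-non-fat must be strictly below total solids", call. = FALSE)
  }
  closure <- abs(records$fat + records$snf - records$ts)
  if (any(closure > closure_tol)) {
    warning(sum(closure > closure_tol),
            " record(s) with |fat + snf - ts| > ", closure_tol, " % w/w",
            call. = FALSE)
  }
  if ("area" %in% names(records) && !all(records$area %in% area_levels)) {
    stop("unknown area code(s): ",
         paste(unique(setdiff(records$area, area_levels)), collapse = ", "),
         call. = FALSE)
  }
  if ("origin" %in% names(records) && !all(records$origin %in% .origin_levels)) {
    stop("unknown origin value(s)", call. = FALSE)
  }
  invisible(records)
}

#' Per-variable mean and standard deviation of a composition table
#'
#' @param records composition table.
#' @return data.frame with columns `variable`, `mean`, `sd`, `n`.
#' @export
column_stats <- function(records) {
  validate_records(records)
  data.frame(
    variable = composition_vars,
    mean = vapply(composition_vars, function(v) mean(records[[v]]), 0),
    sd = vapply(composition_vars, function(v) stats::sd(records[[v]]), 0),
    n = nrow(records),
    row.names = NULL
  )
}

.read_boundary_row <- function(tab, prov, percentiles = c(0.5, 99.5)) {
  lo <- tab[tab$provenance == prov & tab$bound == "lower", composition_vars]
  hi <- tab[tab$provenance == prov & tab$bound == "upper", composition_vars]
  boundary_set(lower = unlist(lo), upper = unlist(hi),
               provenance = prov, percentiles = percentiles)
}

#' Load the control-pool summary fixture
#'
#' Reads the bundled summary of the 15-sample control set: the three pool
#' composition profiles (pool A premium North, pools B and C normal North and
#' South), the per-variable means and SDs, and the two univariate boundary
#' sets (measured and variance-adjusted, 0.5th/99.5th percentiles). The raw
#' per-sample control measurements were never published, so the boundaries
#' are fixture inputs rather than re-derivable quantities.
#'
#' @return list with elements `pools` (data.frame), `stats` (data.frame as
#'   [column_stats]), and `boundaries` (list of two [boundary_set] objects
#'   named `measured` and `variance_adjusted`).
#' @export
load_table1_fixture <- function() {
  pools <- utils::read.csv(.extdata("table1_pools.csv"), stringsAsFactors = FALSE)
  stats <- utils::read.csv(.extdata("table1_stats.csv"), stringsAsFactors = FALSE)
  btab <- utils::read.csv(.extdata("table1_boundaries.csv"), stringsAsFactors = FALSE)
  if (nrow(pools) != 3L || nrow(stats) != 7L || nrow(btab) != 4L) {
    stop("control summary fixture corrupt", call. = FALSE)
  }
  if (!identical(stats$variable, composition_vars)) {
    stop("control stats fixture: unexpected variable set", call. = FALSE)
  }
  # printed premium pool dominates the normal pools on every feature
  for (v in composition_vars) {
    if (pools[[v]][pools$pool_id == "A"] < max(pools[[v]][pools$pool_id != "A"])) {
      stop("pool fixture violates premium-pool dominance for '", v, "'",
           call. = FALSE)
    }
  }
  list(
    pools = pools,
    stats = stats,
    boundaries = list(
      measured = .read_boundary_row(btab, "measured"),
      variance_adjusted = .read_boundary_row(btab, "variance_adjusted")
    )
  )
}

#' Load the market-survey fixture
#'
#' Reads the 43 printed market-survey records (seven compositional features,
#' production area, province) together with their published detection
#' annotations: the two univariate violation counts and the two KNN one-class
#' flags. The remaining 9 survey samples were never printed (they raised no
#' flag); they are represented only by the per-area totals fixture (see
#' [load_area_totals]), never fabricated. The annotation columns exist for
#' validation and for reproducing the consensus when the unpublished control
#' samples behind the fitted KNN are unavailable; boundary detection code
#' never reads them.
#'
#' @return list with `records` (43-row composition data.frame, origin
#'   `"market"`) and `annotations` (parallel data.frame keyed by `sample_id`
#'   with integer counts `uni_measured_count`, `uni_varadj_count` and logical
#'   `knn_measured`, `knn_varadj`).
#' @export
load_table3_fixture <- function() {
  rec <- utils::read.csv(.extdata("table3_survey.csv"),
                         colClasses = c(sample_id = "character"),
                         stringsAsFactors = FALSE)
  ann <- utils::read.csv(.extdata("table3_annotations.csv"),
                         colClasses = c(sample_id = "character"),
                         stringsAsFactors = FALSE)
  if (nrow(rec) != 43L || nrow(ann) != 43L) {
    stop("market-survey fixture integrity error: expected 43 records",
         call. = FALSE)
  }
  if (!identical(rec$sample_id, ann$sample_id)) {
    stop("market-survey fixture: record/annotation id mismatch", call. = FALSE)
  }
  rec$origin <- "market"
  ann$knn_measured <- ann$knn_measured == "yes"
  ann$knn_varadj <- ann$knn_varadj == "yes"
  validate_records(rec)
  list(records = rec, annotations = ann)
}

#' Load the per-area survey sample totals
#'
#' Denominators of the 52-sample market survey by production area, including
#' the 9 never-flagged samples that were not printed individually.
#'
#' @return data.frame with columns `area`, `n_total`.
#' @export
load_area_totals <- function() {
  tot <- utils::read.csv(.extdata("survey_area_totals.csv"), stringsAsFactors = FALSE)
  if (sum(tot$n_total) != 52L) stop("area totals fixture corrupt", call. = FALSE)
  tot
}

#' Load the fraud-vulnerability factor ranks
#'
#' Mean ranks of the 13 fraud-vulnerability factors (opportunities,
#' motivations and controls) for the four main milk production areas, taken
#' as given from the published vulnerability assessment.
#'
#' @return data.frame with columns `factor_id`, `group`, `description` and one
#'   rank column per area (`east`, `north`, `northwest`, `northeast`).
#' @export
load_fraud_factors <- function() {
  ff <- utils::read.csv(.extdata("fraud_factors.csv"), stringsAsFactors = FALSE)
  if (nrow(ff) != 13L) stop("fraud-factor fixture corrupt", call. = FALSE)
  if (any(ff[, c("east", "north", "northwest", "northeast")] <= 0)) {
    stop("fraud-factor ranks must be positive", call. = FALSE)
  }
  ff
}

.round_half_up <- function(x) floor(x + 0.5)

#' Generate synthetic control samples around the pool profiles
#'
#' Draws `n` synthetic genuine-milk records by cycling through the three pool
#' profiles and sampling each compositional variable independently from a
#' normal distribution centred on the pool mean. The within-pool dispersion is
#' derived from the published pooled SDs: within-pool variance = pooled
#' variance minus the between-pool-mean variance (floored at 20\% of the
#' pooled SD), so that the SD across a generated n = 15 set approximates the
#' published per-variable SD. Total solids are generated by closure (pool TS
#' mean plus the fat and SNF deviations) to keep records internally
#' consistent; no between-variable covariance beyond that closure is
#' modelled.
#'
#' @param pools pool profile data.frame as returned by [load_table1_fixture].
#' @param stats per-variable pooled stats (`variable`, `mean`, `sd`).
#' @param n number of records (>= 2).
#' @param seed integer seed; the draw is deterministic given `seed`.
#' @return composition data.frame with `sample_id`, `pool_id`, the seven
#'   variables, `area` and `origin = "control"`.
#' @export
generate_controls <- function(pools, stats, n = 15, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n < 2) stop("n must be >= 2 (SD undefined otherwise)", call. = FALSE)
  sds <- stats$sd[match(composition_vars, stats$variable)]
  if (any(is.na(sds))) stop("stats must cover all seven variables", call. = FALSE)
  names(sds) <- composition_vars

  # within-pool SD: pooled variance less the spread of the printed pool means
  within <- vapply(composition_vars, function(v) {
    between <- mean((pools[[v]] - mean(pools[[v]]))^2)
    sqrt(max(sds[[v]]^2 - between, (0.2 * sds[[v]])^2))
  }, 0)
  if (all(sds == 0)) within[] <- 0

  pool_idx <- rep_len(seq_len(nrow(pools)), n)
  draw_vars <- setdiff(composition_vars, "ts")
  out <- withr::with_seed(seed, {
    cols <- lapply(draw_vars, function(v) {
      stats::rnorm(n, mean = pools[[v]][pool_idx], sd = within[[v]])
    })
    names(cols) <- draw_vars
    as.data.frame(cols)
  })
  # closure: ts tracks the fat and snf deviations around the pool ts mean
  out$ts <- pools$ts[pool_idx] +
    (out$fat - pools$fat[pool_idx]) + (out$snf - pools$snf[pool_idx])

  # clamp to the physical domain (relevant only under extreme dispersion)
  for (v in c("protein", "fat", "snf", "lactose")) out[[v]] <- pmax(out[[v]], 0.01)
  out$fpd <- pmin(pmax(out$fpd, 0.001), 0.999)
  out$density <- pmin(pmax(out$density, 1000.5), 1059.5)
  out$ts <- pmax(out$ts, out$snf + 0.01)

  res <- data.frame(
    sample_id = sprintf("CTRL%02d", seq_len(n)),
    pool_id = pools$pool_id[pool_idx],
    out[, composition_vars],
    area = ifelse(pools$region[pool_idx] == "South", "S", "N"),
    origin = "control",
    stringsAsFactors = FALSE
  )
  validate_records(res, closure_tol = Inf)
  res
}

#' Write and read composition tables in the package CSV dialect
#'
#' Values are written at the measurement precision of the source tables
#' (2 decimals for \% w/w, 3 for FPD, integer g/L) so a write/read round trip
#' is exact at that precision.
#'
#' @param records composition table.
#' @param path file path.
#' @return `write_records`: `path` invisibly; `read_records`: the table.
#' @export
write_records <- function(records, path) {
  out <- records
  for (v in c("protein", "fat", "ts", "snf", "lactose")) {
    out[[v]] <- sprintf("%.2f", out[[v]])
  }
  out$density <- sprintf("%d", as.integer(.round_half_up(out$density)))
  out$fpd <- sprintf("%.3f", out$fpd)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("sample_id" %in% names(rec)) rec$sample_id <- as.character(rec$sample_id)
  validate_records(rec)
  rec
}
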