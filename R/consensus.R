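# Consensus flagging of market-survey samples: four detection criteria (two
# univariate boundary sets, two KNN one-class models), a minimum-vote rule,
# per-area prevalence, and the PCA projection used for visualisation.

#' Build the samples-by-criteria matrix
#'
#' Evaluates the four detection criteria per sample: violation of the
#' measured univariate boundaries, violation of the variance-adjusted
#' boundaries (each true iff the violation count is >= 1), and the two KNN
#' one-class flags. The KNN flags come either from fitted `occ_model`s or,
#' when reproducing the published survey (whose control samples behind the
#' fitted models were never released), from the fixture annotation columns.
#'
#' @param records composition table.
#' @param bounds_measured,bounds_varadj the two [boundary_set]s.
#' @param knn_measured,knn_varadj fitted `occ_model`s, or `NULL` to use
#'   `annotations`.
#' @param annotations annotation data.frame with `sample_id`, logical
#'   `knn_measured`, `knn_varadj` (used for any model given as `NULL`).
#' @return data.frame of class `criteria_matrix`: `sample_id`, four logical
#'   criterion columns and integer `vote` (their row sum).
#' @export
build_criteria <- function(records, bounds_measured, bounds_varadj,
                           knn_measured = NULL, knn_varadj = NULL,
                           annotations = NULL) {
  uni_m <- flag_records(records, bounds_measured)$violation_count >= 1L
  uni_v <- flag_records(records, bounds_varadj)$violation_count >= 1L
  ids <- if ("sample_id" %in% names(records)) {
    as.character(records$sample_id)
  } else {
    as.character(seq_len(nrow(records)))
  }
  knn_flag <- function(model, column) {
    if (!is.null(model)) {
      !predict(model, records)$inside
    } else {
      if (is.null(annotations)) {
        stop("KNN detector missing and no annotations supplied", call. = FALSE)
      }
      i <- match(ids, as.character(annotations$sample_id))
      if (anyNA(i)) stop("annotations do not cover all samples", call. = FALSE)
      annotations[[column]][i]
    }
  }
  knn_m <- knn_flag(knn_measured, "knn_measured")
  knn_v <- knn_flag(knn_varadj, "knn_varadj")
  out <- data.frame(sample_id = ids, uni_measured = uni_m, uni_varadj = uni_v,
                    knn_measured = knn_m, knn_varadj = knn_v,
                    stringsAsFactors = FALSE)
  out$vote <- rowSums(out[, c("uni_measured", "uni_varadj",
                              "knn_measured", "knn_varadj")])
  class(out) <- c("criteria_matrix", "data.frame")
  out
}

#' Consensus suspect list
#'
#' Samples whose criteria vote reaches `min_votes` (the screening rule uses
#' 3 of 4), in the stable order of the input.
#'
#' @param criteria a `criteria_matrix` from [build_criteria].
#' @param min_votes minimum number of firing criteria, in 1..4.
#' @return character vector of suspected `sample_id`s.
#' @export
consensus <- function(criteria, min_votes = 3) {
  if (!(min_votes %in% 1:4)) stop("min_votes must be in 1..4", call. = FALSE)
  criteria$sample_id[criteria$vote >= min_votes]
}

#' Per-area prevalence of suspected samples
#'
#' @param suspects data.frame with `sample_id` and `area` for each suspected
#'   sample (e.g. the suspect subset of the survey table).
#' @param area_totals data.frame with `area`, `n_total` covering every area
#'   (see [load_area_totals]).
#' @return data.frame of class `prevalence_summary`: per area `n_suspected`,
#'   `n_total`, exact `percentage` and round-half-up integer `pct_display`.
#' @export
prevalence_by_area <- function(suspects, area_totals) {
  unknown <- setdiff(unique(suspects$area), area_totals$area)
  if (length(unknown)) {
    stop("suspect in area absent from totals: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n_susp <- vapply(area_totals$area,
                   function(a) sum(suspects$area == a), 0L)
  out <- data.frame(area = area_totals$area, n_suspected = n_susp,
                    n_total = area_totals$n_total,
                    percentage = 100 * n_susp / area_totals$n_total,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$pct_display <- .round_half_up(out$percentage)
  class(out) <- c("prevalence_summary", "data.frame")
  out
}

#' PCA projection of a composition table
#'
#' Autoscales the table and projects it onto its leading principal
#' components, ordered by decreasing explained variance. Component signs are
#' fixed so each component's largest-magnitude loading is positive.
#'
#' @param records composition table.
#' @param n_components number of components (<= rank of the data).
#' @param scaling optional [autoscale_fit] result; defaults to autoscaling on
#'   `records` itself (projection of survey samples onto control-sample
#'   components uses the control scaling).
#' @return list with `scores` (n x k matrix), `loadings` (7 x k),
#'   `explained_variance` (length-k, non-increasing) and `center` of the
#'   scaled data.
#' @export
pca_project <- function(records, n_components = 2, scaling = NULL) {
  if (is.null(scaling)) scaling <- autoscale_fit(records)
  X <- autoscale_apply(scaling, records)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (n_components > rank) stop("n_components exceeds rank", call. = FALSE)
  V <- sv$v[, seq_len(n_components), drop = FALSE]
  # sign convention: dominant loading positive
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  rownames(V) <- composition_vars
  colnames(V) <- colnames(scores) <- paste0("PC", seq_len(n_components))
  list(scores = scores, loadings = V,
       explained_variance = sv$d[seq_len(n_components)]^2 / (nrow(X) - 1),
       center = attr(Xc, "scaled:center"))
}
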