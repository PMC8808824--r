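# Agreement and reliability statistics: Dice/Jaccard segmentation overlap,
# SEM/SDC test-retest reliability, manual-vs-automated layer agreement and
# lesion vs lesion-free group comparison.

#' Dice and Jaccard overlap between two segmentations
#'
#' Jaccard = |A intersect M| / |A union M|; Dice = 2 |A intersect M| /
#' (|A| + |M|). The two satisfy Dice = 2 J / (1 + J) voxel-exactly. If one
#' mask is empty both coefficients are 0; two empty masks are an error.
#'
#' @param a,m [label_map()] objects (or logical arrays) on the same grid.
#' @param region optional region name or code: restricts both maps to that
#'   label before comparison; default compares the nonzero masks.
#' @return data.frame with columns `region`, `jaccard`, `dice`.
#' @export
dice_jaccard <- function(a, m, region = NULL) {
  pick <- function(x) {
    if (is.array(x) && is.logical(x)) return(x)
    stopifnot(inherits(x, "label_map"))
    if (is.null(region)) return(x$values > 0L)
    code <- if (is.character(region)) x$dict[[region]] else as.integer(region)
    if (is.null(code) || is.na(code)) stop("region not found: ", region)
    x$values == code
  }
  if (inherits(a, "label_map") && inherits(m, "label_map"))
    stopifnot_same_grid(a, m)
  av <- pick(a); mv <- pick(m)
  if (!identical(dim(av), dim(mv)))
    stop("masks are not on the same grid")
  na <- sum(av); nm <- sum(mv)
  if (na == 0L && nm == 0L) stop("both masks are empty")
  inter <- sum(av & mv)
  union <- sum(av | mv)
  data.frame(region = if (is.null(region)) "all" else as.character(region),
             jaccard = inter / union,
             dice = 2 * inter / (na + nm),
             stringsAsFactors = FALSE)
}

#' Standard error of measurement and smallest detectable change
#'
#' From paired test-retest observations: with visit differences
#' `d = visit2 - visit1`, SEM = SD(d) / sqrt(2) (the within-subject
#' measurement error) and SDC = 1.96 sqrt(2) SEM, the smallest change
#' exceeding measurement error at 95% confidence.
#'
#' @param visit1,visit2 numeric vectors paired by subject (n >= 2).
#' @return list with `sem`, `sdc`, `mean_change`, `n`.
#' @export
sem_sdc <- function(visit1, visit2) {
  if (length(visit1) != length(visit2))
    stop("visit vectors must be paired (equal length)")
  ok <- is.finite(visit1) & is.finite(visit2)
  v1 <- visit1[ok]; v2 <- visit2[ok]
  if (length(v1) < 2L) stop("need at least 2 paired observations")
  d <- v2 - v1
  sem <- stats::sd(d) / sqrt(2)
  list(sem = sem, sdc = 1.96 * sqrt(2) * sem, mean_change = mean(d),
       n = length(d))
}

#' Layer-wise agreement between two evaluations
#'
#' Compares mean T2 and voxel counts between two feature tables (for
#' example automated vs manual evaluation) per (subregion, layer):
#' `delta_t2_ms = a - b`, `delta_t2_pct = 100 (a - b) / b` (denominator =
#' the reference evaluation `b`), `delta_voxels = n_a - n_b`. The attribute
#' `summary` holds the mean absolute differences across rows.
#'
#' @param eval_a,eval_b data.frames with `subregion`, `layer`, `n_voxels`,
#'   `mean_t2_ms` (as from [region_mean_t2()]). Keys must match exactly.
#' @return data.frame with columns `subregion`, `layer`, `delta_t2_pct`,
#'   `delta_t2_ms`, `delta_voxels`.
#' @export
layer_agreement <- function(eval_a, eval_b) {
  need <- c("subregion", "layer", "n_voxels", "mean_t2_ms")
  stopifnot(all(need %in% names(eval_a)), all(need %in% names(eval_b)))
  ka <- paste(eval_a$subregion, eval_a$layer)
  kb <- paste(eval_b$subregion, eval_b$layer)
  unmatched <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(unmatched))
    stop("unmatched (subregion, layer) keys: ",
         paste(unique(unmatched), collapse = "; "))
  b <- eval_b[match(ka, kb), ]
  out <- data.frame(subregion = eval_a$subregion, layer = eval_a$layer,
                    delta_t2_pct = 100 * (eval_a$mean_t2_ms - b$mean_t2_ms) /
                      b$mean_t2_ms,
                    delta_t2_ms = eval_a$mean_t2_ms - b$mean_t2_ms,
                    delta_voxels = eval_a$n_voxels - b$n_voxels,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- c(
    mean_abs_delta_t2_ms = mean(abs(out$delta_t2_ms), na.rm = TRUE),
    mean_abs_delta_t2_pct = mean(abs(out$delta_t2_pct), na.rm = TRUE),
    mean_abs_delta_voxels = mean(abs(out$delta_voxels), na.rm = TRUE))
  out
}

#' Compare a metric between lesional and lesion-free segments
#'
#' Two-sample Student t test with pooled variance, with per-group means,
#' SDs and 95% confidence intervals of the mean (half-width
#' `t_{0.975, n-1} SD / sqrt(n)`), flagged significant at P < 0.05. A
#' paired variant is available for genuinely paired designs.
#'
#' @param values numeric vector of the metric.
#' @param lesion logical vector: TRUE = lesional segment.
#' @param paired if TRUE, a paired t test (groups must align and have equal
#'   length).
#' @return list with `groups` (data.frame: group, n, mean, sd, ci_lower,
#'   ci_upper), `t`, `df`, `p_value`, `significant`.
#' @export
group_compare <- function(values, lesion, paired = FALSE) {
  stopifnot(length(values) == length(lesion))
  x <- values[lesion & is.finite(values)]
  y <- values[!lesion & is.finite(values)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  ci <- function(v) {
    hw <- stats::qt(0.975, length(v) - 1) * stats::sd(v) / sqrt(length(v))
    c(mean(v) - hw, mean(v) + hw)
  }
  if (paired) {
    if (length(x) != length(y))
      stop("paired test needs equal group sizes")
    d <- x - y
    tstat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    df <- length(d) - 1
  } else {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  cix <- ci(x); ciy <- ci(y)
  list(groups = data.frame(group = c("lesion", "no_lesion"),
                           n = c(length(x), length(y)),
                           mean = c(mean(x), mean(y)),
                           sd = c(stats::sd(x), stats::sd(y)),
                           ci_lower = c(cix[1], ciy[1]),
                           ci_upper = c(cix[2], ciy[2]),
                           stringsAsFactors = FALSE),
       t = tstat, df = df, p_value = p, significant = p < 0.05)
}

#' Test-retest reliability report
#'
#' SEM, SDC and mean change per metric and (subregion, layer) across a
#' cohort measured at two visits, plus the cross-region mean SDC per metric
#' as a summary. Subjects missing either visit are dropped with a warning.
#'
#' @param visit1,visit2 named lists of per-subject feature tables (as from
#'   [region_feature_table()]); names identify subjects.
#' @param metrics feature columns to analyze (default: all numeric feature
#'   columns present).
#' @return list with `per_region` (data.frame: metric, subregion, layer,
#'   sem, sdc, mean_change, n) and `summary` (data.frame: metric,
#'   mean_sdc).
#' @export
reliability_report <- function(visit1, visit2, metrics = NULL) {
  subjects <- intersect(names(visit1), names(visit2))
  dropped <- setdiff(union(names(visit1), names(visit2)), subjects)
  if (length(dropped))
    warning("subjects missing a visit, dropped: ",
            paste(dropped, collapse = ", "))
  if (length(subjects) < 2L) stop("need at least 2 subjects with both visits")
  tmpl <- visit1[[subjects[1]]]
  if (is.null(metrics))
    metrics <- intersect(setdiff(feature_table_columns(),
                                 c("subregion", "layer")), names(tmpl))
  keys <- unique(tmpl[, c("subregion", "layer")])
  rows <- list()
  for (met in metrics) {
    for (r in seq_len(nrow(keys))) {
      sr <- keys$subregion[r]; ly <- keys$layer[r]
      get_val <- function(tabs, s) {
        tb <- tabs[[s]]
        i <- which(tb$subregion == sr & tb$layer == ly)
        if (length(i) != 1L) return(NA_real_)
        as.numeric(tb[[met]][i])
      }
      v1 <- vapply(subjects, function(s) get_val(visit1, s), numeric(1))
      v2 <- vapply(subjects, function(s) get_val(visit2, s), numeric(1))
      ok <- is.finite(v1) & is.finite(v2)
      if (sum(ok) < 2L) next
      ss <- sem_sdc(v1[ok], v2[ok])
      rows[[length(rows) + 1L]] <-
        data.frame(metric = met, subregion = sr, layer = ly,
                   sem = ss$sem, sdc = ss$sdc, mean_change = ss$mean_change,
                   mean_visit1 = mean(v1[ok]), mean_visit2 = mean(v2[ok]),
                   n = ss$n, stringsAsFactors = FALSE)
    }
  }
  per_region <- do.call(rbind, rows)
  if (is.null(per_region)) stop("no metric had enough paired data")
  summary <- do.call(rbind, lapply(split(per_region, per_region$metric),
                                   function(df)
                                     data.frame(metric = df$metric[1],
                                                mean_sdc = mean(df$sdc),
                                                stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(per_region = per_region, summary = summary)
}
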