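#' Age-mRNA Pearson correlations for all metrics and strata
#'
#' Correlates donor age with each of the four mRNA metrics, across all
#' specimens and stratified by neurotype, keeping each metric's region-specific
#' sample (a specimen enters a metric's correlation only if that metric is
#' non-missing for it). Verdicts use 0.05 (significant) and 0.10 (trending).
#'
#' @param table data.frame with `specimen_id`, `neurotype`, `age`, and metric
#'   columns.
#' @param metrics metric column names.
#' @return data.frame (class `age_analysis`): metric, stratum, r, p, n,
#'   verdict, k_excluded = 0, excluded_specimens = "".
#' @export
age_correlation_suite <- function(table,
                                  metrics = c("nbm_oxtr_area", "chatplus_oxtr_area",
                                              "chatminus_oxtr_area", "vp_oxtr_area")) {
  rows <- list()
  for (m in metrics) for (st in c("all", "ASD", "AST")) {
    res <- correlate_metric_binding(table, m, against = "age", stratum = st)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = m, stratum = st, r = res$r, p = res$p, n = res$n,
      verdict = verdict_of(res$p), k_excluded = 0L,
      excluded_specimens = "", flagged = res$flagged,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("age_analysis", "data.frame")
  out
}

verdict_of <- function(p) {
  if (is.na(p)) "undefined"
  else if (p < 0.05) "significant"
  else if (p < 0.10) "trending"
  else "ns"
}

#' Leave-out-oldest sensitivity of the age correlations
#'
#' Re-runs [age_correlation_suite()] after removing the k oldest donors
#' (per metric, among specimens with that metric non-missing; age ties broken
#' deterministically by specimen id). `k = 0` reproduces the base suite
#' bit-identically.
#'
#' @param table as in [age_correlation_suite()].
#' @param k_list exclusion levels.
#' @param metrics metric column names.
#' @return data.frame with one row per metric x stratum x exclusion level,
#'   recording the excluded specimen ids and verdict at each level.
#' @export
drop_oldest_sensitivity <- function(table, k_list = c(1L, 2L),
                                    metrics = c("nbm_oxtr_area", "chatplus_oxtr_area",
                                                "chatminus_oxtr_area", "vp_oxtr_area")) {
  rows <- list()
  for (k in sort(unique(c(0L, k_list)))) {
    for (m in metrics) {
      avail <- table[!is.na(table[[m]]), , drop = FALSE]
      ord <- order(-avail$age, avail$specimen_id)
      drop_ids <- if (k > 0) avail$specimen_id[ord[seq_len(min(k, nrow(avail)))]] else character(0)
      sub <- avail[!avail$specimen_id %in% drop_ids, , drop = FALSE]
      for (st in c("all", "ASD", "AST")) {
        res <- correlate_metric_binding(sub, m, against = "age", stratum = st)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = m, stratum = st, r = res$r, p = res$p, n = res$n,
          verdict = verdict_of(res$p), k_excluded = k,
          excluded_specimens = paste(drop_ids, collapse = ";"),
          flagged = res$flagged || res$n < 3L,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("age_analysis", "data.frame")
  out
}
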