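#' Render a cohort participation report
#'
#' Produces a human-readable markdown report from pipeline outputs: the
#' cohort summary, the top-ranked participants, the P-index distribution
#' at the 10/90 thresholds, per-stratum summaries, the most prevalent
#' conditions, and the geographic cluster overview. Rendering is pure:
#' the same inputs always produce the same text.
#'
#' @param pipeline result of [pindex_pipeline()].
#' @param strata optional [stratify_by_field()] table.
#' @param prevalence optional [prevalence_table()] table.
#' @param clusters optional [cluster_geopoints()] table.
#' @param top_k rows to show in ranking/prevalence tables (default 10).
#' @param decimals decimal places for reported indexes (default 2).
#' @param min_group echoed in the strata section when empty.
#' @return character vector of markdown lines.
#' @export
render_report <- function(pipeline, strata = NULL, prevalence = NULL,
                          clusters = NULL, top_k = 10L, decimals = 2L,
                          min_group = 30L) {
  fmt <- function(x) formatC(x, format = "f", digits = decimals)
  ptable <- pipeline$ptable
  dist <- pindex_distribution(ptable)
  out <- c(
    "# Cohort participation report",
    "",
    sprintf("- Participants (N): %d", nrow(ptable)),
    sprintf("- Valid phenotypes (M): %d", nrow(pipeline$valid$phenotypes)),
    sprintf("- Theoretical maximum (sum of valid scores): %s",
            format(pipeline$valid$denominator, big.mark = ",")),
    "",
    "## Top-ranked participants",
    "",
    "| Rank | Participant | P-index |",
    "|---:|---|---:|"
  )
  top <- utils::head(ptable, top_k)
  out <- c(out, sprintf("| %d | %s | %s |", top$rank, top$participant_id,
                        fmt(top$p_index)))
  if (!is.null(pipeline$qtp)) {
    qtop <- utils::head(pipeline$qtp, top_k)
    out <- c(out, "", "## Top-ranked participants (QtP-index)", "",
             "| Rank | Participant | QtP-index |", "|---:|---|---:|",
             sprintf("| %d | %s | %s |", qtop$rank, qtop$participant_id,
                     fmt(qtop$p_index)))
  }
  out <- c(out, "",
    "## P-index distribution",
    "",
    sprintf("- P-index > 90: %d participants (%s%%)",
            dist$n_above_hi, fmt(dist$pct_above_hi)),
    sprintf("- P-index < 10: %d participants (%s%%)",
            dist$n_below_lo, fmt(dist$pct_below_lo)),
    sprintf("- P-index = 0: %d participants (%s%%)",
            dist$n_zero, fmt(dist$pct_zero)),
    sprintf("- Dichotomy (either tail): %s%%", fmt(dist$pct_dichotomy)),
    sprintf("- Median P-index: %s (nonzero only: %s)",
            fmt(dist$median_all),
            if (is.na(dist$median_nonzero)) "NA" else fmt(dist$median_nonzero))
  )
  out <- c(out, "", "## Strata", "")
  if (is.null(strata) || nrow(strata) == 0L) {
    out <- c(out, sprintf("No groups with at least %d participants.", min_group))
  } else {
    out <- c(out,
      "| Group | n | Median P-index | % > 90 | % < 10 |",
      "|---|---:|---:|---:|---:|",
      sprintf("| %s | %d | %s | %s | %s |", strata$label, strata$n,
              fmt(strata$median_p_index), fmt(strata$pct_above_90),
              fmt(strata$pct_below_10)))
  }
  if (!is.null(prevalence) && nrow(prevalence) > 0L) {
    pv <- utils::head(prevalence, top_k)
    out <- c(out, "", "## Most prevalent conditions", "",
      "| Phenotype | Yes | No | Prevalence (%) |", "|---|---:|---:|---:|",
      sprintf("| %s | %d | %d | %s |", pv$phenotype, pv$n_yes, pv$n_no,
              fmt(pv$prevalence_percent)))
  }
  if (!is.null(clusters) && nrow(clusters) > 0L) {
    out <- c(out, "", "## Geographic clusters", "",
      sprintf("%d one-degree cells; largest holds %d participants.",
              nrow(clusters), max(clusters$n)))
  }
  out
}
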