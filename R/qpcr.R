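#' qPCR delta-Ct against the 16S reference assay
#'
#' Replicate Ct values of the species assay and the pan-bacterial 16S
#' reference assay are each averaged (arithmetic mean over uncensored
#' replicates), and the difference `mean(species) - mean(reference)` is
#' returned. One ΔCt unit corresponds to one doubling of relative deficit
#' against total bacterial DNA.
#'
#' Censored replicates ("no amplification") carry `ct = NA` with
#' `censored = TRUE` and are dropped from the means. If every species
#' replicate is censored the species is below detection in that sample and
#' `NA` is returned; a missing or fully censored reference assay is a data
#' error.
#'
#' @param sample_records data.frame slice for one sample with columns
#'   `assay`, `ct` and optionally `censored`.
#' @param species_assay,reference_assay assay names.
#' @return ΔCt in cycles, or `NA` when the species is below detection.
#' @export
delta_ct <- function(sample_records, species_assay, reference_assay = "16S") {
  if (is.null(sample_records$censored))
    sample_records$censored <- is.na(sample_records$ct)
  ref <- sample_records[sample_records$assay == reference_assay &
                          !sample_records$censored, "ct"]
  if (!length(ref))
    stop_data("delta_ct: no uncensored '%s' reference replicates", reference_assay)
  sp <- sample_records[sample_records$assay == species_assay &
                         !sample_records$censored, "ct"]
  if (!length(sp)) return(NA_real_)  # below detection
  mean(sp) - mean(ref)
}

#' Percent abundance from delta-Ct
#'
#' `100 * 2^(-delta_ct)`: the species' share of total bacterial DNA under
#' ideal doubling per cycle. ΔCt = 0 gives 100%, each additional cycle
#' halves the percentage. Values above 100 (species assay crossing before
#' the 16S reference) are allowed but flagged with a warning.
#'
#' @param delta_ct numeric vector of ΔCt values (cycles); NA passes through.
#' @return percent abundance, same length as `delta_ct`.
#' @export
percent_abundance <- function(delta_ct) {
  pct <- 100 * 2^(-delta_ct)
  n_over <- sum(pct > 100, na.rm = TRUE)
  if (n_over)
    warning(sprintf("percent_abundance: %d value(s) exceed 100%%", n_over))
  pct
}

#' Convert a replicate Ct table into per-sample percent abundances
#'
#' @param ct_table data.frame with columns `sample_id`, `host`, `assay`,
#'   `replicate`, `ct`, and optionally `censored`. Every sample must carry
#'   the reference assay.
#' @param reference_assay name of the pan-bacterial reference (default "16S").
#' @return data.frame (`sample_id`, `host`, `species`, `delta_ct`, `percent`,
#'   `below_detection`); species below detection have NA delta_ct/percent.
#' @export
quantify_abundance <- function(ct_table, reference_assay = "16S") {
  if (is.null(ct_table$censored)) ct_table$censored <- is.na(ct_table$ct)
  bad <- !ct_table$censored & (!is.finite(ct_table$ct) | ct_table$ct <= 0)
  if (any(bad)) stop_data("quantify_abundance: nonpositive or nonfinite Ct values")
  species <- setdiff(unique(ct_table$assay), reference_assay)
  out <- list()
  for (sid in unique(ct_table$sample_id)) {
    rec <- ct_table[ct_table$sample_id == sid, ]
    if (!any(rec$assay == reference_assay))
      stop_data("quantify_abundance: sample '%s' lacks the '%s' reference assay",
                sid, reference_assay)
    for (sp in species) {
      if (!any(rec$assay == sp)) next
      d <- delta_ct(rec, sp, reference_assay)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, host = rec$host[1L], species = sp,
        delta_ct = d, percent = 100 * 2^(-d), below_detection = is.na(d))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  n_over <- sum(res$percent > 100, na.rm = TRUE)
  if (n_over) warning(sprintf("quantify_abundance: %d abundance value(s) exceed 100%%", n_over))
  res
}

#' Classify each species' host adaptation from percent abundances
#'
#' Per species, host groups are compared by the Kruskal-Wallis test; when
#' significant at `alpha`, Dunn's post hoc test (adjusted by `adjustment`)
#' decides whether the host group with the highest median abundance is
#' significantly above every other host group — only then is the species
#' labelled adapted to that host. Otherwise the call is
#' "no significant host signal".
#'
#' Below-detection samples enter the ranking at the species' minimum
#' detected abundance (tied bottom ranks); a species censored in an entire
#' host group in every sample is still ranked this way, but a species with
#' no detected sample at all is skipped with a notice.
#'
#' @param abundance data.frame from [quantify_abundance()].
#' @param alpha significance level for both tests (default 0.01).
#' @param adjustment Dunn adjustment method (default "holm").
#' @return data.frame with one row per species: `species`, `label`,
#'   `kw_H`, `kw_p`, medians per host (list-column `group_medians`), and a
#'   list-column `pairwise` of Dunn results.
#' @export
classify_host_adaptation <- function(abundance, alpha = 0.01, adjustment = "holm") {
  hosts <- unique(abundance$host)
  if (length(hosts) < 2L)
    stop_data("classify_host_adaptation: >= 2 host groups required")
  calls <- list()
  for (sp in unique(abundance$species)) {
    a <- abundance[abundance$species == sp, ]
    if (all(is.na(a$percent))) {
      message(sprintf("classify_host_adaptation: species '%s' never detected; skipped", sp))
      next
    }
    floor_pct <- min(a$percent, na.rm = TRUE)
    a$percent[is.na(a$percent)] <- floor_pct
    grp <- split(a$percent, a$host)
    if (any(lengths(grp) < 3L))
      stop_data("classify_host_adaptation: species '%s' has a host group with < 3 samples", sp)
    kw <- kruskal_wallis(grp)
    med <- vapply(grp, median, 0)
    dunn <- dunn_posthoc(grp, adjustment = adjustment)
    top <- names(med)[which.max(med)]
    label <- "no significant host signal"
    if (kw$p < alpha) {
      beats <- vapply(setdiff(names(med), top), function(h) {
        row <- dunn[(dunn$group1 == top & dunn$group2 == h) |
                      (dunn$group1 == h & dunn$group2 == top), ]
        row$p_adjusted < alpha && med[[top]] > med[[h]]
      }, TRUE)
      if (all(beats)) label <- paste("adapted to", top)
    }
    calls[[length(calls) + 1L]] <- data.frame(
      species = sp, label = label, kw_H = kw$H, kw_p = kw$p,
      group_medians = I(list(med)), pairwise = I(list(dunn)))
  }
  res <- do.call(rbind, calls)
  rownames(res) <- NULL
  res
}

#' Pick the species-specific assay with the lowest mean Ct
#'
#' Candidate primer pairs are run on a shared template; the assay whose
#' uncensored replicates have the lowest mean Ct is selected, ties broken
#' by assay name order so the choice is deterministic.
#'
#' @param candidate_assays named list, one numeric vector of replicate Ct
#'   values per assay; `NA` marks a censored replicate.
#' @return the selected assay name.
#' @export
select_best_assay <- function(candidate_assays) {
  if (!length(candidate_assays) || is.null(names(candidate_assays)))
    stop_data("select_best_assay: a named list of candidates is required")
  means <- vapply(candidate_assays, function(ct) {
    ct <- ct[!is.na(ct)]
    if (!length(ct)) NA_real_ else mean(ct)
  }, 0)
  if (all(is.na(means)))
    stop_data("select_best_assay: every candidate is fully censored")
  ok <- which(!is.na(means))
  ok <- ok[order(means[ok], names(means)[ok])]
  names(means)[ok[1L]]
}
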