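## Shortlisting of responsive AS-NMD events from delta-PSI tables and the
## splicing--expression correlation / trend / enrichment statistics.

#' Variance-stabilising transform for inclusion fractions
#'
#' `vst_psi(p) = 2*asin(sqrt(p))/pi`: the arcsine-square-root transform with
#' a 2/pi coefficient so the transformed value stays in \[0, 1\], with fixed
#' points at 0, 0.5 and 1. Strictly increasing and symmetric:
#' `vst_psi(1 - p) = 1 - vst_psi(p)`.
#'
#' @param psi inclusion fraction(s) in \[0, 1\].
#' @export
vst_psi <- function(psi) {
  if (any(psi < 0 | psi > 1, na.rm = TRUE))
    stop("psi outside [0, 1]")
  2 * asin(sqrt(psi)) / pi
}

#' Inverse of [vst_psi()]
#' @param v transformed value(s) in \[0, 1\].
#' @export
vst_psi_inverse <- function(v) {
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("value outside [0, 1]")
  sin(v * pi / 2)^2
}

#' Shortlist condition-responsive AS-NMD events
#'
#' Applies the delta-PSI response filters: an NS event is retained when
#' `dpsi > dpsi_cutoff` and `probability > prob_cutoff`, an NR event when
#' `dpsi < -dpsi_cutoff` and `probability > prob_cutoff`. Events with little
#' room to change splicing but likely constitutive NMD control are kept by
#' the inclusion-level rule: NS with mean PSI across conditions
#' `> high_inclusion`, NR with mean PSI `< low_inclusion`. The stringent
#' preset raises the cutoffs to |dPSI| > 0.25, probability > 0.95.
#'
#' @param dpsi data.frame with event_id, dpsi, probability and (for the
#'   inclusion rule) psi_mean columns; extra columns pass through.
#' @param catalog event catalog from [build_event_catalog()] supplying
#'   `nmd_effect` per event_id (rows joining to no catalogued NS/NR event
#'   are skipped with a warning).
#' @param dpsi_cutoff,prob_cutoff,high_inclusion,low_inclusion filter
#'   parameters (defaults 0.1 / 0.9 / 0.9 / 0.1).
#' @param stringent use the |dPSI| > 0.25, probability > 0.95 preset.
#' @return the retained rows with `nmd_effect` and a `reason` column
#'   (`responsive` or `inclusion-level`).
#' @export
shortlist_responsive <- function(dpsi, catalog, dpsi_cutoff = 0.1,
                                 prob_cutoff = 0.9, high_inclusion = 0.9,
                                 low_inclusion = 0.1, stringent = FALSE) {
  if (stringent) { dpsi_cutoff <- 0.25; prob_cutoff <- 0.95 }
  key <- if ("contrast" %in% names(dpsi))
    paste(dpsi$event_id, dpsi$contrast) else dpsi$event_id
  dpsi <- dpsi[!duplicated(key), , drop = FALSE]
  eff <- catalog$nmd_effect[match(dpsi$event_id, catalog$event_id)]
  unknown <- is.na(eff) | !eff %in% c("NS", "NR")
  if (any(unknown))
    warning(sum(unknown), " record(s) for uncatalogued/unlabelled events skipped")
  dpsi <- dpsi[!unknown, , drop = FALSE]
  eff <- eff[!unknown]
  if (!"psi_mean" %in% names(dpsi)) dpsi$psi_mean <- NA_real_
  responsive <- ifelse(eff == "NS",
                       dpsi$dpsi >  dpsi_cutoff & dpsi$probability > prob_cutoff,
                       dpsi$dpsi < -dpsi_cutoff & dpsi$probability > prob_cutoff)
  inclusion <- ifelse(eff == "NS",
                      !is.na(dpsi$psi_mean) & dpsi$psi_mean > high_inclusion,
                      !is.na(dpsi$psi_mean) & dpsi$psi_mean < low_inclusion)
  keep <- responsive | inclusion
  out <- dpsi[keep, , drop = FALSE]
  out$nmd_effect <- eff[keep]
  out$reason <- ifelse(responsive[keep], "responsive", "inclusion-level")
  out <- out[order(out$event_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Splicing--expression correlation for one AS-NMD event
#'
#' Pearson product-moment correlation between variance-stabilised gene
#' expression and the NMD-protective splicing pattern: `vst_psi(psi)` for
#' NMD-repressing events and `1 - vst_psi(psi)` for NMD-stimulating events
#' (inclusion of an NR event, and skipping of an NS event, protect the mRNA
#' from decay). Two-sided p from the t distribution via `stats::cor.test`.
#'
#' @param psi inclusion fractions per timepoint (matched to `expr`).
#' @param expr variance-stabilised gene expression per timepoint.
#' @param nmd_effect `"NS"` or `"NR"`.
#' @param event_id optional id copied to the result.
#' @param min_n minimum matched timepoints (default 3).
#' @return one-row data.frame: event_id, r, p, n, orientation
#'   (`VST` or `1-VST`), low_power flag (n < 5), degenerate flag with
#'   reason when either series has zero variance (then r/p are NA and the
#'   event is non-significant by construction).
#' @export
test_gene_corr <- function(psi, expr, nmd_effect, event_id = NA_character_,
                           min_n = 3) {
  stopifnot(nmd_effect %in% c("NS", "NR"), length(psi) == length(expr))
  ok <- stats::complete.cases(psi, expr)
  psi <- psi[ok]; expr <- expr[ok]
  n <- length(psi)
  if (n < min_n) stop("need >= ", min_n, " matched timepoints, got ", n)
  v <- vst_psi(psi)
  protective <- if (nmd_effect == "NS") 1 - v else v
  orientation <- if (nmd_effect == "NS") "1-VST" else "VST"
  if (stats::sd(protective) == 0 || stats::sd(expr) == 0)
    return(data.frame(event_id = event_id, r = NA_real_, p = NA_real_,
                      n = n, orientation = orientation, low_power = n < 5,
                      degenerate = TRUE, reason = "zero variance",
                      stringsAsFactors = FALSE))
  ct <- stats::cor.test(protective, expr, method = "pearson",
                        alternative = "two.sided")
  data.frame(event_id = event_id, r = unname(ct$estimate), p = ct$p.value,
             n = n, orientation = orientation, low_power = n < 5,
             degenerate = FALSE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Correlation screen over an event catalog
#'
#' Runs [test_gene_corr()] for every catalogued NS/NR event with PSI and
#' expression series, BH-adjusts p-values within event-type strata (NS-CE,
#' NR-CE and other, the groups reported separately; `fdr_scope = "global"`
#' adjusts across all events), and flags events with `r > 0`, `p < p_cutoff`
#' and `fdr < fdr_cutoff` as `facilitating`.
#'
#' @param catalog event catalog with event_id, gene_id, event_type,
#'   nmd_effect.
#' @param psi_mat matrix/data.frame of PSI fractions, rows = event_id,
#'   columns = timepoints.
#' @param expr_mat matrix of variance-stabilised expression, rows = gene_id,
#'   columns = matching timepoints.
#' @param p_cutoff,fdr_cutoff significance cutoffs (defaults 0.05 / 0.1).
#' @param fdr_scope `"stratum"` (default) or `"global"`.
#' @return data.frame with r, p, fdr, stratum and `facilitating` flag.
#' @export
correlate_catalog <- function(catalog, psi_mat, expr_mat, p_cutoff = 0.05,
                              fdr_cutoff = 0.1, fdr_scope = "stratum") {
  cat2 <- catalog[catalog$nmd_effect %in% c("NS", "NR") &
                  catalog$event_id %in% rownames(psi_mat) &
                  catalog$gene_id %in% rownames(expr_mat), , drop = FALSE]
  if (!nrow(cat2)) return(NULL)
  res <- do.call(rbind, lapply(seq_len(nrow(cat2)), function(i)
    test_gene_corr(as.numeric(psi_mat[cat2$event_id[i], ]),
                   as.numeric(expr_mat[cat2$gene_id[i], ]),
                   cat2$nmd_effect[i], event_id = cat2$event_id[i])))
  res$gene_id <- cat2$gene_id
  res$stratum <- ifelse(cat2$event_type == "CE",
                        paste0(cat2$nmd_effect, "-CE"), "other")
  res$fdr <- NA_real_
  groups <- if (identical(fdr_scope, "global"))
    rep("all", nrow(res)) else res$stratum
  for (gvar in unique(groups)) {
    k <- which(groups == gvar & !is.na(res$p))
    res$fdr[k] <- bh_fdr(res$p[k])
  }
  res$facilitating <- !is.na(res$r) & res$r > 0 &
    !is.na(res$p) & res$p < p_cutoff & !is.na(res$fdr) & res$fdr < fdr_cutoff
  res
}

#' Kendall rank-correlation trend against time
#'
#' Kendall's tau-b of a series against its timepoints with tie handling,
#' two-sided p (`stats::cor.test`: exact null for small tie-free series,
#' normal approximation otherwise). Classification helpers:
#' monotonically downregulated when `tau < -tau_cutoff` and `p < p_cutoff`;
#' upregulated when `tau > tau_cutoff` and `p < p_cutoff` (cutoffs 0.75 and
#' 0.05).
#'
#' @param values numeric series.
#' @param times timepoints (defaults to the series index).
#' @param tau_cutoff,p_cutoff classification cutoffs.
#' @return one-row data.frame: tau, p, n, trend
#'   (`down` / `up` / `flat`).
#' @export
kendall_trend <- function(values, times = seq_along(values),
                          tau_cutoff = 0.75, p_cutoff = 0.05) {
  stopifnot(length(values) == length(times))
  ok <- stats::complete.cases(values, times)
  values <- values[ok]; times <- times[ok]
  if (length(values) < 4) stop("need >= 4 points for a trend call")
  if (stats::sd(values) == 0)
    return(data.frame(tau = 0, p = 1, n = length(values), trend = "flat",
                      stringsAsFactors = FALSE))
  ct <- suppressWarnings(stats::cor.test(times, values, method = "kendall",
                                         alternative = "two.sided"))
  tau <- unname(ct$estimate)
  trend <- if (tau < -tau_cutoff && ct$p.value < p_cutoff) "down"
  else if (tau > tau_cutoff && ct$p.value < p_cutoff) "up" else "flat"
  data.frame(tau = tau, p = ct$p.value, n = length(values), trend = trend,
             stringsAsFactors = FALSE)
}

#' One-sided Fisher enrichment test
#'
#' Hypergeometric one-sided (`greater`) Fisher's exact test on a 2x2 count
#' table, as used to compare trend membership between genes carrying
#' facilitating events and control genes. A table with an empty margin has
#' no evidence either way: p = 1 and an undefined odds ratio.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list: `odds_ratio` (conditional MLE; NA when undefined) and `p`.
#' @export
fisher_enrichment <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(odds_ratio = NA_real_, p = 1))
  ft <- stats::fisher.test(table, alternative = "greater")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (monotone), `stats::p.adjust(method =
#' "BH")` behind the module surface.
#'
#' @param pvals p-values in \[0, 1\].
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Shortlist regulator-dependent AS-NMD events
#'
#' An event depends on the regulator (e.g. PTBP1) iff (a) it responds
#' significantly in at least one knockdown contrast
#' (`|dpsi| > dpsi_cutoff`, `probability > prob_cutoff`), and is annotated
#' from the highest-priority significant contrast (single knockdown over
#' double knockdown, then ESC over NPC, then lexicographic); (b) its PSI
#' correlates with regulator expression across the time course
#' (`p < corr_p_cutoff`); and (c) the correlation and knockdown responses
#' point in opposite directions: `sign(r) == -sign(dpsi)` in the annotated
#' contrast.
#'
#' @param kd data.frame of knockdown contrasts: event_id, dpsi, probability,
#'   knockdown (`"single"`/`"double"`), cell_type (`"ESC"`/`"NPC"`).
#' @param regulator_corr data.frame: event_id, r, p (PSI vs regulator
#'   expression over the time course).
#' @param dpsi_cutoff,prob_cutoff,corr_p_cutoff filter parameters.
#' @return data.frame of retained events with the annotated contrast and a
#'   `reason` column for exclusions of events that passed (a) but failed
#'   (b)/(c).
#' @export
shortlist_regulator_dependent <- function(kd, regulator_corr,
                                          dpsi_cutoff = 0.1,
                                          prob_cutoff = 0.9,
                                          corr_p_cutoff = 0.05) {
  sig <- kd[abs(kd$dpsi) > dpsi_cutoff & kd$probability > prob_cutoff, ,
            drop = FALSE]
  if (!nrow(sig))
    return(data.frame(event_id = character(0), stringsAsFactors = FALSE))
  pri <- order(sig$event_id,
               match(sig$knockdown, c("single", "double")),
               match(sig$cell_type, c("ESC", "NPC")),
               sig$cell_type, sig$knockdown)
  sig <- sig[pri, , drop = FALSE]
  best <- sig[!duplicated(sig$event_id), , drop = FALSE]
  k <- match(best$event_id, regulator_corr$event_id)
  r <- regulator_corr$r[k]; p <- regulator_corr$p[k]
  best$r <- r; best$corr_p <- p
  best$included <- !is.na(r) & !is.na(p) & p < corr_p_cutoff &
    sign(r) == -sign(best$dpsi)
  best$reason <- ifelse(best$included, "regulator-dependent",
                 ifelse(is.na(r), "no time-course correlation",
                 ifelse(p >= corr_p_cutoff, "correlation not significant",
                        "correlation sign matches knockdown sign")))
  rownames(best) <- NULL
  best
}
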