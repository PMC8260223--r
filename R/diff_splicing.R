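# Differential splicing between two conditions by two routes: a per-candidate
# t-test on PSI and a per-event Dirichlet-multinomial likelihood-ratio test.

result_columns <- c("event_id", "event_type", "novelty", "gene_id", "chrom",
                    "strand", "candidate", "inclusion", "exon_start",
                    "exon_end", "mean_psi_control", "mean_psi_treated",
                    "delta_psi", "p_raw", "p_adj", "test", "significant")

split_samples <- function(condition, treated, control) {
  labels <- unique(unname(condition))
  stop_if_not(treated %in% labels, paste0("no samples labelled ", treated))
  if (is.null(control)) {
    control <- setdiff(labels, treated)
    stop_if_not(length(control) == 1,
                "control label is ambiguous; pass `control`")
  }
  list(treated = names(condition)[condition == treated],
       control = names(condition)[condition == control])
}

#' Per-candidate t-test on PSI
#'
#' Two-sample t-test (pooled variance by default, the conventional behavior
#' of junction-count comparison tools; set `var_equal = FALSE` for Welch) on
#' per-sample PSI between conditions. Candidates whose observed
#' `|delta PSI|` is below `delta_thresh` receive no p-value (the testing
#' gate, distinct from the significance filter), as do candidates with fewer
#' than two non-missing PSI values in either group. BH adjustment runs over
#' all assigned p-values. For two-candidate events only the inclusion
#' candidate is tested (the exclusion row is its mirror image and is reported
#' untested); events with more candidates test each candidate's
#' one-vs-rest PSI.
#'
#' @param psi A [psi_table()].
#' @param treated Condition label of the treated group (delta is
#'   treated minus control).
#' @param control Control label; inferred when only two labels exist.
#' @param delta_thresh Testing gate on `|delta PSI|` in percent (default 5).
#' @param var_equal Pooled-variance t-test? (default `TRUE`).
#' @return Results `data.frame`, one row per event candidate.
#' @export
ttest_diff <- function(psi, treated = "LPS", control = NULL, delta_thresh = 5,
                       var_equal = TRUE) {
  grp <- split_samples(psi$condition, treated, control)
  ev <- psi$events
  m <- psi$psi
  n_cand <- stats::ave(ev$candidate, ev$event_id, FUN = length)
  mt <- rowMeans(m[, grp$treated, drop = FALSE], na.rm = TRUE)
  mc <- rowMeans(m[, grp$control, drop = FALSE], na.rm = TRUE)
  mt[is.nan(mt)] <- NA_real_
  mc[is.nan(mc)] <- NA_real_
  delta <- mt - mc
  testable <- ev$inclusion | n_cand > 2
  p_raw <- rep(NA_real_, nrow(ev))
  for (i in which(testable)) {
    xt <- m[i, grp$treated]
    xc <- m[i, grp$control]
    if (sum(!is.na(xt)) < 2 || sum(!is.na(xc)) < 2) next
    if (is.na(delta[i]) || abs(delta[i]) < delta_thresh) next
    p_raw[i] <- tryCatch(
      t.test(xt, xc, var.equal = var_equal)$p.value,
      error = function(e) if (delta[i] != 0) 0 else NA_real_)
  }
  res <- data.frame(ev[, c("event_id", "event_type", "novelty", "gene_id",
                           "chrom", "strand", "candidate", "inclusion",
                           "exon_start", "exon_end")],
                    mean_psi_control = unname(mc),
                    mean_psi_treated = unname(mt),
                    delta_psi = unname(delta),
                    p_raw = p_raw,
                    p_adj = bh_adjust(p_raw),
                    test = "ttest",
                    significant = NA,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Dirichlet-multinomial likelihood-ratio test per event
#'
#' Events are filtered before testing: at least `min_samps_gene_expr` samples
#' must carry an event total of at least `min_gene_expr` reads, and every
#' candidate must reach `min_feature_expr` reads in at least
#' `min_samps_feature_expr` samples. Passing events are fit with [dm_fit()];
#' the raw p-value is the upper chi-squared tail of the LRT statistic and BH
#' adjustment runs across tested events. Delta PSI is reported from observed
#' mean count proportions (treated minus control, in percent). Results carry
#' one row per candidate (sharing the event's p-value); excluded events are
#' recorded with their reason in `attr(, "excluded")`.
#'
#' @param events Event table ([build_events()]).
#' @param counts [count_table()] keyed by `row_id`.
#' @param treated,control Condition labels as in [ttest_diff()].
#' @param min_samps_gene_expr,min_gene_expr Event-level expression filter
#'   (defaults 6 samples at >= 10 reads).
#' @param min_samps_feature_expr,min_feature_expr Candidate-level filter
#'   (defaults 3 samples at >= 0 reads).
#' @param phi_grid Passed to [dm_fit()].
#' @param reference Reference distribution for the LRT statistic.
#'   `"small_sample_f"` (default) inverts the exact normal-theory relation
#'   between a maximum-likelihood ratio and the pooled t/F statistic
#'   (`F = ((S-C)/df) * (exp(LRT/S) - 1)` on `F(df, S-C)` for `S` samples
#'   and `C` conditions), which reduces to the chi-squared tail as `S`
#'   grows but stays calibrated at the few-replicate designs this test is
#'   meant for; `"chisq"` uses the plain asymptotic chi-squared tail, which
#'   is anticonservative at small `S`.
#' @return Results `data.frame` as in [ttest_diff()] with `test = "dmlrt"`.
#' @export
dm_lrt <- function(events, counts, treated = "LPS", control = NULL,
                   min_samps_gene_expr = 6, min_samps_feature_expr = 3,
                   min_gene_expr = 10, min_feature_expr = 0,
                   phi_grid = 10^seq(log10(0.5), log10(1e5), length.out = 15),
                   reference = c("small_sample_f", "chisq")) {
  reference <- match.arg(reference)
  grp <- split_samples(counts$condition, treated, control)
  rows <- list()
  excluded <- list()
  for (eid in unique(events$event_id)) {
    ev <- events[events$event_id == eid, , drop = FALSE]
    y <- t(counts$counts[ev$row_id, , drop = FALSE])  # samples x candidates
    tot <- rowSums(y)
    if (sum(tot >= min_gene_expr) < min_samps_gene_expr) {
      excluded[[eid]] <- "min_samps_gene_expr"
      next
    }
    feat_ok <- colSums(y >= min_feature_expr) >= min_samps_feature_expr
    if (!all(feat_ok)) {
      excluded[[eid]] <- "min_samps_feature_expr"
      next
    }
    y_by <- list(control = y[grp$control, , drop = FALSE],
                 treated = y[grp$treated, , drop = FALSE])
    fit <- dm_fit(y_by, phi_grid = phi_grid)
    p <- if (reference == "chisq") {
      pchisq(fit$lrt_stat, df = fit$df, lower.tail = FALSE)
    } else {
      S <- nrow(y)
      C <- length(y_by)
      fstat <- (S - C) / fit$df * expm1(fit$lrt_stat / S)
      stats::pf(fstat, fit$df, S - C, lower.tail = FALSE)
    }
    prop_mean <- function(ys) {
      ns <- rowSums(ys)
      colMeans(ys[ns > 0, , drop = FALSE] / ns[ns > 0])
    }
    mc <- 100 * prop_mean(y_by$control)
    mt <- 100 * prop_mean(y_by$treated)
    rows[[eid]] <- data.frame(
      ev[, c("event_id", "event_type", "novelty", "gene_id", "chrom",
             "strand", "candidate", "inclusion", "exon_start", "exon_end")],
      mean_psi_control = unname(mc),
      mean_psi_treated = unname(mt),
      delta_psi = unname(mt - mc),
      p_raw = p,
      test = "dmlrt",
      significant = NA,
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else {
    cbind(empty_events()[, c("event_id", "event_type", "novelty", "gene_id",
                             "chrom", "strand", "candidate", "inclusion",
                             "exon_start", "exon_end")],
          data.frame(mean_psi_control = numeric(0),
                     mean_psi_treated = numeric(0), delta_psi = numeric(0),
                     p_raw = numeric(0), test = character(0),
                     significant = logical(0)))
  }
  # BH across events (each event counted once), mapped back to candidates
  ev_first <- !duplicated(res$event_id)
  adj <- bh_adjust(res$p_raw[ev_first])
  res$p_adj <- adj[match(res$event_id, res$event_id[ev_first])]
  res <- res[, result_columns]
  rownames(res) <- NULL
  attr(res, "excluded") <- if (length(excluded)) {
    data.frame(event_id = names(excluded), reason = unlist(excluded),
               stringsAsFactors = FALSE)
  } else data.frame(event_id = character(0), reason = character(0))
  res
}

#' Filter results to significant events
#'
#' Keeps rows with `p_adj <= alpha` and `|delta PSI| >= delta` and removes
#' novel intron-retention rows (`event_type == "IR"` and `novelty == "N"`),
#' the standard discovery filter (defaults alpha 0.25, delta 10; use
#' `alpha = 0.05` for the strict preset).
#'
#' @param results Results from [ttest_diff()] or [dm_lrt()].
#' @param alpha Adjusted p-value cutoff.
#' @param delta Minimum `|delta PSI|` in percent.
#' @param drop_novel_ir Remove novel intron-retention rows?
#' @return Filtered results with `significant = TRUE`.
#' @export
significant_events <- function(results, alpha = 0.25, delta = 10,
                               drop_novel_ir = TRUE) {
  keep <- !is.na(results$p_adj) & results$p_adj <= alpha &
    !is.na(results$delta_psi) & abs(results$delta_psi) >= delta
  if (drop_novel_ir) {
    keep <- keep & !(results$event_type == "IR" & results$novelty == "N")
  }
  out <- results[keep, , drop = FALSE]
  out$significant <- TRUE
  rownames(out) <- NULL
  out
}

#' Union of significant genes per event type across the two tests
#'
#' @param res_ttest,res_dm Significant results from the two routes
#'   ([significant_events()] output).
#' @return Named list: event type -> sorted unique gene ids.
#' @export
union_genes <- function(res_ttest, res_dm) {
  both <- rbind(res_ttest[, c("event_type", "gene_id")],
                res_dm[, c("event_type", "gene_id")])
  lapply(split(both$gene_id, both$event_type), function(g) sort(unique(g)))
}

#' Event-type composition among the top-ranked events
#'
#' Events with `|delta PSI| >= delta_min` are ordered by increasing raw
#' p-value (ties broken by event id) and the event-type composition is
#' tabulated among the top `k` percent for each `k` (subset size
#' `ceiling(k% * N)`).
#'
#' @param results Results table (candidate rows are collapsed per event by
#'   their smallest p-value).
#' @param percents Percent cutoffs (default 5, 10, 15, 20, 25).
#' @param delta_min `|delta PSI|` restriction (default 10).
#' @return Long `data.frame`: `percent`, `event_type`, `count`.
#' @export
ranking_composition <- function(results, percents = c(5, 10, 15, 20, 25),
                                delta_min = 10) {
  ok <- !is.na(results$p_raw)
  r <- results[ok, , drop = FALSE]
  # collapse candidates to events: best (smallest) p, its delta
  o <- order(r$event_id, r$p_raw)
  r <- r[o, , drop = FALSE]
  r <- r[!duplicated(r$event_id), , drop = FALSE]
  r <- r[!is.na(r$delta_psi) & abs(r$delta_psi) >= delta_min, , drop = FALSE]
  r <- r[order(r$p_raw, r$event_id), , drop = FALSE]
  n <- nrow(r)
  out <- lapply(percents, function(k) {
    top <- r[seq_len(min(n, ceiling(k / 100 * n))), , drop = FALSE]
    tab <- table(top$event_type)
    if (!length(tab)) return(NULL)
    data.frame(percent = k, event_type = names(tab),
               count = as.integer(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out %||% data.frame(percent = numeric(0), event_type = character(0),
                      count = integer(0))
}

#' Genes with conserved events across species
#'
#' @param gene_sets_by_species Named list (one element per species) of
#'   per-event-type gene lists, as produced by [union_genes()].
#' @param ortholog_map Optional function mapping gene ids to a shared
#'   namespace; default is case-insensitive symbol matching (`toupper`).
#' @return Named list: event type -> genes (ids of the first species) whose
#'   ortholog is significant in every species.
#' @export
conserved_genes <- function(gene_sets_by_species, ortholog_map = NULL) {
  stop_if_not(length(gene_sets_by_species) >= 2, "need >= 2 species")
  map <- ortholog_map %||% toupper
  types <- unique(unlist(lapply(gene_sets_by_species, names)))
  out <- lapply(types, function(ty) {
    sets <- lapply(gene_sets_by_species, function(sp) map(sp[[ty]] %||% character(0)))
    shared <- Reduce(intersect, sets)
    first <- gene_sets_by_species[[1]][[ty]] %||% character(0)
    sort(first[map(first) %in% shared])
  })
  names(out) <- types
  out
}
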