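# Multiple-comparisons inference: per-agent Bonferroni adjustment, the
# all-three-matchings consensus rule, agent summary percentages and
# volcano-plot exports.

#' Bonferroni adjustment
#'
#' \code{p_adj = min(1, m * p)} with \code{m} the family size (the number
#' of evaluable definitions tested for one agent under one matching method
#' and cancer type).
#'
#' @param p raw p-values in (0, 1].
#' @param m family size; defaults to \code{length(p)}.
#' @return adjusted p-values.
#' @examples
#' bonferroniAdjust(0.001, m = 40)  # 0.04
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (length(p) == 0L) return(numeric(0))
  stopIf(any(is.finite(p) & (p <= 0 | p > 1)), "p-values must lie in (0, 1]")
  pmin(1, m * p)
}

#' Adjust CLR results within per-agent families
#'
#' Groups results by agent, matching method (and cancer type when
#' present), sets the family size m to the number of evaluable ("ok")
#' definitions in the group, and adds Bonferroni-adjusted p-values, a
#' significance flag (\code{p_adj < alpha}) and the direction of
#' association.
#'
#' @param results data.frame from \code{\link{fitAllExposures}} (rows from
#'   several methods/cancers may be stacked).
#' @param alpha adjusted-significance threshold (default 0.01).
#' @return the results with columns \code{m}, \code{p_adj},
#'   \code{significant}, \code{direction}.
#' @export
adjustResults <- function(results, alpha = 0.01) {
  key <- paste(results$agent, results$method,
               if (!is.null(results$cancer)) results$cancer else "")
  results$m <- ave(as.numeric(results$status == "ok"), key, FUN = sum)
  results$p_adj <- ifelse(results$status == "ok",
                          pmin(1, results$m * results$p_raw), NA_real_)
  results$significant <- !is.na(results$p_adj) & results$p_adj < alpha
  results$direction <- sign(results$beta)
  results
}

#' Consensus across the three matching analyses
#'
#' A definition is overall-significant only when it is evaluable with
#' adjusted p below \code{alpha} under all three matching methods and the
#' direction of association agrees across them; definitions missing from
#' (or non-evaluable in) any method cannot be overall-significant.
#'
#' @param adjusted output of \code{\link{adjustResults}} containing all
#'   three methods (for one cancer type).
#' @param alpha adjusted-significance threshold.
#' @return data.frame with one row per definition: identifiers, per-method
#'   \code{or_*} and \code{p_adj_*} columns, \code{direction_consistent}
#'   and \code{overall_significant}.
#' @export
consensusResults <- function(adjusted, alpha = 0.01) {
  ids <- unique(adjusted$definition_id)
  meta <- adjusted[!duplicated(adjusted$definition_id),
                   c("definition_id", "agent", "metric", "buffer_km",
                     "lag_years"), drop = FALSE]
  rownames(meta) <- meta$definition_id
  out <- meta[ids, , drop = FALSE]
  for (m in .MATCH_METHODS) {
    sub <- adjusted[adjusted$method == m, , drop = FALSE]
    idx <- match(ids, sub$definition_id)
    suffix <- c(nearest_neighbor = "nn", exact = "exact",
                optimal = "optimal")[[m]]
    out[[paste0("or_", suffix)]] <- sub$or[idx]
    out[[paste0("p_adj_", suffix)]] <- sub$p_adj[idx]
    out[[paste0("ok_", suffix)]] <- !is.na(idx) & sub$status[idx] == "ok"
    out[[paste0("dir_", suffix)]] <- sub$direction[idx]
  }
  okAll <- out$ok_nn & out$ok_exact & out$ok_optimal
  sigAll <- okAll &
    !is.na(out$p_adj_nn) & out$p_adj_nn < alpha &
    !is.na(out$p_adj_exact) & out$p_adj_exact < alpha &
    !is.na(out$p_adj_optimal) & out$p_adj_optimal < alpha
  dirs <- cbind(out$dir_nn, out$dir_exact, out$dir_optimal)
  consistent <- okAll & (rowSums(dirs > 0) == 3L | rowSums(dirs < 0) == 3L)
  out$direction_consistent <- consistent
  out$overall_significant <- sigAll & consistent
  out$ok_nn <- out$ok_exact <- out$ok_optimal <- NULL
  out$dir_nn <- out$dir_exact <- out$dir_optimal <- NULL
  rownames(out) <- NULL
  out
}

#' Per-agent summary of significant positive associations
#'
#' For each agent and matching method, the percentage of evaluable
#' definitions that are significant (adjusted p below threshold) with an
#' odds ratio above 1, rounded half-up to an integer percent. Agents
#' without a single significant definition in any method (or cancer) are
#' omitted when \code{omitNullAgents} is TRUE; agents with zero evaluable
#' definitions report NA.
#'
#' @param adjusted output of \code{\link{adjustResults}}.
#' @param omitNullAgents drop all-null agents from the table.
#' @return data.frame: \code{agent} (and \code{cancer} when present) by
#'   method columns of integer percentages.
#' @export
agentSummary <- function(adjusted, omitNullAgents = TRUE) {
  hasCancer <- !is.null(adjusted$cancer)
  keyCols <- if (hasCancer) c("agent", "cancer") else "agent"
  keys <- unique(adjusted[, keyCols, drop = FALSE])
  rownames(keys) <- NULL
  out <- keys
  for (m in .MATCH_METHODS) {
    pct <- numeric(nrow(keys))
    for (i in seq_len(nrow(keys))) {
      sel <- adjusted$method == m & adjusted$agent == keys$agent[i]
      if (hasCancer) sel <- sel & adjusted$cancer == keys$cancer[i]
      nEval <- sum(adjusted$status[sel] == "ok")
      pct[i] <- if (nEval == 0L) NA_real_ else
        roundHalfUp(100 * sum(adjusted$significant[sel] &
                                adjusted$direction[sel] > 0) / nEval)
    }
    out[[m]] <- pct
  }
  if (omitNullAgents) {
    anySig <- vapply(seq_len(nrow(keys)), function(i) {
      sel <- adjusted$agent == keys$agent[i]
      any(adjusted$significant[sel])
    }, logical(1))
    keep <- out$agent %in% unique(keys$agent[anySig])
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Volcano-plot export for one matching analysis
#'
#' x is the natural logarithm of the odds ratio, y the negative base-10
#' logarithm of the Bonferroni-adjusted p-value; since adjusted p-values
#' are capped at 1, y is nonnegative. The horizontal significance
#' threshold, \code{-log10(alpha)}, is carried both as a constant column
#' and as attributes (with the logarithm bases) for plotting. Rows that
#' are not evaluable are excluded.
#'
#' @param adjusted output of \code{\link{adjustResults}}.
#' @param method matching method to export.
#' @param alpha adjusted-significance threshold.
#' @return data.frame with \code{definition_id}, \code{agent}, \code{x},
#'   \code{y}, \code{significant}, \code{threshold_y}.
#' @export
volcanoExport <- function(adjusted, method, alpha = 0.01) {
  stopIf(!method %in% .MATCH_METHODS, "unknown matching method")
  sub <- adjusted[adjusted$method == method & adjusted$status == "ok", ,
                  drop = FALSE]
  out <- data.frame(definition_id = sub$definition_id, agent = sub$agent,
                    x = log(sub$or), y = -log10(sub$p_adj),
                    significant = sub$significant,
                    threshold_y = rep(-log10(alpha), nrow(sub)),
                    stringsAsFactors = FALSE)
  attr(out, "threshold_y") <- -log10(alpha)
  attr(out, "x_base") <- "e"
  attr(out, "y_base") <- "10"
  rownames(out) <- NULL
  out
}
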