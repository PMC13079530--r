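# Matched case-control dataset construction: nearest-neighbor (greedy),
# exact (coarsened strata) and optimal (minimum-cost assignment) matching,
# plus covariate-balance diagnostics.

.CATEGORICAL_PENALTY <- 1000

# Pre-match standard deviations of the continuous matching variables,
# computed over the pooled case + control dataset.
#' Pre-match scales for continuous matching variables
#'
#' @param participants pooled case + control table.
#' @param variables matching variables (continuous ones are age,
#'   visit_year, adi_std).
#' @return named numeric of sample SDs.
#' @export
matchScales <- function(participants, variables) {
  cont <- intersect(variables, .CONTINUOUS_VARS)
  vapply(cont, function(v) {
    stopIf(any(!is.finite(participants[[v]])),
           "continuous matching variable with missing values: ", v)
    sd(participants[[v]])
  }, numeric(1))
}

.asCategory <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ".missing"  # missing is its own category
  x
}

#' Matching distance between a case and a control
#'
#' Euclidean distance over the continuous matching variables after
#' standardization by the pre-match dataset SDs, plus a fixed penalty of
#' 1000 per mismatched categorical variable; symmetric and nonnegative.
#' The penalty effectively enforces categorical agreement whenever any
#' same-category control remains.
#'
#' @param case,control one-row data.frames (or lists) with the matching
#'   variables.
#' @param spec a \linkS4class{MatchSpec}.
#' @param scales named SDs from \code{\link{matchScales}}; defaults to 1
#'   for any missing variable.
#' @return nonnegative scalar.
#' @export
matchDistance <- function(case, control, spec, scales = NULL) {
  cont <- intersect(spec@variables, .CONTINUOUS_VARS)
  cat <- setdiff(spec@variables, cont)
  d2 <- 0
  for (v in cont) {
    s <- if (!is.null(scales) && v %in% names(scales)) scales[[v]] else 1
    d2 <- d2 + (case[[v]] / s - control[[v]] / s)^2
  }
  mis <- sum(vapply(cat, function(v)
    .asCategory(case[[v]]) != .asCategory(control[[v]]), logical(1)))
  sqrt(d2) + .CATEGORICAL_PENALTY * mis
}

# Full case x control distance matrix (compiled matchDistance).
.distanceMatrix <- function(cases, controls, spec, scales) {
  cont <- intersect(spec@variables, .CONTINUOUS_VARS)
  cat <- setdiff(spec@variables, cont)
  sc <- function(df) {
    m <- matrix(0, nrow(df), length(cont))
    for (k in seq_along(cont)) {
      s <- if (cont[k] %in% names(scales)) scales[[cont[k]]] else 1
      m[, k] <- df[[cont[k]]] / s
    }
    m
  }
  codes <- function(df, levs) {
    m <- matrix(0L, nrow(df), length(cat))
    for (k in seq_along(cat))
      m[, k] <- match(.asCategory(df[[cat[k]]]), levs[[k]])
    m
  }
  levs <- lapply(cat, function(v)
    sort(unique(c(.asCategory(cases[[v]]), .asCategory(controls[[v]])))))
  .distKernel(sc(cases), sc(controls), codes(cases, levs),
              codes(controls, levs), .CATEGORICAL_PENALTY)
}

.splitCasesControls <- function(participants) {
  stopIf(is.null(participants$case), "participants needs a 0/1 case column")
  list(cases = participants[participants$case == 1L, , drop = FALSE],
       controls = participants[participants$case == 0L, , drop = FALSE])
}

# Deterministic case processing order: descending age, then id.
.caseOrder <- function(cases) {
  order(-cases$age, cases$participant_id)
}

.newMatchedData <- function(setList, method, spec, dropped, partial, total) {
  sets <- if (length(setList)) do.call(rbind, setList) else
    data.frame(set_id = character(0), participant_id = character(0),
               role = character(0), stringsAsFactors = FALSE)
  rownames(sets) <- NULL
  new("MatchedData", sets = sets, method = method, spec = spec,
      droppedCases = dropped, partialSets = partial, totalDistance = total)
}

.oneSet <- function(id, caseId, controlIds) {
  data.frame(set_id = id,
             participant_id = c(caseId, controlIds),
             role = c("case", rep("control", length(controlIds))),
             stringsAsFactors = FALSE)
}

#' Greedy nearest-neighbor matching
#'
#' Cases are processed in a fixed order (descending age, then id); each
#' case takes its k nearest unused controls by \code{\link{matchDistance}},
#' ties broken by control id, without replacement. Cases with no admissible
#' control (caliper) are dropped with a warning; sets with fewer than k
#' controls are flagged partial.
#'
#' @param participants pooled case + control table (0/1 \code{case}
#'   column), or pass \code{cases}/\code{controls} explicitly.
#' @param spec a \linkS4class{MatchSpec} with
#'   \code{method = "nearest_neighbor"}.
#' @param scales optional \code{\link{matchScales}} override.
#' @return a \linkS4class{MatchedData}.
#' @export
nearestNeighborMatch <- function(participants, spec, scales = NULL) {
  stopIf(spec@method != "nearest_neighbor", "spec method mismatch")
  sc <- .splitCasesControls(participants)
  cases <- sc$cases; controls <- sc$controls
  if (is.null(scales)) scales <- matchScales(participants, spec@variables)
  D <- .distanceMatrix(cases, controls, spec, scales)
  ord <- .caseOrder(cases)
  used <- rep(FALSE, nrow(controls))
  dropped <- character(0); partial <- character(0)
  setList <- list(); total <- 0
  for (rank in seq_along(ord)) {
    i <- ord[rank]
    adm <- which(!used &
                   (is.na(spec@caliper) | D[i, ] <= spec@caliper))
    if (length(adm) == 0L) {
      dropped <- c(dropped, cases$participant_id[i])
      next
    }
    pick <- adm[order(D[i, adm], controls$participant_id[adm])]
    pick <- pick[seq_len(min(spec@ratio, length(pick)))]
    used[pick] <- TRUE
    total <- total + sum(D[i, pick])
    sid <- sprintf("nn_%05d", length(setList) + 1L)
    if (length(pick) < spec@ratio) partial <- c(partial, sid)
    setList[[length(setList) + 1L]] <-
      .oneSet(sid, cases$participant_id[i],
              sort(controls$participant_id[pick]))
  }
  if (length(dropped))
    warning(length(dropped), " case(s) dropped (no admissible control)")
  .newMatchedData(setList, "nearest_neighbor", spec, dropped, partial, total)
}

#' Exact matching on a coarsened joint key
#'
#' Strata are formed on the exact joint key of the matching variables with
#' age coarsened into \code{ageBinWidth}-year bins (visit year used as is).
#' Within a stratum, controls are dealt to that stratum's cases (up to k
#' each) by a seeded random draw, so every emitted set has exactly one
#' case. Cases in strata without controls are dropped with a warning.
#'
#' @inheritParams nearestNeighborMatch
#' @param spec a \linkS4class{MatchSpec} with \code{method = "exact"}.
#' @return a \linkS4class{MatchedData}.
#' @export
exactMatch <- function(participants, spec) {
  stopIf(spec@method != "exact", "spec method mismatch")
  sc <- .splitCasesControls(participants)
  cases <- sc$cases; controls <- sc$controls
  keyOf <- function(df) {
    cols <- lapply(spec@variables, function(v) {
      if (v == "age") floor(df$age / spec@ageBinWidth) * spec@ageBinWidth
      else .asCategory(df[[v]])
    })
    do.call(paste, c(cols, sep = "|"))
  }
  ck <- keyOf(cases); tk <- keyOf(controls)
  dropped <- character(0); partial <- character(0)
  setList <- list()
  for (key in sort(unique(ck))) {
    cs <- sort(cases$participant_id[ck == key])
    ctl <- sort(controls$participant_id[tk == key])
    if (length(ctl) == 0L) { dropped <- c(dropped, cs); next }
    assign <- withSeed(subSeed(spec@seed, paste0("exact|", key)), {
      caseOrd <- if (length(cs) > 1L) sample(cs) else cs
      perm <- if (length(ctl) > 1L) sample(ctl) else ctl
      alloc <- setNames(vector("list", length(caseOrd)), caseOrd)
      ci <- 1L
      for (ct in perm) {
        tries <- 0L
        while (length(alloc[[ci]]) >= spec@ratio && tries < length(caseOrd)) {
          ci <- ci %% length(caseOrd) + 1L
          tries <- tries + 1L
        }
        if (length(alloc[[ci]]) >= spec@ratio) break
        alloc[[ci]] <- c(alloc[[ci]], ct)
        ci <- ci %% length(caseOrd) + 1L
      }
      alloc
    })
    for (cid in names(assign)) {
      got <- assign[[cid]]
      if (length(got) == 0L) { dropped <- c(dropped, cid); next }
      sid <- sprintf("ex_%05d", length(setList) + 1L)
      if (length(got) < spec@ratio) partial <- c(partial, sid)
      setList[[length(setList) + 1L]] <- .oneSet(sid, cid, sort(got))
    }
  }
  if (length(setList) == 0L)
    stop("matching failure: no stratum contains both a case and a control",
         call. = FALSE)
  if (length(dropped))
    warning(length(dropped), " case(s) dropped (stratum without controls)")
  .newMatchedData(setList, "exact", spec, dropped, partial, NA_real_)
}

#' Optimal (minimum-cost assignment) matching
#'
#' Finds the assignment of k distinct controls to every case minimizing the
#' total \code{\link{matchDistance}}, by replicating each case k times and
#' solving the rectangular minimum-cost bipartite assignment exactly (a
#' global optimum, not greedy). When the control pool cannot supply k
#' controls per case, a maximum-cardinality minimum-cost fallback assigns
#' as many controls as possible (capacities balanced across cases in the
#' deterministic case order) with a warning.
#'
#' @inheritParams nearestNeighborMatch
#' @param spec a \linkS4class{MatchSpec} with \code{method = "optimal"}.
#' @return a \linkS4class{MatchedData}.
#' @export
optimalMatch <- function(participants, spec, scales = NULL) {
  stopIf(spec@method != "optimal", "spec method mismatch")
  sc <- .splitCasesControls(participants)
  cases <- sc$cases; controls <- sc$controls
  controls <- controls[order(controls$participant_id), , drop = FALSE]
  if (is.null(scales)) scales <- matchScales(participants, spec@variables)
  nCa <- nrow(cases); nCo <- nrow(controls)
  stopIf(nCa == 0L || nCo == 0L, "matching failure: empty cases or controls")
  ord <- .caseOrder(cases)
  caps <- rep(spec@ratio, nCa)
  dropped <- character(0)
  if (nCo < spec@ratio * nCa) {
    warning("controls < k * cases; falling back to max-cardinality ",
            "min-cost assignment")
    base <- nCo %/% nCa
    extra <- nCo %% nCa
    caps <- integer(nCa)
    caps[ord] <- pmin(spec@ratio, base + (seq_len(nCa) <= extra))
  }
  rows <- rep(seq_len(nCa), caps)
  D <- .distanceMatrix(cases, controls, spec, scales)
  assign <- .lapAssign(D[rows, , drop = FALSE])
  total <- sum(D[cbind(rows, assign)])
  setList <- list(); partial <- character(0)
  for (rank in seq_along(ord)) {
    i <- ord[rank]
    got <- assign[rows == i]
    if (length(got) == 0L) {
      dropped <- c(dropped, cases$participant_id[i])
      next
    }
    sid <- sprintf("op_%05d", length(setList) + 1L)
    if (length(got) < spec@ratio) partial <- c(partial, sid)
    setList[[length(setList) + 1L]] <-
      .oneSet(sid, cases$participant_id[i],
              sort(controls$participant_id[got]))
  }
  if (length(dropped))
    warning(length(dropped), " case(s) left unmatched (control pool exhausted)")
  .newMatchedData(setList, "optimal", spec, dropped, partial, total)
}

#' Dispatch a matching method
#'
#' @param participants pooled case + control table.
#' @param spec a \linkS4class{MatchSpec}; its \code{method} selects the
#'   algorithm.
#' @param scales optional \code{\link{matchScales}} override (ignored by
#'   exact matching).
#' @return a \linkS4class{MatchedData}.
#' @export
matchCaseControl <- function(participants, spec, scales = NULL) {
  switch(spec@method,
         nearest_neighbor = nearestNeighborMatch(participants, spec, scales),
         exact = exactMatch(participants, spec),
         optimal = optimalMatch(participants, spec, scales))
}

#' Covariate balance before and after matching
#'
#' For continuous matching variables, the standardized mean difference
#' (case mean minus control mean over the pooled pre-match SD,
#' \code{sqrt((s1^2 + s0^2)/2)}); the after-matching value uses matched
#' means over the same pre-match SD. For categorical variables, per-level
#' proportion differences. |difference| <= 0.1 is flagged as adequate
#' balance (reported, not enforced).
#'
#' @param matched a \linkS4class{MatchedData}.
#' @param participants the pre-match pooled table.
#' @param spec defaults to \code{matched@spec}.
#' @return data.frame with columns \code{variable}, \code{level},
#'   \code{type}, \code{before}, \code{after}, \code{balanced}; attributes
#'   \code{n_matched_cases} and \code{n_unmatched_cases}.
#' @export
balanceReport <- function(matched, participants, spec = matched@spec) {
  stopIf(nrow(matched@sets) == 0L, "matched data is empty")
  rownames(participants) <- participants$participant_id
  m <- matched@sets
  post <- participants[m$participant_id, , drop = FALSE]
  post$case <- as.integer(m$role == "case")
  smd <- function(df, v) {
    x1 <- df[[v]][df$case == 1L]; x0 <- df[[v]][df$case == 0L]
    s <- sqrt((sd(participants[[v]][participants$case == 1L])^2 +
                 sd(participants[[v]][participants$case == 0L])^2) / 2)
    dm <- mean(x1) - mean(x0)
    if (s == 0) return(if (dm == 0) 0 else Inf)
    dm / s
  }
  rows <- list()
  for (v in spec@variables) {
    if (v %in% .CONTINUOUS_VARS) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_, type = "smd",
        before = smd(participants, v), after = smd(post, v),
        stringsAsFactors = FALSE)
    } else {
      levs <- sort(unique(.asCategory(participants[[v]])))
      for (lv in levs) {
        pd <- function(df) {
          x <- .asCategory(df[[v]])
          mean(x[df$case == 1L] == lv) - mean(x[df$case == 0L] == lv)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv, type = "prop_diff",
          before = pd(participants), after = pd(post),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$balanced <- is.finite(out$after) & abs(out$after) <= 0.1
  attr(out, "n_matched_cases") <- sum(m$role == "case")
  attr(out, "n_unmatched_cases") <- length(matched@droppedCases)
  out
}

#' Matched sets accessor
#'
#' @param x a \linkS4class{MatchedData}.
#' @return the sets data.frame (\code{set_id}, \code{participant_id},
#'   \code{role}).
#' @export
matchedSets <- function(x) x@sets

#' Matching method accessor
#'
#' @param x a \linkS4class{MatchedData}.
#' @return the method string.
#' @export
matchMethod <- function(x) x@method
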