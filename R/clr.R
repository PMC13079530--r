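# Conditional logistic regression for 1:k matched sets, fit by direct
# Newton-Raphson maximization of the conditional likelihood.

.LIFESTYLE_ADJUST <- c("alcohol", "tobacco")

# Dummy-code a lifestyle covariate: reference "never", "unknown" kept as an
# explicit level (large unknown strata; dropping would discard most data).
.dummyCols <- function(x, var) {
  x <- .asCategory(x)
  levs <- if (var %in% .LIFESTYLE_ADJUST) {
    l <- .LIFESTYLE_LEVELS[.LIFESTYLE_LEVELS %in% unique(x)]
    c(l, setdiff(sort(unique(x)), l))
  } else sort(unique(x))
  ref <- if (var %in% .LIFESTYLE_ADJUST && "never" %in% levs) "never"
         else levs[1]
  keep <- setdiff(levs, ref)
  if (length(keep) == 0L)  # single-level covariate carries no contrast
    return(matrix(numeric(0), nrow = length(x), ncol = 0))
  out <- sapply(keep, function(lv) as.numeric(x == lv))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(keep))
  colnames(out) <- paste(var, keep, sep = ".")
  out
}

.withinSetConstant <- function(x, set) {
  n <- tabulate(set)
  sx <- drop(rowsum(x, set))
  sxx <- drop(rowsum(x * x, set))
  all(n * sxx - sx * sx <= 1e-12 * pmax(1, sx * sx))
}

#' Build a conditional-logistic design
#'
#' Assembles the model matrix for one exposure: the binary exposure coding
#' plus optional adjustment covariates (alcohol and tobacco dummy-coded
#' with reference "never" and "unknown" as its own level; \code{adi_std}
#' linear). Adjustment columns that are constant within every matched set
#' are inestimable under the conditional likelihood and are dropped with a
#' warning; the exposure column is always kept (a fully set-constant
#' exposure yields a non-evaluable fit).
#'
#' @param data data.frame with one row per set member; needs the set,
#'   case and exposure columns plus any adjustment covariates.
#' @param exposure name of the binary exposure column.
#' @param adjust adjustment covariate names (default none).
#' @param set,case column names of the set id and 0/1 case indicator.
#' @return a \linkS4class{CLRDesign}.
#' @export
clrDesign <- function(data, exposure = "exposure", adjust = character(0),
                      set = "set_id", case = "case") {
  setIdx <- as.integer(factor(data[[set]], levels = unique(data[[set]])))
  y <- as.integer(data[[case]])
  stopIf(any(tapply(y, setIdx, sum) != 1L),
         "every matched set must contain exactly one case")
  cols <- list(matrix(as.numeric(data[[exposure]]), ncol = 1,
                      dimnames = list(NULL, exposure)))
  for (v in adjust) {
    cols[[length(cols) + 1L]] <-
      if (v %in% .CONTINUOUS_VARS || is.numeric(data[[v]]))
        matrix(as.numeric(data[[v]]), ncol = 1, dimnames = list(NULL, v))
      else .dummyCols(data[[v]], v)
  }
  X <- do.call(cbind, cols)
  stopIf(any(!is.finite(X)), "input error: non-finite covariates")
  constant <- vapply(seq_len(ncol(X)), function(j)
    .withinSetConstant(X[, j], setIdx), logical(1))
  constant[1L] <- FALSE  # exposure handled by the fitter
  dropped <- colnames(X)[constant]
  if (length(dropped))
    warning("dropping set-constant (inestimable) covariates: ",
            paste(dropped, collapse = ", "))
  X <- X[, !constant, drop = FALSE]
  new("CLRDesign", X = X, y = y, set = setIdx, exposure = exposure,
      dropped = dropped)
}

#' Conditional log-likelihood
#'
#' For matched sets with one case each,
#' \eqn{\ell(\beta) = \sum_s [x_{case}\beta - \log \sum_{j \in s}
#' \exp(x_j\beta)]}, where j ranges over all members of set s. Computed
#' with a per-set max shift for numerical stability; finite for finite
#' \eqn{\beta}.
#'
#' @param design a \linkS4class{CLRDesign}.
#' @param beta coefficient vector (length \code{ncol(design@X)}).
#' @return scalar log-likelihood.
#' @examples
#' d <- simulateMatchedSets(20, 1, log(2), seed = 1)
#' dd <- clrDesign(d)
#' conditionalLoglik(dd, 0)  # equals -sum(log(set sizes))
#' @export
conditionalLoglik <- function(design, beta) {
  stopIf(any(!is.finite(beta)), "beta must be finite")
  eta <- drop(design@X %*% beta)
  mx <- as.numeric(tapply(eta, design@set, max))
  lse <- log(drop(rowsum(exp(eta - mx[design@set]), design@set))) + mx
  sum(eta[design@y == 1L]) - sum(lse)
}

# One evaluation of loglik, score and information at beta. A global
# exponent shift suffices unless the linear predictor spans an extreme
# range, in which case the exact per-set shift is used.
.clrDerivs <- function(X, y, set, beta) {
  eta <- drop(X %*% beta)
  nSets <- max(set)
  if (max(eta) - min(eta) < 500) {
    shift <- max(eta)
    mx <- rep(shift, nSets)
  } else {
    mx <- as.numeric(tapply(eta, set, max))
  }
  w <- exp(eta - mx[set])
  sw <- drop(rowsum(w, set))
  p <- w / sw[set]
  ll <- sum(eta[y == 1L]) - sum(log(sw) + mx)
  score <- drop(crossprod(X, y - p))
  M <- rowsum(X * p, set)
  info <- crossprod(X, X * p) - crossprod(M)
  list(ll = ll, score = score, info = info)
}

#' Fit conditional logistic regression
#'
#' Newton-Raphson with step-halving on the conditional log-likelihood.
#' Convergence when the maximum absolute score falls below \code{scoreTol}
#' or the relative log-likelihood change falls below \code{llTol}, capped
#' at \code{maxIter} iterations. Monotone separation (the exposure
#' perfectly predicting the case within informative sets) is detected by
#' \code{|beta| > separationThreshold} and flagged non-evaluable, as are
#' designs with no informative sets; a singular information matrix falls
#' back to a small ridge with a warning.
#'
#' @param design a \linkS4class{CLRDesign}.
#' @param maxIter,scoreTol,llTol,separationThreshold,ridge numerical
#'   controls.
#' @return a \linkS4class{CLRFit}.
#' @examples
#' d <- simulateMatchedSets(200, 4, log(2), seed = 1)
#' fitCLR(clrDesign(d))
#' @export
fitCLR <- function(design, maxIter = 100L, scoreTol = 1e-8, llTol = 1e-12,
                   separationThreshold = 15, ridge = 1e-8) {
  X <- design@X; y <- design@y; set <- design@set
  nSets <- length(unique(set))
  expo <- X[, design@exposure]
  nSz <- tabulate(set)
  sx <- drop(rowsum(expo, set))
  sxx <- drop(rowsum(expo * expo, set))
  nInf <- sum(nSz * sxx - sx * sx > 1e-12 * pmax(1, sx * sx))
  blank <- function(status) new(
    "CLRFit", coef = setNames(rep(NA_real_, ncol(X)), colnames(X)),
    se = setNames(rep(NA_real_, ncol(X)), colnames(X)),
    vcov = matrix(NA_real_, ncol(X), ncol(X)), loglik = NA_real_,
    iterations = 0L, converged = FALSE, status = status,
    nSets = as.integer(nSets), nInformative = as.integer(nInf),
    exposure = design@exposure)
  if (nInf == 0L) return(blank("non_evaluable"))

  beta <- numeric(ncol(X))
  d <- .clrDerivs(X, y, set, beta)
  converged <- FALSE; iter <- 0L; ridged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    step <- tryCatch(solve(d$info, d$score), error = function(e) NULL)
    if (is.null(step)) {
      ridged <- TRUE
      step <- solve(d$info + diag(ridge, ncol(X)), d$score)
    }
    newBeta <- beta + step
    dNew <- .clrDerivs(X, y, set, newBeta)
    halvings <- 0L
    while ((!is.finite(dNew$ll) || dNew$ll < d$ll) && halvings < 30L) {
      step <- step / 2
      newBeta <- beta + step
      dNew <- .clrDerivs(X, y, set, newBeta)
      halvings <- halvings + 1L
    }
    relChange <- abs(dNew$ll - d$ll) / (abs(d$ll) + llTol)
    beta <- newBeta; d <- dNew
    if (max(abs(d$score)) < scoreTol || relChange < llTol) {
      converged <- TRUE
      break
    }
  }
  if (ridged)
    warning("singular information matrix; ridge fallback (", ridge, ") used")
  status <- if (any(abs(beta) > separationThreshold)) "separation"
            else if (!converged) "not_converged" else "ok"
  if (status != "ok") {
    out <- blank(status)
    out@iterations <- iter
    return(out)
  }
  V <- tryCatch(solve(d$info), error = function(e)
    solve(d$info + diag(ridge, ncol(X))))
  dimnames(V) <- list(colnames(X), colnames(X))
  new("CLRFit", coef = setNames(beta, colnames(X)),
      se = setNames(sqrt(diag(V)), colnames(X)), vcov = V,
      loglik = d$ll, iterations = iter, converged = TRUE, status = "ok",
      nSets = as.integer(nSets), nInformative = as.integer(nInf),
      exposure = design@exposure)
}

#' Wald test and confidence interval for one coefficient
#'
#' \eqn{z = \hat\beta / se}, two-sided \eqn{p = 2\Phi(-|z|)}, and the 95
#' percent interval \eqn{\exp(\hat\beta \pm 1.959964\, se)} on the odds
#' ratio scale. Non-evaluable fits (and zero standard errors) propagate
#' NA.
#'
#' @param fit a \linkS4class{CLRFit}.
#' @param coefficient coefficient name; default the exposure.
#' @return one-row data.frame with \code{beta}, \code{se}, \code{z},
#'   \code{p}, \code{or}, \code{ci_low}, \code{ci_high}.
#' @export
waldTest <- function(fit, coefficient = fit@exposure) {
  b <- fit@coef[[coefficient]]
  s <- fit@se[[coefficient]]
  if (fit@status != "ok" || !is.finite(s) || s == 0)
    return(data.frame(coefficient = coefficient, beta = NA_real_,
                      se = NA_real_, z = NA_real_, p = NA_real_,
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      stringsAsFactors = FALSE))
  z <- b / s
  q <- qnorm(0.975)
  data.frame(coefficient = coefficient, beta = b, se = s, z = z,
             p = 2 * pnorm(-abs(z)), or = exp(b),
             ci_low = exp(b - q * s), ci_high = exp(b + q * s),
             stringsAsFactors = FALSE)
}

# Fit one CLR per retained definition for one matched dataset. The
# adjustment design is assembled once; only the exposure column changes
# across definitions. Default adjustment follows the study design:
# alcohol + tobacco + adi_std for nearest-neighbor and exact matching,
# exposure-only for optimal matching (those covariates were matched on).
#' Fit CLR models for every retained exposure definition
#'
#' @param es an \linkS4class{ExposureSet} through
#'   \code{\link{prevalenceFilter}}.
#' @param matched a \linkS4class{MatchedData} built from the same
#'   participants.
#' @param adjust adjustment covariates; if NULL, chosen by matching method
#'   (alcohol, tobacco, adi_std for nearest-neighbor/exact; none for
#'   optimal).
#' @return data.frame with one row per retained definition: identifiers,
#'   set counts, \code{beta}, \code{se}, \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{p_raw} and \code{status}.
#' @export
fitAllExposures <- function(es, matched, adjust = NULL) {
  if (is.null(adjust))
    adjust <- if (matched@method == "optimal") character(0)
              else c("alcohol", "tobacco", "adi_std")
  defs <- retainedDefinitions(es)
  bin <- binaryCoding(es)
  members <- matched@sets
  cov <- as.data.frame(colData(es), optional = TRUE)
  rownames(cov) <- cov$participant_id
  mdata <- cbind(members,
                 cov[members$participant_id,
                     setdiff(colnames(cov), c("case", "participant_id")),
                     drop = FALSE])
  mdata$case <- as.integer(members$role == "case")
  rownames(mdata) <- NULL
  pidx <- match(members$participant_id, colnames(bin))
  # adjustment design depends only on the matched data: assemble once
  setIdx <- as.integer(factor(mdata$set_id, levels = unique(mdata$set_id)))
  y <- mdata$case
  Xadj <- NULL
  if (length(adjust)) {
    cols <- lapply(adjust, function(v)
      if (v %in% .CONTINUOUS_VARS)
        matrix(as.numeric(mdata[[v]]), ncol = 1, dimnames = list(NULL, v))
      else .dummyCols(mdata[[v]], v))
    Xadj <- do.call(cbind, cols)
    constant <- vapply(seq_len(ncol(Xadj)), function(j)
      .withinSetConstant(Xadj[, j], setIdx), logical(1))
    Xadj <- Xadj[, !constant, drop = FALSE]
  }
  nD <- nrow(defs)
  nSets <- nInf <- integer(nD)
  beta <- se <- rep(NA_real_, nD)
  status <- character(nD)
  q <- qnorm(0.975)
  for (i in seq_len(nD)) {
    expo <- matrix(as.numeric(bin[defs$definition_id[i], pidx]), ncol = 1,
                   dimnames = list(NULL, "exposure"))
    X <- if (is.null(Xadj)) expo else cbind(expo, Xadj)
    design <- new("CLRDesign", X = X, y = y, set = setIdx,
                  exposure = "exposure", dropped = character(0))
    fit <- withCallingHandlers(
      fitCLR(design),
      warning = function(w) invokeRestart("muffleWarning"))
    nSets[i] <- fit@nSets
    nInf[i] <- fit@nInformative
    status[i] <- fit@status
    if (fit@status == "ok" && is.finite(fit@se[["exposure"]]) &&
        fit@se[["exposure"]] > 0) {
      beta[i] <- fit@coef[["exposure"]]
      se[i] <- fit@se[["exposure"]]
    } else if (fit@status == "ok") {
      status[i] <- "non_evaluable"
    }
  }
  z <- beta / se
  res <- data.frame(
    definition_id = defs$definition_id, agent = defs$agent,
    metric = defs$metric, buffer_km = defs$buffer_km,
    lag_years = defs$lag_years, method = matched@method,
    n_sets = nSets, n_informative = nInf, beta = beta, se = se,
    or = exp(beta), ci_low = exp(beta - q * se),
    ci_high = exp(beta + q * se), p_raw = 2 * pnorm(-abs(z)),
    status = status, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
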