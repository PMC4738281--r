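# Diversification-rate model fitting on branching times, the rate-constancy
# statistic deltaAIC_RC, and the relative cladogenesis test.

# Interval bookkeeping: with branching times t_1 > ... > t_{n-1} (t_1 the
# root) there are k lineages during [t_k, t_{k-1}] for k = 2..n-1 and n
# lineages during the final interval [0, t_{n-1}].
.btIntervals <- function(bt) {
  bt <- sort(as.numeric(bt), decreasing = TRUE)
  if (any(bt <= 0)) stop("branching times must be positive")
  n <- length(bt) + 1L
  a <- c(-diff(bt), bt[n - 1L])        # durations for k = 2..n lineages
  list(n = n, bt = bt, k = 2:n, a = a)
}

# log-likelihood for a per-lineage rate function r(k): events happen at the
# end of every interval except the last, with rate k * r(k); each interval
# contributes the survival term -k * r(k) * a_k.
.lnLRateByCount <- function(iv, r) {
  rk <- r(iv$k)
  if (any(!is.finite(rk)) || any(rk < 0)) return(-Inf)
  events <- seq_len(iv$n - 2L)       # intervals ending in an event
  if (any(rk[events] <= 0)) return(-Inf)
  sum(log(iv$k[events] * rk[events])) - sum(iv$k * rk * iv$a)
}

#' Log-likelihood of a diversification model at given parameters
#'
#' Evaluates the branching-times log-likelihood of one of the five supported
#' models at user-supplied parameters, e.g. to inspect profile likelihoods or
#' verify nesting identities.
#'
#' @param bt branching times (node ages, any order; the root is the oldest).
#' @param model one of `"pureBirth"`, `"birthDeath"`, `"DDL"`, `"DDX"`,
#'   `"yule2rate"`.
#' @param params named numeric vector of the model's parameters:
#'   `lambda`; `lambda`, `mu`; `lambda0`, `K`; `lambda0`, `x`; or `lambda1`,
#'   `lambda2`, `tShift`.
#' @return the log-likelihood (scalar; `-Inf` when the parameters are outside
#'   the model's support).
#' @export
rateModelLogLik <- function(bt, model, params) {
  iv <- .btIntervals(bt)
  switch(model,
    pureBirth = .lnLRateByCount(iv, function(k) rep(params[["lambda"]],
                                                    length(k))),
    DDX = .lnLRateByCount(iv, function(k) params[["lambda0"]] *
                            k^(-params[["x"]])),
    DDL = .lnLRateByCount(iv, function(k) params[["lambda0"]] *
                            (1 - k / params[["K"]])),
    yule2rate = .lnLYule2Rate(iv, params[["lambda1"]], params[["lambda2"]],
                              params[["tShift"]]),
    birthDeath = .lnLBirthDeath(iv, params[["lambda"]], params[["mu"]]),
    stop("unknown model: ", model))
}

# two-rate Yule: rate lambda1 older than tShift, lambda2 younger; the
# interval containing the shift is split, and an event falling exactly on
# the shift is billed to the older segment.
.lnLYule2Rate <- function(iv, lambda1, lambda2, tShift) {
  if (lambda1 < 0 || lambda2 < 0) return(-Inf)
  bt <- iv$bt
  n <- iv$n
  L1 <- 0; L2 <- 0; n1 <- 0L; n2 <- 0L
  for (k in 2:n) {
    top <- bt[k - 1L]
    bottom <- if (k <= n - 1L) bt[k] else 0
    oldPart <- max(0, top - max(bottom, tShift))
    newPart <- (top - bottom) - oldPart
    L1 <- L1 + k * oldPart
    L2 <- L2 + k * newPart
    if (k <= n - 1L) {                 # event at age bt[k]
      if (bt[k] >= tShift) n1 <- n1 + 1L else n2 <- n2 + 1L
    }
  }
  term <- function(nev, lam, Ltot) {
    if (lam == 0) { if (nev > 0L) return(-Inf) else return(0) }
    nev * log(lam) - lam * Ltot
  }
  t1 <- term(n1, lambda1, L1)
  t2 <- term(n2, lambda2, L2)
  if (!is.finite(t1) || !is.finite(t2)) return(-Inf)
  sum(log(iv$k[seq_len(n - 2L)])) + t1 + t2
}

# Nee et al. birth-death likelihood on branching times, conditioned on the
# root age and survival of both root lineages, written with the same
# lfactorial(n - 1) constant as the pure-birth likelihood so that mu = 0
# reduces to it exactly.
.lnLBirthDeath <- function(iv, lambda, mu) {
  if (lambda <= 0 || mu < 0 || mu >= lambda) return(-Inf)
  r <- lambda - mu
  a <- mu / lambda
  bt <- iv$bt
  n <- iv$n
  lfactorial(n - 1) + (n - 2) * log(r) + n * log(1 - a) +
    r * sum(bt[-1L]) - 2 * sum(log(exp(r * bt) - a))
}

.fitOne <- function(iv, negFn, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negFn, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 1000L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("rate-model optimizer failed")
  best
}

#' Fit the five diversification-rate models
#'
#' Fits the two rate-constant models (pure birth; birth-death in the Nee et
#' al. formulation, conditioned on root age and survival of both root
#' lineages) and the three rate-variable models (logistic density-dependent
#' `DDL`, exponential density-dependent `DDX`, and two-rate Yule
#' `yule2rate` with the shift time searched over the observed branching
#' times) by maximum likelihood, and computes the rate-constancy statistic
#' `deltaAICrc = min AIC(rate-constant) - min AIC(rate-variable)`. A positive
#' value favours rate variation. The pure-birth MLE is the closed form
#' `lambda = (n - 2) / sum_k k a_k`.
#'
#' @param bt branching times (from [branchingTimes()]), `n >= 4` tips.
#' @return a [DivRateResult-class].
#' @export
fitRateModels <- function(bt) {
  if (inherits(bt, "phylo")) bt <- branchingTimes(bt)
  bt <- sort(as.numeric(bt), decreasing = TRUE)
  iv <- .btIntervals(bt)
  n <- iv$n
  if (n < 4L) stop("rate-model fitting requires at least 4 tips")
  S <- sum(iv$k * iv$a)                 # total lineage-time

  # pure birth: closed-form MLE
  lamHat <- (n - 2) / S
  pbLnL <- rateModelLogLik(bt, "pureBirth", c(lambda = lamHat))
  pbPar <- c(lambda = lamHat)

  # birth-death over (log r, a)
  bdNeg <- function(p) {
    r <- exp(p[1L]); a <- p[2L]
    lam <- r / (1 - a); mu <- a * lam
    ll <- .lnLBirthDeath(iv, lam, mu)
    if (!is.finite(ll)) 1e10 else -ll
  }
  bdFit <- .fitOne(iv, bdNeg,
                   starts = list(c(log(lamHat), 0.001), c(log(lamHat), 0.5)),
                   lower = c(log(1e-8), 0), upper = c(log(1e6), 0.9999))
  rHat <- exp(bdFit$par[1L]); aHat <- bdFit$par[2L]
  bdPar <- c(lambda = rHat / (1 - aHat), mu = aHat * rHat / (1 - aHat))
  bdLnL <- -bdFit$value
  if (bdLnL < pbLnL) {                  # mu = 0 boundary dominates
    bdPar <- c(lambda = lamHat, mu = 0)
    bdLnL <- pbLnL
  }

  # DDX: r(k) = lambda0 * k^(-x), x >= 0 (density-dependent decline;
  # x = 0 recovers pure birth at the boundary)
  ddxNeg <- function(p) {
    ll <- .lnLRateByCount(iv, function(k) exp(p[1L]) * k^(-p[2L]))
    if (!is.finite(ll)) 1e10 else -ll
  }
  ddxFit <- .fitOne(iv, ddxNeg,
                    starts = list(c(log(lamHat), 0), c(log(lamHat), 0.5)),
                    lower = c(log(1e-8), 0), upper = c(log(1e6), 3))
  ddxPar <- c(lambda0 = exp(ddxFit$par[1L]), x = ddxFit$par[2L])
  ddxLnL <- -ddxFit$value

  # DDL: r(k) = lambda0 * (1 - k / K), K > n - 1 for positive event rates
  Kmin <- n - 1 + 1e-3
  ddlNeg <- function(p) {
    ll <- .lnLRateByCount(iv, function(k) exp(p[1L]) * (1 - k / p[2L]))
    if (!is.finite(ll)) 1e10 else -ll
  }
  ddlFit <- .fitOne(iv, ddlNeg,
                    starts = list(c(log(lamHat), 10 * n), c(log(lamHat),
                                                            n + 1)),
                    lower = c(log(1e-8), Kmin), upper = c(log(1e6), 1e7))
  ddlPar <- c(lambda0 = exp(ddlFit$par[1L]), K = ddlFit$par[2L])
  ddlLnL <- -ddlFit$value
  ddlBoundary <- ddlPar[["K"]] <= n
  if (ddlBoundary)
    message("fitRateModels: DDL carrying capacity at boundary (K <= n)")

  # yule2rate: shift over observed branching times, per-segment closed forms
  y2rBest <- NULL
  for (st in bt[-1L]) {
    L1 <- 0; L2 <- 0; n1 <- 0L; n2 <- 0L
    for (k in 2:n) {
      top <- bt[k - 1L]
      bottom <- if (k <= n - 1L) bt[k] else 0
      oldPart <- max(0, top - max(bottom, st))
      L1 <- L1 + k * oldPart
      L2 <- L2 + k * (top - bottom - oldPart)
      if (k <= n - 1L) {
        if (bt[k] >= st) n1 <- n1 + 1L else n2 <- n2 + 1L
      }
    }
    lam1 <- if (L1 > 0) n1 / L1 else 0
    lam2 <- if (L2 > 0) n2 / L2 else 0
    ll <- .lnLYule2Rate(iv, lam1, lam2, st)
    if (is.null(y2rBest) || ll > y2rBest$lnL)
      y2rBest <- list(lnL = ll, par = c(lambda1 = lam1, lambda2 = lam2,
                                        tShift = st))
  }
  y2rLnL <- y2rBest$lnL
  y2rPar <- y2rBest$par
  if (y2rLnL < pbLnL) {                 # constant rate dominates
    y2rLnL <- pbLnL
    y2rPar <- c(lambda1 = lamHat, lambda2 = lamHat, tShift = bt[2L])
  }

  fits <- data.frame(
    model = c("pureBirth", "birthDeath", "DDL", "DDX", "yule2rate"),
    lnL = c(pbLnL, bdLnL, ddlLnL, ddxLnL, y2rLnL),
    nParams = c(1L, 2L, 2L, 2L, 3L))
  fits$AIC <- 2 * fits$nParams - 2 * fits$lnL
  aicRC <- min(fits$AIC[fits$model %in% c("pureBirth", "birthDeath")])
  aicRV <- min(fits$AIC[fits$model %in% c("DDL", "DDX", "yule2rate")])
  new("DivRateResult", fits = fits,
      params = list(pureBirth = pbPar, birthDeath = bdPar, DDL = ddlPar,
                    DDX = ddxPar, yule2rate = y2rPar),
      deltaAICrc = aicRC - aicRV,
      bestModel = fits$model[which.min(fits$AIC)])
}

#' Rate-constancy statistic
#'
#' @param x a [DivRateResult-class].
#' @return `deltaAICrc = AIC_RC - AIC_RV`, the AIC of the best rate-constant
#'   model minus that of the best rate-variable model.
#' @export
deltaAICrc <- function(x) {
  stopifnot(is(x, "DivRateResult"))
  x@deltaAICrc
}

#' Relative cladogenesis test
#'
#' At each internal node, with `k` lineages alive immediately after the
#' node's split jointly leaving the tree's `n` tips, all compositions of `n`
#' tips into `k` positive parts are equally likely under the equal-rates
#' Markov null; the probability that a given lineage leaves at least `r`
#' descendants is `choose(n - r, k - 1) / choose(n - 1, k - 1)`. One test per
#' node is performed on its larger daughter clade, and p-values are
#' Bonferroni-adjusted by the number of node tests.
#'
#' @param tree a rooted, binary, ultrametric `ape::phylo` with `n >= 4` tips.
#' @param alpha significance level for flagging nodes (default 0.05).
#' @param tol relative ultrametricity tolerance.
#' @return an [RCResult-class].
#' @export
rcTest <- function(tree, alpha = 0.05, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape 'phylo' object")
  if (!ape::is.binary(tree)) stop("RC test requires a binary tree")
  if (!ape::is.rooted(tree)) stop("RC test requires a rooted tree")
  ntip <- length(tree$tip.label)
  if (ntip < 4L) stop("RC test requires at least 4 tips")
  ages <- .nodeAges(tree, tol = tol, what = "RC input tree")
  edge <- tree$edge
  tipsBelow <- .tipsBelow(tree)
  nTipsBelow <- lengths(tipsBelow)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  nodeAges <- ages[nodes]
  rows <- lapply(nodes, function(v) {
    tv <- ages[v]
    # lineages alive immediately after this split: one initial lineage plus
    # one per split at this age or older (ties count as simultaneous)
    k <- 1L + sum(nodeAges >= tv)
    kidTips <- sort(nTipsBelow[edge[edge[, 1L] == v, 2L]], decreasing = TRUE)
    r <- kidTips[1L]
    pRaw <- choose(ntip - r, k - 1L) / choose(ntip - 1L, k - 1L)
    data.frame(node = v, age = tv, k = k, tipsLarger = kidTips[1L],
               tipsSmaller = kidTips[2L], pRaw = pRaw)
  })
  tab <- do.call(rbind, rows)
  nTests <- nrow(tab)
  tab$pAdjusted <- pmin(1, tab$pRaw * nTests)
  tab$significant <- tab$pAdjusted <= alpha
  tab <- tab[order(tab$age, decreasing = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  new("RCResult", table = tab, alpha = alpha, nTests = as.integer(nTests))
}
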