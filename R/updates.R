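## Full conditional updates of the Gibbs sampler (pure-R reference engine).
## Draw order per full scan: sigma2_eps, mu, (theta_j, alpha_j) for j = 1..p
## ascending, sigma2_alpha, pi.  The compiled engine consumes the identical
## random stream; keep the two in lock-step when editing either.

rScaledInvChisq <- function(df, scale) df * scale / rchisq(1L, df)

#' Draw the residual variance from its full conditional
#'
#' The full conditional of \eqn{\sigma^2_\epsilon} is scaled inverse
#' chi-square with degrees of freedom \eqn{v_\epsilon + n} and scale
#' \eqn{(v_\epsilon S_\epsilon + r'r) / (v_\epsilon + n)} where r is the
#' current residual vector.
#'
#' @param resid current residual vector r = y - mu - X (theta * alpha).
#' @param priors a \linkS4class{BvsPriors}.
#' @return one positive draw.
#' @export
sampleResidualVariance <- function(resid, priors) {
    rss <- sum(resid * resid)
    if (!is.finite(rss)) stop("non-finite residual sum of squares")
    n <- length(resid)
    df <- priors@vEps + n
    rScaledInvChisq(df, (priors@vEps * priors@sEps + rss) / df)
}

#' Draw the intercept from its full conditional
#'
#' Normal with mean \eqn{1'(y - X(\theta \circ \alpha))/n} and variance
#' \eqn{\sigma^2_\epsilon / n} (flat prior on mu).
#'
#' @param y phenotype vector.
#' @param fitted the genetic values X (theta * alpha).
#' @param sigma2Eps current residual variance.
#' @return one draw.
#' @export
sampleIntercept <- function(y, fitted, sigma2Eps) {
    n <- length(y)
    if (n == 0L) stop("cannot sample an intercept from zero individuals")
    m <- sum(y - fitted) / n
    rnorm(1L, m, sqrt(sigma2Eps / n))
}

#' Posterior probability that a SNP is included
#'
#' Collapsed inclusion probability based on the sufficient scalar
#' \eqn{u_j = x_j' r_{-j}} (residual with SNP j's contribution removed):
#' under exclusion \eqn{u_j \sim N(0, c_{jj}\sigma^2_\epsilon)}; under
#' inclusion, with the effect integrated over its slab,
#' \eqn{u_j \sim N(0, c_{jj}\sigma^2_\epsilon + c_{jj}^2\sigma^2_\alpha)}.
#' Returns \eqn{\pi f_1 / (\pi f_1 + (1-\pi) f_0)}, computed in log space.
#'
#' @param u the scalar x_j' r_-j.
#' @param cjj x_j' x_j, must be positive (monomorphic columns are excluded
#'   upstream).
#' @param sigma2Eps,sigma2Alpha current residual and slab variances.
#' @param pi current inclusion probability; the boundary values 0 and 1
#'   short-circuit to 0 and 1.
#' @return probability in [0, 1].
#' @export
inclusionProbability <- function(u, cjj, sigma2Eps, sigma2Alpha, pi) {
    if (cjj <= 0) stop("cjj must be positive (monomorphic column?)")
    if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
    if (pi == 0) return(0)
    if (pi == 1) return(1)
    # log f1 - log f0 for the two zero-mean normals with variances
    # v0 = cjj*s2e and v1 = v0 + cjj^2*s2a, written with one log:
    # -log(v1/v0)/2 + u^2 (1/v0 - 1/v1)/2
    w <- cjj * sigma2Alpha
    lo <- log(pi) - log(1 - pi) -
        0.5 * log((sigma2Eps + w) / sigma2Eps) +
        0.5 * u * u * w / (cjj * sigma2Eps * (sigma2Eps + w))
    1 / (1 + exp(-lo))
}

#' Joint update of one SNP's indicator and effect
#'
#' Removes SNP j from the residual (\eqn{r_{-j} = r + \theta_j \alpha_j
#' x_j}), draws the indicator from its collapsed full conditional, then --
#' if included -- draws the effect from \eqn{N(u_j / c_j,
#' \sigma^2_\epsilon / c_j)} with \eqn{c_j = x_j'x_j + \sigma^2_\epsilon /
#' \sigma^2_\alpha}; the excluded effect contributes exactly 0.  The
#' residual is updated incrementally.
#'
#' @param j SNP (column) index.
#' @param state chain state list (see [newChainState()]).
#' @param X dosage matrix, individuals in rows.
#' @return the updated state.
#' @export
sampleEffectAndIndicator <- function(j, state, X) {
    xj <- X[, j]
    cjj <- state$cjj[j]
    s2a <- if (length(state$sigma2Alpha) > 1L) state$sigma2Alpha[j]
           else state$sigma2Alpha
    r <- state$resid
    if (state$theta[j] == 1L) r <- r + state$alpha[j] * xj
    u <- sum(xj * r)
    p1 <- inclusionProbability(u, cjj, state$sigma2Eps, s2a, state$pi)
    th <- as.integer(runif(1L) < p1)
    al <- 0
    if (th == 1L) {
        cj <- cjj + state$sigma2Eps / s2a
        al <- rnorm(1L, u / cj, sqrt(state$sigma2Eps / cj))
        if (!is.finite(al)) stop("non-finite effect draw")
        r <- r - al * xj
    }
    state$theta[j] <- th
    state$alpha[j] <- al
    state$resid <- r
    state$k <- sum(state$theta)
    state
}

#' Draw the slab variance from its full conditional
#'
#' Shared-slab form: scaled inverse chi-square with df \eqn{v_\alpha + k}
#' and scale \eqn{(v_\alpha S_\alpha + \sum_{j: \theta_j = 1} \alpha_j^2) /
#' (v_\alpha + k)}; with k = 0 this is a draw from the prior.  In
#' per-locus mode each included locus gets df \eqn{v_\alpha + 1} with its
#' own \eqn{\alpha_j^2}, and excluded loci draw from the prior.
#'
#' @param alpha current effect vector.
#' @param theta current 0/1 indicator vector.
#' @param priors a \linkS4class{BvsPriors}.
#' @param updatable logical vector of columns participating in updates
#'   (per-locus mode only).
#' @return a positive scalar (shared) or a vector of length p (per-locus).
#' @export
sampleSlabVariance <- function(alpha, theta, priors,
                               updatable = rep(TRUE, length(alpha))) {
    if (priors@sharedSlab) {
        k <- sum(theta)
        ss <- sum(alpha[theta == 1L]^2)
        df <- priors@vAlpha + k
        rScaledInvChisq(df, (priors@vAlpha * priors@sAlpha + ss) / df)
    } else {
        out <- rep(priors@sAlpha, length(alpha))
        for (j in seq_along(alpha)) {
            if (!updatable[j]) next
            if (theta[j] == 1L) {
                df <- priors@vAlpha + 1
                out[j] <- rScaledInvChisq(
                    df, (priors@vAlpha * priors@sAlpha + alpha[j]^2) / df)
            } else {
                out[j] <- rScaledInvChisq(priors@vAlpha, priors@sAlpha)
            }
        }
        out
    }
}

#' Draw the inclusion probability from its Beta full conditional
#'
#' @param k number of currently included SNPs.
#' @param p total number of SNPs.
#' @param priors a \linkS4class{BvsPriors} supplying the Beta(a0, b0)
#'   prior.
#' @return one draw from Beta(a0 + k, b0 + p - k).
#' @export
samplePi <- function(k, p, priors) {
    if (k > p || k < 0) stop("invalid inclusion count: k must lie in 0..p")
    rbeta(1L, priors@a0 + k, priors@b0 + p - k)
}

#' Initialise a chain state
#'
#' Neutral start: mu at the phenotype mean, all effects and indicators 0,
#' residual variance at var(y), slab variance at its prior scale, pi at its
#' prior mean -- each replaced by the fixed value when the corresponding
#' testing hook is set.
#'
#' @param X dosage matrix, individuals in rows (already imputed).
#' @param y phenotype vector.
#' @param priors a \linkS4class{BvsPriors}.
#' @param updatable logical: columns taking part in updates (non-monomorphic).
#' @return a chain state list with fields mu, alpha, theta, sigma2Eps,
#'   sigma2Alpha, pi, k, resid, cjj, updatable.
#' @export
newChainState <- function(X, y, priors,
                          updatable = rep(TRUE, ncol(X))) {
    n <- length(y)
    mu <- if (length(priors@fixMu)) priors@fixMu else sum(y) / n
    s2e <- if (length(priors@fixSigma2Eps)) priors@fixSigma2Eps else var(y)
    s2a <- if (length(priors@fixSigma2Alpha)) priors@fixSigma2Alpha
           else priors@sAlpha
    if (!priors@sharedSlab) s2a <- rep(s2a, ncol(X))
    pi <- if (length(priors@fixPi)) priors@fixPi
          else priors@a0 / (priors@a0 + priors@b0)
    list(mu = mu, alpha = numeric(ncol(X)),
         theta = integer(ncol(X)), sigma2Eps = s2e, sigma2Alpha = s2a,
         pi = pi, k = 0L, resid = y - mu,
         cjj = colSums(X * X), updatable = updatable)
}

#' One full Gibbs scan
#'
#' Updates, in order: the residual variance, the intercept, each SNP's
#' (indicator, effect) pair for j = 1..p ascending, the slab variance, and
#' pi -- honouring any fixed-value hooks in the priors, which are then
#' skipped without consuming random draws.
#'
#' @param state chain state from [newChainState()] or a previous step.
#' @param X dosage matrix, individuals in rows.
#' @param y phenotype vector.
#' @param priors a \linkS4class{BvsPriors}.
#' @return the updated state.
#' @export
gibbsStep <- function(state, X, y, priors) {
    if (!length(priors@fixSigma2Eps))
        state$sigma2Eps <- sampleResidualVariance(state$resid, priors)
    if (!length(priors@fixMu)) {
        n <- length(y)
        # same draw as sampleIntercept(y, X(theta*alpha), s2e): the FCPF
        # mean 1'(y - X(theta*alpha))/n equals mu + mean(resid)
        muNew <- rnorm(1L, state$mu + sum(state$resid) / n,
                       sqrt(state$sigma2Eps / n))
        state$resid <- state$resid - (muNew - state$mu)
        state$mu <- muNew
    }
    for (j in seq_len(ncol(X))) {
        if (!state$updatable[j]) next
        state <- sampleEffectAndIndicator(j, state, X)
    }
    if (!length(priors@fixSigma2Alpha))
        state$sigma2Alpha <- sampleSlabVariance(state$alpha, state$theta,
                                                priors, state$updatable)
    if (!length(priors@fixPi))
        state$pi <- samplePi(state$k, ncol(X), priors)
    state
}
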