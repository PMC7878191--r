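#' Automatic bimodal expression threshold
#'
#' Replaces a manually chosen marker-high versus marker-low cut point with a
#' reproducible procedure: a two-component one-dimensional Gaussian mixture
#' is fitted by EM with deterministic initialization (component means at the
#' 25th and 75th percentiles, equal weights and standard deviations), and
#' the threshold is the point of equal posterior probability between the two
#' components. When the component separation |mu2 - mu1| / pooled sd falls
#' below \code{minSeparation} the distribution is flagged non-bimodal and
#' the threshold should not be used for classification.
#'
#' @param values numeric vector (e.g. log2 expression of one marker across
#'   samples), length >= 10.
#' @param minSeparation minimum separation (in pooled standard deviations)
#'   to call the distribution bimodal; default 1.
#' @param marker optional marker gene id stored in the result.
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-8).
#' @param maxIter maximum EM iterations (default 500).
#' @return A \linkS4class{MarkerThreshold}.
#' @export
bimodalThreshold <- function(values, minSeparation = 1.0,
                             marker = NA_character_, tol = 1e-8,
                             maxIter = 500L) {
    x <- as.numeric(values)
    if (length(x) < 10L)
        stop("need at least 10 values")
    if (any(!is.finite(x)))
        stop("values must be finite")
    mu <- unname(quantile(x, c(0.25, 0.75)))
    if (diff(mu) < 1e-8) mu <- mu + c(-1, 1) * max(sd(x), 1e-6) / 4
    sg <- rep(max(sd(x) / 2, 1e-6), 2L)
    w <- c(0.5, 0.5)
    sdFloor <- max(sd(x) * 1e-4, 1e-12)
    ll <- -Inf
    for (it in seq_len(maxIter)) {
        d1 <- w[1] * dnorm(x, mu[1], sg[1])
        d2 <- w[2] * dnorm(x, mu[2], sg[2])
        tot <- d1 + d2
        tot[tot == 0] <- .Machine$double.xmin
        r <- d1 / tot
        llNew <- sum(log(tot))
        n1 <- sum(r); n2 <- length(x) - n1
        if (n1 < 1e-8 || n2 < 1e-8) break
        mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
        sg <- c(sqrt(sum(r * (x - mu[1])^2) / n1),
                sqrt(sum((1 - r) * (x - mu[2])^2) / n2))
        sg <- pmax(sg, sdFloor)
        w <- c(n1, n2) / length(x)
        if (abs(llNew - ll) < tol) break
        ll <- llNew
    }
    ord <- order(mu)
    mu <- mu[ord]; sg <- sg[ord]; w <- w[ord]
    pooled <- sqrt(w[1] * sg[1]^2 + w[2] * sg[2]^2)
    separation <- abs(diff(mu)) / pooled
    thr <- .equalPosteriorCrossing(mu, sg, w)
    new("MarkerThreshold", marker = as.character(marker), threshold = thr,
        componentMeans = mu, componentSds = sg, weights = w,
        separation = separation, bimodal = separation >= minSeparation)
}

# Solve w1 N(x | mu1, s1) = w2 N(x | mu2, s2) for x between the means;
# falls back to the midpoint if the quadratic has no root in the interval.
.equalPosteriorCrossing <- function(mu, sg, w) {
    A <- 1 / (2 * sg[2]^2) - 1 / (2 * sg[1]^2)
    B <- mu[1] / sg[1]^2 - mu[2] / sg[2]^2
    C <- mu[2]^2 / (2 * sg[2]^2) - mu[1]^2 / (2 * sg[1]^2) -
        log(w[2] / w[1]) - log(sg[1] / sg[2])
    roots <- if (abs(A) < 1e-12) {
        if (abs(B) < 1e-12) numeric(0) else -C / B
    } else {
        disc <- B^2 - 4 * A * C
        if (disc < 0) numeric(0)
        else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    }
    inside <- roots[roots > mu[1] & roots < mu[2]]
    if (length(inside) > 0L) inside[which.min(abs(inside - mean(mu)))]
    else mean(mu)
}

#' Cross-tabulate two label assignments
#'
#' @param labelsA,labelsB named character vectors (sample -> label); only
#'   samples present in both are tabulated.
#' @return list with the contingency \code{table} (rows = labelsA), the
#'   \code{agreement} count (samples with identical labels), and
#'   \code{nShared}.
#' @export
crosstabCompare <- function(labelsA, labelsB) {
    if (is.null(names(labelsA)) || is.null(names(labelsB)))
        stop("label vectors must be named by sample")
    shared <- intersect(names(labelsA), names(labelsB))
    if (length(shared) == 0L)
        stop("no shared samples between the two label sets")
    a <- labelsA[shared]; b <- labelsB[shared]
    list(table = table(a, b), agreement = sum(a == b),
         nShared = length(shared))
}

#' Combine adenoma-component diagnoses into ADC
#'
#' Maps every histological diagnosis with an adenoma component (e.g.
#' adenocarcinoma and adenosquamous carcinoma) to "ADC" and all remaining
#' vocabulary diagnoses to "SCC". A diagnosis absent from the supplied
#' vocabulary is an error.
#'
#' @param histology named character vector, sample -> diagnosis string.
#' @param adenomaTerms diagnoses with an adenoma component (mapped to ADC).
#' @param otherTerms remaining recognized diagnoses (mapped to SCC).
#' @return named character vector of "ADC"/"SCC" labels.
#' @export
combineAdenomaDiagnoses <- function(histology,
        adenomaTerms = c("adenocarcinoma", "adenosquamous carcinoma"),
        otherTerms = c("squamous cell carcinoma")) {
    vocab <- c(adenomaTerms, otherTerms)
    unknown <- setdiff(unique(histology), vocab)
    if (length(unknown) > 0L)
        stop("diagnoses absent from the vocabulary: ",
             paste(unknown, collapse = ", "))
    out <- ifelse(histology %in% adenomaTerms, "ADC", "SCC")
    names(out) <- names(histology)
    out
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed from rank sums with average ranks for ties. The two-sided
#' p-value uses the exact null distribution of U when both feasible
#' (n1 * n2 <= 400) and valid (no ties), and a tie-corrected normal
#' approximation with continuity correction otherwise; \code{mode = "auto"}
#' picks per this rule.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param mode "auto", "exact" or "normal_approx". Requesting "exact" in the
#'   presence of ties is an error.
#' @return list with \code{U} (statistic for group \code{a}), two-sided
#'   \code{p}, and the \code{method} used.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6), mode = "exact")  # p = 0.1
#' @export
mannWhitneyU <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
    mode <- match.arg(mode)
    if (length(a) == 0L || length(b) == 0L)
        stop("both groups must be non-empty")
    n1 <- length(a); n2 <- length(b)
    pooled <- c(a, b)
    r <- rank(pooled)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    hasTies <- anyDuplicated(pooled) > 0L
    if (mode == "exact" && hasTies)
        stop("exact p-value undefined in the presence of ties")
    useExact <- switch(mode,
        exact = TRUE,
        normal_approx = FALSE,
        auto = !hasTies && n1 * n2 <= 400)
    if (useExact) {
        p <- if (U > n1 * n2 / 2)
            pwilcox(U - 1, n1, n2, lower.tail = FALSE)
        else pwilcox(U, n1, n2)
        p <- min(2 * p, 1)
        method <- "exact"
    } else {
        N <- n1 + n2
        ties <- table(pooled)
        sigma2 <- n1 * n2 / 12 *
            ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
        zc <- U - n1 * n2 / 2
        z <- (zc - sign(zc) * 0.5) / sqrt(sigma2)
        p <- min(2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)), 1)
        method <- "normal_approx"
    }
    list(U = U, p = p, method = method)
}
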