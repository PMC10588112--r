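# Composition statistics: the two key differences between transposon traps
# and reference regions — tail fractions of the abundance distribution, and
# Kendall rank correlations between regional and rest-of-genome counts.

#' Pool per-individual regional counts across an ensemble
#'
#' @param ensemble an [InvasionEnsemble-class] (or a plain list of
#'   [ReplicateSummary-class] objects).
#' @param includeExtinct keep replicates that went extinct before sampling
#'   (default \code{FALSE}).
#' @return data.frame with one row per individual per replicate:
#'   \code{replicate}, \code{trap}, \code{reference}, \code{genome}
#'   (diploid counts).
#' @export
regionCounts <- function(ensemble, includeExtinct = FALSE) {
    reps <- if (is(ensemble, "InvasionEnsemble")) replicates(ensemble)
            else ensemble
    out <- do.call(rbind, lapply(reps, function(r) {
        if (!includeExtinct && r@extinct) return(NULL)
        cbind(replicate = r@replicateId, individualCounts(r))
    }))
    if (is.null(out))
        stop("no non-extinct replicates to pool")
    attr(out, "scale") <- "diploid"
    out
}

#' Per-replicate mean haploid counts
#'
#' One observation per replicate (i.e. per TE family): the mean insertion
#' count per haploid genome in traps, reference regions, and the whole
#' genome. Diploid counts are divided by 2.0 to obtain haploid estimates.
#'
#' @inheritParams regionCounts
#' @return data.frame with columns \code{replicate}, \code{trap},
#'   \code{reference}, \code{genome} (haploid scale).
#' @export
replicateMeans <- function(ensemble, includeExtinct = FALSE) {
    cc <- regionCounts(ensemble, includeExtinct = includeExtinct)
    agg <- aggregate(cc[c("trap", "reference", "genome")],
                     by = list(replicate = cc$replicate), FUN = mean)
    agg$trap <- agg$trap / 2
    agg$reference <- agg$reference / 2
    agg$genome <- agg$genome / 2
    agg
}

#' Tail fractions of the regional abundance distribution
#'
#' Fraction of individuals with fewer than \code{low} and more than
#' \code{high} insertions in the chosen region (strict inequalities).
#' Under the trap model very few individuals carry fewer than 1 or more
#' than 14 trap insertions, whereas the reference-region distribution is
#' much broader.
#'
#' @param counts data.frame from [regionCounts()], or any data.frame with
#'   the region column.
#' @param region \code{"trap"} or \code{"reference"} (any column name
#'   works).
#' @param low,high count thresholds (defaults 1 and 14).
#' @return list with \code{frac_below}, \code{frac_above}, \code{low},
#'   \code{high}, \code{n}, \code{region}.
#' @export
tailFractions <- function(counts, region = c("trap", "reference"),
                          low = 1, high = 14) {
    region <- region[1]
    x <- counts[[region]]
    if (is.null(x) || length(x) == 0L) stop("no counts for region ", region)
    list(frac_below = mean(x < low), frac_above = mean(x > high),
         low = low, high = high, n = length(x), region = region)
}

#' Kendall rank correlation (tau-b) with a two-sided p-value
#'
#' Tie-corrected Kendall tau; exact p-value for very small samples and a
#' normal approximation otherwise. Constant input vectors leave tau
#' undefined and are flagged rather than raising an error.
#'
#' @param x,y numeric vectors of equal length \code{>= 3}.
#' @return list with \code{tau}, \code{p}, \code{n}, \code{undefined}.
#' @examples
#' kendallTau(1:5, c(2, 1, 4, 3, 5))
#' @export
kendallTau <- function(x, y) {
    stopifnot(length(x) == length(y))
    if (length(x) < 3L) stop("need at least 3 observations")
    if (length(unique(x)) == 1L || length(unique(y)) == 1L)
        return(list(tau = NA_real_, p = NA_real_, n = length(x),
                    undefined = TRUE))
    ct <- suppressWarnings(
        cor.test(x, y, method = "kendall", exact = length(x) < 10L))
    list(tau = unname(ct$estimate), p = ct$p.value, n = length(x),
         undefined = FALSE)
}

#' @rdname correlationReport
#' @param includeExtinct keep extinct replicates (ensemble input).
#' @export
setMethod("correlationReport", "InvasionEnsemble",
    function(x, region = c("trap", "reference"), includeExtinct = FALSE) {
        region <- match.arg(region)
        rm <- replicateMeans(x, includeExtinct = includeExtinct)
        rest <- rm$genome - rm[[region]]
        out <- kendallTau(rm[[region]], rest)
        out$region <- region
        out
    })

#' @rdname correlationReport
#' @export
setMethod("correlationReport", "data.frame", function(x, ...) {
    stopifnot(all(c("cluster_count", "noncluster_count") %in% names(x)))
    out <- kendallTau(x$cluster_count, x$noncluster_count)
    out$region <- "cluster"
    out
})

#' Abundance histogram of per-haploid counts
#'
#' Bins a vector of (per-haploid) insertion counts; bin masses always sum
#' to 1. Truncation of the x-axis is a display concern and is applied only
#' when writing (see [writeHistogram()]).
#'
#' @param x numeric vector of counts (e.g. \code{replicateMeans(ens)$trap},
#'   or per-individual diploid counts divided by 2).
#' @param binWidth bin width in insertions (default 1).
#' @return data.frame with columns \code{bin} (left edge) and \code{mass}.
#' @export
abundanceHistogram <- function(x, binWidth = 1) {
    stopifnot(binWidth > 0, length(x) > 0L)
    b <- floor(x / binWidth) * binWidth
    tb <- table(b)
    data.frame(bin = as.numeric(names(tb)),
               mass = as.numeric(tb) / length(x))
}

#' Empirical central band of a histogram's underlying values
#'
#' The \code{[alpha/2, 1 - alpha/2]} quantile band; with the default
#' \code{alpha = 0.02} at least 98\% of the values fall inside.
#'
#' @param x numeric vector of counts.
#' @param alpha total tail mass outside the band.
#' @return numeric length-2 vector (lower, upper).
#' @export
abundanceBand <- function(x, alpha = 0.02) {
    unname(stats::quantile(x, c(alpha / 2, 1 - alpha / 2)))
}
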