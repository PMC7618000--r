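# Exact inference on a 2x2 carrier table, conditional on both margins.
#
# Written in-house (rather than delegating to stats::fisher.test) so the
# conditional-MLE and interval roots can be solved to near machine precision;
# stats::fisher.test serves as an independent cross-check in the test suite.

#' Build the sex-by-carrier contingency table
#'
#' @param flags Named logical vector of carrier flags (names are sample ids),
#'   as returned by \code{\link{carrier_flags}}.
#' @param samples Sample sheet containing every flagged sample.
#' @return A 2x2 integer matrix, rows \code{female}/\code{male}, columns
#'   \code{carrier}/\code{noncarrier}.
#' @export
build_table <- function(flags, samples) {
  stopifnot(is.logical(flags), !is.null(names(flags)))
  miss <- setdiff(names(flags), samples$sample_id)
  if (length(miss)) {
    stop("flagged samples absent from sample sheet: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  carrier <- stats::setNames(rep(FALSE, nrow(samples)), samples$sample_id)
  carrier[names(flags)] <- flags
  f <- samples$sex == "female"
  matrix(c(sum(carrier[samples$sample_id[f]]), sum(f) - sum(carrier[samples$sample_id[f]]),
           sum(carrier[samples$sample_id[!f]]), sum(!f) - sum(carrier[samples$sample_id[!f]])),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("female", "male"), c("carrier", "noncarrier")))
}

#' Exact conditional test on a 2x2 table
#'
#' Conditional on both margins, the first cell follows a (noncentral)
#' hypergeometric distribution with odds ratio \eqn{\psi}. Reported are the
#' two-sided exact p-value (the sum of the probabilities of all tables, under
#' \eqn{\psi = 1}, no more probable than the observed one), the conditional
#' maximum-likelihood estimate of \eqn{\psi}, and the central exact
#' conditional confidence interval (each tail at \eqn{\alpha/2}). A cell
#' count at the edge of its conditional support yields a one-sided interval
#' (lower bound 0 or upper bound \code{Inf}).
#'
#' With rows female/male and columns carrier/non-carrier, an odds ratio
#' above 1 means carrier enrichment in females.
#'
#' @param x 2x2 matrix of counts, or a length-4 vector \code{(a, b, c, d)}
#'   read row-wise.
#' @param conf_level Confidence level for the interval.
#' @param conf_int Compute the interval? Setting \code{FALSE} skips the two
#'   interval root-solves (used in large calibration scans).
#' @return List with \code{p}, \code{or_cmle}, \code{ci95} = c(lower, upper).
#' @examples
#' fisher_exact(c(20, 254, 14, 542))  # OR ~ 3.04, p ~ 0.0023
#' @export
fisher_exact <- function(x, conf_level = 0.95, conf_int = TRUE) {
  x <- as_table2x2(x)
  a <- x[1L, 1L]
  r1 <- sum(x[1L, ]); r2 <- sum(x[2L, ])
  c1 <- sum(x[, 1L]); c2 <- sum(x[, 2L])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    stop("untestable table: an entire margin is zero")
  }
  lo <- max(0, r1 - c2)
  hi <- min(r1, c1)
  support <- lo:hi
  logdc <- stats::dhyper(support, c1, c2, r1, log = TRUE)
  dc <- exp(logdc - max(logdc))
  dc <- dc / sum(dc)
  pobs <- dc[a - lo + 1L]
  p <- sum(dc[dc <= pobs * (1 + 1e-7)])
  p <- min(p, 1)

  or_cmle <- cond_mle(a, support, logdc)
  ci <- c(NA_real_, NA_real_)
  if (conf_int) {
    alpha <- (1 - conf_level) / 2
    ci <- c(cond_ci_lower(a, support, logdc, alpha),
            cond_ci_upper(a, support, logdc, alpha))
  }
  list(p = p, or_cmle = or_cmle, ci95 = ci)
}

#' Sample (cross-product) odds ratio
#'
#' The unconditional estimate \code{a*d / (b*c)}, reported alongside the
#' conditional MLE for transparency; \code{Inf} when a zero cell makes it
#' undefined.
#'
#' @inheritParams fisher_exact
#' @return A single number, possibly \code{Inf}.
#' @export
sample_or <- function(x) {
  x <- as_table2x2(x)
  if (x[1L, 2L] * x[2L, 1L] == 0) return(Inf)
  (x[1L, 1L] * x[2L, 2L]) / (x[1L, 2L] * x[2L, 1L])
}

as_table2x2 <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2L, 2L)))
  } else {
    stopifnot(length(x) == 4L)
    x <- matrix(x, nrow = 2L, byrow = TRUE)
  }
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("table cells must be non-negative integers")
  }
  x
}

# Mean of the noncentral hypergeometric at log-odds lpsi, computed stably.
nchg_mean <- function(lpsi, support, logdc) {
  lw <- logdc + support * lpsi
  w <- exp(lw - max(lw))
  sum(support * w) / sum(w)
}

# P(X >= a) and P(X <= a) under odds ratio exp(lpsi).
nchg_tail <- function(lpsi, support, logdc, a, upper) {
  lw <- logdc + support * lpsi
  w <- exp(lw - max(lw))
  if (upper) sum(w[support >= a]) / sum(w) else sum(w[support <= a]) / sum(w)
}

# Root bracketing on the log-odds scale: expand symmetrically until the
# objective changes sign, then refine with uniroot at tight tolerance.
solve_logpsi <- function(f) {
  lo <- -1; hi <- 1
  flo <- f(lo); fhi <- f(hi)
  while (flo * fhi > 0 && hi < 745) {
    lo <- lo * 2; hi <- hi * 2
    flo <- f(lo); fhi <- f(hi)
  }
  if (flo * fhi > 0) stop("failed to bracket root on log-odds scale")
  stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                 tol = 1e-12, maxiter = 2000L)$root
}

cond_mle <- function(a, support, logdc) {
  if (a == support[1L]) return(0)
  if (a == support[length(support)]) return(Inf)
  exp(solve_logpsi(function(l) nchg_mean(l, support, logdc) - a))
}

cond_ci_lower <- function(a, support, logdc, alpha) {
  if (a == support[1L]) return(0)
  exp(solve_logpsi(function(l) nchg_tail(l, support, logdc, a, TRUE) - alpha))
}

cond_ci_upper <- function(a, support, logdc, alpha) {
  if (a == support[length(support)]) return(Inf)
  exp(solve_logpsi(function(l) nchg_tail(l, support, logdc, a, FALSE) - alpha))
}
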