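#' Two-way ANOVA with interaction (Type II sums of squares)
#'
#' Fits \code{response ~ A * B} by least squares and reports Type II F
#' tests for both main effects and the interaction, which remain
#' meaningful for unbalanced cohorts. A constant response is reported
#' as F = 0, p = 1 for every term.
#'
#' @param formula a formula of the form \code{y ~ A * B} with two
#'   categorical factors.
#' @param data data frame containing the variables.
#' @return Data frame with columns \code{term}, \code{df}, \code{F},
#'   \code{p} (one row per main effect and the interaction).
#' @examples
#' d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
#' d$y <- rnorm(nrow(d))
#' two_way_anova(y ~ A * B, d)
#' @export
two_way_anova <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  terms_lbl <- attr(stats::terms(formula), "term.labels")
  if (length(terms_lbl) != 3L)
    stop("`formula` must be of the form y ~ A * B")
  if (stats::var(y) == 0 || !is.finite(stats::var(y)))
    return(data.frame(term = terms_lbl,
                      df = NA_real_, F = 0, p = 1))
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design: some factor cells are empty")
  if (stats::df.residual(fit) < 1)
    stop("no residual degrees of freedom")
  if (stats::deviance(fit) < .Machine$double.eps * sum(y^2) + 1e-300) {
    # saturated noiseless fit: F undefined; treat cell-exact data as F=0,p=1
    return(data.frame(term = terms_lbl, df = NA_real_, F = 0, p = 1))
  }
  tab <- car::Anova(fit, type = 2)
  rows <- match(terms_lbl, rownames(tab))
  data.frame(term = terms_lbl,
             df = tab$Df[rows],
             F = tab$`F value`[rows],
             p = tab$`Pr(>F)`[rows])
}

#' Sidak multiplicity adjustment
#'
#' \code{p_adj = 1 - (1 - p)^m}, capped at 1. The family size defaults
#' to the number of p-values (the number of distance bins tested in an
#' analysis).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param m family size, at least \code{length(p)}.
#' @return Adjusted p-values, same length and order.
#' @examples
#' sidak_adjust(0.01, m = 15)  # 0.1399
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("`m` must be at least length(p)")
  pmin(1, 1 - (1 - p)^m)
}

#' Unpaired two-tailed Student's t-test
#'
#' Classic pooled-variance two-sample t-test.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @return List with \code{t}, \code{df} and two-tailed \code{p}.
#' @examples
#' unpaired_t(c(1, 2, 3), c(4, 5, 6))  # |t| = 3.674
#' @export
unpaired_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(a) + stats::var(b) == 0)
    stop("pooled variance is zero")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
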