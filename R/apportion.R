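#' @include AllClasses.R domain.R
NULL

## Bias quantification: population-weighted daily deltas between the raw CTM
## field and each fused scenario, apportioned to the input components by
## ordinary least squares.

#' Daily population-weighted bias series
#'
#' For the chosen scope, computes for every day the population-weighted
#' deltas \deqn{\Delta C_{Total} = pw(C_{CMAQ}) - pw(C_{S1})} and, per
#' component k, \eqn{\Delta C_k = pw(C_{CMAQ}) - pw(C_{Sk})} (EM vs S2, BC vs
#' S3, MT vs S4, LU vs S5). Positive values mean the CTM overestimates
#' relative to the fused reference.
#'
#' @param sc a \linkS4class{ScenarioConcentrations} with all five fused
#'   fields.
#' @param pop a \linkS4class{PopulationGrid}.
#' @param scope region name or \code{"all"}.
#' @return data.frame of class \code{"biasSeries"} with columns \code{day},
#'   \code{dTotal}, \code{dEM}, \code{dBC}, \code{dMT}, \code{dLU};
#'   attribute \code{"scope"}.
#' @export
buildBiasSeries <- function(sc, pop, scope = "all") {
  need <- c("S1", "S2", "S3", "S4", "S5")
  if (!all(need %in% names(sc@fused)))
    stop("bias apportionment needs fused fields ",
         paste(setdiff(need, names(sc@fused)), collapse = ", "))
  days <- sc@cmaq@days
  pw <- function(field) vapply(seq_along(days), function(j)
    populationWeightedMean(field, pop, region = scope, day = days[j]),
    numeric(1))
  base <- pw(sc@cmaq)
  out <- data.frame(day = days,
                    dTotal = base - pw(sc@fused$S1),
                    dEM = base - pw(sc@fused$S2),
                    dBC = base - pw(sc@fused$S3),
                    dMT = base - pw(sc@fused$S4),
                    dLU = base - pw(sc@fused$S5))
  attr(out, "scope") <- scope
  class(out) <- c("biasSeries", "data.frame")
  out
}

#' Apportion total CTM bias to its input components
#'
#' Ordinary least squares of the daily total bias on the four component
#' deltas with an intercept:
#' \deqn{\Delta C_{Total} = \beta_0 + \beta_1 \Delta C_{EM} +
#'   \beta_2 \Delta C_{BC} + \beta_3 \Delta C_{MT} + \beta_4 \Delta C_{LU} +
#'   \varepsilon}
#' The residuals \eqn{\varepsilon}, together with \eqn{\beta_0}, represent
#' bias from unidentified factors. Each component's contribution is reported
#' as \eqn{\beta_k \cdot \overline{\Delta C_k}} (concentration units); shares
#' are the absolute contributions normalized by their sum plus
#' \eqn{|\beta_0|}.
#'
#' @param bs a bias series from \code{\link{buildBiasSeries}} (>= 10 days).
#' @return List of class \code{"apportionmentFit"}: \code{coefficients}
#'   (beta0..beta4), \code{contributions} and \code{shares} (per component),
#'   \code{residuals}, \code{fitted}, \code{r2}, \code{se},
#'   \code{conditionNumber}, and the underlying \code{lm} fit.
#' @export
apportion <- function(bs) {
  if (nrow(bs) < 10L) stop("apportionment needs at least 10 days")
  X <- as.matrix(bs[, c("dEM", "dBC", "dMT", "dLU")])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < 5L) {
    const <- colnames(X)[apply(X, 2, sd) == 0]
    if (length(const))
      stop("component deltas are rank deficient: ",
           paste(const, collapse = ", "), " constant over days")
    cm <- abs(cor(X))
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "component deltas are collinear (rank %d < 5); worst pair %s / %s (|r| = %.4f)",
      qrX$rank, colnames(X)[worst[1]], colnames(X)[worst[2]], max(cm)))
  }
  fit <- lm(dTotal ~ dEM + dBC + dMT + dLU, data = bs)
  beta <- coef(fit)
  contrib <- beta[-1] * colMeans(X)
  names(contrib) <- c("em", "bc", "mt", "lu")
  denom <- sum(abs(contrib)) + abs(beta[1])
  # R^2 and coefficient standard errors computed directly: perfect fits are a
  # legitimate input here (oracle scenarios), and summary.lm warns on them
  rss <- sum(residuals(fit)^2)
  tss <- sum((bs$dTotal - mean(bs$dTotal))^2)
  sigma2 <- rss / (nrow(bs) - 5L)
  se <- sqrt(diag(sigma2 * solve(crossprod(cbind(1, X)))))
  names(se) <- names(beta)
  structure(list(
    coefficients = beta,
    contributions = contrib,
    shares = abs(contrib) / denom,
    unidentified = unname(beta[1]),
    residuals = residuals(fit),
    fitted = fitted(fit),
    r2 = 1 - rss / tss,
    se = se,
    conditionNumber = kappa(scale(X), exact = TRUE),
    lm = fit, scope = attr(bs, "scope")), class = "apportionmentFit")
}

#' @export
print.apportionmentFit <- function(x, ...) {
  cat(sprintf("apportionmentFit (scope %s): R2 = %.3f, kappa = %.1f\n",
              x$scope, x$r2, x$conditionNumber))
  cat("  contributions:",
      paste(sprintf("%s %.3f (%.0f%%)", names(x$contributions),
                    x$contributions, 100 * x$shares), collapse = ", "), "\n")
  cat(sprintf("  unidentified (beta0): %.3f\n", x$unidentified))
  invisible(x)
}

#' Per-cell mean bias maps
#'
#' Time-mean of \eqn{C_{CMAQ} - C_{Sk}} per cell: the total map (vs S1) and
#' one map per component (vs S2..S5), the latter optionally scaled by the
#' fitted apportionment slopes.
#'
#' @param sc a \linkS4class{ScenarioConcentrations}.
#' @param fit optional \code{"apportionmentFit"} whose slopes scale the
#'   component maps.
#' @return Named list of per-cell numeric vectors: \code{total}, \code{em},
#'   \code{bc}, \code{mt}, \code{lu}.
#' @export
biasMap <- function(sc, fit = NULL) {
  keys <- c(total = "S1", em = "S2", bc = "S3", mt = "S4", lu = "S5")
  maps <- lapply(keys, function(s)
    rowMeans(sc@cmaq@values - sc@fused[[s]]@values, na.rm = TRUE))
  if (!is.null(fit)) {
    b <- fit$coefficients[-1]
    for (i in 1:4) maps[[i + 1L]] <- maps[[i + 1L]] * b[i]
  }
  maps
}
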