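#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact null enumeration (via the exact rank-sum distribution) when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with midranks and tie-corrected variance.  The U
#' statistic is the number of (a, b) pairs with `a > b`, counting ties as
#' half.
#'
#' @param a,b Non-empty numeric samples.
#' @param exact_max Largest combined sample size for the exact branch
#'   (default 20).
#' @return List: `U`, `p` (two-sided), `method` ("exact" or "approximate").
#' @examples
#' mann_whitney(1:4, 5:8)$p   # 0.02857... = 2/choose(8, 4)
#' @export
mann_whitney <- function(a, b, exact_max = 20) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA")
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2   # pairs with a > b, ties half
  ties <- any(duplicated(c(a, b)))
  if (!ties && (m + n) <= exact_max) {
    # exact two-sided p: double the smaller tail of the null U distribution
    p <- if (U > m * n / 2) 2 * (1 - stats::pwilcox(U - 1, m, n))
         else 2 * stats::pwilcox(U, m, n)
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- m * n / 2
    tab <- table(r)
    tie_term <- sum(tab^3 - tab) / ((m + n) * (m + n - 1))
    sigma2 <- m * n / 12 * ((m + n + 1) - tie_term)
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)  # continuity corrected
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "approximate"
  }
  list(U = U, p = p, method = method)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment: with `m` p-values sorted ascending, the adjusted
#' value at rank `i` is `min over j >= i of min(1, m p_(j) / j)`, returned
#' in the original input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values, same length and order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdr_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
    out[ok] <- adj
  }
  out
}

#' Per-age, per-feature group comparison table
#'
#' For every (feature, age) cell with both regions present, tests whether
#' the HPC and CTX array values differ (two-sided Mann-Whitney), then
#' adjusts all p-values for multiple comparisons with the
#' Benjamini-Hochberg procedure.  By default the correction family pools
#' every feature x age test (the conservative reading); `family =
#' "per_feature"` corrects across ages within each feature instead.
#' Stars: `*` for adjusted p below 0.05, `**` below 0.01.
#'
#' @param features Tidy feature table from [features_table()] (columns: the
#'   11 features, `region`, `age_div`).
#' @param family `"pooled"` (default) or `"per_feature"`.
#' @param alpha Significance levels for the stars (length 2).
#' @return Data frame: `feature`, `age_div`, `n_ctx`, `n_hpc`, `U`,
#'   `p_raw`, `p_adjusted`, `significance`.  Cells with a missing group or
#'   fewer than 2 defined values per group carry `NA` test fields.
#' @export
comparison_table <- function(features, family = c("pooled", "per_feature"),
                             alpha = c(0.05, 0.01)) {
  family <- match.arg(family)
  feats <- intersect(feature_names(), names(features))
  ages <- sort(unique(features$age_div))
  rows <- list()
  for (f in feats) for (a in ages) {
    x <- features[features$age_div == a, ]
    ctx <- x[[f]][x$region == "CTX"]
    hpc <- x[[f]][x$region == "HPC"]
    ctx <- ctx[!is.na(ctx)]; hpc <- hpc[!is.na(hpc)]
    if (length(ctx) >= 2 && length(hpc) >= 2) {
      mw <- mann_whitney(ctx, hpc)
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, age_div = a, n_ctx = length(ctx), n_hpc = length(hpc),
        U = mw$U, p_raw = mw$p, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, age_div = a, n_ctx = length(ctx), n_hpc = length(hpc),
        U = NA_real_, p_raw = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (family == "pooled") fdr_adjust(out$p_raw)
  else stats::ave(out$p_raw, out$feature, FUN = fdr_adjust)
  out$significance <- ifelse(is.na(out$p_adjusted), NA_character_,
                      ifelse(out$p_adjusted < alpha[2], "**",
                      ifelse(out$p_adjusted < alpha[1], "*", "ns")))
  out
}
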