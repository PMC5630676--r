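# Differential hydroxymethylation statistics: Welch t, empirical-Bayes
# moderated t (two-group, no covariates/weights/trend), Benjamini-Hochberg
# adjustment, and threshold-based differential gene selection.

#' Welch two-sample t-test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom and a
#' two-tailed p-value. Degenerate inputs are handled explicitly: zero
#' variance in both groups with equal means gives `t = 0, p = 1`; zero
#' variance with unequal means gives `p = 0` and is flagged via the
#' `degenerate` field.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = na + nb - 2, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = na + nb - 2, p = 0,
                degenerate = TRUE))
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df), degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-down BH: `q_(i) = min_(j >= i) p_(j) * n / j`, capped at 1 and
#' returned in input order (delegates to [stats::p.adjust()]).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  p.adjust(pvals, method = "BH")
}

# Vectorized per-row two-group t statistics on a feature matrix.
# kind = "student" uses pooled variance (feature selection), "welch" unequal
# variances (cohort contrasts).
row_t <- function(mat, in_a, in_b, kind = c("student", "welch")) {
  kind <- match.arg(kind)
  na <- sum(in_a); nb <- sum(in_b)
  stopifnot(na >= 2, nb >= 2)
  A <- mat[, in_a, drop = FALSE]; B <- mat[, in_b, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  if (kind == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(mat))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    df[!is.finite(df)] <- na + nb - 2
  }
  t <- (ma - mb) / se
  t[se == 0 & ma == mb] <- 0
  p <- 2 * pt(-abs(t), df)
  p[se == 0 & ma == mb] <- 1
  p[se == 0 & ma != mb] <- 0
  list(t = t, df = df, p = p, mean_a = ma, mean_b = mb, var_a = va,
       var_b = vb)
}

# Newton inversion of the trigamma function (used by the empirical-Bayes
# variance moment matching); monotone decreasing, so the iteration is safe.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated t-statistics for a two-group contrast
#'
#' Per-feature residual variances `s_g^2` (with `d_g = n_A + n_B - 2` df) are
#' shrunk toward a common prior: the prior df `d_0` and prior variance
#' `s_0^2` are estimated by closed-form moment matching on `log s_g^2` using
#' digamma/trigamma relations, the posterior variance is
#' `(d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)`, and the moderated t is referred
#' to a t distribution with `d_0 + d_g` df. Log2 fold change is computed on
#' group means with a small offset (`log2((mean_B + eps)/(mean_A + eps))`).
#'
#' @param mat Features x samples numeric matrix (>= 50 features recommended
#'   for stable hyperparameter estimation).
#' @param labels Vector of two group labels, one per column; the first level
#'   (or `ref`) is group A and the fold change is B relative to A.
#' @param ref Optional reference (group A) label.
#' @param eps Fold-change offset on the FPKM scale (default 0.1).
#' @param d0_override Force the prior df (0 recovers the ordinary pooled-t;
#'   `Inf` fully shrinks every variance to `s_0^2`).
#' @return A `diff_result` data frame: feature, mean_a, mean_b, log2fc, t,
#'   df, p, q; attributes `d0` and `s02`.
#' @export
moderated_t <- function(mat, labels, ref = NULL, eps = 0.1,
                        d0_override = NULL) {
  groups <- unique(as.character(labels))
  stopifnot(length(groups) == 2)
  if (!is.null(ref)) groups <- c(ref, setdiff(groups, ref))
  in_a <- labels == groups[1]; in_b <- labels == groups[2]
  na <- sum(in_a); nb <- sum(in_b)
  if (na < 2 || nb < 2) stop("need at least 2 samples per group")
  rt <- row_t(mat, in_a, in_b, kind = "student")
  dg <- na + nb - 2
  s2 <- ((na - 1) * rt$var_a + (nb - 1) * rt$var_b) / dg
  pos <- s2 > 0
  if (!is.null(d0_override)) {
    d0 <- d0_override
    s02 <- if (is.finite(d0) && d0 == 0) 0 else exp(mean(log(s2[pos])))
  } else {
    z <- log(s2[pos])
    e <- z - digamma(dg / 2) + log(dg / 2)
    ebar <- mean(e)
    rhs <- mean((e - ebar)^2 * length(e) / (length(e) - 1) -
                  trigamma(dg / 2))
    if (rhs > 0) {
      d0 <- 2 * trigamma_inverse(rhs)
      s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(ebar)
    }
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + dg * s2) / (d0 + dg)
  # variance floor for features that are identically zero everywhere
  s2_post[s2_post <= 0] <- max(min(s2_post[s2_post > 0], na.rm = TRUE) * 1e-6,
                               .Machine$double.eps)
  tmod <- (rt$mean_b - rt$mean_a) / sqrt(s2_post * (1 / na + 1 / nb))
  df_tot <- d0 + dg
  p <- if (is.infinite(df_tot)) 2 * pnorm(-abs(tmod)) else
    2 * pt(-abs(tmod), df_tot)
  res <- data.frame(feature = rownames(mat) %||% seq_len(nrow(mat)),
                    mean_a = rt$mean_a, mean_b = rt$mean_b,
                    log2fc = .safe_log2fc(rt$mean_a, rt$mean_b, eps),
                    t = tmod, df = df_tot, p = p, q = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("diff_result", "data.frame"), d0 = d0, s02 = s02,
            test_kind = "moderated", groups = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log2 fold change on offset means; finite for non-negative (FPKM-scale)
# inputs, NA where a negative-valued matrix makes the ratio non-positive
.safe_log2fc <- function(mean_a, mean_b, eps) {
  ratio <- (mean_b + eps) / (mean_a + eps)
  ifelse(ratio > 0, log2(pmax(ratio, .Machine$double.xmin)), NA_real_)
}

#' Welch-t differential table for a two-group contrast
#'
#' Row-wise Welch t on a feature matrix with BH adjustment; same output
#' contract as [moderated_t()].
#' @inheritParams moderated_t
#' @return A `diff_result` data frame.
#' @export
welch_diff <- function(mat, labels, ref = NULL, eps = 0.1) {
  groups <- unique(as.character(labels))
  stopifnot(length(groups) == 2)
  if (!is.null(ref)) groups <- c(ref, setdiff(groups, ref))
  in_a <- labels == groups[1]; in_b <- labels == groups[2]
  rt <- row_t(mat, in_a, in_b, kind = "welch")
  res <- data.frame(feature = rownames(mat) %||% seq_len(nrow(mat)),
                    mean_a = rt$mean_a, mean_b = rt$mean_b,
                    log2fc = .safe_log2fc(rt$mean_a, rt$mean_b, eps),
                    t = -rt$t, df = rt$df, p = rt$p, q = bh_adjust(rt$p),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("diff_result", "data.frame"),
            test_kind = "welch", groups = groups)
}

#' Select differential features by q-value and fold-change thresholds
#'
#' Keeps features with `q < q_max` and `max(FC, 1/FC) > fc_min` (fold change
#' `FC = 2^log2fc`), split into enriched (`log2fc > 0`) and depleted.
#'
#' @param res A `diff_result` from [moderated_t()] or [welch_diff()].
#' @param q_max,fc_min Selection thresholds (e.g. 0.01 and 2; a threshold of
#'   1.41 corresponds to |log2FC| > 0.5).
#' @return List with `selected` data frame (adds a `call` column with
#'   `enriched`/`depleted`), and `enriched`/`depleted` feature id vectors.
#' @export
select_differential <- function(res, q_max, fc_min) {
  fc <- 2^res$log2fc
  sel <- res$q < q_max & pmax(fc, 1 / fc) > fc_min
  sel[is.na(sel)] <- FALSE
  out <- res[sel, , drop = FALSE]
  out$call <- ifelse(out$log2fc > 0, "enriched", "depleted")
  list(selected = out,
       enriched = out$feature[out$call == "enriched"],
       depleted = out$feature[out$call == "depleted"])
}
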