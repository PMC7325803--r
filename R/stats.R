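# Inferential layer: restricted sign-flip permutation t-test, ICC/CoV
# reliability matrices, 2x2 repeated-measures ANOVA, paired motion t-tests.

#' One-tailed paired t statistic on hemisphere-wise differences
#'
#' `t = mean(d) / (sd(d) / sqrt(H))` on the differences
#' `d = retinotopic - nonretinotopic` (sample SD, H-1 denominator). Because
#' retinotopic and non-retinotopic strength come from the same hemisphere
#' (and, in percent units, are complementary), a paired one-sample t on the
#' differences is the valid form of the "one-tailed t-test over hemispheres".
#' Zero-variance differences yield a signed-infinity sentinel (0 when the
#' differences are identically zero) rather than an error, so the exhaustive
#' permutation enumeration can compare them by value.
#'
#' @param retinotopic per-hemisphere retinotopic strengths, or, if
#'   `nonretinotopic` is NULL, the differences themselves.
#' @param nonretinotopic per-hemisphere non-retinotopic strengths.
#' @return t statistic (possibly +/-Inf).
#' @export
paired_one_tailed_t <- function(retinotopic, nonretinotopic = NULL) {
  d <- if (is.null(nonretinotopic)) retinotopic else retinotopic - nonretinotopic
  h <- length(d)
  if (h < 2) stopf("need at least two hemispheres")
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) return(if (m == 0) 0 else sign(m) * Inf)
  m / (s / sqrt(h))
}

#' Restricted (within-hemisphere) sign-flip permutation t-test
#'
#' Exhaustively enumerates all `2^H` assignments that keep or swap the
#' retinotopic / non-retinotopic strengths within each hemisphere (swapping
#' across hemispheres is not allowed, so total connectivity per hemisphere is
#' preserved), computes the one-tailed paired t for each, and reports the
#' one-tailed p-value as the proportion of permutation t values that exceed
#' or equal the observed t. The identity assignment is included, so
#' `p >= 1/2^H`; for six hemispheres the null distribution has exactly 64
#' members.
#'
#' @param retinotopic,nonretinotopic per-hemisphere strength vectors
#'   (consistent units; typically mean per-cell percent strengths from
#'   [partition_connectivity()]).
#' @return object of class `permutation_test`: `t_obs`, `t_perm` (length
#'   `2^H`), `p`, `H`.
#' @export
restricted_permutation_test <- function(retinotopic, nonretinotopic) {
  if (length(retinotopic) != length(nonretinotopic))
    stopf("retinotopic and nonretinotopic must pair up per hemisphere")
  h <- length(retinotopic)
  if (h < 2) stopf("need at least two hemispheres")
  if (h > 20) stopf("exhaustive enumeration supports at most 20 hemispheres")
  d <- retinotopic - nonretinotopic
  if (all(d == 0) && all(retinotopic == 0)) stopf("degenerate all-zero data")

  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), h)))  # 2^H x H
  m <- drop(signs %*% d) / h
  ss <- sum(d^2)                       # invariant under sign flips
  v <- (ss - h * m^2) / (h - 1)
  v[v < 0] <- 0                        # guard rounding
  t_perm <- ifelse(v == 0, ifelse(m == 0, 0, sign(m) * Inf), m / sqrt(v / h))
  id_row <- which(rowSums(signs == 1) == h)
  t_obs <- t_perm[id_row]
  p <- mean(t_perm >= t_obs)
  structure(list(t_obs = t_obs, t_perm = t_perm, p = p, H = h),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("restricted permutation test: H = %d, %d assignments, t = %.3f, p = %.4f\n",
              x$H, length(x$t_perm), x$t_obs, x$p))
  invisible(x)
}

# ICC(2,1): two-way random effects, single measure, absolute agreement,
# for an n x k matrix (rows = subjects/hemispheres, cols = raters/measurements).
icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  sst <- sum((x - grand)^2)
  mse <- (sst - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(denom) < 1e-14) return(NA_real_)
  (msr - mse) / denom
}

as_cell_array <- function(meas) {
  if (is.array(meas) && length(dim(meas)) == 3L) return(meas)
  if (is.list(meas)) {
    ms <- lapply(meas, function(m) if (inherits(m, "connectivity_matrix")) m$percent else as.matrix(m))
    return(simplify2array(ms))
  }
  stopf("expected a 6x6xH array or a list of 6x6 matrices")
}

#' Element-wise intraclass correlation between two measurement stacks
#'
#' Per matrix cell, the ICC across hemispheres between measurements A and B.
#' The variant is two-way random effects, single measure, absolute agreement
#' (ICC(2,1)); cells with no between-hemisphere variance are undefined (NA).
#'
#' @param measA,measB 6x6xH arrays (or lists of H matrices): the same
#'   quantity measured twice per hemisphere, e.g. scan-rescan or two coils.
#' @return object of class `reliability_matrix`: `icc` (6x6), `summary`
#'   (mean/sd over all, diagonal and off-diagonal cells), `variant`.
#' @export
icc_matrix <- function(measA, measB) {
  a <- as_cell_array(measA); b <- as_cell_array(measB)
  if (!all(dim(a) == dim(b))) stopf("measurement stacks must agree in shape")
  if (dim(a)[3] < 3) stopf("need at least three hemispheres")
  icc <- matrix(NA_real_, dim(a)[1], dim(a)[2], dimnames = dimnames(a)[1:2])
  for (i in seq_len(nrow(icc))) for (j in seq_len(ncol(icc)))
    icc[i, j] <- icc21(cbind(a[i, j, ], b[i, j, ]))
  structure(list(icc = icc, summary = cell_summary(icc), variant = "ICC(2,1)"),
            class = "reliability_matrix")
}

cell_summary <- function(m) {
  offd <- m[row(m) != col(m)]
  data.frame(
    cells = c("all", "retinotopic", "nonretinotopic"),
    mean = c(mean(m, na.rm = TRUE), mean(diag(m), na.rm = TRUE), mean(offd, na.rm = TRUE)),
    sd = c(stats::sd(m[!is.na(m)]), stats::sd(diag(m)[!is.na(diag(m))]),
           stats::sd(offd[!is.na(offd)]))
  )
}

#' Element-wise coefficient of variation between two measurement stacks
#'
#' Default (`"within_pair"`): per hemisphere and cell, the sample SD of the
#' two measurements divided by their mean, averaged over hemispheres.
#' Alternative (`"across_hemispheres"`): per cell, SD/mean across the H
#' hemisphere values, averaged over the two measurements. Cells touching a
#' zero mean are undefined.
#'
#' @inheritParams icc_matrix
#' @param method aggregation scheme (see Details).
#' @return object of class `reliability_matrix`: `cov` (6x6), `summary`,
#'   `method`.
#' @export
cov_matrix <- function(measA, measB, method = c("within_pair", "across_hemispheres")) {
  method <- match.arg(method)
  a <- as_cell_array(measA); b <- as_cell_array(measB)
  if (!all(dim(a) == dim(b))) stopf("measurement stacks must agree in shape")
  cv <- matrix(NA_real_, dim(a)[1], dim(a)[2], dimnames = dimnames(a)[1:2])
  for (i in seq_len(nrow(cv))) for (j in seq_len(ncol(cv))) {
    x <- a[i, j, ]; y <- b[i, j, ]
    if (method == "within_pair") {
      mu <- (x + y) / 2
      if (any(mu == 0)) next
      cv[i, j] <- mean(abs(x - y) / sqrt(2) / mu)  # sample SD of a pair = |x-y|/sqrt(2)
    } else {
      if (mean(x) == 0 || mean(y) == 0) next
      cv[i, j] <- mean(c(stats::sd(x) / mean(x), stats::sd(y) / mean(y)))
    }
  }
  structure(list(cov = cv, summary = cell_summary(cv), method = method),
            class = "reliability_matrix")
}

#' Two-way repeated-measures ANOVA on a 2x2 within-hemisphere design
#'
#' Classical within-subject decomposition for the factors connection type
#' (retinotopic vs non-retinotopic) and coil, both measured in every
#' hemisphere: each effect is tested against its own effect-by-hemisphere
#' interaction, `F = MS_effect / MS_(effect x hemisphere)` with df (1, H-1).
#' Absolute streamline counts (not percentages) should be supplied so the two
#' connection types are not complementary by construction.
#'
#' @param counts numeric array H x 2 x 2: hemispheres x type
#'   (retinotopic, nonretinotopic) x coil. No missing cells are allowed.
#' @return object of class `anova_result`: vectors `F`, `p`, and `df` (a
#'   2-column matrix) for effects `type`, `coil`, `interaction`.
#' @export
rm_anova_2x2 <- function(counts) {
  if (!(is.array(counts) && length(dim(counts)) == 3L && all(dim(counts)[2:3] == 2L)))
    stopf("counts must be an H x 2 x 2 array (hemisphere x type x coil)")
  if (anyNA(counts)) stopf("missing cells are not allowed (no imputation)")
  h <- dim(counts)[1]
  if (h < 3) stopf("need at least three hemispheres")

  grand <- mean(counts)
  m_s <- apply(counts, 1, mean)          # hemisphere means
  m_a <- apply(counts, 2, mean)          # type means
  m_b <- apply(counts, 3, mean)          # coil means
  m_sa <- apply(counts, c(1, 2), mean)
  m_sb <- apply(counts, c(1, 3), mean)
  m_ab <- apply(counts, c(2, 3), mean)

  ss_a <- 2 * h * sum((m_a - grand)^2)
  ss_b <- 2 * h * sum((m_b - grand)^2)
  ss_ab <- h * sum((m_ab - outer(m_a, rep(1, 2)) - outer(rep(1, 2), m_b) + grand)^2)
  ss_as <- 2 * sum((m_sa - outer(m_s, rep(1, 2)) - outer(rep(1, h), m_a) + grand)^2)
  ss_bs <- 2 * sum((m_sb - outer(m_s, rep(1, 2)) - outer(rep(1, h), m_b) + grand)^2)
  fitted_low <- array(NA_real_, dim(counts))
  for (s in 1:h) for (a in 1:2) for (b in 1:2)
    fitted_low[s, a, b] <- m_sa[s, a] + m_sb[s, b] + m_ab[a, b] - m_s[s] - m_a[a] - m_b[b] + grand
  ss_abs <- sum((counts - fitted_low)^2)

  f_of <- function(ss_eff, ss_err) {
    ms_eff <- ss_eff / 1
    ms_err <- ss_err / (h - 1)
    if (ms_eff <= 1e-12 * max(1, grand^2)) return(0)
    if (ms_err <= 1e-12 * max(1, grand^2)) return(Inf)
    ms_eff / ms_err
  }
  f <- c(type = f_of(ss_a, ss_as), coil = f_of(ss_b, ss_bs),
         interaction = f_of(ss_ab, ss_abs))
  p <- ifelse(is.infinite(f), 0, stats::pf(f, 1, h - 1, lower.tail = FALSE))
  names(p) <- names(f)
  df <- cbind(df1 = rep(1, 3), df2 = rep(h - 1, 3))
  rownames(df) <- names(f)
  structure(list(F = f, p = p, df = df), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  for (e in names(x$F))
    cat(sprintf("  %-12s F(%d,%d) = %.3g, p = %.3g\n",
                e, x$df[e, 1], x$df[e, 2], x$F[e], x$p[e]))
  invisible(x)
}

#' Paired t-tests on per-participant motion-parameter SDs
#'
#' Two-tailed paired t per motion parameter (conventionally 6: three
#' translations, three rotations) comparing the spread of motion estimates
#' between two acquisition setups. Zero-variance differences yield the same
#' signed-infinity sentinel as [paired_one_tailed_t()] (with p = 0, or t = 0,
#' p = 1 when the two setups agree exactly).
#'
#' @param sdA,sdB numeric matrices, participants x parameters.
#' @return data.frame with columns `parameter`, `t`, `p`.
#' @export
motion_sd_paired_test <- function(sdA, sdB) {
  sdA <- as.matrix(sdA); sdB <- as.matrix(sdB)
  if (!all(dim(sdA) == dim(sdB))) stopf("participant sets must agree")
  if (nrow(sdA) < 2) stopf("need at least two participants")
  params <- colnames(sdA)
  if (is.null(params)) params <- paste0("param", seq_len(ncol(sdA)))
  res <- lapply(seq_len(ncol(sdA)), function(j) {
    d <- sdA[, j] - sdB[, j]
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) c(t = 0, p = 1) else c(t = sign(mean(d)) * Inf, p = 0)
    } else {
      tt <- stats::t.test(sdA[, j], sdB[, j], paired = TRUE)
      c(t = unname(tt$statistic), p = tt$p.value)
    }
  })
  out <- do.call(rbind, res)
  data.frame(parameter = params, t = out[, "t"], p = out[, "p"], row.names = NULL)
}
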