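# Statistical battery over abundance/expression tables: log(x+1)
# transformation, Welch t tests with significance tiers, exact /
# approximate Mann-Whitney U with BH-FDR, Spearman correlation, rank AUC,
# random-intercept logistic mixed models, depth-offset presence/absence
# GLMs, taxa-function correlation and the temporal-variability statistic.

#' log(x + 1) transformation
#'
#' @param x Nonnegative numeric vector.
#' @return `log(x + 1)`; monotone, maps 0 to 0.
#' @export
log_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stopf("log_transform requires x >= 0")
  log1p(x)
}

#' Significance tier symbols
#'
#' `"*"` for p < 0.05, `"+"` for p < 0.1, `""` otherwise.
#' @param p Numeric p-values.
#' @return Character vector of tier symbols.
#' @export
significance_tier <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.05, "*", ifelse(p < 0.1, "+", "")))
}

#' Welch t test on log-transformed abundances
#'
#' Two-sided unequal-variance t test comparing two arms; by convention
#' p = 1 (flagged) when both arms have zero variance, including the case
#' of identical constant arms.
#'
#' @param values Log-transformed abundances (see [log_transform()]).
#' @param arms Two-level grouping vector (factor or character).
#' @return data.frame with `statistic`, `p`, `direction` (sign of
#'   group-2 mean minus group-1 mean), `tier`, `degenerate` flag.
#' @export
welch_t_test <- function(values, arms) {
  arms <- as.factor(arms)
  if (nlevels(arms) != 2L) stopf("exactly two arms required")
  a <- values[arms == levels(arms)[1L]]
  b <- values[arms == levels(arms)[2L]]
  if (length(a) < 2L || length(b) < 2L) stopf(">= 2 samples per arm required")
  dirn <- sign(mean(b) - mean(a))
  if (sd(a) == 0 && sd(b) == 0) {
    # both arms constant: p = 1 by convention when the constants agree,
    # 0 under exact separation; flagged either way
    p0 <- if (mean(a) == mean(b)) 1 else 0
    return(data.frame(statistic = NA_real_, p = p0, direction = dirn,
                      tier = significance_tier(p0), degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  tt <- t.test(b, a, var.equal = FALSE)
  data.frame(statistic = unname(tt$statistic), p = tt$p.value,
             direction = dirn, tier = significance_tier(tt$p.value),
             degenerate = FALSE, stringsAsFactors = FALSE)
}

# Exact two-sided Mann-Whitney p by enumeration of group assignments
# (handles ties through average ranks); two-sided p doubles the smaller
# tail, capped at 1.
mwu_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- combn(nx + ny, nx)
  us <- apply(idx, 2L, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

#' Mann-Whitney U tests with BH-FDR over a declared family
#'
#' For each group in `family`, compares `values` between the two `arms`.
#' Exact p-values are computed by full enumeration when both arms have
#' at most `exact_max` observations (ties handled via average ranks);
#' otherwise the normal approximation with tie correction is used.
#' Benjamini-Hochberg q-values are computed within the family of all
#' tests in the call.
#'
#' @param values Numeric outcome.
#' @param arms Two-level grouping vector.
#' @param family Family labels (e.g. genus x pathway within a dataset);
#'   one test per label.
#' @param exact_max Largest per-arm n for exact enumeration (default 8).
#' @return data.frame `family`, `statistic` (U of arm 1), `p`, `q`,
#'   `direction`, `tier`.
#' @export
mwu_fdr <- function(values, arms, family = "all", exact_max = 8L) {
  arms <- as.factor(arms)
  if (nlevels(arms) != 2L) stopf("exactly two arms required")
  fam <- as.character(family)
  if (length(fam) == 1L) fam <- rep(fam, length(values))
  res <- lapply(split(seq_along(values), fam), function(i) {
    x <- values[i][arms[i] == levels(arms)[1L]]
    y <- values[i][arms[i] == levels(arms)[2L]]
    if (!length(x) || !length(y))
      return(data.frame(statistic = NA_real_, p = NA_real_,
                        direction = NA_real_, stringsAsFactors = FALSE))
    u <- sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
    p <- if (length(x) <= exact_max && length(y) <= exact_max)
      mwu_exact_p(x, y)
    else suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    data.frame(statistic = u, p = p,
               direction = sign(median(y) - median(x)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- data.frame(family = names(res), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out$tier <- significance_tier(out$p)
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is Pearson correlation of average ranks; the p-value uses the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` with n-2 degrees of
#' freedom (two-sided).  Constant input yields NA.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @return data.frame `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stopf("n >= 4 required for spearman_test")
  if (sd(x) == 0 || sd(y) == 0)
    return(data.frame(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tv <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tv), df = n - 2)
  }
  data.frame(rho = rho, p = p, n = n)
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Probability that a random positive scores above a random negative,
#' ties counted 1/2.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, 0/1, or two-level factor; the
#'   larger level is "positive").
#' @return AUC in \[0,1\].
#' @export
auc <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) != 2L) stopf("both classes required for AUC")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Disease association by random-intercept logistic regression
#'
#' Fits `disease ~ log(abundance + 1) + (1 | dataset)` by
#' Laplace-approximated maximum likelihood (lme4), falling back to plain
#' logistic regression when fewer than two datasets are present (as done
#' for single-dataset diseases).  Reports the fixed effect, the
#' random-intercept variance and the in-sample AUC of the fitted
#' probabilities; non-convergence is flagged, never silently replaced.
#'
#' @param abundance Raw abundance values (log(x+1) applied internally).
#' @param disease Binary outcome (1 = patient).
#' @param dataset Dataset (cohort) labels for the random effect.
#' @return List of class `pathofun_glmm`: `beta` (fixed effect on
#'   log-abundance), `intercept`, `intercept_var` (random-intercept
#'   variance; NA for the glm fallback), `auc`, `converged`, `messages`,
#'   `model`.
#' @export
glmm_disease <- function(abundance, disease, dataset) {
  y <- as.integer(disease > 0)
  x <- log_transform(abundance)
  df <- data.frame(y = y, x = x, dataset = as.factor(dataset))
  msgs <- character()
  if (nlevels(df$dataset) >= 2L) {
    fit <- withCallingHandlers(
      suppressMessages(
        lme4::glmer(y ~ x + (1 | dataset), data = df, family = binomial())),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    beta <- unname(lme4::fixef(fit)["x"])
    icpt <- unname(lme4::fixef(fit)["(Intercept)"])
    vr <- as.data.frame(lme4::VarCorr(fit))$vcov[1L]
    # a singular (zero-variance) random intercept is a boundary fit, not a
    # convergence failure
    bad <- Filter(function(m) !grepl("boundary \\(singular\\)", m),
                  c(msgs, unlist(fit@optinfo$conv$lme4$messages)))
    conv <- length(bad) == 0L
    prob <- fitted(fit)
  } else {
    fit <- glm(y ~ x, data = df, family = binomial())
    beta <- unname(coef(fit)["x"])
    icpt <- unname(coef(fit)["(Intercept)"])
    vr <- NA_real_
    conv <- fit$converged
    prob <- fitted(fit)
  }
  structure(list(beta = beta, intercept = icpt, intercept_var = vr,
                 auc = auc(prob, y), converged = conv, messages = msgs,
                 model = fit),
            class = "pathofun_glmm")
}

#' @export
print.pathofun_glmm <- function(x, ...) {
  cat(sprintf("logistic %s: beta(log-abundance) = %.3f, intercept var = %s, AUC = %.3f%s\n",
              if (is.na(x$intercept_var)) "GLM" else "GLMM",
              x$beta,
              if (is.na(x$intercept_var)) "-" else sprintf("%.3f", x$intercept_var),
              x$auc, if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

# Firth-style bias-reduced logistic regression (Newton iterations with
# hat-value score correction); used when ordinary ML separates.
firth_logistic <- function(X, y, offset = NULL, max_iter = 100L,
                           tol = 1e-8) {
  offset <- offset %||% rep(0, length(y))
  beta <- rep(0, ncol(X))
  # start the intercept where the weights are non-degenerate
  beta[1L] <- qlogis(pmin(pmax(mean(y), 0.05), 0.95)) - mean(offset)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    p <- plogis(eta)
    w <- p * (1 - p)
    W <- sqrt(w)
    XW <- X * W
    XtWX <- crossprod(XW)
    inv <- solve(XtWX)
    h <- rowSums((XW %*% inv) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    delta <- drop(inv %*% U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  list(coef = beta, iterations = it)
}

#' Compare detection between omics levels with a depth offset
#'
#' Binomial GLM of pathway presence/absence on omics level (MTG vs MTX)
#' with log(total reads) as an offset in the linear predictor, adjusting
#' for the lower sequencing depth of metatranscriptomes.  On complete
#' separation the ordinary fit is replaced by a Firth-style penalized
#' fit and flagged.
#'
#' @param presence Logical/0-1 vector: pathway detected in the sample.
#' @param level Factor/character: `"MTG"` or `"MTX"` per sample.
#' @param total_reads Positive per-sample sequencing depth.
#' @return data.frame `level_effect` (log-odds of detection for MTX vs
#'   MTG after depth adjustment), `p`, `favors` (`"MTX"`, `"MTG"` or
#'   `"none"`), `separation`, `degenerate`.
#' @export
glm_mtg_vs_mtx <- function(presence, level, total_reads) {
  y <- as.integer(presence > 0)
  lev <- factor(level, levels = c("MTG", "MTX"))
  if (nlevels(droplevels(lev)) != 2L) stopf("both levels required")
  if (any(total_reads <= 0)) stopf("total_reads must be positive")
  if (length(unique(y)) == 1L)
    return(data.frame(level_effect = NA_real_, p = NA_real_,
                      favors = "none", separation = FALSE,
                      degenerate = TRUE, stringsAsFactors = FALSE))
  off <- log(total_reads)
  fit <- suppressWarnings(glm(y ~ lev + offset(off), family = binomial()))
  pv <- summary(fit)$coefficients
  # complete separation: the level coefficient diverges or fitted
  # probabilities pin at 0/1 (the intercept absorbs the offset scale and
  # is not diagnostic)
  sep <- !fit$converged || abs(coef(fit)["levMTX"]) > 15 ||
    all(fitted(fit) > 1 - 1e-8) || all(fitted(fit) < 1e-8)
  if (sep) {
    X <- cbind(1, as.integer(lev == "MTX"))
    fr <- firth_logistic(X, y, offset = off)
    eff <- fr$coef[2L]
    p <- NA_real_
  } else {
    eff <- unname(coef(fit)["levMTX"])
    p <- pv["levMTX", "Pr(>|z|)"]
  }
  data.frame(level_effect = eff, p = p,
             favors = if (abs(eff) < 1e-8) "none" else
               if (eff > 0) "MTX" else "MTG",
             separation = sep, degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Taxa-function correlation across datasets
#'
#' Per dataset, Spearman correlation between a genus's pathway abundance
#' and the genus's total abundance (HKG share, see
#' [genus_total_abundance()]); q-values by BH within each dataset's
#' correlation family.  Reports, per (pathway, genus), the number of
#' datasets supporting the correlation (p < 0.05, q < 0.05, rho > 0.35)
#' and the mean rho.
#'
#' @param genus_pathway Long data.frame `sample_id`, `pathway`, `genus`,
#'   `abundance` (from [genus_abundance()]).
#' @param genus_total Long data.frame `sample_id`, `genus`,
#'   `abundance_pct` (from [genus_total_abundance()]).
#' @param dataset Named vector mapping sample_id -> dataset.
#' @param rho_threshold,p_threshold,q_threshold Support thresholds
#'   (rho strictly greater; p and q strictly smaller).
#' @return List: `per_dataset` (data.frame dataset, pathway, genus, rho,
#'   p, q, n, supported) and `summary` (pathway, genus, n_supporting,
#'   mean_rho, sd_rho).
#' @export
taxa_function_correlation <- function(genus_pathway, genus_total, dataset,
                                      rho_threshold = 0.35,
                                      p_threshold = 0.05,
                                      q_threshold = 0.05) {
  gp <- genus_pathway
  gp$dataset <- dataset[gp$sample_id]
  key <- paste(genus_total$sample_id, genus_total$genus, sep = "\r")
  tot <- setNames(genus_total$abundance_pct, key)
  gp$total <- tot[paste(gp$sample_id, gp$genus, sep = "\r")]
  gp$total[is.na(gp$total)] <- 0
  rows <- list()
  for (d in unique(gp$dataset)) {
    sub <- gp[gp$dataset == d, , drop = FALSE]
    for (k in split(seq_len(nrow(sub)), paste(sub$pathway, sub$genus,
                                              sep = "\r"))) {
      if (length(k) < 4L) next
      st <- tryCatch(spearman_test(sub$abundance[k], sub$total[k]),
                     error = function(e) NULL)
      if (is.null(st)) next
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = d, pathway = sub$pathway[k[1L]],
        genus = sub$genus[k[1L]], rho = st$rho, p = st$p, n = st$n,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(list(per_dataset = data.frame(), summary = data.frame()))
  per <- do.call(rbind, rows)
  per$q <- ave(per$p, per$dataset, FUN = bh_adjust)
  per$supported <- !is.na(per$rho) & per$rho > rho_threshold &
    !is.na(per$p) & per$p < p_threshold & per$q < q_threshold
  agg <- lapply(split(per, paste(per$pathway, per$genus, sep = "\r")),
                function(s) data.frame(
                  pathway = s$pathway[1L], genus = s$genus[1L],
                  n_supporting = sum(s$supported),
                  mean_rho = mean(s$rho, na.rm = TRUE),
                  sd_rho = sd(s$rho), stringsAsFactors = FALSE))
  list(per_dataset = per,
       summary = do.call(rbind, c(agg, make.row.names = FALSE)))
}

#' Temporal variability between two time points
#'
#' `100 * |v1 - v2| / max(v1, v2)`: 0% means no change, 100% means the
#' value is absent at one time point.  Symmetric and scale-invariant;
#' undefined (NA) when both values are 0.
#'
#' @param v1,v2 Nonnegative values (vectorized).
#' @return Percent change in \[0, 100\] (NA where both are 0).
#' @export
temporal_variability <- function(v1, v2) {
  if (any(c(v1, v2) < 0, na.rm = TRUE)) stopf("values must be >= 0")
  hi <- pmax(v1, v2)
  ifelse(hi == 0, NA_real_, 100 * abs(v1 - v2) / hi)
}
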