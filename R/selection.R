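#' Define a two-group comparison
#'
#' The four clinical contrasts: `C_vs_B`, `C_vs_NB`, `B_vs_NB`, `C_vs_A`,
#' where `A` is the derived union of `B` and `NB` (all ALS patients). The
#' positive class is the (more) affected group. Sexes are always analyzed
#' separately.
#'
#' @param name One of the four comparison names.
#' @param sex `"M"` or `"F"`.
#' @return A list of class `bv_comparison` with `name`, `positive`,
#'   `negative` (each a vector of group labels) and `sex`.
#' @export
comparison <- function(name = c("C_vs_B", "C_vs_NB", "B_vs_NB", "C_vs_A"),
                       sex = c("F", "M")) {
  name <- match.arg(name); sex <- match.arg(sex)
  def <- switch(name,
    C_vs_B  = list(positive = "B",            negative = "C"),
    C_vs_NB = list(positive = "NB",           negative = "C"),
    B_vs_NB = list(positive = "B",            negative = "NB"),
    C_vs_A  = list(positive = c("B", "NB"),   negative = "C"))
  structure(c(list(name = name, sex = sex), def), class = "bv_comparison")
}

#' @export
comparison_names <- function() c("C_vs_B", "C_vs_NB", "B_vs_NB", "C_vs_A")

# Subset a feature table to a comparison's two classes (and sex, if the
# table carries several); returns the feature matrix and a factor with
# levels (negative, positive).
comparison_subset <- function(table, cmp, features) {
  stopifnot(inherits(cmp, "bv_comparison"))
  rows <- table$group %in% c(cmp$positive, cmp$negative)
  if ("sex" %in% names(table) && !all(is.na(table$sex)))
    rows <- rows & table$sex == cmp$sex
  sub <- table[rows, , drop = FALSE]
  y <- factor(ifelse(sub$group %in% cmp$positive, "pos", "neg"),
              levels = c("neg", "pos"))
  X <- as.matrix(sub[, features, drop = FALSE])
  cc <- stats::complete.cases(X)
  if (!all(cc)) {
    warning(sum(!cc), " rows dropped (missing feature values)")
    X <- X[cc, , drop = FALSE]; y <- y[cc]; sub <- sub[cc, , drop = FALSE]
  }
  list(X = X, y = y, meta = sub)
}

# Two-group test per column; equal-variance F (squared t) by default,
# Welch with Satterthwaite df behind var_equal = FALSE. Returns p-values.
per_feature_f <- function(X, y, var_equal = TRUE) {
  i1 <- y == levels(y)[1]; i2 <- !i1
  n1 <- sum(i1); n2 <- sum(i2)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- colMeans(X[i1, , drop = FALSE]); m2 <- colMeans(X[i2, , drop = FALSE])
  ss1 <- colSums(sweep(X[i1, , drop = FALSE], 2, m1)^2)
  ss2 <- colSums(sweep(X[i2, , drop = FALSE], 2, m2)^2)
  if (var_equal) {
    df2 <- n1 + n2 - 2
    s2 <- (ss1 + ss2) / df2
    Fstat <- ifelse(s2 > 0, (m1 - m2)^2 / (s2 * (1 / n1 + 1 / n2)), 0)
    stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  } else {
    v1 <- ss1 / (n1 - 1); v2 <- ss2 / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
    2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
}

#' Significance-based feature screening
#'
#' For one comparison (and sex): a one-way MANOVA omnibus on the feature
#' matrix (Wilks' Lambda with its F approximation, when the within-group
#' covariance is estimable), followed by per-feature equal-variance F tests
#' (the standard univariate follow-ups). Features with p < `alpha` are
#' retained; no multiple-testing correction is applied by default
#' (Benjamini-Hochberg is available behind `adjust = "BH"`).
#'
#' @param table A feature table (data.frame with `group`, optionally `sex`,
#'   plus feature columns).
#' @param cmp A [comparison()].
#' @param alpha Significance threshold (default 0.05).
#' @param features Character vector of feature columns (default: the 50
#'   canonical features present in the table).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param var_equal Equal-variance F tests (default TRUE, the standard
#'   between-subjects follow-up); `FALSE` uses Welch tests.
#' @return A list of class `bv_selection`: `table` (feature, p_value,
#'   selected), `selected` (character vector), `omnibus` (Wilks' Lambda
#'   statistic and p-value, or NA with a warning when p >= n), `comparison`,
#'   `alpha`, `n` (group sizes).
#' @export
screen_features <- function(table, cmp, alpha = 0.05, features = NULL,
                            adjust = c("none", "BH"), var_equal = TRUE) {
  adjust <- match.arg(adjust)
  if (is.null(features))
    features <- intersect(c(phonatory_feature_names(), tf_feature_names()),
                          names(table))
  stopifnot(length(features) >= 1)
  sub <- comparison_subset(table, cmp, features)
  X <- sub$X; y <- sub$y
  if (min(base::table(y)) < 2) stop("need at least 2 observations per group")

  p <- per_feature_f(X, y, var_equal = var_equal)
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")

  omnibus <- list(wilks = NA_real_, p_value = NA_real_)
  if (nrow(X) > length(features) + 2) {
    om <- tryCatch({
      fit <- stats::manova(X ~ y)
      sm <- summary(fit, test = "Wilks")$stats
      list(wilks = sm[1, "Wilks"], p_value = sm[1, "Pr(>F)"])
    }, error = function(e) {
      warning("MANOVA omnibus failed (", conditionMessage(e),
              "); falling back to per-feature tests only")
      NULL
    })
    if (!is.null(om)) omnibus <- om
  } else {
    warning("more features (", length(features), ") than observations allow (",
            nrow(X), "); omnibus skipped, per-feature tests only")
  }

  res <- data.frame(comparison = cmp$name, feature = features,
                    p_value = as.numeric(p),
                    selected = as.numeric(p) < alpha,
                    row.names = NULL)
  structure(list(table = res, selected = features[res$selected],
                 omnibus = omnibus, comparison = cmp, alpha = alpha,
                 n = base::table(y)),
            class = "bv_selection")
}

#' @export
print.bv_selection <- function(x, ...) {
  cat(sprintf("<bv_selection> %s (%s): %d/%d features at p < %g",
              x$comparison$name, x$comparison$sex, length(x$selected),
              nrow(x$table), x$alpha))
  if (!is.na(x$omnibus$p_value))
    cat(sprintf("  [Wilks %.3f, p=%.3g]", x$omnibus$wilks, x$omnibus$p_value))
  cat("\n")
  invisible(x)
}
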