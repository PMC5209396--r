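# Alpha-design count-trait analysis on the square-root scale:
# sqrt(x + 0.375) transform, REML variance components (lme4), GLS
# predicted line means with back-transformation, maximum LSD at 5%,
# Wald test of the line effect, and broad-sense heritability.

#' Variance-stabilizing square-root transform for counts
#'
#' t = sqrt(x + 0.375); the back-transform is max(0, m^2 - 0.375), so
#' back_transform(sqrt_transform(x)) = x for any count x >= 0.
#'
#' @param x non-negative counts.
#' @return transformed values.
#' @export
sqrt_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  sqrt(x + 0.375)
}

#' @rdname sqrt_transform
#' @param m values on the square-root scale.
#' @export
back_transform <- function(m) pmax(0, m^2 - 0.375)

# build the model formula from available strata
pheno_formula <- function(data, line_role, random) {
  terms <- character(0)
  has_rep <- "replicate" %in% random && "replicate" %in% names(data) &&
    length(unique(data$replicate)) > 1
  has_blk <- "block" %in% random && "block" %in% names(data) &&
    length(unique(interaction(data$replicate %||% 1, data$block))) > 1
  if (has_rep) terms <- c(terms, "(1 | replicate)")
  if (has_blk) {
    terms <- c(terms, if (has_rep) "(1 | replicate:block)" else "(1 | block)")
  }
  fixed <- if (line_role == "fixed") ".y ~ 0 + line" else ".y ~ 1 + (1 | line)"
  stats::as.formula(paste(c(fixed, terms), collapse = " + "))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' REML fit of the trial model
#'
#' Model on the transformed scale: t = mu + line + replicate +
#' block(replicate) + e, with replicate and block random.  With
#' `line_role = "fixed"` the fit yields GLS predicted means and the
#' Wald test of the line effect; with `line_role = "random"` it yields
#' the line variance component for heritability.  Strata absent from
#' the data (or with a single level) are dropped; a model with no
#' random terms falls back to least squares.
#'
#' @param trial trial data.frame (needs `line` plus the trait column;
#'   `replicate` and `block` are used when present).
#' @param trait column to analyse ("total", "alate", "apterous", or any
#'   numeric column).
#' @param line_role "fixed" (means, Wald) or "random" (heritability).
#' @param random random strata to include when available.
#' @param transform apply [sqrt_transform()] to the trait (set FALSE
#'   when the response is already on the analysis scale).
#' @return list (`reml_fit`): model (merMod or lm), method, trait,
#'   line_role, transform, vc (named variance components: line,
#'   replicate, block, resid; NA where not in the model), wald (stat,
#'   df, p for the line effect; fixed fits only), n, lines.
#' @export
reml_fit <- function(trial, trait = "total",
                     line_role = c("fixed", "random"),
                     random = c("replicate", "block"),
                     transform = TRUE) {
  line_role <- match.arg(line_role)
  stopifnot(trait %in% names(trial), "line" %in% names(trial))
  data <- as.data.frame(trial)
  data$.y <- if (transform) sqrt_transform(data[[trait]]) else data[[trait]]
  data <- data[!is.na(data$.y), , drop = FALSE]
  data$line <- factor(data$line)
  if ("replicate" %in% names(data)) data$replicate <- factor(data$replicate)
  if ("block" %in% names(data)) data$block <- factor(data$block)

  form <- pheno_formula(data, line_role, random)
  has_ranef <- grepl("\\|", deparse1(form))
  if (has_ranef) {
    model <- lme4::lmer(form, data = data, REML = TRUE,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore",
                          calc.derivs = FALSE))
    method <- "lmer"
    vc_df <- as.data.frame(lme4::VarCorr(model))
    get_vc <- function(g) {
      v <- vc_df$vcov[vc_df$grp == g]
      if (length(v)) v else NA_real_
    }
    vb <- c(get_vc("replicate:block"), get_vc("block"))
    vc <- c(line = get_vc("line"),
            replicate = get_vc("replicate"),
            block = if (all(is.na(vb))) NA_real_ else max(vb, na.rm = TRUE),
            resid = vc_df$vcov[vc_df$grp == "Residual"])
  } else {
    fixed_only <- stats::as.formula(
      if (line_role == "fixed") ".y ~ 0 + line" else ".y ~ 1")
    if (line_role == "random") {
      # no blocking strata: one-way random model still needs lmer
      model <- lme4::lmer(.y ~ 1 + (1 | line), data = data, REML = TRUE,
                          control = lme4::lmerControl(
                            check.conv.singular = "ignore",
                            calc.derivs = FALSE))
      method <- "lmer"
      vc_df <- as.data.frame(lme4::VarCorr(model))
      vc <- c(line = vc_df$vcov[vc_df$grp == "line"],
              replicate = NA_real_, block = NA_real_,
              resid = vc_df$vcov[vc_df$grp == "Residual"])
    } else {
      model <- stats::lm(fixed_only, data = data)
      method <- "lm"
      vc <- c(line = NA_real_, replicate = NA_real_, block = NA_real_,
              resid = summary(model)$sigma^2)
    }
  }

  wald <- NULL
  if (line_role == "fixed") {
    b <- if (method == "lmer") lme4::fixef(model) else stats::coef(model)
    V <- as.matrix(stats::vcov(model))
    keep <- grepl("^line", names(b)) & !is.na(b)
    b <- b[keep]; V <- V[keep, keep, drop = FALSE]
    nl <- length(b)
    if (nl >= 2 && stats::var(b) > 0) {
      L <- cbind(-1, diag(nl - 1))       # differences from the first line
      lb <- as.numeric(L %*% b)
      lv <- L %*% V %*% t(L)
      stat <- as.numeric(crossprod(lb, solve(lv, lb)))
    } else {
      stat <- 0
    }
    wald <- list(stat = stat, df = nl - 1,
                 p = stats::pchisq(stat, nl - 1, lower.tail = FALSE))
  }

  out <- list(model = model, method = method, trait = trait,
              line_role = line_role, transform = transform, vc = vc,
              wald = wald, n = nrow(data), lines = levels(data$line),
              data = data)
  class(out) <- "reml_fit"
  out
}

#' GLS predicted line means with back-transformation
#'
#' On a balanced complete design the predicted means equal the raw line
#' means.  Lines absent from the data return NA with a warning.
#'
#' @param fit a [reml_fit()] with `line_role = "fixed"`.
#' @return data.frame (`means_table`): line, mean_sqrt, se,
#'   mean_count (back-transformed when the fit transformed its
#'   response, otherwise a copy of mean_sqrt).
#' @export
predicted_means <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (fit$line_role != "fixed") {
    stop("predicted means require a fixed-line fit", call. = FALSE)
  }
  b <- if (fit$method == "lmer") lme4::fixef(fit$model) else
    stats::coef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  keep <- grepl("^line", names(b))
  b <- b[keep]
  se <- sqrt(diag(V)[keep])
  lines_fit <- sub("^line", "", names(b))
  out <- data.frame(line = fit$lines,
                    mean_sqrt = b[match(fit$lines, lines_fit)],
                    se = se[match(fit$lines, lines_fit)],
                    row.names = NULL)
  if (any(is.na(out$mean_sqrt))) {
    warning("line(s) without data: ",
            paste(out$line[is.na(out$mean_sqrt)], collapse = ", "),
            call. = FALSE)
  }
  out$mean_count <- if (fit$transform) back_transform(out$mean_sqrt) else
    out$mean_sqrt
  class(out) <- c("means_table", "data.frame")
  out
}

#' Maximum least significant difference
#'
#' LSD = t(1 - alpha/2, resid df) x the maximum standard error of a
#' difference over all line pairs - the conservative yardstick for an
#' unbalanced design.  Residual df are n - p (exact for least squares;
#' a large-sample approximation for the mixed fit).
#'
#' @param fit a fixed-line [reml_fit()].
#' @param alpha significance level (default 0.05).
#' @return list: lsd, max_sed, df, t_crit.
#' @export
max_lsd <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "reml_fit"), fit$line_role == "fixed")
  b <- if (fit$method == "lmer") lme4::fixef(fit$model) else
    stats::coef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  keep <- grepl("^line", names(b))
  V <- V[keep, keep, drop = FALSE]
  d <- diag(V)
  sed2 <- outer(d, d, "+") - 2 * V
  max_sed <- sqrt(max(sed2[upper.tri(sed2)]))
  df <- fit$n - length(b)
  t_crit <- stats::qt(1 - alpha / 2, df)
  list(lsd = t_crit * max_sed, max_sed = max_sed, df = df, t_crit = t_crit)
}

#' Broad-sense heritability from a random-line fit
#'
#' Plot basis (default): h2 = s2_line / (s2_line + s2_rep + s2_block +
#' s2_resid), components absent from the model contributing zero.
#' Line-mean basis: h2 = s2_line / (s2_line + s2_resid / r_bar) with
#' r_bar the mean replication per line.
#'
#' @param fit a [reml_fit()] with `line_role = "random"`.
#' @param basis "plot" or "line_mean".
#' @return h2 in [0, 1]; NA when all components are zero.
#' @export
heritability <- function(fit, basis = c("plot", "line_mean")) {
  basis <- match.arg(basis)
  stopifnot(inherits(fit, "reml_fit"))
  if (fit$line_role != "random") {
    stop("heritability requires a random-line fit", call. = FALSE)
  }
  vc <- fit$vc
  s2l <- vc[["line"]]
  if (basis == "plot") {
    denom <- sum(vc, na.rm = TRUE)
  } else {
    r_bar <- fit$n / length(fit$lines)
    denom <- s2l + vc[["resid"]] / r_bar
  }
  if (!is.finite(denom) || denom == 0) return(NA_real_)
  unname(s2l / denom)
}

#' Analyse one trait of a trial end to end
#'
#' Convenience wrapper: fixed-line fit (means, Wald, max LSD) plus
#' random-line fit (variance components, heritability).
#'
#' @param trial trial data.frame.
#' @param trait trait column.
#' @param alpha LSD significance level.
#' @return list: trait, fit_fixed, fit_random, means, max_lsd, wald,
#'   vc, h2.
#' @export
analyze_trait <- function(trial, trait = "total", alpha = 0.05) {
  ff <- reml_fit(trial, trait, line_role = "fixed")
  fr <- reml_fit(trial, trait, line_role = "random")
  list(trait = trait, fit_fixed = ff, fit_random = fr,
       means = predicted_means(ff), max_lsd = max_lsd(ff, alpha),
       wald = ff$wald, vc = fr$vc, h2 = heritability(fr))
}
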