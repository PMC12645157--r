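#' Covariate-adjusted logistic association of one variable with disease
#'
#' Maximum-likelihood logistic regression of disease status on the immune
#' variable, adjusting for age and sex. The odds ratio is
#' `exp(coefficient)` of the variable, with a Wald 95% CI and p-value.
#' Non-convergence or (quasi-)complete separation flags the record as
#' unusable rather than returning a silently extreme estimate.
#'
#' @param values numeric vector (one standardized immune variable).
#' @param disease outcome; `"AD"`/`"HC"`, logical, or 0/1 with 1 = case.
#' @param age,sex optional covariate vectors (sex coded `"M"`/`"F"`,
#'   reference level F).
#' @param variable name recorded in the output.
#' @return A one-row data.frame (an association record): `variable`,
#'   `model`, `n_used`, `estimate` (OR), `ci_low`, `ci_high`, `p`, `flag`.
#' @export
fit_logistic_association <- function(values, disease, age = NULL, sex = NULL,
                                     variable = "x") {
  y <- .as_case(disease)
  df <- data.frame(y = y, x = values)
  if (!is.null(age)) df$age <- as.numeric(age)
  if (!is.null(sex)) df$sexM <- as.numeric(sex == "M")
  df <- df[complete.cases(df), , drop = FALSE]
  if (sum(df$y == 1) < 10L || sum(df$y == 0) < 10L) {
    stop("need at least 10 subjects in each outcome class")
  }
  rec <- data.frame(variable = variable, model = "logistic_disease",
                    n_used = nrow(df), estimate = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_, flag = "",
                    stringsAsFactors = FALSE)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)$coefficients
  b <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
  if (sep_warn || !fit$converged || se > 10 || abs(b) > 15) {
    rec$flag <- "separation_or_nonconvergence"
    return(rec)
  }
  zq <- qnorm(0.975)
  rec$estimate <- exp(b)
  rec$ci_low <- exp(b - zq * se)
  rec$ci_high <- exp(b + zq * se)
  rec$p <- 2 * pnorm(-abs(b / se))
  rec
}

.as_case <- function(disease) {
  if (is.logical(disease)) return(as.integer(disease))
  if (is.numeric(disease)) return(as.integer(disease != 0))
  as.integer(as.character(disease) == "AD")
}

#' Linear association of one variable with age
#'
#' OLS of the immune variable on z-scored age and sex, optionally within
#' the AD or HC subset; reports the age coefficient with its 95% CI and
#' p-value.
#'
#' @param values numeric vector (one immune variable).
#' @param age ages in years.
#' @param sex `"M"`/`"F"` or `NULL`.
#' @param group group labels, used with `subset`.
#' @param subset `"all"`, `"AD"` or `"HC"`.
#' @param variable name recorded in the output.
#' @return A one-row association record with `model = "linear_age"` and
#'   `estimate` = beta per SD of age.
#' @export
fit_age_association <- function(values, age, sex = NULL, group = NULL,
                                subset = c("all", "AD", "HC"),
                                variable = "x") {
  subset <- match.arg(subset)
  keep <- if (subset == "all") rep(TRUE, length(values)) else group == subset
  df <- data.frame(x = values[keep], age = as.numeric(age[keep]))
  if (!is.null(sex)) df$sexM <- as.numeric(sex[keep] == "M")
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10L) stop("need at least 10 subjects in subset ", subset)
  if (sd(df$age) == 0) stop("age is constant in subset ", subset)
  df$zage <- (df$age - mean(df$age)) / sd(df$age)
  df$age <- NULL
  fit <- lm(x ~ ., data = df)
  sm <- summary(fit)$coefficients
  b <- sm["zage", "Estimate"]; se <- sm["zage", "Std. Error"]
  tq <- qt(0.975, df = fit$df.residual)
  data.frame(variable = variable, model = "linear_age", n_used = nrow(df),
             estimate = b, ci_low = b - tq * se, ci_high = b + tq * se,
             p = sm["zage", "Pr(>|t|)"], flag = "", stringsAsFactors = FALSE)
}

#' Screen every variable of a cohort for disease association
#'
#' Runs [fit_logistic_association()] per variable and appends
#' Benjamini-Hochberg adjusted p-values across the screen.
#'
#' @param table a standardized [cohort_table()].
#' @param meta metadata data.frame aligned with the table's subjects.
#' @return A data.frame of association records plus `p_bh`.
#' @export
associate_disease <- function(table, meta) {
  stopifnot(identical(table$subject_ids, meta$subject_id))
  recs <- lapply(table$variable_names, function(v) {
    fit_logistic_association(table$values[, v], meta$group,
                             age = meta$age, sex = meta$sex, variable = v)
  })
  out <- do.call(rbind, recs)
  out$p_bh <- NA_real_
  ok <- !is.na(out$p)
  out$p_bh[ok] <- p.adjust(out$p[ok], method = "BH")
  out
}

#' Screen every variable for association with age
#'
#' Runs [fit_age_association()] per variable within the chosen subset.
#'
#' @inheritParams associate_disease
#' @param subset `"all"`, `"AD"` or `"HC"`.
#' @return A data.frame of age-association records plus `p_bh`.
#' @export
associate_age <- function(table, meta, subset = "all") {
  stopifnot(identical(table$subject_ids, meta$subject_id))
  recs <- lapply(table$variable_names, function(v) {
    fit_age_association(table$values[, v], meta$age, sex = meta$sex,
                        group = meta$group, subset = subset, variable = v)
  })
  out <- do.call(rbind, recs)
  out$p_bh <- p.adjust(out$p, method = "BH")
  out
}

#' Rank variables by univariate association p-value
#'
#' Ascending by raw p; ties broken by |log OR| (or |beta| for linear
#' models) descending, then by variable name; records flagged unusable are
#' ranked last.
#'
#' @param records a data.frame of association records (one model family).
#' @return Character vector of variable names, best first.
#' @export
rank_by_pvalue <- function(records) {
  if (!nrow(records)) stop("no association records to rank")
  if (length(unique(records$model)) > 1L) {
    stop("records mix model families: ", paste(unique(records$model), collapse = ", "))
  }
  eff <- if (records$model[1] == "logistic_disease") {
    abs(log(records$estimate))
  } else {
    abs(records$estimate)
  }
  flagged <- records$flag != "" | is.na(records$p)
  ord <- order(flagged, records$p, -eff, records$variable)
  records$variable[ord]
}

#' Export association records as a forest-plot table
#'
#' One row per variable per model with CI bounds; no record is dropped
#' (flagged records keep their flag and empty estimates).
#'
#' @param records association records data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_association_tsv <- function(records, path) {
  cols <- c("variable", "model", "n_used", "estimate", "ci_low", "ci_high",
            "p", "p_bh", "flag")
  cols <- intersect(cols, names(records))
  utils::write.table(records[cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
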