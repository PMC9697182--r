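# Statistical stages: age-group assignment, likelihood-ratio tests of fixed
# effects in linear mixed models, permutation comparison of group RDMs to
# the adult RDM, and the RDM-score / completion-score correlation.

#' Assign children to age groups
#'
#' Four groups with boundaries chosen for an approximately equal number of
#' drawings per group in the emulated study: group 1 up to 44 months, group
#' 2 from 45 to 58, group 3 from 59 to 67, group 4 above 67.
#'
#' @param children Tibble with `child_id` and `age_months`.
#' @return The input with an added integer `age_group` column; children with
#'   missing age are dropped with a message.
#' @export
assign_age_groups <- function(children) {
  miss <- is.na(children$age_months)
  if (any(miss)) {
    message(
      sum(miss), " child(ren) without age excluded: ",
      paste(utils::head(children$child_id[miss], 3L), collapse = ", ")
    )
    children <- children[!miss, , drop = FALSE]
  }
  dplyr::mutate(children, age_group = dplyr::case_when(
    .data$age_months <= 44L ~ 1L,
    .data$age_months <= 58L ~ 2L,
    .data$age_months <= 67L ~ 3L,
    TRUE ~ 4L
  ))
}

drop_degenerate_random_terms <- function(data, random_terms) {
  keep <- vapply(random_terms, function(tm) {
    n <- length(unique(data[[tm]]))
    if (n < 2L) {
      warning("random term '", tm, "' has fewer than 2 levels; dropped",
        call. = FALSE
      )
    }
    n >= 2L
  }, logical(1))
  random_terms[keep]
}

#' Likelihood-ratio test of a fixed effect in a mixed model
#'
#' Fits nested linear mixed-effect models by maximum likelihood, with and
#' without `test_term` among the fixed effects, and compares them with a
#' chi-squared likelihood-ratio test: `chi2 = 2 (logLik_full -
#' logLik_reduced)` (clamped at 0), with degrees of freedom equal to the
#' parameter-count difference. ML (not REML) fits are used, as required for
#' comparing models differing in fixed effects. Random terms with fewer
#' than two levels are dropped with a warning; with no usable random term
#' the models degrade to ordinary linear models.
#'
#' @param data A data frame / tibble.
#' @param response Response column name.
#' @param fixed_terms Character vector of fixed-effect terms common to both
#'   models (may be empty).
#' @param test_term The fixed-effect term under test.
#' @param random_terms Character vector of random-intercept grouping
#'   factors.
#' @return A one-row tibble of class `lrt_result`: `term`, `chi2`, `df`,
#'   `p`, `loglik_full`, `loglik_reduced`, `n`.
#' @export
lrt_fixed_effect <- function(data, response, fixed_terms = character(),
                             test_term, random_terms = character()) {
  cols <- c(response, fixed_terms, test_term, random_terms)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    stop("data is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  data <- data[stats::complete.cases(data[, cols]), , drop = FALSE]
  random_terms <- drop_degenerate_random_terms(data, random_terms)
  rhs_reduced <- if (length(fixed_terms) > 0L) {
    paste(fixed_terms, collapse = " + ")
  } else {
    "1"
  }
  rhs_full <- paste(c(fixed_terms, test_term), collapse = " + ")
  fit <- function(rhs) {
    if (length(random_terms) > 0L) {
      f <- stats::as.formula(paste(
        response, "~", rhs, "+",
        paste(sprintf("(1 | %s)", random_terms), collapse = " + ")
      ))
      m <- tryCatch(
        lme4::lmer(f, data = data, REML = FALSE),
        error = function(e) {
          stop(
            structure(
              class = c("lrt_convergence_error", "error", "condition"),
              list(
                message = paste0(
                  "mixed model did not converge for '", deparse(f), "': ",
                  conditionMessage(e)
                ),
                call = NULL
              )
            )
          )
        }
      )
      list(ll = as.numeric(stats::logLik(m)), k = attr(stats::logLik(m), "df"))
    } else {
      m <- stats::lm(stats::as.formula(paste(response, "~", rhs)), data = data)
      list(ll = as.numeric(stats::logLik(m)), k = attr(stats::logLik(m), "df"))
    }
  }
  full <- fit(rhs_full)
  reduced <- fit(rhs_reduced)
  chi2 <- max(0, 2 * (full$ll - reduced$ll))
  if (2 * (full$ll - reduced$ll) < -1e-6) {
    message(
      "nested log-likelihoods out of order (",
      format(2 * (full$ll - reduced$ll), digits = 3),
      "); statistic clamped at 0"
    )
  }
  df <- full$k - reduced$k
  structure(
    tibble::tibble(
      term = test_term, chi2 = chi2, df = as.integer(df),
      p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
      loglik_full = full$ll, loglik_reduced = reduced$ll,
      n = nrow(data)
    ),
    class = c("lrt_result", class(tibble::tibble()))
  )
}

#' @method tidy lrt_result
#' @export
tidy.lrt_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("term", "chi2", "df", "p")]
}

#' @method glance lrt_result
#' @export
glance.lrt_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("loglik_full", "loglik_reduced", "n")]
}

#' Compare a group RDM to the adult RDM by paired permutation
#'
#' The observed statistic is the absolute mean of the paired differences of
#' the off-diagonal entries (upper triangle) of the two RDMs. The null
#' distribution is generated by randomly sign-flipping the paired
#' differences, which respects the dependence structure among RDM entries
#' that would invalidate a naive two-sample test. The two-sided p-value
#' uses the add-one estimator, so `p >= 1 / (1 + n_perm)`.
#'
#' @param group_rdm,adult_rdm `rdm` objects with identical labels in
#'   identical order.
#' @param n_perm Number of sign-flip permutations.
#' @param seed Optional integer seed for reproducible permutations.
#' @return A one-row tibble: `statistic`, `p`, `n_pairs`, `n_perm`.
#' @export
compare_group_to_adult_rdm <- function(group_rdm, adult_rdm, n_perm = 1000L,
                                       seed = NULL) {
  if (!identical(group_rdm$labels, adult_rdm$labels)) {
    stop("RDM labels differ or are ordered differently", call. = FALSE)
  }
  ut <- upper.tri(group_rdm$matrix)
  d <- group_rdm$matrix[ut] - adult_rdm$matrix[ut]
  obs <- abs(mean(d))
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  null <- vapply(seq_len(n_perm), function(i) {
    abs(mean(d * sample(c(-1, 1), length(d), replace = TRUE)))
  }, numeric(1))
  tibble::tibble(
    statistic = obs,
    p = (1 + sum(null >= obs)) / (1 + n_perm),
    n_pairs = length(d),
    n_perm = as.integer(n_perm)
  )
}

#' Correlate per-child RDM scores with completion scores
#'
#' Pearson correlation between the per-child RDM score and the per-child
#' mean completion score, with the two-sided t-based p-value on `n - 2`
#' degrees of freedom.
#'
#' @param per_child Tibble with columns `rdm_score` and `completion` (one
#'   row per child); rows with missing values are dropped.
#' @return A one-row tibble of class `correlation_result`: `r`, `df`, `p`,
#'   `n`.
#' @export
correlate_rdm_completion <- function(per_child) {
  df <- per_child[stats::complete.cases(per_child[, c("rdm_score", "completion")]), ]
  if (nrow(df) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(df$rdm_score) == 0 || stats::sd(df$completion) == 0) {
    stop("constant scores: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(df$rdm_score, df$completion, method = "pearson")
  n_pairs <- nrow(df)
  structure(
    tibble::tibble(
      r = unname(ct$estimate), df = as.integer(unname(ct$parameter)),
      p = ct$p.value, n = n_pairs
    ),
    class = c("correlation_result", class(tibble::tibble()))
  )
}

#' @method tidy correlation_result
#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("r", "df", "p")]
}

#' @method glance correlation_result
#' @export
glance.correlation_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Scatter of RDM score against completion score
#'
#' @param per_child Tibble with `completion`, `rdm_score` and optionally
#'   `dominant_style`.
#' @return A ggplot object.
#' @export
plot_rdm_vs_completion <- function(per_child) {
  aes <- if ("dominant_style" %in% names(per_child)) {
    ggplot2::aes(
      x = .data$completion, y = .data$rdm_score,
      color = .data$dominant_style
    )
  } else {
    ggplot2::aes(x = .data$completion, y = .data$rdm_score)
  }
  ggplot2::ggplot(per_child, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(
      method = "lm", formula = y ~ x, se = FALSE,
      color = "grey40", linewidth = 0.5
    ) +
    ggplot2::labs(
      x = "completion score (crowd rating)", y = "RDM score",
      color = "dominant style"
    ) +
    ggplot2::theme_minimal()
}
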