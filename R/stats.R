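#' The three strain-comparison model specifications
#'
#' Binomial logistic regressions of the strain indicator (`condition`, 0/1
#' within a compared pair) on image features, always adjusting for batch as
#' a categorical fixed effect:
#' \itemize{
#'   \item M1: `condition ~ 1 + hasFilament + batch`, on all classified
#'     cells;
#'   \item M2: `condition ~ 1 + filamentLength + filamentIntensity + batch`,
#'     on Simple cells only (the only cells with both measurements);
#'   \item M3: `condition ~ 1 + spotIntensity + batch`, on Foci cells only.
#' }
#'
#' @param model_id `"M1"`, `"M2"` or `"M3"`.
#' @return Object of class `model_spec`: `model_id`, `formula`,
#'   `terms_of_interest`, `subset` (category filter).
#' @export
model_spec <- function(model_id = c("M1", "M2", "M3")) {
  model_id <- match.arg(model_id)
  spec <- switch(model_id,
    M1 = list(formula = condition ~ 1 + has_filament + batch,
              terms_of_interest = "has_filament",
              subset = cell_categories),
    M2 = list(formula = condition ~ 1 + filament_length_px +
                filament_intensity + batch,
              terms_of_interest = c("filament_length_px",
                                    "filament_intensity"),
              subset = "Simple"),
    M3 = list(formula = condition ~ 1 + spot_intensity + batch,
              terms_of_interest = "spot_intensity",
              subset = "Foci"))
  structure(c(list(model_id = model_id), spec), class = "model_spec")
}

#' Fit one pairwise logistic-regression model
#'
#' Maximum-likelihood logit fit of the binary strain indicator within a
#' pair. Rows with missing predictors are dropped per the model's scope
#' (M2 uses Simple cells, M3 Foci cells). Wald statistics t = estimate/SE
#' are referred by default to a t distribution with residual degrees of
#' freedom; `t_reference = "normal"` uses the standard normal instead. If
#' all retained cells share one batch the batch term is dropped with a
#' note. Complete separation or non-convergence yields a flagged result
#' with missing p, never a silent NaN.
#'
#' @param records A `cell_records` tibble.
#' @param pair Character vector of two strain labels; the second is coded
#'   `condition = 1`.
#' @param spec A [model_spec()] (or a model id string).
#' @param t_reference `"t"` or `"normal"`.
#' @return Object of class `pair_fit` with the underlying `glm` fit (or
#'   `NULL`), the per-term results tibble (via [tidy()]), and fit metadata
#'   (via [glance()]).
#' @export
fit_pair_model <- function(records, pair, spec = model_spec("M1"),
                           t_reference = c("t", "normal")) {
  t_reference <- match.arg(t_reference)
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"), length(pair) == 2)
  if (!all(pair %in% records$strain))
    abort(paste("pair references unknown strain(s):",
                paste(setdiff(pair, records$strain), collapse = ", ")))

  dat <- records[records$strain %in% pair & !is.na(records$category), ]
  dat <- dat[dat$category %in% spec$subset, ]
  vars <- all.vars(spec$formula)
  dat <- dat[complete.cases(dat[, intersect(vars, names(dat))]), ]
  dat$condition <- as.integer(dat$strain == pair[2])

  base <- tibble(strain_a = pair[1], strain_b = pair[2],
                 model_id = spec$model_id, term = spec$terms_of_interest,
                 estimate = NA_real_, se = NA_real_, t = NA_real_,
                 p = NA_real_, flag = NA_character_)
  out <- structure(list(fit = NULL, results = base, pair = pair,
                        spec = spec, n = nrow(dat),
                        t_reference = t_reference, note = NULL),
                   class = "pair_fit")
  if (nrow(dat) < 2 || min(table(dat$condition)) < 2) {
    out$results$flag <- "too_few_cells"
    return(out)
  }
  form <- spec$formula
  if (length(unique(dat$batch)) < 2) {
    form <- stats::update(form, . ~ . - batch)
    out$note <- "single batch: batch term dropped"
    inform(out$note)
  }
  dat$batch <- factor(dat$batch)

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    tryCatch(glm(form, family = binomial(), data = dat),
             error = function(e) NULL),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (is.null(fit)) {
    out$results$flag <- "fit_error"
    return(out)
  }
  out$fit <- fit
  cf <- summary(fit)$coefficients
  df_res <- fit$df.residual
  res <- base
  for (i in seq_len(nrow(res))) {
    tm <- res$term[i]
    if (!tm %in% rownames(cf)) {
      res$flag[i] <- "term_dropped"
      next
    }
    est <- cf[tm, "Estimate"]; se <- cf[tm, "Std. Error"]
    tt <- est / se
    res$estimate[i] <- est; res$se[i] <- se; res$t[i] <- tt
    degenerate <- sep_warn || !fit$converged || abs(est) > 15 || se > 1e3
    if (degenerate) {
      res$flag[i] <- if (sep_warn) "separation" else "non_convergence"
    } else {
      res$p[i] <- if (t_reference == "t")
        2 * pt(-abs(tt), df = df_res) else 2 * pnorm(-abs(tt))
    }
  }
  out$results <- res
  out
}

#' @export
print.pair_fit <- function(x, ...) {
  cat(sprintf("<pair_fit> %s vs %s, model %s, n = %d\n",
              x$pair[1], x$pair[2], x$spec$model_id, x$n))
  print(x$results)
  invisible(x)
}

#' @rdname fit_pair_model
#' @param x A `pair_fit`.
#' @param ... Unused.
#' @method tidy pair_fit
#' @export
tidy.pair_fit <- function(x, ...) x$results

#' @rdname fit_pair_model
#' @method glance pair_fit
#' @export
glance.pair_fit <- function(x, ...) {
  tibble(model_id = x$spec$model_id,
         n = x$n,
         converged = !is.null(x$fit) && x$fit$converged,
         deviance = if (is.null(x$fit)) NA_real_ else x$fit$deviance,
         df_residual = if (is.null(x$fit)) NA_integer_ else x$fit$df.residual,
         note = x$note %||% NA_character_)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `q(i) = min over j >= i of p(j) * m / j` on
#' the sorted p-values; order-preserving and bounded by 1. `NA` entries
#' propagate as `NA` and do not count towards m.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted q-values, same length and order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
fdr_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

#' Run all pairwise comparisons and adjust jointly
#'
#' One row per (pair, model, term of interest): 4 tested coefficients per
#' pair across the three models (hasFilament; filamentLength and
#' filamentIntensity; spotIntensity), so 13 pairs give 52 hypotheses.
#' q-values are computed by Benjamini-Hochberg over all rows jointly;
#' flagged fits keep their rows with missing p and are excluded from the
#' adjustment (count reported as attribute `n_flagged`). Row order is
#' deterministic: pair, then model, then term. Significance stars mark
#' q < 0.05 / 0.01 / 0.001.
#'
#' @param records A `cell_records` tibble.
#' @param pairs List of 2-element character vectors of strain labels.
#' @param models Character vector of model ids.
#' @param t_reference Passed to [fit_pair_model()].
#' @return Tibble of test results with columns `strain_a`, `strain_b`,
#'   `model_id`, `term`, `estimate`, `se`, `t`, `p`, `q`, `stars`, `flag`.
#' @export
compare_all <- function(records, pairs, models = c("M1", "M2", "M3"),
                        t_reference = "t") {
  strains <- unique(records$strain)
  for (pr in pairs) {
    if (length(pr) != 2 || !all(pr %in% strains))
      abort(paste("invalid pair:", paste(pr, collapse = " vs ")))
  }
  rows <- list()
  for (pr in pairs) for (m in models) {
    rows[[length(rows) + 1]] <-
      tidy(fit_pair_model(records, pr, model_spec(m),
                          t_reference = t_reference))
  }
  out <- bind_rows(rows)
  out <- arrange(out, .data$strain_a, .data$strain_b, .data$model_id,
                 .data$term)
  out$q <- fdr_adjust(out$p)
  out$stars <- dplyr::case_when(
    is.na(out$q) ~ "",
    out$q < 0.001 ~ "***",
    out$q < 0.01 ~ "**",
    out$q < 0.05 ~ "*",
    TRUE ~ "")
  n_flagged <- sum(!is.na(out$flag))
  if (n_flagged > 0)
    inform(sprintf("%d flagged test(s) excluded from FDR adjustment",
                   n_flagged))
  attr(out, "n_flagged") <- n_flagged
  out
}

#' Per-strain category proportions
#'
#' The pie-chart summary: fraction of cells in each of the four categories
#' per strain, with the number of cells analysed. Cells with missing
#' category (failed processing) are excluded.
#'
#' @param records A `cell_records` tibble.
#' @return Tibble `strain`, `category`, `n_cells`, `fraction`, `n` (total
#'   classified cells per strain); fractions sum to 1 within each strain.
#' @export
category_proportions <- function(records) {
  x <- records[!is.na(records$category), ]
  if (nrow(x) == 0) abort("no classified cells")
  x$category <- factor(x$category, levels = cell_categories)
  out <- count(group_by(x, .data$strain), .data$category,
               name = "n_cells", .drop = FALSE)
  out <- mutate(out, n = sum(.data$n_cells),
                fraction = .data$n_cells / .data$n)
  ungroup(out)
}
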