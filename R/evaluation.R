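#' Assign peptides to cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment: folds partition the
#' data and fold sizes differ by at most one. The same assignment can (and
#' should) be reused verbatim across methods being compared.
#'
#' @param n Number of records, or a data frame whose rows are assigned.
#' @param k Number of folds (default 5).
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return Integer vector of fold ids in `1..k`, one per record.
#' @export
make_folds <- function(n, k = 5L, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n)
  k <- as.integer(k)
  if (k < 2L || k > n) {
    stop("`k` must be between 2 and the number of records", call. = FALSE)
  }
  o <- with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[o] <- rep_len(seq_len(k), n)
  folds
}

#' Blinded predictions by k-fold cross-validation
#'
#' Each peptide is predicted exactly once, by a model trained on the other
#' `k - 1` folds. The trainer is any function mapping a training tibble to a
#' model accepted by [predict_many()].
#'
#' @param data Affinity tibble (single allele) with columns `sequence`,
#'   `ic50`, `binder`.
#' @param trainer Function `f(train_data) -> model`, e.g. [baseline_trainer()].
#' @param k Number of folds (default 5).
#' @param seed Seed for [make_folds()] (ignored when `folds` is supplied).
#' @param folds Optional precomputed fold assignment, to share data
#'   separations across methods.
#' @return Tibble: the prediction columns of [predict_many()] plus `ic50`,
#'   `binder` and `fold` for audit.
#' @export
cross_validate <- function(data, trainer, k = 5L, seed = 1L, folds = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(folds)) folds <- make_folds(nrow(data), k = k, seed = seed)
  stopifnot(length(folds) == nrow(data))
  out <- vector("list", max(folds))
  for (f in sort(unique(folds))) {
    test <- folds == f
    model <- tryCatch(trainer(data[!test, , drop = FALSE]), error = function(e) {
      stop("training failed on fold ", f, ": ", conditionMessage(e),
           call. = FALSE)
    })
    pred <- predict_many(model, data$sequence[test])
    pred$ic50 <- data$ic50[test]
    pred$binder <- data$binder[test]
    pred$fold <- f
    out[[f]] <- pred
  }
  dplyr::bind_rows(out)
}

orient_scores <- function(scores, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  if (orientation == "lower") -scores else scores
}

#' ROC curve and AUC for binder classification
#'
#' Sweeps the decision threshold from the best to the worst predicted score,
#' plotting the true-positive rate against the false-positive rate. Tied
#' scores are grouped into a single sweep step, which makes the trapezoidal
#' area equal to the Mann-Whitney U statistic with half credit for ties. An
#' AUC of 0.5 is random prediction and 1.0 is perfect prediction.
#'
#' @param scores Numeric predicted scores.
#' @param labels Logical (or 0/1) binder labels; both classes must be present.
#' @param orientation `"lower"` (default) when smaller scores mean stronger
#'   predicted binding (IC50-like), `"higher"` otherwise.
#' @return A `roc_curve` object: `points` (tibble of `fpr`, `tpr` from (0,0)
#'   to (1,1)), `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels, orientation = c("lower", "higher")) {
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: need at least one binder and one non-binder",
         call. = FALSE)
  }
  s <- orient_scores(scores, orientation)   # higher = better after this
  # Mann-Whitney U with average ranks (half credit for ties)
  r <- rank(s)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # threshold sweep, best-to-worst, tied scores grouped
  o <- order(s, decreasing = TRUE)
  grp <- cumsum(!duplicated(s[o]))
  tp <- cumsum(labels[o])
  fp <- cumsum(!labels[o])
  last <- !duplicated(grp, fromLast = TRUE)
  points <- tibble::tibble(fpr = c(0, fp[last] / n_neg),
                           tpr = c(0, tp[last] / n_pos))
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC =", formatC(x$auc, digits = 3, format = "f"),
      sprintf("(%d binders, %d non-binders)\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' @describeIn roc_auc The swept (fpr, tpr) points as a tibble.
#' @param x,object A `roc_curve`.
#' @param ... Unused.
#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @describeIn roc_auc One-row summary with `auc`, `n_pos`, `n_neg`.
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @describeIn roc_auc ROC plot with the chance diagonal.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Spearman rank correlation between predictions and measurements
#'
#' Standard rank correlation with average ranks on ties, sign-aligned so that
#' a better predictor gives a value closer to +1: with IC50-like scores
#' (`orientation = "lower"`) low predicted scores should accompany low
#' measured IC50s.
#'
#' @param scores Predicted scores.
#' @param ic50 Measured IC50 values (nM); lower = stronger binding.
#' @param orientation As in [roc_auc()].
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(scores, ic50, orientation = c("lower", "higher")) {
  keep <- is.finite(scores) & is.finite(ic50)
  scores <- scores[keep]
  ic50 <- ic50[keep]
  if (length(scores) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (length(unique(scores)) == 1L || length(unique(ic50)) == 1L) {
    stop("Spearman rho undefined for a constant vector", call. = FALSE)
  }
  s <- -orient_scores(scores, orientation)  # IC50-like after this
  cor(s, ic50, method = "spearman")
}

#' Evaluate a fixed (training-free) method on a full dataset
#'
#' Methods not trained on peptide binding data (combinatorial-library
#' matrices, externally supplied matrices) are evaluated by predicting the
#' entire dataset once, without cross-validation folds.
#'
#' @param model Model accepted by [predict_many()].
#' @param data Affinity tibble with `sequence`, `ic50`, `binder`.
#' @param method Method label for the report (defaults to the model's label).
#' @param variant Dataset variant tag: `"ALL"`, `"SR"` or `"SP"`.
#' @return One-row tibble: `allele`, `method`, `variant`, `n`, `n_binder`,
#'   `auc`, `rho`.
#' @export
evaluate_fixed_method <- function(model, data, method = NULL,
                                  variant = "ALL") {
  data <- tibble::as_tibble(data)
  pred <- predict_many(model, data$sequence, method = method)
  allele <- if ("allele" %in% names(data)) unique(data$allele) else "unknown"
  tibble::tibble(
    allele = paste(allele, collapse = ","),
    method = pred$method[1],
    variant = variant,
    n = nrow(data),
    n_binder = sum(data$binder),
    auc = roc_auc(pred$score, data$binder, "lower")$auc,
    rho = safe_rho(pred$score, data$ic50)
  )
}

# rho is reported as NA (blank cell) when undefined, e.g. constant scores
safe_rho <- function(scores, ic50) {
  tryCatch(spearman_rho(scores, ic50, "lower"), error = function(e) NA_real_)
}

#' Evaluate a trainable method by cross-validation
#'
#' @inheritParams cross_validate
#' @param method Method label for the report.
#' @param variant Dataset variant tag.
#' @return One-row tibble as in [evaluate_fixed_method()].
#' @export
evaluate_cv_method <- function(data, trainer, k = 5L, seed = 1L,
                               folds = NULL, method = "baseline",
                               variant = "ALL") {
  data <- tibble::as_tibble(data)
  cv <- cross_validate(data, trainer, k = k, seed = seed, folds = folds)
  allele <- if ("allele" %in% names(data)) unique(data$allele) else "unknown"
  tibble::tibble(
    allele = paste(allele, collapse = ","),
    method = method,
    variant = variant,
    n = nrow(data),
    n_binder = sum(data$binder),
    auc = roc_auc(cv$score, cv$binder, "lower")$auc,
    rho = safe_rho(cv$score, cv$ic50)
  )
}

#' Summary rows for an evaluation report
#'
#' Appends the average / min / max rows (3-decimal convention) per method and
#' variant over the per-allele rows of an evaluation report.
#'
#' @param report Tibble of rows from [evaluate_fixed_method()] /
#'   [evaluate_cv_method()].
#' @return Tibble with `allele` set to `"Average"`, `"Min"`, `"Max"`.
#' @export
report_summary <- function(report) {
  dplyr::summarise(
    dplyr::group_by(report, .data$method, .data$variant),
    Average = round(mean(.data$auc), 3),
    Min = round(min(.data$auc), 3),
    Max = round(max(.data$auc), 3),
    .groups = "drop"
  ) |>
    tidyr::pivot_longer(c("Average", "Min", "Max"), names_to = "allele",
                        values_to = "auc") |>
    dplyr::select("allele", "method", "variant", "auc")
}

#' Impact of homologous training peptides on prediction of unrelated peptides
#'
#' For each allele, runs two cross-validations with a shared seed: one on the
#' full (ALL) dataset and one on the similarity-reduced (SR) dataset. For
#' every singular peptide (SP; no similar partner in the ALL set) there are
#' then two blinded predictions: one from training that included homologs and
#' one from training that excluded them. The per-allele AUCs on the SP set
#' are compared, and a paired two-tailed t-test over alleles tests whether
#' including homologs changes performance on unrelated peptides.
#'
#' @param data Affinity tibble, possibly spanning several alleles.
#' @param trainer Trainer function as in [cross_validate()].
#' @param k,seed Cross-validation folds and seed (shared by both runs).
#' @param scope,identity_threshold Passed to [similarity_reduce()].
#' @return An `sp_impact` object; `tidy()` gives the per-allele table
#'   (`auc_sr`, `auc_all`, `auc_reduction` = ALL - SR, `n_reduced`,
#'   `frac_reduced` over ALL -> SR), `glance()` the average row and the
#'   paired t-test p-value.
#' @export
sp_impact_analysis <- function(data, trainer, k = 5L, seed = 1L,
                               scope = "partition", identity_threshold = 0.8) {
  ann <- similarity_reduce(data, scope = scope,
                           identity_threshold = identity_threshold)
  rows <- lapply(split(ann, ann$allele), function(d) {
    sp <- d$sequence[d$in_sp]
    base <- tibble::tibble(allele = d$allele[1], n_all = nrow(d),
                           n_sr = sum(d$in_sr), n_sp = length(sp),
                           auc_sr = NA_real_, auc_all = NA_real_)
    if (length(sp) == 0L || length(unique(d$binder[d$in_sp])) < 2L) {
      warning("allele ", d$allele[1],
              ": SP set empty or single-class; AUCs skipped", call. = FALSE)
      return(base)
    }
    cv_all <- cross_validate(d, trainer, k = k, seed = seed)
    dsr <- d[d$in_sr, , drop = FALSE]
    cv_sr <- cross_validate(dsr, trainer, k = k, seed = seed)
    pa <- cv_all[match(sp, cv_all$sequence), ]
    ps <- cv_sr[match(sp, cv_sr$sequence), ]
    base$auc_all <- roc_auc(pa$score, pa$binder, "lower")$auc
    base$auc_sr <- roc_auc(ps$score, ps$binder, "lower")$auc
    base
  })
  tab <- dplyr::bind_rows(rows)
  tab$auc_reduction <- tab$auc_all - tab$auc_sr
  tab$n_reduced <- tab$n_all - tab$n_sr
  tab$frac_reduced <- 1 - tab$n_sr / tab$n_all
  ok <- !is.na(tab$auc_reduction)
  p <- if (sum(ok) >= 2L && stats::sd(tab$auc_reduction[ok]) > 0) {
    t.test(tab$auc_all[ok], tab$auc_sr[ok], paired = TRUE)$p.value
  } else {
    NA_real_
  }
  structure(list(table = tab, p_value = p, k = k, seed = seed),
            class = "sp_impact")
}

#' @export
print.sp_impact <- function(x, ...) {
  cat("<sp_impact>", nrow(x$table), "allele(s); mean AUC(ALL) - AUC(SR) on SP =",
      formatC(mean(x$table$auc_reduction, na.rm = TRUE), digits = 3,
              format = "f"),
      "; paired t-test p =", formatC(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' @describeIn sp_impact_analysis Per-allele paired AUC table.
#' @param x,... An `sp_impact` object; unused.
#' @export
tidy.sp_impact <- function(x, ...) x$table

#' @describeIn sp_impact_analysis Averages and the paired t-test p-value.
#' @export
glance.sp_impact <- function(x, ...) {
  tibble::tibble(
    n_alleles = nrow(x$table),
    mean_auc_sr = mean(x$table$auc_sr, na.rm = TRUE),
    mean_auc_all = mean(x$table$auc_all, na.rm = TRUE),
    mean_auc_reduction = mean(x$table$auc_reduction, na.rm = TRUE),
    mean_frac_reduced = mean(x$table$frac_reduced),
    p_value = x$p_value
  )
}
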