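#' Genus panels for classification
#'
#' Three presets mirror the case-control biomarker analysis: four
#' case-associated bacterial genera, four fungal genera, and their
#' eight-genus union.
#'
#' @param name `"bacterial4"`, `"fungal4"`, `"combined8"`, or `"custom"`
#' @param genera for `"custom"`: data.frame with columns `genus`, `kingdom`
#' @return object of class `genus_panel`: `name` plus a `genera` data.frame
#' @export
genus_panel <- function(name = c("bacterial4", "fungal4", "combined8",
                                 "custom"), genera = NULL) {
  name <- match.arg(name)
  bact <- data.frame(genus = c("Akkermansia", "Clostridium_sensu_stricto_1",
                               "UBA1819", "Veillonella"),
                     kingdom = "bacteria", stringsAsFactors = FALSE)
  fungi <- data.frame(genus = c("Candida", "Chaetomium", "Neocosmospora",
                                "Occultifur"),
                      kingdom = "fungi", stringsAsFactors = FALSE)
  genera <- switch(name, bacterial4 = bact, fungal4 = fungi,
                   combined8 = rbind(bact, fungi), custom = genera)
  if (is.null(genera) || !all(c("genus", "kingdom") %in% names(genera)))
    stop("custom panels need a data.frame with 'genus' and 'kingdom'")
  if (anyDuplicated(genera$genus))
    stop("duplicate genera in panel")
  structure(list(name = name, genera = genera), class = "genus_panel")
}

## extract the panel's relative-abundance feature matrix from the two tables
panel_features <- function(bact, fungi, panel) {
  tabs <- list(bacteria = relative_abundance(bact),
               fungi = relative_abundance(fungi))
  cols <- lapply(seq_len(nrow(panel$genera)), function(i) {
    g <- panel$genera$genus[i]
    k <- panel$genera$kingdom[i]
    tab <- tabs[[k]]
    if (g %in% taxon_ids(tab)) return(tab$counts[, g])
    if (!is.null(tab$taxonomy)) {  # fall back to genus-rank lookup
      gen <- parse_lineage(tab$taxonomy)[, "genus"]
      hit <- which(gen == g)
      if (length(hit))
        return(rowSums(tab$counts[, hit, drop = FALSE]))
    }
    stop("panel genus '", g, "' (", k, ") not found in the supplied tables")
  })
  m <- do.call(cbind, cols)
  colnames(m) <- panel$genera$genus
  m
}

## ridge-penalized logistic regression by IRLS; lambda = 0 gives plain ML
logistic_fit <- function(X, y, lambda = 0, max_iter = 100, tol = 1e-10) {
  Xd <- cbind(`(Intercept)` = 1, X)
  k <- ncol(Xd)
  beta <- rep(0, k)
  pen <- diag(c(0, rep(lambda, k - 1)), k)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, w * Xd) + pen
    g <- crossprod(Xd, y - mu) - pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(coef = stats::setNames(drop(beta), colnames(Xd)),
       fitted = 1 / (1 + exp(-drop(Xd %*% beta))))
}

#' Rank-formulation ROC AUC
#'
#' AUC = (sum of case ranks - n1(n1+1)/2) / (n1 n0): the Mann-Whitney
#' probability that a random case scores above a random control (ties count
#' half).
#'
#' @param scores numeric predictions
#' @param labels logical or 0/1, TRUE/1 = case
#' @return AUC in [0, 1]
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return data.frame `threshold`, `fpr`, `tpr`
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  do.call(rbind, lapply(thr, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               fpr = sum(pred & !labels) / sum(!labels),
               tpr = sum(pred & labels) / sum(labels))
  }))
}

#' Fit a genus-panel logistic classifier
#'
#' Multivariable logistic regression of case status on the panel genera's
#' relative abundances.  Reports the apparent (resubstitution) AUC — the
#' convention when a single fitted ROC is presented for a small cohort —
#' with a stratified bootstrap percentile CI of the score AUC, and
#' optionally a stratified k-fold cross-validated AUC (the honest estimator;
#' recommended).  Perfect separation triggers a ridge-penalized refit with a
#' warning.
#'
#' @param bact,fungi sample-aligned `abundance_table`s of counts
#' @param meta metadata with `sample_id` and two-level `group`
#' @param panel a [genus_panel()]
#' @param case_group group treated as the positive class (default: first
#'   factor level)
#' @param n_boot bootstrap resamples for the CI (0 disables)
#' @param ci_method `"bootstrap"` (stratified percentile) or `"delong"`
#' @param cv_folds 0 for none, else stratified k-fold CV AUC is added
#' @param transform `"identity"` or `"log10"` (log10(x + 1e-6))
#' @param seed RNG seed for bootstrap/CV
#' @return object of class `panel_classifier_result`: `panel`, `coef`,
#'   `scores`, `labels`, `auc`, `ci`, `scheme`, optionally `cv_auc`
#' @export
fit_panel <- function(bact, fungi, meta, panel, case_group = NULL,
                      n_boot = 2000, ci_method = c("bootstrap", "delong"),
                      cv_folds = 0, transform = c("identity", "log10"),
                      seed = NULL) {
  ci_method <- match.arg(ci_method)
  transform <- match.arg(transform)
  meta <- validate_metadata(meta)
  if (!identical(sample_ids(bact), meta$sample_id) ||
      !identical(sample_ids(fungi), meta$sample_id))
    stop("tables and metadata are not sample-aligned")
  if (is.null(case_group)) case_group <- levels(meta$group)[1]
  y <- as.integer(meta$group == case_group)
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  X <- panel_features(bact, fungi, panel)
  if (transform == "log10") X <- log10(X + 1e-6)
  fit <- logistic_fit(X, y, lambda = 0)
  if (any(abs(fit$coef[-1]) > 1e3) || any(!is.finite(fit$coef)) ||
      all(round(fit$fitted, 8) %in% c(0, 1))) {
    warning("(quasi-)separation detected; refitting with a small L2 penalty")
    fit <- logistic_fit(X, y, lambda = 1e-3)
  }
  scores <- fit$fitted
  auc <- roc_auc(scores, y)
  if (!is.null(seed)) set.seed(seed)
  ci <- c(NA_real_, NA_real_)
  if (ci_method == "delong") {
    ci <- delong_ci(scores, y)
  } else if (n_boot > 0) {
    i1 <- which(y == 1); i0 <- which(y == 0)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      roc_auc(scores[idx], y[idx])
    }, numeric(1))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  }
  ci[1] <- min(ci[1], auc); ci[2] <- max(ci[2], auc)
  res <- list(panel = panel, coef = fit$coef, scores = scores, labels = y,
              sample_id = meta$sample_id, case_group = case_group,
              auc = auc, ci = ci, scheme = "apparent")
  if (cv_folds > 1) {
    folds <- integer(length(y))
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
    cv_scores <- numeric(length(y))
    for (f in seq_len(cv_folds)) {
      train <- folds != f
      ft <- suppressWarnings(logistic_fit(X[train, , drop = FALSE],
                                          y[train], lambda = 1e-3))
      eta <- drop(cbind(1, X[!train, , drop = FALSE]) %*% ft$coef)
      cv_scores[!train] <- 1 / (1 + exp(-eta))
    }
    res$cv_scores <- cv_scores
    res$cv_auc <- roc_auc(cv_scores, y)
    if (n_boot > 0) {  # CI of the cross-validated AUC: the honest pairing
      i1 <- which(y == 1); i0 <- which(y == 0)
      boots <- vapply(seq_len(n_boot), function(b) {
        idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
        roc_auc(cv_scores[idx], y[idx])
      }, numeric(1))
      res$cv_ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
      res$cv_ci[1] <- min(res$cv_ci[1], res$cv_auc)
      res$cv_ci[2] <- max(res$cv_ci[2], res$cv_auc)
    }
  }
  structure(res, class = "panel_classifier_result")
}

## DeLong variance-based 95% CI for a single AUC
delong_ci <- function(scores, y) {
  xs <- scores[y == 1]; ys <- scores[y == 0]
  m <- length(xs); n <- length(ys)
  v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), numeric(1))
  v01 <- vapply(ys, function(yv) mean((xs > yv) + 0.5 * (xs == yv)),
                numeric(1))
  auc <- mean(v10)
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  pmin(pmax(auc + c(-1, 1) * 1.96 * se, 0), 1)
}

#' @export
print.panel_classifier_result <- function(x, ...) {
  cat(sprintf("<panel_classifier> %s: AUC %.3f (95%% CI %.3f-%.3f, %s)\n",
              x$panel$name, x$auc, x$ci[1], x$ci[2], x$scheme))
  if (!is.null(x$cv_auc)) cat(sprintf("  cross-validated AUC %.3f\n",
                                      x$cv_auc))
  invisible(x)
}

#' Compare classifier panels
#'
#' Tabulates AUC and CI per fitted panel (all must share the same samples)
#' and flags whether the combined panel reaches at least the best
#' single-kingdom panel.
#'
#' @param ... named `panel_classifier_result`s (e.g. bacterial4, fungal4,
#'   combined8)
#' @return data.frame `panel`, `auc`, `ci_low`, `ci_high`, `cv_auc`, with
#'   attribute `combined_best` when a combined8 panel is supplied
#' @export
compare_panels <- function(...) {
  results <- list(...)
  if (length(results) == 1 && is.list(results[[1]]) &&
      !inherits(results[[1]], "panel_classifier_result"))
    results <- results[[1]]
  ids <- lapply(results, `[[`, "sample_id")
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]])))
    stop("panels were fitted on different sample sets")
  out <- do.call(rbind, lapply(results, function(r)
    data.frame(panel = r$panel$name, auc = r$auc, ci_low = r$ci[1],
               ci_high = r$ci[2],
               cv_auc = if (is.null(r$cv_auc)) NA_real_ else r$cv_auc,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  comb <- out$auc[out$panel == "combined8"]
  single <- out$auc[out$panel %in% c("bacterial4", "fungal4")]
  if (length(comb) && length(single))
    attr(out, "combined_best") <- comb[1] >= max(single)
  out
}
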