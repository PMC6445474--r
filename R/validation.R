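#' Class-stratified haul-level train/test split
#'
#' The haul is the resampling unit; stratification balances the presence
#' and absence classes so each keeps the target train fraction to within
#' one haul.
#'
#' @param haul_ids Haul identifiers.
#' @param presence Logical presence flag per haul.
#' @param ratio Train fraction, default 0.7.
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors.
#' @export
stratified_split <- function(haul_ids, presence, ratio = 0.7, seed) {
  stopifnot(length(haul_ids) == length(presence))
  if (length(haul_ids) < 10) stop("need at least 10 hauls to split")
  if (min(table(presence)) < 2)
    stop("each presence class needs at least 2 hauls")
  withr::with_seed(as.integer(seed), {
    classes <- sort(unique(presence))
    n_c <- vapply(classes, function(cl) sum(presence == cl), numeric(1))
    target <- ratio * n_c
    n_train_c <- floor(target)
    remainder <- round(ratio * length(haul_ids)) - sum(n_train_c)
    if (remainder > 0) {
      extra <- order(target - n_train_c, decreasing = TRUE)[seq_len(remainder)]
      n_train_c[extra] <- n_train_c[extra] + 1
    }
    n_train_c <- pmin(pmax(n_train_c, 1), n_c - 1)
    train <- character(0)
    for (i in seq_along(classes)) {
      ids <- haul_ids[presence == classes[i]]
      train <- c(train, sample(ids, n_train_c[i]))
    }
    list(train = sort(train), test = sort(setdiff(haul_ids, train)))
  })
}

#' Area under the ROC curve by the rank formula
#'
#' `AUC = P(score+ > score-) + 0.5 P(tie)`, computed from mid-ranks.
#'
#' @param labels Logical or 0/1 class labels.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`; error when only one class is present.
#' @export
auc_roc <- function(labels, scores) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("AUC undefined with a single class")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spearman rank correlation with mid-rank ties
#'
#' Pearson correlation of mid-ranks; errors when either vector has zero
#' rank variance.
#'
#' @param predicted,observed Numeric vectors (n >= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 3)
  if (var(rank(predicted)) == 0 || var(rank(observed)) == 0)
    stop("Spearman correlation undefined: zero rank variance")
  cor(predicted, observed, method = "spearman")
}

#' Repeated stratified cross-validation of a hurdle model structure
#'
#' Per iteration: stratified 7:3 haul split, refit of both components on
#' the training hauls, and scoring on the test hauls — AUC of the presence
#' component, Spearman correlation of the count component on positive test
#' hauls, and Spearman correlation of the combined prediction against
#' observed CPUE including zeros. Failed refits are logged and excluded;
#' more than 20% failures aborts.
#'
#' @param data Covariate tibble keyed by `haul_id`.
#' @param cpue Stage CPUE per row of `data`.
#' @param presence_terms,count_terms Model structure.
#' @param iterations Number of splits (the reference design uses 100).
#' @param seed Integer seed; iteration `i` uses `seed + i`.
#' @param control An [hgam_control()].
#' @param refit_sp Re-select smoothing parameters each iteration
#'   (default); `FALSE` freezes them at full-data values.
#' @param stage Label carried through.
#' @return A `cv_result`: list with `per_iteration` and `summary` tibbles.
#' @export
cross_validate <- function(data, cpue, presence_terms, count_terms,
                           iterations = 100, seed = 1,
                           control = hgam_control(), refit_sp = TRUE,
                           stage = NA_character_) {
  stopifnot(nrow(data) == length(cpue))
  presence <- cpue > 0
  sp_p <- sp_c <- NULL
  if (!refit_sp) {
    full <- fit_hurdle(data, cpue, presence_terms, count_terms,
                       stage = stage, control = control)
    sp_p <- full$presence$sp
    sp_c <- full$count$sp
  }
  rows <- list()
  failures <- 0L
  for (i in seq_len(iterations)) {
    res <- tryCatch({
      sp <- stratified_split(data$haul_id, presence, 0.7, seed = seed + i)
      tr <- data$haul_id %in% sp$train
      te <- !tr
      fit <- fit_hurdle(data[tr, , drop = FALSE], cpue[tr],
                        presence_terms, count_terms, stage = stage,
                        control = control,
                        sp_presence = sp_p, sp_count = sp_c)
      p_hat <- predict(fit$presence, data[te, , drop = FALSE],
                       type = "response", population = FALSE)
      lam <- exp(predict(fit$count, data[te, , drop = FALSE],
                         type = "link", population = FALSE))
      auc <- auc_roc(presence[te], p_hat)
      pos_te <- te & presence
      rho_count <- if (sum(pos_te) >= 3) {
        mu <- predict(fit$count, data[pos_te, , drop = FALSE],
                      type = "response", population = FALSE)
        tryCatch(spearman_rho(mu, cpue[pos_te]), error = function(e) NA_real_)
      } else NA_real_
      comb <- combined_cpue(p_hat, lam)
      rho_comb <- tryCatch(spearman_rho(comb, cpue[te]),
                           error = function(e) NA_real_)
      tibble::tibble(iteration = i, auc = auc, rho_count = rho_count,
                     rho_combined = rho_comb)
    }, error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L else
      rows[[length(rows) + 1]] <- res
  }
  if (failures > 0.2 * iterations)
    stop("cross-validation failed in ", failures, " of ", iterations,
         " iterations")
  per <- dplyr::bind_rows(rows)
  summ <- tidyr::pivot_longer(per, -"iteration", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     n_iterations = sum(!is.na(.data$value)),
                     .groups = "drop") |>
    dplyr::mutate(stage = stage) |>
    dplyr::relocate("stage")
  out <- list(stage = stage, per_iteration = per, summary = summ,
              failures = failures)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s> %d iterations (%d failed)\n", x$stage,
              nrow(x$per_iteration) + x$failures, x$failures))
  print(x$summary)
  invisible(x)
}

#' Plot cross-validation metric distributions
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_iteration, -"iteration",
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "held-out metric",
                  title = paste("Cross-validation:", object$stage)) +
    ggplot2::theme_minimal()
}
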