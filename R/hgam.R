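#' Control parameters for the penalized GAM engine
#'
#' Basis sizes default to 10 for one-dimensional cubic regression splines,
#' 5 per margin for tensor products and 8 for the cyclic aspect spline —
#' small enough for survey-scale data while leaving room for effective
#' degrees of freedom above 10 on wiggly terms.
#'
#' @param k_s,k_te,k_cc Basis sizes (1-d spline, tensor margin, cyclic).
#' @param maxit Maximum IRLS iterations.
#' @param sp_maxit Maximum smoothing-criterion evaluations.
#' @param gcv_gamma Inflation factor on effective degrees of freedom in the
#'   GCV denominator; values around 1.4 are the standard guard against the
#'   criterion's tendency to undersmooth at survey sample sizes.
#' @return A list of class `hgam_control`.
#' @export
hgam_control <- function(k_s = 10L, k_te = 5L, k_cc = 8L, maxit = 60L,
                         sp_maxit = 300L, gcv_gamma = 1.4) {
  structure(list(k_s = as.integer(k_s), k_te = as.integer(k_te),
                 k_cc = as.integer(k_cc), maxit = as.integer(maxit),
                 sp_maxit = as.integer(sp_maxit), gcv_gamma = gcv_gamma),
            class = "hgam_control")
}

# ---- families -------------------------------------------------------------

hgam_family <- function(name) {
  switch(
    name,
    binomial = list(
      name = "binomial",
      eta_clamp = c(-30, 30),
      mu = function(eta) plogis(eta),
      weight = function(eta, mu) pmax(mu * (1 - mu), 1e-10),
      ll = function(y, eta) {
        mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
        sum(y * log(mu) + (1 - y) * log(1 - mu))
      },
      sat_ll = function(y) 0,
      init_eta = function(y) qlogis((y + 0.5) / 2)
    ),
    ztp = list(
      name = "ztp",
      eta_clamp = c(-15, 15),
      mu = function(eta) {
        lam <- exp(eta)
        lam / (-expm1(-lam))
      },
      weight = function(eta, mu) {
        lam <- exp(eta)
        pmax(mu * (1 + lam - mu), 1e-10)
      },
      ll = function(y, eta) {
        lam <- exp(eta)
        sum(y * eta - lam - lfactorial(y) - log(-expm1(-lam)))
      },
      sat_ll = function(y) sum(ztp_sat_ll(y)),
      init_eta = function(y) log(pmax(y - 0.7, 0.3))
    ),
    stop("unknown family: ", name))
}

# Per-observation saturated log-likelihood of the zero-truncated Poisson:
# the supremum over lambda of the ZTP log pmf at y. For y = 1 the supremum
# (0) is attained in the limit lambda -> 0; otherwise at the lambda with
# truncated mean y, bracketed by [y - 1, y].
ztp_sat_ll <- function(y) {
  uy <- sort(unique(y))
  sat <- vapply(uy, function(k) {
    if (k == 1) return(0)
    mu_fun <- function(lam) lam / (-expm1(-lam))
    lam <- uniroot(function(l) mu_fun(l) - k, c(k - 1, k),
                   tol = 1e-10)$root
    k * log(lam) - lam - lfactorial(k) - log(-expm1(-lam))
  }, numeric(1))
  sat[match(y, uy)]
}

#' Zero-truncated Poisson log-likelihood
#'
#' `sum(y * log(lambda) - lambda - log(y!) - log(1 - exp(-lambda)))` for
#' strictly positive integer counts; zeros belong to the presence component
#' of the hurdle and are rejected.
#'
#' @param y Integer counts >= 1.
#' @param lambda Untruncated Poisson rates > 0 (recycled).
#' @return Scalar log-likelihood.
#' @export
ztp_loglik <- function(y, lambda) {
  if (any(y < 1)) stop("zero counts belong to the presence component")
  if (any(y != round(y))) stop("counts must be integers")
  if (any(lambda <= 0)) stop("lambda must be positive")
  lambda <- rep_len(lambda, length(y))
  sum(y * log(lambda) - lambda - lfactorial(y) - log(-expm1(-lambda)))
}

# ---- design construction --------------------------------------------------

parse_hgam_term <- function(label) {
  label <- gsub(" ", "", label)
  if (grepl("^re\\([^,)]+\\)$", label)) {
    list(label = label, type = "re", vars = sub("^re\\(([^)]+)\\)$", "\\1",
                                                label))
  } else if (grepl("^te\\([^,)]+,[^,)]+\\)$", label)) {
    v <- strsplit(sub("^te\\(([^)]+)\\)$", "\\1", label), ",")[[1]]
    list(label = label, type = "te", vars = v)
  } else if (grepl("^s\\([^,)]+\\)$", label)) {
    v <- sub("^s\\(([^)]+)\\)$", "\\1", label)
    list(label = label, type = if (v == "aspect") "cc" else "s", vars = v)
  } else if (grepl("^[A-Za-z._][A-Za-z0-9._]*$", label)) {
    list(label = label, type = "par", vars = label)
  } else stop("cannot parse model term: ", label)
}

build_hgam_design <- function(data, term_labels, control) {
  n <- nrow(data)
  X <- matrix(1, n, 1)
  colnames(X) <- "(Intercept)"
  penalties <- list() # each: list(S, cols, term)
  terms <- list()
  for (label in term_labels) {
    spec <- parse_hgam_term(label)
    for (v in spec$vars)
      if (!v %in% names(data)) stop("covariate not in data: ", v)
    block <- NULL
    if (spec$type == "par") {
      x <- data[[spec$vars]]
      if (is.character(x) || is.factor(x) || is.logical(x)) {
        f <- factor(x)
        if (nlevels(f) < 2) stop("factor term ", label, " has < 2 levels")
        block <- model.matrix(~f)[, -1, drop = FALSE]
        colnames(block) <- paste0(label, levels(f)[-1])
        spec$levels <- levels(f)
      } else {
        block <- matrix(x, ncol = 1, dimnames = list(NULL, label))
      }
    } else if (spec$type == "re") {
      f <- factor(data[[spec$vars]])
      spec$levels <- levels(f)
      df2 <- data.frame(x = f)
      names(df2) <- spec$vars
      sm <- mgcv::smoothCon(eval(str2lang(
        sprintf("mgcv::s(%s, bs = 're')", spec$vars))),
        data = df2, absorb.cons = FALSE)[[1]]
      spec$smooth <- sm
      block <- sm$X
      colnames(block) <- paste0(label, ".", seq_len(ncol(block)))
      for (S in sm$S)
        penalties[[length(penalties) + 1]] <-
          list(S = S, term = label,
               cols = ncol(X) + seq_len(ncol(block)))
    } else {
      sm_call <- switch(
        spec$type,
        s = sprintf("mgcv::s(%s, bs = 'cr', k = %d)", spec$vars,
                    control$k_s),
        cc = sprintf("mgcv::s(%s, bs = 'cc', k = %d)", spec$vars,
                     control$k_cc),
        te = sprintf("mgcv::te(%s, %s, bs = 'cr', k = c(%d, %d))",
                     spec$vars[1], spec$vars[2], control$k_te,
                     control$k_te))
      knots <- if (spec$type == "cc")
        setNames(list(seq(0, 360, length.out = control$k_cc)), spec$vars)
      sm <- mgcv::smoothCon(eval(str2lang(sm_call)), data = data,
                            knots = knots, absorb.cons = TRUE)[[1]]
      spec$smooth <- sm
      block <- sm$X
      colnames(block) <- paste0(label, ".", seq_len(ncol(block)))
      for (S in sm$S)
        penalties[[length(penalties) + 1]] <-
          list(S = S, term = label,
               cols = ncol(X) + seq_len(ncol(block)))
    }
    spec$cols <- ncol(X) + seq_len(ncol(block))
    X <- cbind(X, block)
    terms[[label]] <- spec
  }
  list(X = X, penalties = penalties, terms = terms)
}

predict_block <- function(spec, newdata, population = TRUE) {
  n <- nrow(newdata)
  if (spec$type == "par") {
    if (!is.null(spec$levels)) {
      x <- as.character(newdata[[spec$vars]])
      bad <- setdiff(unique(x), spec$levels)
      if (length(bad))
        stop("unseen level(s) for ", spec$label, ": ",
             paste(bad, collapse = ", "))
      f <- factor(x, levels = spec$levels)
      model.matrix(~f)[, -1, drop = FALSE]
    } else matrix(newdata[[spec$vars]], ncol = 1)
  } else if (spec$type == "re") {
    if (population) {
      matrix(0, n, length(spec$levels))
    } else {
      x <- as.character(newdata[[spec$vars]])
      bad <- setdiff(unique(x), spec$levels)
      if (length(bad))
        stop("unseen level(s) for ", spec$label, ": ",
             paste(bad, collapse = ", "))
      nd <- data.frame(x = factor(x, levels = spec$levels))
      names(nd) <- spec$vars
      mgcv::PredictMat(spec$smooth, nd)
    }
  } else {
    mgcv::PredictMat(spec$smooth, as.data.frame(newdata))
  }
}

# ---- penalized IRLS -------------------------------------------------------

penalty_matrix <- function(penalties, rho, p) {
  rho <- pmin(pmax(rho, -25), 25)
  A <- matrix(0, p, p)
  for (j in seq_along(penalties)) {
    pen <- penalties[[j]]
    A[pen$cols, pen$cols] <- A[pen$cols, pen$cols] + exp(rho[j]) * pen$S
  }
  A
}

# solve with escalating ridge regularisation; H is PSD by construction but
# can be numerically rank-deficient at extreme smoothing parameters
safe_solve <- function(H, b = NULL) {
  scale <- max(diag(H), 1e-300)
  for (ridge in c(0, 1e-10, 1e-7, 1e-4, 1e-2)) {
    Hr <- if (ridge == 0) H else H + diag(ridge * scale, nrow(H))
    out <- tryCatch(
      if (is.null(b)) solve(Hr) else solve(Hr, b),
      error = function(e) NULL)
    if (!is.null(out) && all(is.finite(out))) return(out)
  }
  stop("linear system unsolvable even with ridge regularisation")
}

pirls <- function(X, y, fam, penalties, rho, control, beta_init = NULL) {
  n <- nrow(X); p <- ncol(X)
  A <- penalty_matrix(penalties, rho, p)
  eta <- if (!is.null(beta_init)) as.vector(X %*% beta_init)
  else fam$init_eta(y)
  eta <- pmin(pmax(eta, fam$eta_clamp[1]), fam$eta_clamp[2])
  dev_old <- Inf
  beta <- beta_init %||% rep(0, p)
  H <- XtWX <- NULL
  for (it in seq_len(control$maxit)) {
    mu <- fam$mu(eta)
    w <- fam$weight(eta, mu)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    XtWX <- XtW %*% X
    H <- XtWX + A
    beta_new <- safe_solve(H, XtW %*% z)
    # step halving towards the previous coefficients if the penalized
    # deviance worsens
    step <- 1
    repeat {
      b_try <- step * beta_new + (1 - step) * beta
      eta_try <- pmin(pmax(as.vector(X %*% b_try), fam$eta_clamp[1]),
                      fam$eta_clamp[2])
      pdev_try <- -2 * fam$ll(y, eta_try) +
        as.numeric(t(b_try) %*% A %*% b_try)
      if (is.finite(pdev_try) && (pdev_try <= dev_old + 1e-8 ||
                                  step < 1e-3)) break
      step <- step / 2
    }
    beta <- as.vector(b_try)
    eta <- eta_try
    if (abs(dev_old - pdev_try) < 1e-9 * (abs(pdev_try) + 0.1)) {
      dev_old <- pdev_try
      break
    }
    dev_old <- pdev_try
  }
  mu <- fam$mu(eta)
  w <- fam$weight(eta, mu)
  XtWX <- t(X * w) %*% X
  H <- XtWX + A
  Finv <- safe_solve(H)
  Fmat <- Finv %*% XtWX
  ll <- fam$ll(y, eta)
  dev <- 2 * (fam$sat_ll(y) - ll)
  edf_by_col <- diag(Fmat)
  edf <- sum(edf_by_col)
  list(beta = beta, eta = eta, mu = mu, ll = ll, dev = dev,
       edf = edf, edf_by_col = edf_by_col, Vb = Finv,
       gcv = n * dev / (n - min(control$gcv_gamma * edf, n - 0.5))^2, iterations = it)
}

# Performance iteration for smoothing-parameter selection: at each IRLS
# step the working penalized least-squares problem is handed to
# mgcv::magic(), which optimises the GCV score over all smoothing
# parameters jointly. Returns log smoothing parameters.
pirls_select_sp <- function(X, y, fam, penalties, control) {
  S_small <- lapply(penalties, `[[`, "S")
  off <- vapply(penalties, function(p) p$cols[1], numeric(1))
  sp_cur <- rep(-1, length(penalties)) # negative: let magic autoinitialise
  eta <- pmin(pmax(fam$init_eta(y), fam$eta_clamp[1]), fam$eta_clamp[2])
  dev_old <- Inf
  for (it in seq_len(control$maxit)) {
    mu <- fam$mu(eta)
    w <- fam$weight(eta, mu)
    z <- eta + (y - mu) / w
    mg <- mgcv::magic(z, X, sp = sp_cur, S = S_small, off = off,
                      w = sqrt(w), gamma = control$gcv_gamma)
    sp_cur <- mg$sp
    eta <- pmin(pmax(as.vector(X %*% mg$b), fam$eta_clamp[1]),
                fam$eta_clamp[2])
    dev <- -2 * fam$ll(y, eta)
    if (is.finite(dev) && abs(dev_old - dev) < 1e-7 * (abs(dev) + 0.1))
      break
    dev_old <- dev
  }
  log(pmax(sp_cur, 1e-10))
}

# ---- user-facing fitting --------------------------------------------------

#' Fit a penalized GAM component of the hurdle model
#'
#' Penalized-likelihood fit of a binomial (logit) or zero-truncated Poisson
#' (log) additive model. Terms are given as labels: `"s(x)"` penalized
#' cubic regression spline (cyclic for aspect), `"te(x,y)"` tensor-product
#' interaction, `"re(g)"` ridge-penalized random intercept, and bare names
#' for parametric factor or linear terms. Smoothing parameters are chosen
#' by minimising a GCV criterion `n * deviance / (n - edf)^2` (recorded in
#' the fit) unless supplied.
#'
#' @param data Covariate tibble.
#' @param y Response: 0/1 for `family = "binomial"`, integer counts >= 1
#'   for `family = "ztp"`.
#' @param terms Character vector of term labels.
#' @param family `"binomial"` or `"ztp"`.
#' @param control An [hgam_control()].
#' @param sp Optional fixed smoothing parameters (one per penalty).
#' @return An `hgam` object.
#' @export
fit_hgam <- function(data, y, terms, family = c("binomial", "ztp"),
                     control = hgam_control(), sp = NULL) {
  family <- match.arg(family)
  fam <- hgam_family(family)
  data <- tibble::as_tibble(data)
  if (family == "binomial") {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("binomial response must be 0/1")
    if (length(unique(y)) < 2)
      stop("both presence classes must be present")
  } else {
    if (any(y < 1)) stop("zero counts belong to the presence component")
    y <- as.numeric(round(y))
  }
  if (nrow(data) != length(y)) stop("data and response lengths differ")
  des <- build_hgam_design(data, terms, control)
  m <- length(des$penalties)
  if (!is.null(sp)) {
    if (length(sp) != m) stop("need ", m, " smoothing parameters")
    rho <- log(sp)
    fit <- pirls(des$X, y, fam, des$penalties, rho, control)
  } else if (m == 0) {
    rho <- numeric(0)
    fit <- pirls(des$X, y, fam, des$penalties, rho, control)
  } else {
    rho <- pirls_select_sp(des$X, y, fam, des$penalties, control)
    fit <- pirls(des$X, y, fam, des$penalties, rho, control)
  }
  edf_by_term <- vapply(des$terms, function(spec)
    sum(fit$edf_by_col[spec$cols]), numeric(1))
  out <- list(
    terms = terms, design = des, family = family,
    beta = setNames(fit$beta, colnames(des$X)),
    sp = exp(rho), rho = rho,
    edf = fit$edf, edf_by_term = edf_by_term,
    ll = fit$ll, deviance = fit$dev,
    aic = -2 * fit$ll + 2 * fit$edf,
    gcv = fit$gcv, Vb = fit$Vb,
    fitted = fit$mu, y = y, n = length(y),
    data = data[, intersect(names(data),
                            unique(unlist(lapply(des$terms, `[[`, "vars")))),
                drop = FALSE],
    control = control,
    smoothing_criterion = "GCV: n * deviance / (n - edf)^2",
    iterations = fit$iterations)
  class(out) <- "hgam"
  out
}

#' @export
print.hgam <- function(x, ...) {
  cat(sprintf("<hgam %s> n = %d, edf = %.2f, deviance = %.3f, AIC = %.2f\n",
              x$family, x$n, x$edf, x$deviance, x$aic))
  cat("  terms:", paste(x$terms, collapse = " + "), "\n")
  invisible(x)
}

#' @export
tidy.hgam <- function(x, ...) {
  tibble::tibble(term = names(x$edf_by_term),
                 edf = unname(x$edf_by_term),
                 sp = vapply(names(x$edf_by_term), function(tm) {
                   i <- which(vapply(x$design$penalties, function(p)
                     p$term == tm, logical(1)))
                   if (length(i)) x$sp[i[1]] else NA_real_
                 }, numeric(1)))
}

#' @export
glance.hgam <- function(x, ...) {
  tibble::tibble(family = x$family, n = x$n, edf = x$edf,
                 log_lik = x$ll, deviance = x$deviance, aic = x$aic,
                 gcv = x$gcv)
}

#' Predict from a fitted hurdle component
#'
#' @param object An `hgam`.
#' @param newdata Covariate tibble.
#' @param type `"link"` or `"response"`.
#' @param population Zero the random intercept (gear) columns? Set `FALSE`
#'   for per-gear predictions.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.hgam <- function(object, newdata, type = c("link", "response"),
                         population = TRUE, ...) {
  type <- match.arg(type)
  newdata <- tibble::as_tibble(newdata)
  n <- nrow(newdata)
  X <- matrix(1, n, 1)
  for (spec in object$design$terms)
    X <- cbind(X, predict_block(spec, newdata, population = population))
  eta <- as.vector(X %*% object$beta)
  if (type == "link") eta else hgam_family(object$family)$mu(eta)
}

#' Gear (random-intercept) contrast and its standard error
#'
#' With two gear levels the random-intercept variance is weakly identified,
#' so the quantity reported is the contrast between the two level effects,
#' with a standard error from the penalized fit's posterior covariance.
#'
#' @param object An `hgam` containing a `re(...)` term.
#' @return Tibble with `contrast` and `se`.
#' @export
re_contrast <- function(object) {
  re <- purrr::detect(object$design$terms, function(s) s$type == "re")
  if (is.null(re)) stop("model has no random-intercept term")
  cols <- re$cols[1:2]
  cvec <- rep(0, length(object$beta))
  cvec[cols] <- c(1, -1)
  tibble::tibble(
    contrast = unname(object$beta[cols[1]] - object$beta[cols[2]]),
    se = sqrt(as.numeric(t(cvec) %*% object$Vb %*% cvec)))
}

#' @rdname fit_hgam
#' @param presence Logical/0-1 presence flags.
#' @export
fit_presence_gam <- function(data, presence, terms,
                             control = hgam_control(), sp = NULL) {
  fit_hgam(data, as.numeric(presence), terms, family = "binomial",
           control = control, sp = sp)
}

#' @rdname fit_hgam
#' @param counts Integer counts >= 1 (positive hauls only).
#' @export
fit_ztp_gam <- function(data, counts, terms, control = hgam_control(),
                        sp = NULL) {
  fit_hgam(data, counts, terms, family = "ztp", control = control, sp = sp)
}

#' Single-term-deletion deviance importance
#'
#' Refits the component without each term in turn, holding the remaining
#' terms' smoothing parameters at their selected values, and reports the
#' deviance increase, the term's effective degrees of freedom, a chi-square
#' statistic (the deviance increase) and its p-value.
#'
#' @param object An `hgam`.
#' @return Tibble with `term`, `delta_deviance`, `edf`, `chi_sq`,
#'   `p_value`.
#' @export
delta_deviance <- function(object) {
  purrr::map_dfr(object$terms, function(tm) {
    keep <- setdiff(object$terms, tm)
    pen_terms <- vapply(object$design$penalties, `[[`, character(1), "term")
    sp_keep <- object$sp[pen_terms %in% keep]
    refit <- fit_hgam(object$data, object$y, keep, family = object$family,
                      control = object$control,
                      sp = if (length(sp_keep)) sp_keep else NULL)
    dd <- refit$deviance - object$deviance
    edf <- unname(object$edf_by_term[tm])
    tibble::tibble(term = tm, delta_deviance = dd, edf = edf,
                   chi_sq = max(dd, 0),
                   p_value = pchisq(max(dd, 0), df = max(edf, 1e-6),
                                    lower.tail = FALSE))
  })
}

#' Bidirectional stepwise selection by AIC
#'
#' From the full candidate model, evaluates every single-term drop and
#' every single-term re-addition, takes the move with the lowest AIC
#' (`-2 log-likelihood + 2 edf`; ties favour fewer terms), and stops at a
#' local minimum. Fitter failures during a move skip that move and are
#' logged in the returned path.
#'
#' @param data Covariate tibble.
#' @param y Response vector.
#' @param candidate_terms Full candidate term labels.
#' @param family `"binomial"` or `"ztp"`.
#' @param control An [hgam_control()].
#' @return List with `terms` (selected labels), `fit` (the selected
#'   `hgam`), and `path` (move log tibble).
#' @export
stepwise_aic <- function(data, y, candidate_terms,
                         family = c("binomial", "ztp"),
                         control = hgam_control()) {
  family <- match.arg(family)
  safe_fit <- function(terms) {
    tryCatch(fit_hgam(data, y, terms, family = family, control = control),
             error = function(e) NULL)
  }
  current <- candidate_terms
  fit <- safe_fit(current)
  if (is.null(fit)) stop("fitter failed on the full candidate model")
  path <- list(tibble::tibble(move = "start",
                              terms = paste(current, collapse = "+"),
                              aic = fit$aic))
  repeat {
    moves <- c(lapply(current, function(tm)
      list(action = paste("drop", tm), terms = setdiff(current, tm))),
      lapply(setdiff(candidate_terms, current), function(tm)
        list(action = paste("add", tm), terms = c(current, tm))))
    if (!length(moves)) break
    fits <- lapply(moves, function(mv)
      if (length(mv$terms)) safe_fit(mv$terms) else NULL)
    aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic,
                   numeric(1))
    if (!any(is.finite(aics))) break
    best_aic <- min(aics)
    if (best_aic >= fit$aic - 1e-6) break
    near <- which(aics <= best_aic + 1e-6)
    sizes <- vapply(moves[near], function(mv) length(mv$terms), numeric(1))
    pick <- near[which.min(sizes)]
    current <- moves[[pick]]$terms
    fit <- fits[[pick]]
    path[[length(path) + 1]] <- tibble::tibble(
      move = moves[[pick]]$action, terms = paste(current, collapse = "+"),
      aic = fit$aic)
  }
  list(terms = current, fit = fit, path = dplyr::bind_rows(path))
}
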